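# shared ground-truth parameter sets and small builders used across tests

oocyte_params <- function() {
  recovery_params("two_population", f = 0.15, s = 0.85,
                  tf_half = 8, ts_half = 300)
}

embryo_params <- function() {
  recovery_params("single_plus_immobile", f = 0.85, tf_half = 15)
}

# a spindle_image wrapping arbitrary matrices, poles on the horizontal
# midline one margin in from each side
image_from_matrix <- function(mat, pixel_size = 0.1, margin_px = 10,
                              name = "tubulin") {
  cy <- nrow(mat) / 2 + 0.5
  channels <- list(mat)
  names(channels) <- name
  spindle_image(channels, pixel_size = pixel_size,
                poles = rbind(c(margin_px, cy),
                              c(ncol(mat) - margin_px, cy)))
}

# dense synthetic profile from an intensity function of position in [0, 1]
profile_from_function <- function(fn, n = 2000, length_um = 15) {
  u <- seq(0, 1, length.out = n)
  tibble::tibble(position_um = u * length_um, intensity = fn(u))
}
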