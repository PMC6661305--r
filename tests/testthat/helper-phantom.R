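# small, fast phantom protocol used throughout the suite: 128x128 matrix
# at 0.1 cm/pixel keeps one Poisson draw under 10 ms while leaving room
# for the largest cohort glands
small_spec <- function(...) {
  phantom_spec(matrix_size = 128, pixel_spacing = 0.1, ...)
}

# a tiny blank image to rasterize polygons onto
blank_image <- function(n = 64, spacing = 1) {
  planar_image(matrix(0L, n, n), pixel_spacing = spacing,
               acquisition_duration = 60)
}
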