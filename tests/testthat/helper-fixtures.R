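# Shared fixtures built in code.

# A wedge whose footprints fit on a small 64 x 64 canvas (unit tests only).
small_wedge <- function() {
  wedge_spec(footprints = data.frame(
    step = 1:10, x0 = 5L, x1 = 60L,
    y0 = 2L + 6L * (0:9), y1 = 7L + 6L * (0:9)
  ))
}

# Wrap a plain HU matrix as a radiograph (default 50 kV; 1.2 mAs, no wedge).
as_rad <- function(px, exposure = exposure_setting(50, 1.2), wedge = NULL,
                   limb_mask = NULL) {
  radiograph(px, pixel_spacing = 0.2, exposure = exposure, wedge = wedge,
             limb_mask = limb_mask, source_id = "fixture")
}

# A hand-built calibration table (for tests that need exact ranges).
make_table <- function(mins, maxs, exposure = exposure_setting(50, 1.2),
                       source_id = "fixture") {
  structure(data.frame(step = seq_along(mins), min_hu = mins, max_hu = maxs),
            class = c("calibration_table", "data.frame"),
            exposure = exposure, source_id = source_id)
}

# Ten adjacent disjoint ranges covering [lo, hi).
disjoint_table <- function(lo = 0, hi = 1000, ...) {
  edges <- seq(lo, hi, length.out = 11)
  make_table(head(edges, 10), head(edges, 10) + diff(edges) * 0.999, ...)
}

# Random RGB raster drawn from a set of hex colors.
random_color_image <- function(h, w, colors) {
  rgb <- t(vapply(colors, function(cl) {
    strtoi(c(substr(cl, 2, 3), substr(cl, 4, 5), substr(cl, 6, 7)), 16L)
  }, integer(3)))
  pick <- sample.int(length(colors), h * w, replace = TRUE)
  array(c(rgb[pick, 1], rgb[pick, 2], rgb[pick, 3]), dim = c(h, w, 3))
}

# Cohort analysis is expensive; compute once per test session and share
# between the pipeline and acceptance test files.
.cda_cache <- new.env(parent = emptyenv())

cohort_analysis <- function() {
  if (is.null(.cda_cache$analysis)) {
    cohort <- generate_cohort(seed = 20240905)
    .cda_cache$analysis <- analyze_cohort(cohort)
  }
  .cda_cache$analysis
}
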