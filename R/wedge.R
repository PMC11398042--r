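#' Aluminum step-wedge density standard
#'
#' Describes the stepped aluminum block imaged beside the joint: ten steps
#' S1--S10 of strictly increasing thickness (S1 thinnest, so S1 attenuates
#' least), their rectangular footprints in image coordinates, and the block's
#' bulk properties. The default step heights are free parameters of the
#' synthetic phantom, chosen so the rendered 50 kV; 1.2 mAs wedge spans
#' roughly 880--2800 HU; they are not a physical standard's dimensions.
#'
#' @param n_steps Number of steps; the density standard has 10.
#' @param step_heights Thickness of each step in mm, strictly increasing from
#'   S1 to S10.
#' @param footprints Data frame with columns `step`, `x0`, `x1`, `y0`, `y1`
#'   giving each step's inclusive pixel rectangle (x = column, y = row).
#' @param material Wedge material name (must exist in the phantom model).
#' @param density Bulk density in g/cm^3 (aluminum standard: 2.65).
#' @param mass Block mass in g (aluminum standard: 9.39).
#' @return An object of class `wedge_spec`.
#' @export
wedge_spec <- function(n_steps = 10,
                       step_heights = seq(6.6853, 12.1276, length.out = 10),
                       footprints = default_wedge_footprints(),
                       material = "aluminum", density = 2.65, mass = 9.39) {
  if (n_steps != 10) stop("the density standard has exactly 10 steps")
  if (length(step_heights) != n_steps) {
    stop("'step_heights' must have one entry per step")
  }
  if (any(step_heights <= 0)) stop("step heights must be positive thicknesses")
  if (is.unsorted(step_heights, strictly = TRUE)) {
    stop("step heights must strictly increase from S1 (thinnest) to S10")
  }
  stopifnot(is.data.frame(footprints),
            all(c("step", "x0", "x1", "y0", "y1") %in% names(footprints)))
  if (!setequal(footprints$step, seq_len(n_steps))) {
    stop("footprints must cover steps 1..", n_steps, " exactly once")
  }
  if (.footprints_overlap(footprints)) stop("wedge step footprints overlap")
  structure(
    list(n_steps = n_steps, step_heights = step_heights,
         footprints = footprints[order(footprints$step), , drop = FALSE],
         material = material, density = density, mass = mass),
    class = "wedge_spec"
  )
}

.footprints_overlap <- function(fp) {
  n <- nrow(fp)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (fp$x0[i] <= fp$x1[j] && fp$x1[i] >= fp$x0[j] &&
          fp$y0[i] <= fp$y1[j] && fp$y1[i] >= fp$y0[j]) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Default wedge footprints on the 512 x 512 canvas
#'
#' Ten 70 x 40 pixel rectangles stacked vertically along the left edge of the
#' default scene, S1 on top.
#'
#' @return A data frame with columns `step`, `x0`, `x1`, `y0`, `y1`.
#' @export
default_wedge_footprints <- function() {
  data.frame(
    step = 1:10,
    x0 = 31L, x1 = 100L,
    y0 = 56L + 40L * (0:9),
    y1 = 95L + 40L * (0:9)
  )
}

#' @export
print.wedge_spec <- function(x, ...) {
  cat("<wedge_spec>", x$n_steps, "steps,", x$material, "\n")
  cat(sprintf("  heights: %.2f .. %.2f mm (S1 thinnest)\n",
              min(x$step_heights), max(x$step_heights)))
  invisible(x)
}

#' Noise-free wedge step values (generator ground truth)
#'
#' The HU-like value each wedge step takes on a noise-free render, i.e. the
#' model's HU map applied to mu_material(kV) * step height. Used as the
#' oracle for calibration recovery.
#'
#' @param wedge A [wedge_spec()].
#' @param exposure An [exposure_setting()].
#' @param model A [phantom_model()].
#' @return Named numeric vector (`S1` .. `S10`) of step HU values.
#' @export
wedge_step_hu <- function(wedge, exposure, model = phantom_model()) {
  mu <- effective_mu(wedge$material, exposure$kv, model)
  hu <- hu_from_attenuation(mu * wedge$step_heights, exposure, model)
  names(hu) <- paste0("S", seq_along(hu))
  hu
}
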