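#' Knee-like tissue phantom specification
#'
#' An idealized mediolateral feline knee: a soft-tissue envelope (the limb)
#' containing three bone bodies (femur, tibia, patella). Each component is an
#' ellipse in image coordinates with a projected-thickness profile
#' `t(x, y) = t_max * (1 - m)^q`, where `m` is the squared normalized ellipse
#' radius. The bone exponent `q = 2` concentrates area at small thickness, so
#' the pixel count per attenuation band falls off toward thick (dense) bone
#' -- the anatomy behind the decreasing percent-color trend from low to high
#' wedge steps. The envelope (`q = 0.5`) approximates a cylindrical
#' soft-tissue cross-section of roughly 10--40 HU at 50 kV.
#'
#' @param bone_scale Multiplier on bone thickness (per-subject variation).
#' @param size_scale Multiplier on ellipse radii (per-subject variation).
#' @return A list of component lists (fields `material`, `x0`, `y0`, `rx`,
#'   `ry`, `t_max`, `q`, `limb`), suitable for [render_radiograph()].
#' @export
knee_tissue_spec <- function(bone_scale = 1, size_scale = 1) {
  stopifnot(bone_scale > 0, size_scale > 0)
  comp <- function(material, x0, y0, rx, ry, t_max, q, limb = FALSE) {
    list(material = material, x0 = x0, y0 = y0,
         rx = rx * size_scale, ry = ry * size_scale,
         t_max = t_max * if (material == "bone") bone_scale else 1,
         q = q, limb = limb)
  }
  list(
    comp("soft_tissue", 320, 256, 150, 210, 50.0, 0.5, limb = TRUE),
    comp("bone",        310, 140,  40,  90, 16.5, 2),
    comp("bone",        335, 370,  40,  95, 16.5, 2),
    comp("bone",        240, 160,  18,  30,  9.0, 2)
  )
}

#' Construct a radiograph object
#'
#' A radiograph is a 2-D grid of Hounsfield-like values with pixel spacing,
#' exposure metadata, the wedge layout it was (or is assumed to be) acquired
#' with, and an optional ground-truth limb mask.
#'
#' @param pixels Numeric matrix of HU-like values, at least 64 x 64, finite.
#' @param pixel_spacing Pixel size in mm/pixel.
#' @param exposure An [exposure_setting()].
#' @param wedge A [wedge_spec()] describing the co-imaged density standard.
#' @param limb_mask Optional logical matrix (same shape) marking the limb.
#' @param source_id Identifier string for provenance.
#' @return An object of class `radiograph`.
#' @export
radiograph <- function(pixels, pixel_spacing = 0.2, exposure, wedge,
                       limb_mask = NULL, source_id = "radiograph") {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (nrow(pixels) < 64 || ncol(pixels) < 64) {
    stop("radiograph must be at least 64 x 64 pixels")
  }
  if (!all(is.finite(pixels))) stop("radiograph pixels must be finite")
  if (!is.null(limb_mask)) {
    stopifnot(is.logical(limb_mask), all(dim(limb_mask) == dim(pixels)))
  }
  structure(
    list(pixels = pixels, pixel_spacing = pixel_spacing, exposure = exposure,
         wedge = wedge, limb_mask = limb_mask, source_id = source_id),
    class = "radiograph"
  )
}

#' @export
print.radiograph <- function(x, ...) {
  cat("<radiograph>", x$source_id, "-", format(x$exposure), "\n")
  cat(sprintf("  %d x %d px @ %.3g mm/px, HU range [%.1f, %.1f]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Render a synthetic radiograph
#'
#' Beer-Lambert style projection: every pixel accumulates optical depth
#' `sum(mu(material, kV) * thickness)` over the wedge step it falls on and
#' the tissue components covering it; the model's affine HU map (anchored at
#' air = -1000 HU) converts optical depth to Hounsfield-like values, and
#' Gaussian noise with sd proportional to `1/sqrt(mAs)` is added. The render
#' is a pure function of its specifications and `seed`.
#'
#' @param wedge A [wedge_spec()].
#' @param tissue A tissue specification as from [knee_tissue_spec()], or
#'   `NULL` for a wedge-only scene.
#' @param exposure An [exposure_setting()].
#' @param model A [phantom_model()].
#' @param seed Integer seed for the noise field.
#' @param size Image size `c(rows, cols)`.
#' @param pixel_spacing Pixel size in mm/pixel.
#' @param noise If `FALSE`, return the noise-free render.
#' @param source_id Identifier stored on the radiograph.
#' @return A [radiograph()] whose `limb_mask` is the union of the tissue
#'   components flagged `limb`.
#' @export
render_radiograph <- function(wedge, tissue = knee_tissue_spec(), exposure,
                              model = phantom_model(), seed = 1,
                              size = c(512, 512), pixel_spacing = 0.2,
                              noise = TRUE, source_id = "synthetic") {
  h <- size[1]; w <- size[2]
  a <- matrix(0, h, w)
  limb <- matrix(FALSE, h, w)

  if (!is.null(wedge)) {
    fp <- wedge$footprints
    if (.footprints_overlap(fp)) stop("wedge step footprints overlap")
    if (any(fp$x0 < 1 | fp$y0 < 1 | fp$x1 > w | fp$y1 > h)) {
      stop("wedge footprints extend outside the image bounds")
    }
    mu_w <- effective_mu(wedge$material, exposure$kv, model)
    for (i in seq_len(nrow(fp))) {
      a[fp$y0[i]:fp$y1[i], fp$x0[i]:fp$x1[i]] <-
        a[fp$y0[i]:fp$y1[i], fp$x0[i]:fp$x1[i]] +
        mu_w * wedge$step_heights[fp$step[i]]
    }
  }

  for (comp in tissue %||% list()) {
    if (comp$t_max <= 0) stop("tissue component thickness must be positive")
    mu_c <- effective_mu(comp$material, exposure$kv, model)
    rows <- max(1, floor(comp$y0 - comp$ry)):min(h, ceiling(comp$y0 + comp$ry))
    cols <- max(1, floor(comp$x0 - comp$rx)):min(w, ceiling(comp$x0 + comp$rx))
    m <- outer(((rows - comp$y0) / comp$ry)^2, ((cols - comp$x0) / comp$rx)^2, `+`)
    inside <- m <= 1
    t_c <- comp$t_max * pmax(0, 1 - m)^comp$q
    a[rows, cols] <- a[rows, cols] + mu_c * t_c
    if (isTRUE(comp$limb)) limb[rows, cols] <- limb[rows, cols] | inside
  }

  hu <- hu_from_attenuation(a, exposure, model)
  if (noise) {
    sd_hu <- noise_sd_at(exposure, model)
    hu <- hu + with_seed(seed, matrix(stats::rnorm(h * w, 0, sd_hu), h, w))
  }
  rad <- radiograph(hu, pixel_spacing, exposure, wedge,
                    limb_mask = if (any(limb)) limb else NULL,
                    source_id = source_id)
  attr(rad, "seed") <- seed
  attr(rad, "noise") <- noise
  rad
}

# One step of 8-connected binary dilation.
.dilate3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-h, ]
  out[-h, ] <- out[-h, ] | m[-1, ]
  out[, -1] <- out[, -1] | out[, -w]
  out[, -w] <- out[, -w] | out[, -1]
  out
}

#' Inject hair-like background clutter
#'
#' Paints thin filamentous strokes in the background near the limb (never
#' inside the limb mask, never over the wedge) whose HU values are drawn from
#' the calibrated low-step ranges of this radiograph's exposure, emulating
#' long hair whose gray values coincide with the lowest density-standard
#' steps. The total clutter pixel budget is a severity-dependent fraction of
#' the radiograph's white-reference (bone-annotation) pixel count, increasing
#' mild < moderate < severe, and placement is deterministic per `seed`.
#'
#' @param rad A [radiograph()] with a `limb_mask`.
#' @param severity One of `"mild"`, `"moderate"`, `"severe"`.
#' @param seed Integer seed.
#' @param steps Wedge steps targeted by the clutter; defaults to S1 for mild,
#'   S1--S2 for moderate, S1--S3 for severe.
#' @param fractions Per-severity clutter budgets as fractions of the
#'   white-reference count, one value per targeted step.
#' @param reach How far (pixels) from the limb outline clutter may appear.
#' @return The radiograph with clutter pixels painted; the per-step pixel
#'   indices are stored in `attr(, "clutter_pixels")`.
#' @export
add_background_clutter <- function(rad, severity = c("mild", "moderate", "severe"),
                                   seed = 1,
                                   steps = NULL,
                                   fractions = list(mild = 0.02,
                                                    moderate = c(0.12, 0.04),
                                                    severe = c(0.30, 0.12, 0.03)),
                                   reach = 28) {
  severity <- match.arg(severity)
  if (is.null(rad$limb_mask)) {
    stop("clutter requires a radiograph with a limb mask")
  }
  frac <- fractions[[severity]]
  if (is.null(steps)) steps <- seq_along(frac)
  frac <- frac[seq_along(steps)]

  table <- build_calibration_table(rad)
  white_native <- sum(rad$limb_mask & .in_any_range(rad$pixels, table))

  h <- nrow(rad$pixels); w <- ncol(rad$pixels)
  band <- rad$limb_mask
  for (i in seq_len(reach)) band <- .dilate3(band)
  fp <- rad$wedge$footprints
  wedge_zone <- matrix(FALSE, h, w)
  wedge_zone[max(1, min(fp$y0) - 10):min(h, max(fp$y1) + 10),
             max(1, min(fp$x0) - 10):min(w, max(fp$x1) + 10)] <- TRUE
  available <- band & !rad$limb_mask & !wedge_zone
  available[c(1, h), ] <- FALSE
  available[, c(1, w)] <- FALSE

  pixels <- rad$pixels
  clutter_idx <- attr(rad, "clutter_pixels") %||% list()
  with_seed(seed, {
    for (si in seq_along(steps)) {
      s <- steps[si]
      target <- round(frac[si] * white_native)
      if (target < 1) next
      # hair sits at the dark (low-attenuation) end of the step's range
      lo <- table$min_hu[table$step == s]
      hi <- lo + 0.60 * (table$max_hu[table$step == s] - lo)
      margin <- 0.05 * (hi - lo)
      placed <- integer(0)
      open <- which(available)
      iter <- 0
      while (length(placed) < target && length(open) > 0 && iter < 5000) {
        iter <- iter + 1
        start <- open[sample.int(length(open), 1)]
        r0 <- ((start - 1) %% h) + 1
        c0 <- ((start - 1) %/% h) + 1
        len <- sample(20:60, 1)
        theta <- stats::runif(1, 0, 2 * pi) +
          cumsum(stats::rnorm(len, 0, 0.25))
        rr <- round(r0 + cumsum(sin(theta)))
        cc <- round(c0 + cumsum(cos(theta)))
        ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
        idx <- unique((cc[ok] - 1) * h + rr[ok])
        idx <- idx[available[idx]]
        if (!length(idx)) next
        placed <- c(placed, idx)
        available[idx] <- FALSE
        open <- setdiff(open, idx)
      }
      placed <- placed[seq_len(min(length(placed), target))]
      pixels[placed] <- stats::runif(length(placed), lo + margin, hi - margin)
      clutter_idx[[paste0("S", s)]] <-
        c(clutter_idx[[paste0("S", s)]], placed)
    }
  })
  rad$pixels <- pixels
  attr(rad, "clutter_pixels") <- clutter_idx
  rad
}
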