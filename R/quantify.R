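#' Convert sRGB HEX colors to CIELAB
#'
#' Standard sRGB (D65 white point, 2 degree observer) to CIE L*a*b*:
#' inverse-gamma linearization, the sRGB-to-XYZ matrix, then the Lab cube
#' root transfer.
#'
#' @param hex Character vector of `#RRGGBB` codes.
#' @return n x 3 numeric matrix with columns `L`, `a`, `b`.
#' @export
srgb_to_lab <- function(hex) {
  rgb <- .parse_hex(hex) / 255
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041),
              nrow = 3, byrow = TRUE)
  xyz <- lin %*% t(m)
  white <- c(0.95047, 1.00000, 1.08883)   # D65
  t_ <- sweep(xyz, 2, white, "/")
  eps <- (6 / 29)^3
  f <- ifelse(t_ > eps, t_^(1 / 3), t_ / (3 * (6 / 29)^2) + 4 / 29)
  lab <- cbind(L = 116 * f[, 2] - 16,
               a = 500 * (f[, 1] - f[, 2]),
               b = 200 * (f[, 2] - f[, 3]))
  rownames(lab) <- hex
  lab
}

#' CIE76 color difference
#'
#' Euclidean distance in CIELAB:
#' `deltaE = sqrt((L1-L2)^2 + (a1-a2)^2 + (b1-b2)^2)`. Symmetric, zero iff
#' the Lab coordinates coincide; black to white is 100 (L* 0 vs 100).
#'
#' @param c1,c2 HEX color codes (vectorized, recycled).
#' @return Numeric vector of delta-E values.
#' @export
cie76_delta_e <- function(c1, c2) {
  lab1 <- srgb_to_lab(c1)
  lab2 <- srgb_to_lab(c2)
  n <- max(nrow(lab1), nrow(lab2))
  lab1 <- lab1[rep_len(seq_len(nrow(lab1)), n), , drop = FALSE]
  lab2 <- lab2[rep_len(seq_len(nrow(lab2)), n), , drop = FALSE]
  unname(sqrt(rowSums((lab1 - lab2)^2)))
}

# Rasterize a polygon (n x 2 matrix of x, y vertices) on an h x w grid by
# even-odd scanline crossing at pixel centers.
.polygon_mask <- function(h, w, poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2)
  if (nrow(poly) < 3) stop("polygon needs at least 3 vertices")
  xs <- poly[, 1]; ys <- poly[, 2]
  mask <- matrix(FALSE, h, w)
  n <- nrow(poly)
  for (row in seq_len(h)) {
    y <- row
    crossings <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- ys[i]; y2 <- ys[j]
      if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
        crossings <- c(crossings, xs[i] + (y - y1) / (y2 - y1) * (xs[j] - xs[i]))
      }
    }
    if (length(crossings) >= 2) {
      crossings <- sort(crossings)
      for (k in seq(1, length(crossings) - 1, by = 2)) {
        c0 <- max(1L, ceiling(crossings[k]))
        c1 <- min(w, floor(crossings[k + 1]))
        if (c0 <= c1) mask[row, c0:c1] <- TRUE
      }
    }
  }
  mask
}

#' Mask the density-standard region in black
#'
#' Sets the polygonal region covering the density standard to #000000; black
#' pixels are excluded from the pixel-counting domain, so the wedge's own
#' colored pixels never contribute to percent-color results.
#'
#' @param img h x w x 3 RGB raster.
#' @param region n x 2 matrix of polygon vertices (x, y) in image
#'   coordinates.
#' @return The raster with the region blacked out.
#' @export
mask_standard_region <- function(img, region) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (!is.matrix(region) || nrow(region) < 3) {
    stop("empty or degenerate masking polygon")
  }
  if (any(region[, 1] < 0 | region[, 1] > w + 1 |
          region[, 2] < 0 | region[, 2] > h + 1)) {
    stop("masking polygon extends outside the image bounds")
  }
  .paint(img, .polygon_mask(h, w, region), "#000000")
}

# Pack an RGB raster to single integer codes for fast tabulation.
.pixel_codes <- function(img) {
  as.integer(img[, , 1]) * 65536L + as.integer(img[, , 2]) * 256L +
    as.integer(img[, , 3])
}

.code_of_hex <- function(hex) {
  rgb <- .parse_hex(hex)
  as.integer(rgb[, 1]) * 65536L + as.integer(rgb[, 2]) * 256L +
    as.integer(rgb[, 3])
}

#' Count color pixels by CIE76 similarity
#'
#' Every pixel in the counting domain (all non-#000000 pixels) is credited
#' to the palette entry with the smallest CIE76 distance, provided that
#' distance does not exceed `tolerance`; ties go to the lowest step index,
#' and pixels beyond tolerance (e.g. the background sentinel) stay
#' uncounted.
#'
#' @param img h x w x 3 RGB raster.
#' @param palette Named character vector of HEX codes (a [cda_colormap()]'s
#'   `palette`, or any non-empty set).
#' @param tolerance Maximum delta-E for a match (>= 0). Default 10.
#' @return Data frame with columns `color`, `name`, `count`.
#' @export
count_color_pixels <- function(img, palette, tolerance = 10) {
  if (length(palette) == 0) stop("empty palette")
  if (tolerance < 0) stop("tolerance must be >= 0")
  palette <- toupper(palette)
  if (is.null(names(palette))) names(palette) <- palette
  codes <- .pixel_codes(img)
  domain <- codes != 0L   # #000000 is the standard mask
  tab <- table(codes[domain])
  uniq <- as.integer(names(tab))
  counts <- stats::setNames(rep(0, length(palette)), names(palette))
  if (length(uniq) > 0) {
    uniq_hex <- sprintf("#%02X%02X%02X", uniq %/% 65536L,
                        (uniq %/% 256L) %% 256L, uniq %% 256L)
    pal_lab <- srgb_to_lab(palette)
    ulab <- srgb_to_lab(uniq_hex)
    d <- vapply(seq_along(palette), function(j) {
      sqrt((ulab[, 1] - pal_lab[j, 1])^2 + (ulab[, 2] - pal_lab[j, 2])^2 +
             (ulab[, 3] - pal_lab[j, 3])^2)
    }, numeric(length(uniq_hex)))
    d <- matrix(d, nrow = length(uniq_hex))
    best <- apply(d, 1, which.min)       # which.min takes the first: low step wins ties
    best_d <- d[cbind(seq_along(uniq), best)]
    ok <- best_d <= tolerance + 1e-9
    for (i in which(ok)) {
      counts[best[i]] <- counts[best[i]] + as.numeric(tab[i])
    }
  }
  data.frame(color = unname(palette), name = names(palette),
             count = unname(counts))
}

#' Percent color pixels
#'
#' The per-step percentage of color-annotated pixels relative to the white
#' (bone-reference) pixel count: `100 * count / white_count`.
#'
#' @param counts Data frame from [count_color_pixels()] on the ten
#'   color-annotated images (one row per step), or a named numeric vector.
#' @param white_count White pixel count from the white-annotated image; must
#'   be positive (zero means no bone annotation exists).
#' @return A `percent_color_result`: data frame with columns `step`, `color`,
#'   `count`, `percent`, with `white_count` as an attribute.
#' @export
percent_color <- function(counts, white_count) {
  if (is.null(white_count) || is.na(white_count) || white_count <= 0) {
    stop("white reference count must be positive (no bone annotation)")
  }
  if (is.numeric(counts)) {
    counts <- data.frame(color = names(counts) %||% paste0("S", seq_along(counts)),
                         name = names(counts) %||% paste0("S", seq_along(counts)),
                         count = unname(counts))
  }
  out <- data.frame(step = seq_len(nrow(counts)), color = counts$color,
                    count = counts$count,
                    percent = 100 * counts$count / white_count)
  structure(out, class = c("percent_color_result", "data.frame"),
            white_count = white_count)
}

#' Detect and grade background artifacts
#'
#' Counts, for every step's color-annotated image, the colored pixels lying
#' outside the limb mask (background artifacts such as hair matching a
#' low-step range). Each step's artifact fraction is its artifact pixel
#' count over the white-reference count; a step is flagged when the fraction
#' exceeds the mild threshold, and the radiograph's severity grade is the
#' maximum band reached by any step. The numeric thresholds are package
#' configuration, not published criteria: the clinical grading was visual.
#'
#' @param set A `decomposed_set`.
#' @param limb_mask Logical mask aligned to the decomposed image size;
#'   defaults to the mask stored on the set.
#' @param thresholds Named fractions `c(mild=, moderate=, severe=)`:
#'   band edges on the artifact fraction.
#' @param tolerance CIE76 matching tolerance for recognizing step colors.
#' @return An `artifact_report`: data frame with columns `step`,
#'   `artifact_pixels`, `fraction`, `flagged`, `severity`; attributes
#'   `severity` (overall grade), `n_flagged_steps`, `white_count`.
#' @export
detect_artifacts <- function(set, limb_mask = set$limb_mask,
                             thresholds = c(mild = 0.005, moderate = 0.05,
                                            severe = 0.20),
                             tolerance = 10) {
  if (is.null(limb_mask) || !all(dim(limb_mask) == set$size)) {
    stop("limb mask is missing or misaligned with the decomposed images")
  }
  white_count <- sum(.pixel_codes(set$white) == .code_of_hex(set$colormap$white))
  if (white_count == 0) stop("white reference image has no white pixels")
  grade <- function(f) {
    if (f > thresholds["severe"]) "severe"
    else if (f > thresholds["moderate"]) "moderate"
    else if (f > thresholds["mild"]) "mild"
    else "none"
  }
  out <- do.call(rbind, lapply(seq_along(set$images), function(k) {
    img <- set$images[[k]]
    colored <- .pixel_codes(img) == .code_of_hex(set$colormap$palette[k])
    ap <- sum(colored & !as.vector(limb_mask))
    f <- ap / white_count
    data.frame(step = k, artifact_pixels = ap, fraction = f,
               flagged = f > thresholds["mild"], severity = grade(f))
  }))
  sev_levels <- c("none", "mild", "moderate", "severe")
  overall <- sev_levels[max(match(out$severity, sev_levels))]
  structure(out, class = c("artifact_report", "data.frame"),
            severity = overall, n_flagged_steps = sum(out$flagged),
            white_count = white_count, thresholds = thresholds)
}

#' @export
print.artifact_report <- function(x, ...) {
  cat("<artifact_report> overall severity:", attr(x, "severity"),
      sprintf("(%d flagged step%s)\n", attr(x, "n_flagged_steps"),
              if (attr(x, "n_flagged_steps") == 1) "" else "s"))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Estimate a limb mask from pixel values
#'
#' For radiographs without a ground-truth mask: thresholds the HU image,
#' removes the wedge region, and applies a morphological closing
#' (dilation followed by erosion) to fill internal gaps. A rough estimator
#' intended for whole-joint masking, not anatomical segmentation.
#'
#' @param rad A [radiograph()].
#' @param threshold HU above which a pixel is considered tissue.
#' @param closing Number of 3x3 closing iterations.
#' @return Logical matrix.
#' @export
estimate_limb_mask <- function(rad, threshold = -500, closing = 5) {
  m <- rad$pixels > threshold
  if (!is.null(rad$wedge)) {
    fp <- rad$wedge$footprints
    m[max(1, min(fp$y0) - 10):min(nrow(m), max(fp$y1) + 10),
      max(1, min(fp$x0) - 10):min(ncol(m), max(fp$x1) + 10)] <- FALSE
  }
  for (i in seq_len(closing)) m <- .dilate3(m)
  for (i in seq_len(closing)) m <- !.dilate3(!m)
  m
}
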