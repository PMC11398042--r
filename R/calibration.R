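#' Measuring line across a wedge step
#'
#' A straight segment used to read the reference attenuation of one step,
#' positioned from one edge of the density standard to the opposite edge,
#' optionally averaged over a perpendicular band of pixels.
#'
#' @param step Step index 1..10.
#' @param endpoints 2 x 2 numeric matrix; rows are the two endpoints, columns
#'   are (x, y) image coordinates.
#' @param width Band width in pixels (odd); samples are averaged across the
#'   band perpendicular to the line. Default 1 (the raw single line).
#' @return An object of class `measuring_line`.
#' @export
measuring_line <- function(step, endpoints, width = 1) {
  stopifnot(step %in% 1:10, is.matrix(endpoints), all(dim(endpoints) == c(2, 2)),
            width >= 1, width %% 2 == 1)
  structure(list(step = step, endpoints = endpoints, width = width),
            class = "measuring_line")
}

# The auto-placed line for a step: horizontal, through the footprint's
# centroid, spanning the footprint from edge to edge.
.auto_line <- function(footprint_row, width = 1) {
  y <- round((footprint_row$y0 + footprint_row$y1) / 2)
  measuring_line(
    footprint_row$step,
    rbind(c(footprint_row$x0, y), c(footprint_row$x1, y)),
    width = width
  )
}

#' Sample HU values along a measuring line
#'
#' Nearest-pixel sampling along the segment, averaged across the line's
#' perpendicular band when `width > 1`.
#'
#' @param rad A [radiograph()].
#' @param line A [measuring_line()].
#' @return Numeric vector of sampled HU values (length >= 2).
#' @export
sample_measuring_line <- function(rad, line) {
  p1 <- line$endpoints[1, ]; p2 <- line$endpoints[2, ]
  h <- nrow(rad$pixels); w <- ncol(rad$pixels)
  n <- max(abs(p2 - p1)) + 1
  if (n < 2) stop("measuring line is degenerate (length < 2 pixels)")
  xs <- round(seq(p1[1], p2[1], length.out = n))
  ys <- round(seq(p1[2], p2[2], length.out = n))
  d <- p2 - p1
  perp <- if (abs(d[1]) >= abs(d[2])) c(0, 1) else c(1, 0)
  offs <- seq(-(line$width - 1) / 2, (line$width - 1) / 2)
  acc <- matrix(NA_real_, length(offs), n)
  for (i in seq_along(offs)) {
    xo <- xs + perp[1] * offs[i]
    yo <- ys + perp[2] * offs[i]
    if (any(xo < 1 | xo > w | yo < 1 | yo > h)) {
      stop("measuring line (with band) extends outside the image")
    }
    acc[i, ] <- rad$pixels[cbind(yo, xo)]
  }
  colMeans(acc)
}

#' Min/Max reference attenuation of a sample series
#'
#' The step's relative-density range: the raw minimum and maximum of the
#' sampled values, with no outlier rejection.
#'
#' @param samples Non-empty numeric vector of HU values.
#' @return Named numeric vector `c(min_hu = , max_hu = )`.
#' @export
step_range <- function(samples) {
  if (length(samples) == 0) stop("cannot take a range of zero samples")
  c(min_hu = min(samples), max_hu = max(samples))
}

#' Build the per-radiograph calibration table
#'
#' For each of the ten wedge steps, reads the reference attenuation along the
#' auto-placed measuring line through the step footprint's center and records
#' the Min/Max range. Ranges are per radiograph: each exposure of each
#' subject carries its own table.
#'
#' @param rad A [radiograph()].
#' @param layout A [wedge_spec()] giving the step footprints; defaults to the
#'   wedge stored on the radiograph.
#' @param width Measuring-line band width in pixels (default 1).
#' @return A `calibration_table`: data frame with columns `step`, `min_hu`,
#'   `max_hu`, carrying the exposure and source id as attributes.
#' @export
build_calibration_table <- function(rad, layout = rad$wedge, width = 1) {
  if (is.null(layout)) stop("no wedge layout available")
  fp <- layout$footprints
  ranges <- vapply(1:10, function(s) {
    row <- fp[fp$step == s, , drop = FALSE]
    if (nrow(row) == 0) stop("missing footprint for step S", s)
    step_range(sample_measuring_line(rad, .auto_line(row, width)))
  }, numeric(2))
  out <- data.frame(step = 1:10, min_hu = ranges[1, ], max_hu = ranges[2, ])
  structure(out, class = c("calibration_table", "data.frame"),
            exposure = rad$exposure, source_id = rad$source_id)
}

#' @export
print.calibration_table <- function(x, ...) {
  exp <- attr(x, "exposure")
  cat("<calibration_table>", attr(x, "source_id"),
      if (!is.null(exp)) paste0("(", format(exp), ")"), "\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Summarize replicate calibration tables
#'
#' Per step and bound (Min/Max), the arithmetic mean and sample standard
#' deviation (n - 1 denominator) over replicate radiographs of one exposure
#' setting. With a single replicate the SD is reported as 0 and `n = 1`
#' flags the degenerate case.
#'
#' @param tables List of `calibration_table`s, all from the same exposure.
#' @return A `calibration_summary`: data frame with columns `step`, `bound`,
#'   `mean`, `sd`, `n`.
#' @export
summarize_replicates <- function(tables) {
  if (length(tables) < 1) stop("need at least one calibration table")
  labels <- vapply(tables, function(t) attr(t, "exposure")$label, character(1))
  if (length(unique(labels)) > 1) {
    stop("cannot pool calibration tables from mixed exposures: ",
         paste(unique(labels), collapse = " vs "))
  }
  n <- length(tables)
  mins <- sapply(tables, `[[`, "min_hu")
  maxs <- sapply(tables, `[[`, "max_hu")
  if (n == 1) { mins <- matrix(mins, ncol = 1); maxs <- matrix(maxs, ncol = 1) }
  sdev <- function(m) if (n == 1) rep(0, nrow(m)) else apply(m, 1, stats::sd)
  out <- data.frame(
    step = rep(1:10, 2),
    bound = rep(c("Min", "Max"), each = 10),
    mean = c(rowMeans(mins), rowMeans(maxs)),
    sd = c(sdev(mins), sdev(maxs)),
    n = n
  )
  structure(out, class = c("calibration_summary", "data.frame"),
            exposure = attr(tables[[1]], "exposure"))
}

# Per-step (min, max) matrix from a table or summary (means for a summary).
.range_matrix <- function(x) {
  if (inherits(x, "calibration_summary") ||
      (is.data.frame(x) && "bound" %in% names(x))) {
    mins <- x$mean[x$bound == "Min"][order(x$step[x$bound == "Min"])]
    maxs <- x$mean[x$bound == "Max"][order(x$step[x$bound == "Max"])]
  } else {
    mins <- x$min_hu[order(x$step)]
    maxs <- x$max_hu[order(x$step)]
  }
  if (length(mins) != 10 || length(maxs) != 10) {
    stop("expected ranges for all 10 steps")
  }
  cbind(min_hu = mins, max_hu = maxs)
}

#' Coverage interval of the HU scale
#'
#' The span of the relative-density scale realized by one calibration: from
#' the smallest step Min to the largest step Max.
#'
#' @param x A `calibration_table` or `calibration_summary` (means are used).
#' @return Numeric `c(low, high)` in HU.
#' @export
coverage_interval <- function(x) {
  rm <- .range_matrix(x)
  c(low = min(rm[, "min_hu"]), high = max(rm[, "max_hu"]))
}

#' Gaps between consecutive relative-density ranges
#'
#' `gap_k = max(0, Min(S_(k+1)) - Max(S_k))` for k = 1..9. Positive gaps mean
#' the coverage is scattered (typical of high-mAs calibrations); zeros mean
#' adjacent or overlapping ranges.
#'
#' @inheritParams coverage_interval
#' @return Numeric vector of 9 gap widths in HU.
#' @export
range_gaps <- function(x) {
  rm <- .range_matrix(x)
  pmax(0, rm[2:10, "min_hu"] - rm[1:9, "max_hu"])
}

# Logical mask: which values fall inside the union of the ten closed ranges.
.in_any_range <- function(values, table) {
  rm <- .range_matrix(table)
  out <- array(FALSE, dim = dim(values) %||% length(values))
  for (k in 1:10) {
    out <- out | (values >= rm[k, "min_hu"] & values <= rm[k, "max_hu"])
  }
  out
}

#' Published reference attenuation ranges
#'
#' The study-level summary (mean and SD of the per-radiograph Min and Max
#' reference attenuation, nine limbs) for each of the five tube settings and
#' ten wedge steps, as shipped in `inst/extdata/reference_ranges.csv`.
#'
#' @param setting Optional setting label (e.g. `"50 kV; 1.2 mAs"`) to filter.
#' @return Data frame with columns `setting`, `kv`, `mas`, `step`, `bound`,
#'   `mean`, `sd`, `n`; or, when `setting` is given, a `calibration_summary`.
#' @export
reference_ranges <- function(setting = NULL) {
  path <- system.file("extdata", "reference_ranges.csv", package = "cdar")
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(setting)) return(ref)
  sub <- ref[ref$setting == setting, ]
  if (nrow(sub) == 0) {
    stop("unknown setting '", setting, "'; available: ",
         paste(unique(ref$setting), collapse = ", "))
  }
  out <- data.frame(step = sub$step, bound = sub$bound,
                    mean = sub$mean, sd = sub$sd, n = sub$n)
  structure(out, class = c("calibration_summary", "data.frame"),
            exposure = exposure_setting(sub$kv[1], sub$mas[1]))
}

#' Write / read calibration results
#'
#' Round-trips calibration tables and summaries as CSV (columns `setting`,
#' `step`, `bound`, `value` and, for summaries, `sd`, `n`) or JSON, chosen by
#' file extension.
#'
#' @param x A `calibration_table` or `calibration_summary`.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the reconstructed object.
#' @export
write_calibration <- function(x, path) {
  exp <- attr(x, "exposure")
  label <- if (!is.null(exp)) exp$label else NA_character_
  if (inherits(x, "calibration_summary")) {
    df <- data.frame(setting = label, kv = exp$kv, mas = exp$mas,
                     step = x$step, bound = x$bound,
                     value = x$mean, sd = x$sd, n = x$n)
  } else {
    df <- data.frame(setting = label, kv = exp$kv, mas = exp$mas,
                     step = rep(x$step, 2),
                     bound = rep(c("Min", "Max"), each = nrow(x)),
                     value = c(x$min_hu, x$max_hu))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(df, path, digits = NA)
  } else {
    stop("unsupported calibration format: .", ext)
  }
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (ext == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    stop("unsupported calibration format: .", ext)
  }
  exp <- exposure_setting(df$kv[1], df$mas[1])
  if ("sd" %in% names(df)) {
    out <- data.frame(step = df$step, bound = df$bound, mean = df$value,
                      sd = df$sd, n = df$n)
    structure(out, class = c("calibration_summary", "data.frame"),
              exposure = exp)
  } else {
    mins <- df[df$bound == "Min", ]
    maxs <- df[df$bound == "Max", ]
    out <- data.frame(step = mins$step[order(mins$step)],
                      min_hu = mins$value[order(mins$step)],
                      max_hu = maxs$value[order(maxs$step)])
    structure(out, class = c("calibration_table", "data.frame"),
              exposure = exp, source_id = df$setting[1])
  }
}
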