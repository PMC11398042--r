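#' Default density-standard masking polygon
#'
#' Rectangle covering the wedge footprints plus a safety margin, expressed
#' in the coordinate system of the decomposed (resized) images.
#'
#' @param rad A [radiograph()].
#' @param size Decomposed image size `c(rows, cols)`.
#' @param margin Margin in native pixels around the wedge bounding box.
#' @return 4 x 2 matrix of polygon vertices (x, y).
#' @export
default_standard_region <- function(rad, size = c(847, 899), margin = 10) {
  fp <- rad$wedge$footprints
  sx <- size[2] / ncol(rad$pixels)
  sy <- size[1] / nrow(rad$pixels)
  x0 <- max(0, (min(fp$x0) - margin)) * sx
  x1 <- min(ncol(rad$pixels), (max(fp$x1) + margin)) * sx
  y0 <- max(0, (min(fp$y0) - margin)) * sy
  y1 <- min(nrow(rad$pixels), (max(fp$y1) + margin)) * sy
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

#' Run the full CDA protocol on one radiograph
#'
#' Calibrates the per-step relative-density ranges from the co-imaged
#' density standard, decomposes the radiograph into the ten color-annotated
#' images plus the white bone-reference image (resized to 899 x 847), masks
#' the density standard in black, counts color pixels by CIE76 similarity,
#' converts to percent color pixels against the white reference, and grades
#' background artifacts.
#'
#' @param rad A [radiograph()] with a limb mask (or supply `limb_mask`).
#' @param colormap A [cda_colormap()].
#' @param limb_mask Logical mask at native resolution; defaults to the
#'   radiograph's ground truth, falling back to [estimate_limb_mask()].
#' @param tolerance CIE76 matching tolerance.
#' @param thresholds Artifact grading thresholds, see [detect_artifacts()].
#' @param keep_images Keep the decomposed images in the result (default
#'   FALSE: only counts and reports are returned).
#' @return A list of class `cda_result`: `table` (calibration), `percent`
#'   (percent-color result), `artifacts` (artifact report), `white_count`,
#'   `exposure`, `source_id`, and optionally `set`.
#' @export
cda_pipeline <- function(rad, colormap = cda_colormap(),
                         limb_mask = NULL, tolerance = 10,
                         thresholds = c(mild = 0.005, moderate = 0.05,
                                        severe = 0.20),
                         keep_images = FALSE) {
  if (is.null(limb_mask)) limb_mask <- rad$limb_mask %||% estimate_limb_mask(rad)
  table <- build_calibration_table(rad)
  set <- decompose(rad, table, colormap, limb_mask)
  region <- default_standard_region(rad, set$size)
  set$images <- lapply(set$images, mask_standard_region, region = region)
  set$white <- mask_standard_region(set$white, region)

  counts <- vapply(seq_along(set$images), function(k) {
    count_color_pixels(set$images[[k]], colormap$palette[k], tolerance)$count
  }, numeric(1))
  count_df <- data.frame(color = unname(colormap$palette),
                         name = names(colormap$palette), count = counts)
  white_count <- count_color_pixels(set$white,
                                    c(white = colormap$white), tolerance)$count
  percent <- percent_color(count_df, white_count)
  artifacts <- detect_artifacts(set, thresholds = thresholds,
                                tolerance = tolerance)
  out <- list(table = table, percent = percent, artifacts = artifacts,
              white_count = white_count, exposure = rad$exposure,
              source_id = rad$source_id)
  if (keep_images) out$set <- set
  structure(out, class = "cda_result")
}

#' @export
print.cda_result <- function(x, ...) {
  cat("<cda_result>", x$source_id, "-", format(x$exposure), "\n")
  cat(sprintf("  white reference: %d px; artifact severity: %s\n",
              x$white_count, attr(x$artifacts, "severity")))
  print.data.frame(
    data.frame(step = x$percent$step,
               percent = round(x$percent$percent, 2),
               artifact_pixels = x$artifacts$artifact_pixels),
    row.names = FALSE)
  invisible(x)
}

#' Analyze a synthetic cohort end to end
#'
#' Runs [cda_pipeline()] on every radiograph of a cohort and assembles tidy
#' per-(limb, setting, step) results together with per-setting replicate
#' calibration summaries.
#'
#' @param cohort A `cda_cohort` from [generate_cohort()].
#' @param ... Passed on to [cda_pipeline()].
#' @return A list of class `cda_cohort_analysis`: `results` (tidy data frame
#'   with columns `limb`, `setting`, `kv`, `mas`, `step`, `count`,
#'   `white_count`, `percent`, `artifact_pixels`, `fraction`, `flagged`,
#'   `severity`), `calibrations` (list of per-radiograph tables) and
#'   `summaries` (named list of per-setting `calibration_summary`s).
#' @export
analyze_cohort <- function(cohort, ...) {
  rows <- list()
  calibrations <- list()
  for (entry in cohort) {
    res <- cda_pipeline(entry$rad, ...)
    calibrations[[length(calibrations) + 1]] <- res$table
    rows[[length(rows) + 1]] <- data.frame(
      limb = entry$limb, setting = entry$setting,
      kv = res$exposure$kv, mas = res$exposure$mas,
      step = res$percent$step, count = res$percent$count,
      white_count = res$white_count, percent = res$percent$percent,
      artifact_pixels = res$artifacts$artifact_pixels,
      fraction = res$artifacts$fraction, flagged = res$artifacts$flagged,
      severity = attr(res$artifacts, "severity")
    )
  }
  results <- do.call(rbind, rows)
  settings <- unique(results$setting)
  summaries <- lapply(settings, function(s) {
    idx <- which(vapply(calibrations,
                        function(t) attr(t, "exposure")$label == s, logical(1)))
    summarize_replicates(calibrations[idx])
  })
  names(summaries) <- settings
  structure(list(results = results, calibrations = calibrations,
                 summaries = summaries),
            class = "cda_cohort_analysis")
}

#' @export
print.cda_cohort_analysis <- function(x, ...) {
  cat("<cda_cohort_analysis>", nrow(x$results), "rows,",
      length(unique(x$results$setting)), "settings\n")
  invisible(x)
}

#' Summarize percent-color results per setting and step
#'
#' The coverage-chart summary: for each (setting, step), the calibrated
#' relative-density range (replicate means), the mean and SD of percent
#' color pixels over limbs, and the number of limbs in which that step was
#' flagged as artifact-affected.
#'
#' @param results Tidy results data frame from [analyze_cohort()].
#' @param summaries Named list of `calibration_summary`s, one per setting
#'   appearing in `results`.
#' @return A `setting_summary` data frame with columns `setting`, `kv`,
#'   `mas`, `step`, `min_hu`, `max_hu`, `mean_percent`, `sd_percent`, `n`,
#'   `n_artifact_occurrences`.
#' @export
summarize_settings <- function(results, summaries) {
  missing <- setdiff(unique(results$setting), names(summaries))
  if (length(missing) > 0) {
    stop("no calibration summary for setting(s): ",
         paste(missing, collapse = ", "))
  }
  rows <- lapply(unique(results$setting), function(s) {
    sub <- results[results$setting == s, ]
    rm <- .range_matrix(summaries[[s]])
    do.call(rbind, lapply(sort(unique(sub$step)), function(k) {
      cell <- sub[sub$step == k, ]
      data.frame(setting = s, kv = cell$kv[1], mas = cell$mas[1], step = k,
                 min_hu = rm[k, "min_hu"], max_hu = rm[k, "max_hu"],
                 mean_percent = mean(cell$percent),
                 sd_percent = stats::sd(cell$percent),
                 n = nrow(cell),
                 n_artifact_occurrences = sum(cell$flagged))
    }))
  })
  structure(do.call(rbind, rows),
            class = c("setting_summary", "data.frame"))
}

#' Recommend an X-ray tube setting
#'
#' A setting is most beneficial when it covers the lowest possible HU ranges
#' without inducing background artifacts. Among artifact-free settings the
#' one with the smallest coverage low endpoint wins; ties break toward the
#' wider total coverage. If every setting shows artifacts, the one with the
#' fewest artifact occurrences is returned with `attr(, "warning") = TRUE`.
#'
#' @param summary A `setting_summary` from [summarize_settings()].
#' @return The recommended [exposure_setting()].
#' @export
recommend_setting <- function(summary) {
  settings <- unique(summary$setting)
  if (length(settings) < 2) stop("need at least 2 settings to compare")
  info <- do.call(rbind, lapply(settings, function(s) {
    sub <- summary[summary$setting == s, ]
    data.frame(setting = s, kv = sub$kv[1], mas = sub$mas[1],
               low = min(sub$min_hu), high = max(sub$max_hu),
               artifacts = sum(sub$n_artifact_occurrences))
  }))
  clean <- info[info$artifacts == 0, ]
  warn <- FALSE
  if (nrow(clean) == 0) {
    warning("all settings show background artifacts; ",
            "recommending the least affected")
    clean <- info[info$artifacts == min(info$artifacts), ]
    warn <- TRUE
  }
  clean <- clean[order(clean$low, -(clean$high - clean$low)), ]
  best <- clean[1, ]
  out <- exposure_setting(best$kv, best$mas, best$setting)
  attr(out, "warning") <- warn
  out
}
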