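#' X-ray tube exposure setting
#'
#' Bundles the two exposure knobs of a radiographic acquisition: tube voltage
#' (kV, governing beam energy and penetration) and tube current-time product
#' (mAs, governing photon quantity).
#'
#' @param kv Tube voltage in kilovolt. Must be positive.
#' @param mas Tube current-time product in milliampere-seconds. Must be
#'   positive.
#' @param label Optional free-text label; defaults to `"<kv> kV; <mas> mAs"`.
#' @return An object of class `exposure_setting`.
#' @examples
#' exposure_setting(60, 1.2)
#' @export
exposure_setting <- function(kv, mas, label = NULL) {
  stopifnot(is.numeric(kv), length(kv) == 1L, is.numeric(mas), length(mas) == 1L)
  if (!is.finite(kv) || kv <= 0) stop("'kv' must be a positive tube voltage")
  if (!is.finite(mas) || mas <= 0) stop("'mas' must be a positive mAs value")
  if (is.null(label)) label <- sprintf("%g kV; %g mAs", kv, mas)
  structure(list(kv = kv, mas = mas, label = label), class = "exposure_setting")
}

#' @export
print.exposure_setting <- function(x, ...) {
  cat("<exposure_setting>", x$label, "\n")
  invisible(x)
}

#' @export
format.exposure_setting <- function(x, ...) x$label

#' The five tube settings compared in the study design
#'
#' Five combinations spanning 50--80 kV at a low tube current (1.2 mAs) plus
#' one high-current setting (12 mAs): 50 kV; 1.2 mAs, 60 kV; 1.2 mAs,
#' 60 kV; 12 mAs, 70 kV; 1.2 mAs and 80 kV; 1.2 mAs.
#'
#' @return A named list of [exposure_setting()] objects.
#' @export
study_presets <- function() {
  p <- list(
    exposure_setting(50, 1.2),
    exposure_setting(60, 1.2),
    exposure_setting(60, 12),
    exposure_setting(70, 1.2),
    exposure_setting(80, 1.2)
  )
  names(p) <- vapply(p, `[[`, character(1), "label")
  p
}
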