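#' Write / read radiographs as plain-text raster files
#'
#' A simple lossless text format: `#`-prefixed header lines carrying the
#' metadata (`pixel_spacing`, `kv`, `mas`, `source_id`), followed by the HU
#' matrix as tab-separated values, one image row per line. Wedge layout and
#' limb mask are not stored; supply them on read if needed downstream.
#'
#' @param rad A [radiograph()].
#' @param path Output path (conventionally `.tsv`).
#' @param wedge Optional [wedge_spec()] to attach on read.
#' @return `write_radiograph` returns `path` invisibly; `read_radiograph`
#'   returns a [radiograph()].
#' @export
write_radiograph <- function(rad, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# pixel_spacing\t%.10g", rad$pixel_spacing),
    sprintf("# kv\t%.10g", rad$exposure$kv),
    sprintf("# mas\t%.10g", rad$exposure$mas),
    sprintf("# source_id\t%s", rad$source_id)
  ), con)
  utils::write.table(rad$pixels, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_radiograph
#' @export
read_radiograph <- function(path, wedge = wedge_spec()) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, "\t"), hdr)]
    if (!length(ln)) stop("missing header field: ", key)
    sub(paste0("^# ", key, "\t"), "", ln[1])
  }
  px <- as.matrix(utils::read.table(text = lines[!grepl("^#", lines)],
                                    sep = "\t"))
  dimnames(px) <- NULL
  radiograph(px, pixel_spacing = as.numeric(get("pixel_spacing")),
             exposure = exposure_setting(as.numeric(get("kv")),
                                         as.numeric(get("mas"))),
             wedge = wedge, source_id = get("source_id"))
}

#' Write tidy quantification results
#'
#' Writes the per-(limb, setting, step) results of [analyze_cohort()] as CSV
#' or JSON, chosen by file extension.
#'
#' @param results Tidy results data frame.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(results, path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(results, path, digits = NA)
  } else {
    stop("unsupported results format: .", ext)
  }
  invisible(path)
}
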