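#' Step color palette
#'
#' The HEX codes assigned to the ten density-standard steps: S1 yellow
#' #FFFF00, S2 orange #E08000, S3 red #FF0000, S4 light purple #E080C0, S5
#' dark purple #800080, S6 dark blue #0000FF, S7 dark green #008000, S8 navy
#' green #808000, S9 light green #00FF00, S10 light blue #A6CAF0.
#'
#' @return Named character vector of 10 HEX codes (`S1` .. `S10`).
#' @export
step_palette <- function() {
  c(S1 = "#FFFF00", S2 = "#E08000", S3 = "#FF0000", S4 = "#E080C0",
    S5 = "#800080", S6 = "#0000FF", S7 = "#008000", S8 = "#808000",
    S9 = "#00FF00", S10 = "#A6CAF0")
}

#' Color map for radiograph decomposition
#'
#' Bundles the step palette with the three auxiliary colors of the protocol:
#' white (#FFFFFF) for the bone-reference annotation, black (#000000) for
#' the manually masked density standard (excluded from pixel counting), and
#' a fixed non-palette background sentinel.
#'
#' @param palette Ten step colors, as [step_palette()].
#' @param white White-annotation color.
#' @param standard_mask Mask color for the density standard.
#' @param background Background fill, excluded from the palette.
#' @return An object of class `cda_colormap`.
#' @export
cda_colormap <- function(palette = step_palette(), white = "#FFFFFF",
                         standard_mask = "#000000", background = "#404040") {
  if (length(palette) != 10) stop("the step palette must have 10 entries")
  all_cols <- toupper(c(palette, white, standard_mask, background))
  if (anyDuplicated(all_cols)) {
    stop("palette, white, standard mask and background colors must be distinct")
  }
  .parse_hex(all_cols)  # validates
  structure(list(palette = toupper(palette), white = toupper(white),
                 standard_mask = toupper(standard_mask),
                 background = toupper(background)),
            class = "cda_colormap")
}

# HEX "#RRGGBB" -> n x 3 integer matrix; errors on malformed codes.
.parse_hex <- function(hex) {
  bad <- !grepl("^#[0-9A-Fa-f]{6}$", hex)
  if (any(bad)) stop("malformed HEX color code: ", hex[which(bad)[1]])
  t(vapply(hex, function(h) {
    strtoi(c(substr(h, 2, 3), substr(h, 4, 5), substr(h, 6, 7)), 16L)
  }, integer(3)))
}

.hex_of <- function(rgb_mat) {
  sprintf("#%02X%02X%02X", rgb_mat[, 1], rgb_mat[, 2], rgb_mat[, 3])
}
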