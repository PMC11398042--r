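# Images throughout this module are h x w x 3 integer arrays with values
# 0..255 (R, G, B planes).

.flat_raster <- function(h, w, hex) {
  rgb <- .parse_hex(hex)
  array(rep(as.integer(rgb), each = h * w), dim = c(h, w, 3))
}

.paint <- function(img, mask, hex) {
  rgb <- .parse_hex(hex)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- rgb[ch]
    img[, , ch] <- plane
  }
  img
}

.pixels_of <- function(x) if (inherits(x, "radiograph")) x$pixels else x

#' Mask one relative-density range with a color
#'
#' Paints every pixel whose HU value lies inside the closed interval
#' `[min_hu, max_hu]` with the assigned color; all other pixels take the
#' background fill.
#'
#' @param x A [radiograph()] or a plain HU matrix.
#' @param range Numeric `c(min_hu, max_hu)` (or a 1-row slice of a
#'   calibration table).
#' @param color HEX color for in-range pixels.
#' @param background HEX background fill.
#' @return An h x w x 3 integer RGB raster.
#' @export
mask_in_range <- function(x, range, color, background = "#404040") {
  px <- .pixels_of(x)
  if (is.data.frame(range)) range <- c(range$min_hu[1], range$max_hu[1])
  if (range[1] > range[2]) stop("invalid range: min_hu > max_hu")
  img <- .flat_raster(nrow(px), ncol(px), background)
  .paint(img, px >= range[1] & px <= range[2], color)
}

#' White (bone-reference) annotation
#'
#' Paints white every pixel that lies inside the limb mask AND whose HU value
#' falls in the union of the ten closed relative-density ranges. The white
#' pixel count is the normalization reference for percent-color
#' quantification, which is why it is restricted to the limb: background
#' structures matching low-step ranges then inflate the per-step counts but
#' not the reference, so percentages can exceed 100% in artifact-laden
#' radiographs.
#'
#' @param x A [radiograph()] or HU matrix.
#' @param table A `calibration_table` with the ten step ranges.
#' @param limb_mask Logical matrix marking the limb; must be non-empty.
#' @param white,background HEX colors.
#' @return An h x w x 3 integer RGB raster.
#' @export
white_annotation <- function(x, table, limb_mask, white = "#FFFFFF",
                             background = "#404040") {
  px <- .pixels_of(x)
  if (is.null(limb_mask) || !any(limb_mask)) {
    stop("white annotation requires a non-empty limb mask")
  }
  stopifnot(all(dim(limb_mask) == dim(px)))
  img <- .flat_raster(nrow(px), ncol(px), background)
  .paint(img, .in_any_range(px, table) & limb_mask, white)
}

#' Nearest-neighbour resize
#'
#' Resizes a matrix (or h x w x 3 raster) by nearest-neighbour index
#' mapping. Used for the fixed 899 x 847 output size of decomposed images:
#' any interpolating kernel would blend the categorical annotation colors,
#' so only pixel replication is admissible before pixel counting.
#'
#' @param x Matrix, logical matrix, or 3-d array.
#' @param out_h,out_w Output size (rows, cols).
#' @return The resized object, same type as the input.
#' @export
resize_nearest <- function(x, out_h, out_w) {
  d <- dim(x)
  ri <- pmin(d[1], pmax(1L, as.integer(floor((seq_len(out_h) - 0.5) * d[1] / out_h) + 1L)))
  ci <- pmin(d[2], pmax(1L, as.integer(floor((seq_len(out_w) - 0.5) * d[2] / out_w) + 1L)))
  if (length(d) == 2) x[ri, ci] else x[ri, ci, , drop = FALSE]
}

#' Decompose a radiograph into the eleven annotated images
#'
#' One color-annotated image per step range (Table-of-colors palette) plus
#' one white-annotated bone-reference image, each resized to 899 pixels wide
#' by 847 pixels high with nearest-neighbour interpolation so the palette is
#' preserved exactly. Deterministic: no randomness is involved.
#'
#' @param rad A [radiograph()].
#' @param table A `calibration_table`; defaults to one built from the
#'   radiograph's own wedge.
#' @param colormap A [cda_colormap()].
#' @param limb_mask Logical limb mask at the radiograph's native size;
#'   defaults to the radiograph's ground-truth mask.
#' @param size Output size `c(rows, cols)`; the protocol uses 847 x 899.
#' @return An object of class `decomposed_set`: fields `images` (named list
#'   `S1`..`S10`), `white`, `limb_mask` (resized), `size`, `exposure`,
#'   `source_id`, `colormap`.
#' @export
decompose <- function(rad, table = build_calibration_table(rad),
                      colormap = cda_colormap(),
                      limb_mask = rad$limb_mask,
                      size = c(847, 899)) {
  if (is.null(limb_mask)) stop("decompose requires a limb mask")
  hu <- resize_nearest(rad$pixels, size[1], size[2])
  mask <- resize_nearest(limb_mask, size[1], size[2])
  rm <- .range_matrix(table)
  images <- lapply(1:10, function(k) {
    mask_in_range(hu, rm[k, ], colormap$palette[k],
                  background = colormap$background)
  })
  names(images) <- names(colormap$palette)
  white <- white_annotation(hu, table, mask, white = colormap$white,
                            background = colormap$background)
  structure(
    list(images = images, white = white, limb_mask = mask, size = size,
         exposure = rad$exposure, source_id = rad$source_id,
         colormap = colormap),
    class = "decomposed_set"
  )
}

#' @export
print.decomposed_set <- function(x, ...) {
  cat("<decomposed_set>", x$source_id, "-", format(x$exposure), "\n")
  cat(sprintf("  %d color images + 1 white image, %d x %d px\n",
              length(x$images), x$size[1], x$size[2]))
  invisible(x)
}

#' Write the eleven decomposed images as BMP files
#'
#' Files are named `<prefix>_<S1..S10|white>.bmp`.
#'
#' @param set A `decomposed_set`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; defaults to
#'   `<source>_<kv>kV_<mas>mAs`.
#' @return Character vector of the 11 file paths, invisibly.
#' @export
write_decomposed_set <- function(set, dir, prefix = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(prefix)) {
    prefix <- sprintf("%s_%gkV_%gmAs", set$source_id,
                      set$exposure$kv, set$exposure$mas)
  }
  all_imgs <- c(set$images, list(white = set$white))
  paths <- file.path(dir, paste0(prefix, "_", names(all_imgs), ".bmp"))
  for (i in seq_along(all_imgs)) write_bmp(all_imgs[[i]], paths[i])
  invisible(paths)
}
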