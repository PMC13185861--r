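#' Construct a binary shape mask
#'
#' Keeps the largest connected component (8-connectivity) when the mask has
#' several, with a warning.
#'
#' @param mask Logical or 0/1 matrix; `TRUE`/nonzero = foreground.
#' @param pixel_scale Pixel scale in mm/px.
#' @return A `shape_mask` object with fields `mask` (logical matrix) and
#'   `pixel_scale`.
#' @export
shape_mask <- function(mask, pixel_scale) {
  stop_if_not_scalar_number(pixel_scale, "pixel_scale", positive = TRUE)
  mask <- matrix(as.logical(mask != 0), nrow = nrow(mask))
  if (!any(mask)) stop("mask has no foreground pixels")
  lab <- EBImage::bwlabel(mask)
  n_comp <- max(lab)
  if (n_comp > 1L) {
    warning(sprintf("mask has %d connected components; keeping the largest", n_comp))
    sizes <- tabulate(lab[lab > 0], nbins = n_comp)
    mask <- lab == which.max(sizes)
  }
  structure(list(mask = mask, pixel_scale = pixel_scale), class = "shape_mask")
}

#' Read a mask from a PNG or CSV grid
#'
#' PNG: any nonzero channel value marks foreground. CSV: a headerless 0/1
#' grid.
#'
#' @param path File path (`.png` or `.csv`).
#' @param pixel_scale Pixel scale in mm/px.
#' @return A [shape_mask()].
#' @export
read_mask <- function(path, pixel_scale) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), max)
    shape_mask(img > 0, pixel_scale)
  } else {
    shape_mask(as.matrix(utils::read.csv(path, header = FALSE)), pixel_scale)
  }
}

#' Area, equivalent-ellipse axes and Roundness Index of a body mask
#'
#' The axes come from the ellipse with the same second-order central moments
#' as the foreground region (axis length `4 * sqrt(eigenvalue)` of the pixel
#' covariance matrix, as in standard region-property conventions). The
#' Roundness Index is the minor-to-major axis ratio: 1 for a circle,
#' approaching 0 for elongated bodies.
#'
#' @param mask A [shape_mask()].
#' @return A `shape_metrics` list with `area` (mm^2), `major_axis`,
#'   `minor_axis` (mm), `roundness_index`, `orientation` (rad).
#' @export
shape_metrics <- function(mask) {
  stopifnot(inherits(mask, "shape_mask"))
  ps <- mask$pixel_scale
  idx <- which(mask$mask, arr.ind = TRUE)
  area <- nrow(idx) * ps^2
  x <- idx[, 2L]; y <- idx[, 1L]
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2L), symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  major <- 4 * sqrt(lambda[1L]) * ps
  minor <- 4 * sqrt(lambda[2L]) * ps
  if (minor <= 0) stop("degenerate mask: zero minor axis after moment fit")
  structure(list(area = area, major_axis = major, minor_axis = minor,
                 roundness_index = minor / major,
                 orientation = atan2(ev$vectors[2L, 1L], ev$vectors[1L, 1L])),
            class = "shape_metrics")
}

#' @export
print.shape_metrics <- function(x, ...) {
  cat(sprintf("<shape_metrics> area %.3g mm^2, axes %.3g x %.3g mm, RI %.3f\n",
              x$area, x$major_axis, x$minor_axis, x$roundness_index))
  invisible(x)
}

#' Implant-to-shell area ratio
#'
#' Ratio of the total implanted-clump area to the outer-shell area; multiple
#' clumps are summed before dividing.
#'
#' @param area_implant Numeric vector of clump areas in mm^2 (each >= 0).
#' @param area_shell Outer shell area in mm^2 (> 0).
#' @return `sum(area_implant) / area_shell`.
#' @export
implant_ratio <- function(area_implant, area_shell) {
  if (any(area_implant < 0)) stop("implant areas must be >= 0")
  stop_if_not_scalar_number(area_shell, "area_shell", positive = TRUE)
  sum(area_implant) / area_shell
}

#' Assemble a per-organoid feature table
#'
#' Combines morphometric, neuroanatomical and behavioural measurements per
#' organoid into the table consumed by [pairwise_correlations()]. Normalised
#' columns (`l_neurite_norm` = neurite length / area, `n_mcc_norm` = MCC
#' count / area) are computed where `area` is available and left `NA`
#' (with a message) otherwise. Rows with partially missing fields are
#' retained; the correlation layer is pairwise-complete.
#'
#' @param records A data.frame with any subset of the columns `bot`,
#'   `n_terminals`, `l_neurite` (mm), `n_mcc`, `ri`, `area` (mm^2),
#'   `neu_ect_ratio`, `ci`.
#' @return A `bot_features` data.frame with normalised columns appended.
#' @export
feature_table <- function(records) {
  d <- as.data.frame(records)
  known <- c("bot", "n_terminals", "l_neurite", "n_mcc", "ri", "area",
             "neu_ect_ratio", "ci")
  extra <- setdiff(names(d), known)
  if (length(extra)) message("keeping unrecognised columns: ",
                             paste(extra, collapse = ", "))
  has_area <- "area" %in% names(d)
  if ("l_neurite" %in% names(d)) {
    d$l_neurite_norm <- if (has_area) d$l_neurite / d$area else NA_real_
    if (!has_area) message("area missing: l_neurite_norm left NA")
  }
  if ("n_mcc" %in% names(d)) {
    d$n_mcc_norm <- if (has_area) d$n_mcc / d$area else NA_real_
    if (!has_area) message("area missing: n_mcc_norm left NA")
  }
  class(d) <- c("bot_features", "data.frame")
  d
}
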