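#' Segmentation parameters
#'
#' Controls the blue-channel, intensity-class segmentation. Nuclei are the
#' top intensity class and the cell body the union of the middle and top
#' classes; classes come from three-class automatic thresholding (two-level
#' Otsu) unless a fixed threshold pair is given.
#'
#' @param smoothing_sigma Gaussian pre-smoothing sigma in px.
#' @param thresholds `NULL` for automatic three-class Otsu, or a fixed
#'   numeric pair `c(low, high)` separating background/cytoplasm/nucleus.
#' @param min_contrast Minimum separation (intensity units) between the
#'   top-class and bottom-class means for the automatic thresholds to be
#'   trusted; below it the field is declared empty (guards blank or
#'   constant fields).
#' @param min_area,max_area Nucleus area bounds in px^2.
#' @param watershed_tolerance,watershed_ext Object-splitting controls of the
#'   distance-transform watershed: minimum depth between seeds and the
#'   local-maximum neighbourhood radius (px), i.e. how close two seeds may
#'   sit before they are merged.
#' @param exclude_border Drop nuclei (and their cells) touching the frame
#'   border.
#' @return Named list of parameters.
#' @export
segmentation_params <- function(smoothing_sigma = 2, thresholds = NULL,
                                min_contrast = 500, min_area = 30,
                                max_area = 5000, watershed_tolerance = 1,
                                watershed_ext = 1, exclude_border = TRUE) {
  stopifnot(smoothing_sigma >= 0, min_area < max_area)
  list(smoothing_sigma = smoothing_sigma, thresholds = thresholds,
       min_contrast = min_contrast, min_area = min_area, max_area = max_area,
       watershed_tolerance = watershed_tolerance,
       watershed_ext = watershed_ext, exclude_border = exclude_border)
}

#' Three-class automatic thresholding
#'
#' Two-threshold generalization of Otsu's method: maximizes between-class
#' variance over all threshold pairs on a 256-bin histogram. Used to split
#' the blue channel into background, medium (cytoplasm) and high (nucleus)
#' intensity classes.
#'
#' @param x Numeric matrix or vector of intensities.
#' @param nbins Histogram bins.
#' @return Numeric pair `c(low, high)`; `low < high`.
#' @export
threshold_three_class <- function(x, nbins = 256) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(c(Inf, Inf))  # constant image: nothing above
  br <- seq(rng[1], rng[2], length.out = nbins + 1)
  cnt <- tabulate(findInterval(x, br, all.inside = TRUE), nbins)
  mid <- (br[-1] + br[-(nbins + 1)]) / 2
  w <- cnt / sum(cnt)
  cw <- cumsum(w)
  cm <- cumsum(w * mid)
  tot <- cm[nbins]
  # between-class variance for all i < j, vectorized over j per i
  best <- -Inf; bi <- NA; bj <- NA
  for (i in seq_len(nbins - 2)) {
    if (cw[i] <= 0) next
    j <- (i + 1):(nbins - 1)
    w1 <- cw[i]; w2 <- cw[j] - cw[i]; w3 <- 1 - cw[j]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    m1 <- cm[i] / w1; m2 <- (cm[j] - cm[i]) / w2; m3 <- (tot - cm[j]) / w3
    v <- w1 * m1^2 + ifelse(ok, w2 * m2^2 + w3 * m3^2, -Inf)
    k <- which.max(v)
    if (v[k] > best) { best <- v[k]; bi <- i; bj <- j[k] }
  }
  c(mid[bi], mid[bj])
}

# Strip EBImage's Image class back to a plain base matrix.
as_base_matrix <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

smooth_plane <- function(x, sigma) {
  if (sigma > 0) as_base_matrix(EBImage::gblur(x, sigma = sigma)) else x
}

# Mean of pixels below `low` vs above `high`; used for the blank-field guard.
class_contrast <- function(sm, thr) {
  lo <- sm[sm <= thr[1]]; hi <- sm[sm > thr[2]]
  if (!length(hi) || !length(lo)) return(0)
  mean(hi) - mean(lo)
}

#' Segment nuclei from the blue channel
#'
#' Smooths, splits the intensities into three classes, takes the top class
#' as the nucleus mask, fills holes, separates touching nuclei by a
#' distance-transform watershed, and filters objects by area and (optionally)
#' border contact. A constant or blank field yields an empty mask, not an
#' error.
#'
#' @param blue Blue-channel intensity matrix.
#' @param params Output of [segmentation_params()].
#' @return Integer label matrix (0 = background), with attribute
#'   `thresholds` recording the class boundaries used.
#' @export
segment_nuclei <- function(blue, params = segmentation_params()) {
  stop_if_not_matrix(blue, "blue")
  sm <- smooth_plane(blue, params$smoothing_sigma)
  thr <- params$thresholds
  if (is.null(thr)) {
    thr <- threshold_three_class(sm)
    if (!all(is.finite(thr)) || class_contrast(sm, thr) < params$min_contrast)
      return(structure(matrix(0L, nrow(blue), ncol(blue)), thresholds = thr))
  }
  mask <- sm > thr[2]
  mask <- as_base_matrix(EBImage::fillHull(EBImage::Image(mask * 1)))
  if (!any(mask > 0))
    return(structure(matrix(0L, nrow(blue), ncol(blue)), thresholds = thr))
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                            ext = params$watershed_ext)
  lab <- as_base_matrix(lab)
  lab <- filter_labels(lab, params)
  structure(relabel(lab), thresholds = thr)
}

filter_labels <- function(lab, params) {
  if (!any(lab > 0)) return(lab)
  areas <- tabulate(lab[lab > 0])
  drop <- which(areas < params$min_area | areas > params$max_area)
  if (params$exclude_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, border[border > 0])
  }
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab
}

# Compress labels to the contiguous set 1..K (preserving order).
relabel <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(matrix(0L, nrow(lab), ncol(lab)))
  map <- integer(max(u)); map[u] <- seq_along(u)
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  storage.mode(out) <- "integer"
  out
}

#' Segment cell bodies around nucleus seeds
#'
#' The cell mask is the union of the middle and top intensity classes of the
#' smoothed blue channel; pixels are assigned to nuclei by seeded
#' propagation (Voronoi-like region growing constrained to the mask, as in
#' CellProfiler's secondary-object identification). Cytoplasm regions with
#' no nucleus are discarded; every nucleus pixel is forced into its own
#' cell so containment holds by construction.
#'
#' @param blue Blue-channel intensity matrix (same raster the nuclei came
#'   from).
#' @param nuclei Nucleus label matrix from [segment_nuclei()].
#' @param params Output of [segmentation_params()].
#' @return Integer label matrix of cells; labels match `nuclei`.
#' @export
segment_cells <- function(blue, nuclei, params = segmentation_params()) {
  stop_if_not_matrix(blue, "blue")
  if (!all(dim(blue) == dim(nuclei)))
    stop("`blue` and `nuclei` have different shapes")
  if (!any(nuclei > 0)) return(matrix(0L, nrow(blue), ncol(blue)))
  sm <- smooth_plane(blue, params$smoothing_sigma)
  thr <- attr(nuclei, "thresholds")
  if (is.null(thr)) thr <- params$thresholds
  if (is.null(thr)) thr <- threshold_three_class(sm)
  mask <- sm > thr[1]
  mask[nuclei > 0] <- TRUE
  lab <- EBImage::propagate(EBImage::Image(sm), EBImage::Image(nuclei),
                            mask = mask)
  lab <- as_base_matrix(lab)
  lab[nuclei > 0] <- nuclei[nuclei > 0]
  storage.mode(lab) <- "integer"
  lab
}

#' Derive cytoplasm labels by set difference
#'
#' Per label, cytoplasm = cell pixels minus nucleus pixels. Labels whose
#' cytoplasm is empty are allowed and reported in the `empty_cytoplasm`
#' attribute.
#'
#' @param cells,nuclei Co-registered label matrices with matching labels.
#' @return Integer cytoplasm label matrix with attribute `empty_cytoplasm`
#'   (integer vector of affected labels).
#' @export
derive_cytoplasm <- function(cells, nuclei) {
  if (!all(dim(cells) == dim(nuclei)))
    stop("`cells` and `nuclei` have different shapes")
  viol <- nuclei > 0 & cells != nuclei
  if (any(viol))
    stop(sprintf("%d nucleus pixel(s) fall outside their cell (containment violated)",
                 sum(viol)))
  cyto <- cells
  cyto[nuclei > 0] <- 0L
  storage.mode(cyto) <- "integer"
  nuc_labels <- unique(nuclei[nuclei > 0])
  empty <- sort(setdiff(nuc_labels, unique(cyto[cyto > 0])))
  structure(cyto, empty_cytoplasm = as.integer(empty))
}

#' Segment one field end to end
#'
#' Convenience wrapper: nuclei, cells and cytoplasm from a `field_image`.
#'
#' @param img A `field_image`.
#' @param params Output of [segmentation_params()].
#' @return list with `nuclei`, `cells`, `cytoplasm` label matrices.
#' @export
segment_field <- function(img, params = segmentation_params()) {
  nuclei <- segment_nuclei(img$blue, params)
  cells <- segment_cells(img$blue, nuclei, params)
  cyto <- derive_cytoplasm(cells, nuclei)
  list(nuclei = nuclei, cells = cells, cytoplasm = cyto)
}
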