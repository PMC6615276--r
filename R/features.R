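gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(live <- b != 0)) {
    t <- a[live] %% b[live]
    a[live] <- b[live]
    b[live] <- t
  }
  a
}

# Exposed pixel-edge count per label (4-neighbourhood + image border).
exposed_edges <- function(lab) {
  H <- nrow(lab); W <- ncol(lab); K <- max(lab)
  cnt <- numeric(K)
  add <- function(a, b) {
    m <- a != b & a > 0
    if (any(m)) cnt <<- cnt + tabulate(a[m], K)
  }
  add(lab[, -W, drop = FALSE], lab[, -1, drop = FALSE])
  add(lab[, -1, drop = FALSE], lab[, -W, drop = FALSE])
  add(lab[-H, , drop = FALSE], lab[-1, , drop = FALSE])
  add(lab[-1, , drop = FALSE], lab[-H, , drop = FALSE])
  for (edge in list(lab[1, ], lab[H, ], lab[, 1], lab[, W])) {
    v <- edge[edge > 0]
    if (length(v)) cnt <- cnt + tabulate(v, K)
  }
  cnt
}

# Convex-hull area of a pixel set, expressed in equivalent lattice pixels
# (Pick's theorem: interior + boundary lattice points = A + B/2 + 1).
# Pixel coordinates are unique by construction.
hull_pixels <- function(r, c) {
  if (length(r) < 3) return(length(r))
  h <- grDevices::chull(r, c)
  hx <- r[h]; hy <- c[h]
  n <- length(h)
  if (n < 3) return(length(r))
  nx <- c(hx[-1], hx[1]); ny <- c(hy[-1], hy[1])
  A <- abs(sum(hx * ny - nx * hy)) / 2
  B <- sum(gcd2(nx - hx, ny - hy))
  A + B / 2 + 1
}

moment_eccentricity <- function(r, c) {
  if (length(r) < 2) return(0)
  mr <- mean(r); mc <- mean(c)
  # 1/12 terms: second moment of the unit pixel itself
  mu20 <- mean((r - mr)^2) + 1 / 12
  mu02 <- mean((c - mc)^2) + 1 / 12
  mu11 <- mean((r - mr) * (c - mc))
  d <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  lmax <- (mu20 + mu02 + d) / 2
  lmin <- (mu20 + mu02 - d) / 2
  if (lmax <= 0) return(0)
  e <- sqrt(max(0, 1 - lmin / lmax))
  min(e, 1 - 1e-12)
}

#' Shape features of a label mask
#'
#' Per label: area (pixel count), perimeter (Cauchy-Crofton estimator:
#' pi/4 times the number of exposed pixel edges), solidity (area over
#' convex-hull area, hull area in equivalent lattice pixels via Pick's
#' theorem, clamped to \[0, 1\]), eccentricity of the moment-matched ellipse
#' (`sqrt(1 - lmin/lmax)` of the second-central-moment eigenvalues), and
#' centroid.
#'
#' @param lab Integer label matrix (0 = background).
#' @return data.frame with one row per label.
#' @export
shape_features <- function(lab) {
  if (!any(lab > 0))
    return(data.frame(label = integer(), area = numeric(),
                      perimeter = numeric(), solidity = numeric(),
                      eccentricity = numeric(), centroid_r = numeric(),
                      centroid_c = numeric()))
  idx <- which(lab > 0)
  labs <- lab[idx]
  H <- nrow(lab)
  r <- (idx - 1L) %% H + 1L
  c <- (idx - 1L) %/% H + 1L
  bylab <- split(seq_along(idx), labs)
  labels <- as.integer(names(bylab))
  per <- exposed_edges(lab) * pi / 4
  nlab <- length(bylab)
  area <- integer(nlab); sol <- numeric(nlab); ecc <- numeric(nlab)
  cr <- numeric(nlab); cc <- numeric(nlab)
  for (i in seq_len(nlab)) {
    ii <- bylab[[i]]
    ri <- r[ii]; ci <- c[ii]
    area[i] <- length(ii)
    sol[i] <- min(1, length(ii) / hull_pixels(ri, ci))
    ecc[i] <- moment_eccentricity(ri, ci)
    cr[i] <- mean(ri); cc[i] <- mean(ci)
  }
  data.frame(label = labels, area = area, perimeter = per[labels],
             solidity = sol, eccentricity = ecc,
             centroid_r = cr, centroid_c = cc, row.names = NULL)
}

median_by_label <- function(raster, lab, labels) {
  idx <- which(lab > 0)
  v <- split(raster[idx], lab[idx])
  out <- rep(NA_real_, length(labels))
  hit <- match(names(v), as.character(labels))
  out[hit] <- vapply(v, stats::median, numeric(1))
  out
}

#' Count segmented cells
#'
#' @param nuclei Nucleus label matrix.
#' @return Number of distinct nonzero labels.
#' @export
count_cells <- function(nuclei) {
  length(unique(nuclei[nuclei > 0]))
}

#' Measure per-cell morphometric and intensity features
#'
#' For each cell: nucleus and cell areas and perimeters, solidity and
#' eccentricity of both compartments, and median OCT4 (green) and CCNB1
#' (red) intensities over the nucleus and cytoplasm pixels. Cells with an
#' empty cytoplasm get `NA` cytoplasmic medians and are flagged.
#'
#' @param nuclei,cells,cytoplasm Co-registered label matrices (see
#'   [segment_field()]).
#' @param green,red Marker intensity matrices (OCT4, CCNB1).
#' @param meta Optional list with `plate`, `well`, `site`, `treatment`
#'   carried into every row.
#' @return data.frame of cell records, one row per cell.
#' @export
measure_cells <- function(nuclei, cells, cytoplasm, green, red, meta = list()) {
  stop_if_not_matrix(green, "green")
  stop_if_not_matrix(red, "red")
  cell_labels <- unique(cells[cells > 0])
  nuc_labels <- unique(nuclei[nuclei > 0])
  orphan <- setdiff(cell_labels, nuc_labels)
  if (length(orphan))
    stop("cell label(s) without a nucleus: ", paste(orphan, collapse = ", "))
  nshape <- shape_features(nuclei)
  if (nrow(nshape) == 0) return(empty_cell_records(meta))
  cshape <- shape_features(cells)
  labels <- nshape$label
  ci <- match(labels, cshape$label)
  empty_cyto <- attr(cytoplasm, "empty_cytoplasm")
  rec <- data.frame(
    plate = meta$plate %||% NA_character_,
    well = meta$well %||% NA_character_,
    site = meta$site %||% NA_integer_,
    treatment = meta$treatment %||% NA_character_,
    label = labels,
    nucleus_area = nshape$area,
    cell_area = cshape$area[ci],
    nucleus_perimeter = nshape$perimeter,
    cell_perimeter = cshape$perimeter[ci],
    solidity_nucleus = nshape$solidity,
    solidity_cell = cshape$solidity[ci],
    eccentricity_nucleus = nshape$eccentricity,
    eccentricity_cell = cshape$eccentricity[ci],
    oct4_nuc_median = median_by_label(green, nuclei, labels),
    oct4_cyto_median = median_by_label(green, cytoplasm, labels),
    ccnb1_nuc_median = median_by_label(red, nuclei, labels),
    ccnb1_cyto_median = median_by_label(red, cytoplasm, labels),
    empty_cytoplasm = labels %in% (empty_cyto %||% integer()),
    stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  rec
}

empty_cell_records <- function(meta = list()) {
  data.frame(plate = character(), well = character(), site = integer(),
             treatment = character(), label = integer(),
             nucleus_area = numeric(), cell_area = numeric(),
             nucleus_perimeter = numeric(), cell_perimeter = numeric(),
             solidity_nucleus = numeric(), solidity_cell = numeric(),
             eccentricity_nucleus = numeric(), eccentricity_cell = numeric(),
             oct4_nuc_median = numeric(), oct4_cyto_median = numeric(),
             ccnb1_nuc_median = numeric(), ccnb1_cyto_median = numeric(),
             empty_cytoplasm = logical(), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
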