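#' Centered-correlation distance
#'
#' `1 - r`, with `r` the Pearson correlation of the mean-centered vectors
#' (the "centered correlation" of Cluster 3.0). The uncentered variant
#' skips the mean-centering (cosine similarity).
#'
#' @param x,y Numeric vectors of equal length >= 2. If `y` is `NULL`, `x`
#'   must be a matrix and the full distance matrix over its rows is
#'   returned.
#' @param centered Use the centered (Pearson) form.
#' @return A scalar in \[0, 2\], or a `dist` over matrix rows.
#' @export
centered_cor_dist <- function(x, y = NULL, centered = TRUE) {
  if (is.null(y)) {
    stop_if_not_matrix(x)
    bad <- which(apply(x, 1, stats::sd) == 0)
    if (length(bad))
      stop("zero-variance row(s): ",
           paste(rownames(x)[bad] %||% bad, collapse = ", "))
    r <- if (centered) stats::cor(t(x)) else uncentered_cor(x)
    return(stats::as.dist(1 - r))
  }
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in input vectors")
  if (centered) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("zero variance in input vector")
    1 - stats::cor(x, y)
  } else {
    den <- sqrt(sum(x^2) * sum(y^2))
    if (den == 0) stop("zero norm in input vector")
    1 - sum(x * y) / den
  }
}

uncentered_cor <- function(x) {
  n <- sqrt(rowSums(x^2))
  if (any(n == 0)) stop("zero-norm row(s) for uncentered correlation")
  tcrossprod(x / n)
}

#' Hierarchical clustering of a phenotypic profile
#'
#' Agglomerative average-linkage (UPGMA) clustering of the treatments
#' (rows) or features (columns) under the centered-correlation distance,
#' as produced by Cluster 3.0 on percentage-of-control profiles.
#'
#' @param profile Numeric matrix (e.g. a `phenotypic_profile`).
#' @param axis `"rows"` (treatments) or `"columns"` (features).
#' @param metric `"centered"` or `"uncentered"` correlation distance.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An [stats::hclust] tree with a `metric` attribute.
#' @export
profile_hclust <- function(profile, axis = c("rows", "columns"),
                           metric = c("centered", "uncentered"),
                           linkage = c("average", "complete", "single")) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  m <- unclass(profile)
  if (axis == "columns") m <- t(m)
  if (nrow(m) < 2) stop("need at least 2 items on the chosen axis")
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)
    stop("non-finite profile entries at: ",
         paste(sprintf("[%s, %s]",
                       rownames(m)[bad[, 1]] %||% bad[, 1],
                       colnames(m)[bad[, 2]] %||% bad[, 2]),
               collapse = ", "))
  }
  d <- centered_cor_dist(m, centered = metric == "centered")
  tree <- stats::hclust(d, method = linkage)
  attr(tree, "metric") <- metric
  tree
}

# Order cluster ids by first appearance along the dendrogram leaf order.
order_by_leaf <- function(membership, leaf_order) {
  first <- vapply(unique(membership[leaf_order]), function(u) u, numeric(1))
  match(membership, first)
}

# Cut a branch (subset of leaves) of `tree` into k clusters by replaying
# its internal merges in height order (hclust merge rows are height-sorted
# for monotone linkages, so merge-index order suffices).
branch_cut <- function(tree, leaves, k) {
  n <- length(tree$order) + 1L  # leaf count of the full tree
  stopifnot(k >= 1, k <= length(leaves))
  inset <- rep(FALSE, n); inset[leaves] <- TRUE
  rep_of <- stats::setNames(leaves, leaves)
  leaves_of_node <- vector("list", nrow(tree$merge))
  n_clusters <- length(leaves)
  for (mi in seq_len(nrow(tree$merge))) {
    ch <- tree$merge[mi, ]
    get_leaves <- function(c)
      if (c < 0) -c else leaves_of_node[[c]]
    ll <- get_leaves(ch[1]); rl <- get_leaves(ch[2])
    leaves_of_node[[mi]] <- c(ll, rl)
    if (all(inset[c(ll, rl)]) && length(ll) && length(rl)) {
      if (n_clusters <= k) next
      a <- rep_of[[as.character(ll[1])]]
      b <- rep_of[[as.character(rl[1])]]
      if (a != b) {
        rep_of[as.character(leaves_of_node[[mi]])] <- a
        n_clusters <- n_clusters - 1L
      }
    }
  }
  reps <- rep_of[as.character(leaves)]
  ids <- match(reps, unique(reps[order(match(leaves, tree$order))]))
  stats::setNames(ids, leaves)
}

#' Cut a clustering tree into nested, named clusters
#'
#' Top-level clusters are lettered A, B, ... in dendrogram order; a
#' sub-cut of cluster "B" into 2 yields "B.1", "B.2"; a further cut of
#' "B.2" yields "B.2a", "B.2b" — the naming scheme used for screen
#' sub-clusters.
#'
#' @param tree An [stats::hclust] tree.
#' @param k Top-level number of clusters.
#' @param sub Named list of sub-cuts, e.g. `list(B = 2, B.2 = 3)`; parents
#'   must be cut before children (process order = list order).
#' @return A `cluster_assignment` data.frame with `leaf` and `label`.
#' @export
cut_profile_tree <- function(tree, k = 2, sub = list()) {
  n <- length(tree$labels)
  if (k > n) stop("k exceeds the number of leaves")
  memb <- stats::cutree(tree, k = k)
  ids <- match(memb, unique(memb[tree$order]))
  labels <- LETTERS[ids]
  names(labels) <- tree$labels
  for (nm in names(sub)) {
    ksub <- sub[[nm]]
    sel <- which(labels == nm)
    if (!length(sel))
      stop(sprintf("no cluster labelled '%s' to sub-cut", nm))
    if (ksub > length(sel))
      stop(sprintf("sub-cut k=%d exceeds the %d leaves of cluster %s",
                   ksub, length(sel), nm))
    ids <- branch_cut(tree, sel, ksub)
    depth <- lengths(regmatches(nm, gregexpr("[.]", nm))) + 1L
    suffix <- if (depth == 1) paste0(".", ids) else letters[ids]
    labels[sel] <- paste0(nm, suffix)
  }
  out <- data.frame(leaf = tree$labels, label = unname(labels),
                    stringsAsFactors = FALSE)
  class(out) <- c("cluster_assignment", "data.frame")
  out
}

node_ids <- function(tree, prefix) {
  n <- nrow(tree$merge)
  ref <- function(v)
    ifelse(v < 0, sprintf("%s%dX", prefix, -v - 1L), sprintf("NODE%dX", v))
  data.frame(node = sprintf("NODE%dX", seq_len(n)),
             left = ref(tree$merge[, 1]), right = ref(tree$merge[, 2]),
             corr = 1 - tree$height, stringsAsFactors = FALSE)
}

#' Export a clustered profile in Cluster 3.0 / Java TreeView format
#'
#' Writes `<base>.cdt` (tab-delimited profile in dendrogram leaf order with
#' GID/NAME/GWEIGHT header and EWEIGHT line) and, when trees are given,
#' `<base>.gtr` / `<base>.atr` node files whose last column is
#' `1 - merge height` (the correlation at each join).
#'
#' @param profile Numeric matrix (treatments x features).
#' @param row_tree,col_tree Optional [stats::hclust] trees built from this
#'   matrix (labels must match its dimnames).
#' @param base Output path without extension.
#' @return Invisibly, the paths written.
#' @export
export_treeview <- function(profile, row_tree = NULL, col_tree = NULL, base) {
  m <- unclass(profile)
  rn <- rownames(m); cn <- colnames(m)
  if (!is.null(row_tree) && !identical(row_tree$labels, rn))
    stop("row tree labels do not match profile rownames")
  if (!is.null(col_tree) && !identical(col_tree$labels, cn))
    stop("column tree labels do not match profile colnames")
  paths <- character()
  if (!is.null(row_tree)) {
    g <- node_ids(row_tree, "GENE")
    p <- paste0(base, ".gtr")
    utils::write.table(g, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(col_tree)) {
    a <- node_ids(col_tree, "ARRY")
    p <- paste0(base, ".atr")
    utils::write.table(a, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  rord <- if (!is.null(row_tree)) row_tree$order else seq_along(rn)
  cord <- if (!is.null(col_tree)) col_tree$order else seq_along(cn)
  cdt <- paste0(base, ".cdt")
  con <- file(cdt, "w")
  on.exit(close(con))
  writeLines(paste(c("GID", "UID", "NAME", "GWEIGHT", cn[cord]),
                   collapse = "\t"), con)
  if (!is.null(col_tree))
    writeLines(paste(c("AID", "", "", "",
                       sprintf("ARRY%dX", cord - 1L)), collapse = "\t"), con)
  writeLines(paste(c("EWEIGHT", "", "", "", rep("1", length(cord))),
                   collapse = "\t"), con)
  for (i in rord) {
    writeLines(paste(c(sprintf("GENE%dX", i - 1L), rn[i], rn[i], "1",
                       format(m[i, cord], trim = TRUE, digits = 10)),
                     collapse = "\t"), con)
  }
  invisible(c(paths, cdt))
}

#' Render a profile heatmap to PNG
#'
#' Yellow above / blue below the 100% control level, black at control, with
#' rows and columns ordered by their dendrograms.
#'
#' @inheritParams export_treeview
#' @param path PNG path.
#' @param center Value mapped to black (default 100, the control POC).
#' @return Invisibly, `path`.
#' @export
plot_profile_heatmap <- function(profile, row_tree = NULL, col_tree = NULL,
                                 path, center = 100) {
  m <- unclass(profile)
  rord <- if (!is.null(row_tree)) row_tree$order else seq_len(nrow(m))
  cord <- if (!is.null(col_tree)) col_tree$order else seq_len(ncol(m))
  m <- m[rord, cord, drop = FALSE]
  span <- max(abs(m - center), na.rm = TRUE)
  if (span == 0) span <- 1
  breaks <- seq(center - span, center + span, length.out = 256)
  cols <- grDevices::colorRampPalette(c("blue", "black", "yellow"))(255)
  grDevices::png(path, width = 120 + 24 * ncol(m), height = 120 + 16 * nrow(m))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(8, 10, 2, 2))
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = cols, breaks = breaks, axes = FALSE)
  graphics::axis(1, at = seq(0, 1, length.out = ncol(m)),
                 labels = colnames(m), las = 2, cex.axis = 0.8)
  graphics::axis(2, at = seq(0, 1, length.out = nrow(m)),
                 labels = rev(rownames(m)), las = 2, cex.axis = 0.8)
  invisible(path)
}
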