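# Independent oracles and small fixtures used across test files.

# Naive O(n^3) UPGMA: average inter-cluster distance recomputed from the
# original distance matrix at every step. Returns sorted merge heights.
naive_upgma_heights <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}

# Exhaustive upper-tail hypergeometric: over all C(N, n) draws of the query
# from the universe, the fraction with >= k members of the K-set.
hyper_enum_p <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  inset <- draws <= K  # universe = 1..N with the K-set first
  mean(colSums(inset) >= k)
}

# Exact one-tailed Mann-Whitney by direct pair counting over all C(m+n, m)
# group assignments (independent of the package's rank-based route).
mw_enum_p <- function(x, y, alternative) {
  pooled <- c(x, y)
  m <- length(x)
  u_of <- function(xs, ys)
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  splits <- utils::combn(length(pooled), m)
  u_all <- apply(splits, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  if (alternative == "less") mean(u_all <= u_obs + 1e-9)
  else mean(u_all >= u_obs - 1e-9)
}

# Rasterized shapes as label masks.
disk_mask <- function(r, pad = 4) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  xy <- expand.grid(seq_len(n), seq_len(n))
  m <- matrix(as.integer((xy[[1]] - ctr)^2 + (xy[[2]] - ctr)^2 <= r^2), n, n)
  m
}

ellipse_mask <- function(a, b, theta = 0, pad = 4) {
  n <- 2 * (max(a, b) + pad) + 1
  ctr <- max(a, b) + pad + 1
  xy <- expand.grid(seq_len(n), seq_len(n))
  dx <- xy[[1]] - ctr; dy <- xy[[2]] - ctr
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  matrix(as.integer((u / a)^2 + (v / b)^2 <= 1), n, n)
}

# Minimal ground-truth row(s) for hand-built fields.
gt_cells <- function(x, y, nuc_r = 10, cell_r = 17, elong = 1, theta = 0,
                     amp = 0, oct4_nuc = 5000, oct4_cyto = 2000,
                     ccnb1_nuc = 3000, ccnb1_cyto = 2500) {
  n <- length(x)
  rep_out <- function(v) rep_len(v, n)
  data.frame(plate = rep_out("P1"), well = rep_out("A01"),
             site = rep_out(1L), treatment = rep_out("t"),
             cell_id = seq_len(n), x = x, y = y,
             nuc_a = rep_out(nuc_r * sqrt(elong)),
             nuc_b = rep_out(nuc_r / sqrt(elong)),
             cell_a = rep_out(cell_r * sqrt(elong)),
             cell_b = rep_out(cell_r / sqrt(elong)),
             theta = rep_out(theta), irregularity = rep_out(amp),
             phase = rep_out(0), oct4_nuc = rep_out(oct4_nuc),
             oct4_cyto = rep_out(oct4_cyto),
             ccnb1_nuc = rep_out(ccnb1_nuc),
             ccnb1_cyto = rep_out(ccnb1_cyto),
             overlap = rep_out(FALSE), stringsAsFactors = FALSE)
}

small_baseline <- function(...) {
  baseline_params(shape = c(128L, 128L), cells_per_field = 8, ...)
}

# Site summaries built directly (no imaging), for normalization tests.
fake_summaries <- function(plate, well, site, treatment, value,
                           feature = "oct4_nuc_median", count = 50) {
  n <- length(value)
  out <- data.frame(plate = rep_len(plate, n), well = rep_len(well, n),
                    site = rep_len(site, n),
                    treatment = rep_len(treatment, n),
                    count = rep_len(count, n), stringsAsFactors = FALSE)
  for (f in phenomir:::cell_feature_names()) out[[f]] <- rep_len(value, n)
  out[[feature]] <- value
  out$empty_site <- FALSE
  out
}
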