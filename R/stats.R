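#' Relative expression by the 2^-ddCt method
#'
#' Per measurement, `dCt = Ct_target - Ct_reference`; `ddCt` subtracts the
#' arithmetic mean `dCt` of the control condition; relative expression is
#' `2^-ddCt`, so the control group's mean `dCt` maps to fold 1.
#'
#' @param measurements data.frame with columns `sample`, `condition`,
#'   `target_ct`, `reference_ct` (and optionally `gene`, processed
#'   separately).
#' @param control Value of `condition` identifying the reference group.
#' @return Input data.frame with `dct`, `ddct` and `fold` columns added.
#' @export
ddct_fold <- function(measurements, control = "control") {
  req <- c("sample", "condition", "target_ct", "reference_ct")
  missing <- setdiff(req, names(measurements))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  bad <- !is.finite(measurements$reference_ct)
  if (any(bad))
    stop("missing reference-gene Ct for sample(s): ",
         paste(measurements$sample[bad], collapse = ", "))
  if (any(!is.finite(measurements$target_ct)))
    stop("non-finite target Ct value(s)")
  split_by <- if ("gene" %in% names(measurements))
    measurements$gene else rep("gene", nrow(measurements))
  parts <- lapply(split(measurements, split_by), function(d) {
    if (!any(d$condition == control))
      stop("no control measurements for gene ", d$gene[1] %||% "")
    d$dct <- d$target_ct - d$reference_ct
    ref <- mean(d$dct[d$condition == control])
    d$ddct <- d$dct - ref
    d$fold <- 2^(-d$ddct)
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# All C(m+n, m) splits of the pooled sample: exact permutation null of the
# Mann-Whitney U (handles ties through mid-ranks of the observed data).
mw_exact_p <- function(x, y, alternative) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  splits <- utils::combn(m + n, m)
  u_all <- colSums(matrix(r[splits], nrow = m)) - m * (m + 1) / 2
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  eps <- 1e-9
  if (alternative == "less") mean(u_all <= u_obs + eps)
  else mean(u_all >= u_obs - eps)
}

#' One-tailed Mann-Whitney (Wilcoxon rank-sum) test
#'
#' The U statistic with exact permutation p-value for small samples
#' (combined n <= `exact_limit`, ties handled by mid-ranks over all
#' rearrangements of the observed data) and a tie-corrected normal
#' approximation with continuity correction otherwise. The direction must
#' be stated explicitly.
#'
#' @param x,y Numeric samples.
#' @param alternative `"less"` (x tends smaller than y) or `"greater"`.
#' @param exact_limit Largest combined sample size for exact enumeration.
#' @return A `test_result` data.frame: method, statistic (U of `x`),
#'   p.value, tail, groups.
#' @export
mann_whitney <- function(x, y, alternative = c("less", "greater"),
                         exact_limit = 12) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  m <- length(x); n <- length(y)
  u <- sum(rank(c(x, y))[seq_len(m)]) - m * (m + 1) / 2
  if (m + n <= exact_limit) {
    p <- mw_exact_p(x, y, alternative)
    method <- "Mann-Whitney (exact)"
  } else {
    N <- m + n
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tie_term)
    mu <- m * n / 2
    z <- if (alternative == "less") (u + 0.5 - mu) / sqrt(sigma2)
    else (u - 0.5 - mu) / sqrt(sigma2)
    p <- if (alternative == "less") stats::pnorm(z)
    else stats::pnorm(z, lower.tail = FALSE)
    method <- "Mann-Whitney (normal approximation)"
  }
  test_result(method, statistic = u, p.value = min(max(p, 0), 1),
              tail = alternative, groups = "x vs y")
}

test_result <- function(method, statistic, p.value, tail = NA_character_,
                        groups = NA_character_, adjust = NA_character_,
                        p.adjusted = NA_real_) {
  out <- data.frame(method = method, statistic = statistic,
                    p.value = p.value, tail = tail, groups = groups,
                    adjust = adjust, p.adjusted = p.adjusted,
                    stringsAsFactors = FALSE)
  class(out) <- c("test_result", "data.frame")
  out
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square p-value on g - 1 degrees of
#' freedom (delegates to [stats::kruskal.test]).
#'
#' @param groups List of numeric vectors (>= 2 groups).
#' @return A `test_result` data.frame.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  values <- unlist(groups)
  if (length(unique(values)) < 2)
    stop("all values identical: zero variance")
  kt <- stats::kruskal.test(groups)
  test_result("Kruskal-Wallis", statistic = unname(kt$statistic),
              p.value = kt$p.value, tail = "two.sided",
              groups = paste(length(groups), "groups"))
}

#' Dunn's multiple-comparison post hoc test
#'
#' Following a Kruskal-Wallis test: for each comparison, the difference of
#' mean ranks divided by its tie-corrected standard error,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with
#' `T = sum(t^3 - t) / (12 (N - 1))`, two-sided normal p, then a
#' Bonferroni-style family adjustment (`min(1, m p)`; Holm available).
#'
#' @param groups Named list of numeric vectors.
#' @param comparisons `"all"` pairs or `"vs_control"`.
#' @param control Control group name for `comparisons = "vs_control"`.
#' @param adjust `"bonferroni"` (default), `"holm"` or `"none"`.
#' @return A `test_result` data.frame, one row per comparison.
#' @export
dunn_test <- function(groups, comparisons = c("all", "vs_control"),
                      control = NULL, adjust = c("bonferroni", "holm", "none")) {
  comparisons <- match.arg(comparisons)
  adjust <- match.arg(adjust)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  g <- names(groups)
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(g, lengths(groups))
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, labels, mean)
  nn <- tapply(r, labels, length)
  ties <- table(values)
  T <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- if (comparisons == "all") {
    utils::combn(g, 2, simplify = FALSE)
  } else {
    if (is.null(control) || !control %in% g)
      stop("comparison names a missing group: ", control %||% "<NULL>")
    lapply(setdiff(g, control), function(o) c(control, o))
  }
  rows <- lapply(pairs, function(pr) {
    if (!all(pr %in% g))
      stop("comparison names a missing group: ",
           paste(setdiff(pr, g), collapse = ", "))
    se <- sqrt((N * (N + 1) / 12 - T) * (1 / nn[[pr[1]]] + 1 / nn[[pr[2]]]))
    z <- if (se > 0) (rbar[[pr[1]]] - rbar[[pr[2]]]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    test_result("Dunn", statistic = z, p.value = p, tail = "two.sided",
                groups = paste(pr, collapse = " vs "))
  })
  out <- do.call(rbind, rows)
  out$adjust <- adjust
  out$p.adjusted <- switch(adjust,
    bonferroni = pmin(1, out$p.value * nrow(out)),
    holm = stats::p.adjust(out$p.value, "holm"),
    none = out$p.value)
  out
}
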