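test_that("2^-ddCt folds reproduce hand arithmetic", {
  tab <- data.frame(sample = c("c1", "t1"),
                    condition = c("control", "treated"),
                    target_ct = c(25, 24), reference_ct = c(20, 20))
  res <- ddct_fold(tab)
  expect_equal(res$ddct[res$sample == "t1"], -1)
  expect_equal(res$fold[res$sample == "t1"], 2)
  expect_equal(res$fold[res$sample == "c1"], 1)

  # ddCt of 1 halves, -2 quadruples
  tab2 <- data.frame(sample = c("c1", "c2", "t1", "t2"),
                     condition = c("control", "control", "treated", "treated"),
                     target_ct = c(22, 22, 23, 20), reference_ct = 18)
  res2 <- ddct_fold(tab2)
  expect_equal(res2$fold[res2$sample == "t1"], 0.5)
  expect_equal(res2$fold[res2$sample == "t2"], 4)
  # treated dCt equal to the control mean gives fold 1
  tab3 <- tab2; tab3$target_ct[3:4] <- 22
  expect_equal(ddct_fold(tab3)$fold[3:4], c(1, 1))
})

test_that("folds are invariant to a global Ct shift and need reference Cts", {
  set.seed(2)
  tab <- data.frame(sample = paste0("s", 1:8),
                    condition = rep(c("control", "treated"), each = 4),
                    target_ct = rnorm(8, 24), reference_ct = rnorm(8, 19))
  f1 <- ddct_fold(tab)$fold
  tab2 <- tab
  tab2$target_ct <- tab2$target_ct + 3.7
  tab2$reference_ct <- tab2$reference_ct + 3.7
  expect_equal(ddct_fold(tab2)$fold, f1, tolerance = 1e-12)
  tab$reference_ct[2] <- NA
  expect_error(ddct_fold(tab), "s2")
})

test_that("exact one-tailed Mann-Whitney enumerates all rank splits", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$p.value, 1 / 20)
  expect_equal(r$statistic, 0)
  # symmetry on identical multisets
  x <- c(2, 2, 5, 7)
  expect_gte(mann_whitney(x, x, "less")$p.value, 0.5)
  expect_gte(mann_whitney(x, x, "greater")$p.value, 0.5)
  # agreement with the independent pair-counting oracle, with and without ties
  set.seed(8)
  for (i in 1:15) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    x <- sample(1:6, m, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    alt <- sample(c("less", "greater"), 1)
    expect_equal(mann_whitney(x, y, alt)$p.value, mw_enum_p(x, y, alt),
                 info = sprintf("case %d", i))
  }
  # tie-free case also agrees with the classical exact distribution
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(mann_whitney(x, y, "less")$p.value,
                 stats::wilcox.test(x, y, alternative = "less",
                                    exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("large-sample Mann-Whitney approximates the exact tail", {
  set.seed(4)
  x <- rnorm(15); y <- rnorm(18, 0.5)
  approx_p <- mann_whitney(x, y, "less")$p.value
  ref <- stats::wilcox.test(x, y, alternative = "less", exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(approx_p, ref, tolerance = 1e-10)
})

test_that("Kruskal-Wallis reproduces the hand-ranked H and is exchangeable", {
  r <- kruskal_wallis(list(1:3, 4:6, 7:9))
  # rank sums 6, 15, 24 over N = 9: H = 7.2
  expect_equal(r$statistic, 7.2)
  expect_equal(r$p.value, stats::pchisq(7.2, df = 2, lower.tail = FALSE))
  set.seed(6)
  g <- list(rnorm(5), rnorm(6), rnorm(4))
  h1 <- kruskal_wallis(g)$statistic
  h2 <- kruskal_wallis(g[c(3, 1, 2)])$statistic
  expect_equal(h1, h2)
  expect_error(kruskal_wallis(list(c(2, 2), c(2, 2))), "identical")
})

test_that("Dunn z matches the closed formula with tie correction", {
  groups <- list(a = c(1, 3, 5, 7), b = c(2, 4, 6, 8), c = c(10, 12, 14, 16))
  res <- dunn_test(groups)
  vals <- unlist(groups)
  r <- rank(vals)
  rbar <- tapply(r, rep(names(groups), lengths(groups)), mean)
  N <- length(vals)
  byhand <- function(i, j)
    (rbar[[i]] - rbar[[j]]) / sqrt((N * (N + 1) / 12) * (1 / 4 + 1 / 4))
  expect_equal(res$statistic[res$groups == "a vs b"], byhand("a", "b"))
  expect_equal(res$statistic[res$groups == "a vs c"], byhand("a", "c"))
  expect_equal(res$statistic[res$groups == "b vs c"], byhand("b", "c"))
  # two-sided p and Bonferroni-style family adjustment
  expect_equal(res$p.value, 2 * stats::pnorm(-abs(res$statistic)))
  expect_equal(res$p.adjusted, pmin(1, res$p.value * 3))
  expect_true(all(res$p.adjusted >= res$p.value))

  # identical groups: z = 0, p = 1 (tie-corrected SE stays positive)
  same <- dunn_test(list(g1 = c(1, 2, 3), g2 = c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  # vs-control comparisons and missing-group errors
  vc <- dunn_test(groups, comparisons = "vs_control", control = "a")
  expect_equal(nrow(vc), 2)
  expect_true(all(grepl("^a vs ", vc$groups)))
  expect_error(dunn_test(groups, comparisons = "vs_control", control = "zz"),
               "missing group")
  # Holm adjustment is a monotone transform of raw p
  res_h <- dunn_test(groups, adjust = "holm")
  ord <- order(res_h$p.value)
  expect_true(all(diff(res_h$p.adjusted[ord]) >= -1e-12))
})
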