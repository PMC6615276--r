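test_that("centered correlation distance matches the direct formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(centered_cor_dist(x, x), 0)
  expect_equal(centered_cor_dist(x, -x), 2)
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(9); b <- rnorm(9)
    byhand <- 1 - sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(centered_cor_dist(a, b), byhand, tolerance = 1e-12)
  }
  expect_error(centered_cor_dist(rep(1, 5), rnorm(5)), "variance")
})

test_that("identical rows merge first at height zero", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 1, 0, 2),
             d = c(0, 5, 1, 3))
  tree <- profile_hclust(m, axis = "rows")
  expect_equal(min(tree$height), 0)
  first <- tree$merge[1, ]
  expect_setequal(tree$labels[-first], c("a", "b"))
})

test_that("average-linkage merge heights match a naive UPGMA oracle", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(3:7, 1)
    m <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(paste0("r", 1:n), NULL))
    tree <- profile_hclust(m, axis = "rows")
    D <- as.matrix(centered_cor_dist(m))
    expect_equal(sort(tree$height), naive_upgma_heights(D),
                 tolerance = 1e-10)
  }
})

test_that("clustering is invariant to positive affine row transforms", {
  set.seed(11)
  m <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(letters[1:8], NULL))
  t1 <- profile_hclust(m)
  m2 <- m * rep(runif(8, 0.5, 4), 5) + rep(rnorm(8, 0, 10), 5)
  t2 <- profile_hclust(m2)
  expect_equal(t1$merge, t2$merge)
  expect_equal(t1$height, t2$height, tolerance = 1e-10)
})

test_that("non-finite profile entries are reported by cell", {
  m <- matrix(rnorm(12), 4, 3, dimnames = list(letters[1:4], LETTERS[1:3]))
  m[2, 3] <- NA
  expect_error(profile_hclust(m), "b.*C")
})

test_that("nested cuts recover planted structure with hierarchical labels", {
  set.seed(3)
  base <- rnorm(6)
  mk <- function(center, n, noise = 0.05)
    t(replicate(n, center + rnorm(6, 0, noise)))
  m <- rbind(mk(base + c(3, 0, 0, 0, 0, 0), 4),
             mk(-base, 3),
             mk(-base + c(0, 0, 4, 4, 0, 0), 3))
  rownames(m) <- paste0("t", 1:10)
  tree <- profile_hclust(m)
  top <- cut_profile_tree(tree, k = 2)
  expect_setequal(unique(top$label), c("A", "B"))
  # the group of 4 is one top-level cluster, the two groups of 3 the other
  g1 <- top$label[match(paste0("t", 1:4), top$leaf)]
  g2 <- top$label[match(paste0("t", 5:10), top$leaf)]
  expect_equal(length(unique(g1)), 1)
  expect_equal(length(unique(g2)), 1)
  expect_false(unique(g1) == unique(g2))
  sub_label <- unique(g2)
  cut2 <- cut_profile_tree(tree, k = 2,
                           sub = stats::setNames(list(2), sub_label))
  labs2 <- cut2$label[match(paste0("t", 5:10), cut2$leaf)]
  expect_setequal(unique(labs2), paste0(sub_label, c(".1", ".2")))
  expect_equal(length(unique(labs2[1:3])), 1)
  expect_equal(length(unique(labs2[4:6])), 1)
  # trivial cuts
  expect_equal(unique(cut_profile_tree(tree, k = 1)$label), "A")
  expect_equal(length(unique(cut_profile_tree(tree, k = 10)$label)), 10)
  expect_error(cut_profile_tree(tree, k = 11), "leaves")
})

test_that("the recovered partition ignores input row order", {
  set.seed(5)
  m <- rbind(matrix(rnorm(4 * 6, 2), 4, 6), matrix(rnorm(4 * 6, -2), 4, 6))
  m[, 1] <- c(rep(5, 4), rep(-5, 4)) + rnorm(8, 0, 0.1)
  rownames(m) <- paste0("t", 1:8)
  c1 <- cut_profile_tree(profile_hclust(m), k = 2)
  perm <- sample.int(8)
  c2 <- cut_profile_tree(profile_hclust(m[perm, ]), k = 2)
  part <- function(cl) unname(split(cl$leaf, cl$label))
  same <- function(p, q) setequal(lapply(p, sort), lapply(q, sort))
  expect_true(same(part(c1), part(c2)))
})

test_that("TreeView export round-trips values and leaf order", {
  set.seed(9)
  m <- matrix(round(rnorm(5 * 4, 100, 20), 3), 5, 4,
              dimnames = list(paste0("miR", 1:5), paste0("f", 1:4)))
  rt <- profile_hclust(m, axis = "rows")
  ct <- profile_hclust(m, axis = "columns")
  base <- file.path(withr::local_tempdir(), "toy")
  paths <- export_treeview(m, rt, ct, base)
  gtr <- utils::read.delim(paste0(base, ".gtr"), header = FALSE)
  atr <- utils::read.delim(paste0(base, ".atr"), header = FALSE)
  expect_equal(nrow(gtr), nrow(m) - 1)
  expect_equal(nrow(atr), ncol(m) - 1)
  expect_equal(gtr$V4, 1 - rt$height, tolerance = 1e-10)
  cdt <- utils::read.delim(paste0(base, ".cdt"), header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  body <- cdt[cdt$GID != "AID" & cdt$GID != "EWEIGHT", , drop = FALSE]
  expect_equal(body$NAME, rownames(m)[rt$order])
  vals <- as.matrix(body[, 5:8])
  mode(vals) <- "numeric"
  expect_equal(unname(vals), unname(m[rt$order, ct$order]),
               tolerance = 1e-9)
  expect_error(export_treeview(m[1:4, ], rt, ct, base), "labels")
  png_path <- file.path(dirname(base), "heat.png")
  plot_profile_heatmap(m, rt, ct, png_path)
  expect_true(file.size(png_path) > 0)
})
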