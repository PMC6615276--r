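toy_table <- function() {
  read_targetscan(system.file("extdata", "targetscan_toy.tsv",
                              package = "phenomir"))
}

test_that("target tables are species-filtered, de-duplicated and family-aware", {
  tab <- toy_table()
  # mouse rows dropped
  expect_false(any(grepl("Lefty1|Dnmt3a", unlist(tab$targets))))
  # duplicate (miR, gene) rows collapse
  expect_equal(sum(tab$targets[["miR-29b-3p"]] == "DNMT3A"), 1)
  # family fallback: miR-363-3p is not listed as a mature name
  expect_false("miR-363-3p" %in% names(tab$targets))
  expect_message(g <- phenomir:::resolve_targets("miR-363-3p", tab), "family")
  expect_setequal(g, tab$targets[["miR-92a-3p"]])
  expect_error(phenomir:::resolve_targets("miR-999-5p", tab), "miR-999")

  # 3-row file with one non-human row keeps 2 genes
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("miR_Family\tMiRBase_ID\tGene_Symbol\tSpecies_ID",
               "miR-1\thsa-miR-1-3p\tGENEA\t9606",
               "miR-1\thsa-miR-1-3p\tGENEB\t9606",
               "miR-1\tmmu-miR-1-3p\tGenec\t10090"), f)
  t2 <- read_targetscan(f)
  expect_setequal(t2$targets[["miR-1-3p"]], c("GENEA", "GENEB"))
  # missing column errors by name
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("miR_Family\tGene_Symbol\tSpecies_ID",
               "miR-1\tGENEA\t9606"), f2)
  expect_error(read_targetscan(f2), "MiRBase_ID")
})

test_that("shared targets equal the brute-force intersection", {
  tab <- toy_table()
  one <- shared_targets("miR-101-3p", tab)
  expect_setequal(one, tab$targets[["miR-101-3p"]])
  mirs <- c("miR-92a-3p", "miR-101-3p", "miR-222-3p")
  sets <- lapply(mirs, function(m) tab$targets[[m]])
  all_genes <- unique(unlist(sets))
  brute <- sort(all_genes[vapply(all_genes, function(g)
    all(vapply(sets, function(s) g %in% s, logical(1))), logical(1))])
  expect_equal(shared_targets(mirs, tab), brute)
  # disjoint targets: empty intersection
  expect_length(shared_targets(c("miR-29b-3p", "miR-222-3p"), tab), 0)
  # relaxing the fraction can only grow the set
  strict <- shared_targets(mirs, tab, min_fraction = 1)
  loose <- shared_targets(mirs, tab, min_fraction = 0.6)
  expect_true(all(strict %in% loose))
})

test_that("hypergeometric p-values match exhaustive enumeration", {
  cases <- list(c(k = 3, K = 4, n = 5, N = 20), c(2, 6, 4, 15),
                c(1, 3, 3, 12), c(4, 8, 6, 25), c(0, 5, 4, 18))
  for (cs in cases) {
    k <- cs[[1]]; K <- cs[[2]]; n <- cs[[3]]; N <- cs[[4]]
    p_pkg <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(p_pkg, hyper_enum_p(k, K, n, N), tolerance = 1e-12,
                 info = paste(cs, collapse = ","))
  }
})

test_that("enrichment results carry sane overlaps, p and BH q values", {
  universe <- sprintf("G%02d", 1:20)
  collection <- list(S1 = universe[1:4], S2 = universe[3:10],
                     S3 = universe[11:20], S4 = universe)
  query <- universe[c(1, 2, 3, 5, 7)]
  res <- enrich_hyper(query, collection, universe)
  r1 <- res[res$set == "S1", ]
  expect_equal(r1$k, 3)
  expect_equal(r1$p, hyper_enum_p(3, 4, 5, 20), tolerance = 1e-12)
  # saturated set: all query genes hit, p = 1
  expect_equal(res$p[res$set == "S4"], 1)
  # zero overlap: p = 1
  res0 <- enrich_hyper(universe[1:2], list(S = universe[11:12]), universe)
  expect_equal(res0$p, 1)
  # BH q monotone in p-rank, and >= p
  expect_true(all(diff(res$q) >= -1e-12))
  expect_true(all(res$q >= res$p - 1e-12))
  # EASE is more conservative than the plain hypergeometric
  ease <- enrich_hyper(query, collection, universe, method = "ease")
  plain_p <- res$p[match(ease$set, res$set)]
  expect_true(all(ease$p >= plain_p - 1e-12))
  # genes outside the universe are dropped with a warning
  expect_warning(enrich_hyper(c(query, "NOT_A_GENE"), collection, universe),
                 "outside")
  expect_error(
    suppressWarnings(enrich_hyper("NOT_A_GENE", collection, universe)),
    "empty")
})

test_that("per-miR target counts within a gene list support thresholds", {
  tab <- toy_table()
  notch <- c("NOTCH1", "PSEN1", "JAG1", "DLL1", "DLL3", "HES1", "HEY1",
             "RBPJ", "MAML1", "ADAM10", "ADAM17", "NUMB", "LFNG", "DTX4",
             "NCOR2", "KAT2B", "CREBBP", "EP300", "DTX1", "NOTCH2")
  res <- mirs_targeting_genes(notch, c("miR-92a-3p", "miR-101-3p",
                                       "miR-222-3p", "miR-29b-3p"), tab)
  expect_equal(res$n_targets[res$mir == "miR-92a-3p"], 12)
  expect_equal(res$n_targets[res$mir == "miR-222-3p"], 1)
  expect_equal(res$n_targets[res$mir == "miR-29b-3p"], 0)
  over10 <- res$mir[res$n_targets > 10]
  under5 <- res$mir[res$n_targets < 5]
  expect_true("miR-92a-3p" %in% over10)
  expect_setequal(under5, c("miR-222-3p", "miR-29b-3p"))
  res2 <- mirs_targeting_genes(notch, "miR-92a-3p", tab)
  expect_equal(res2$n_targets, 12)
  # disjoint list: all zero
  res3 <- mirs_targeting_genes(c("XXX1", "XXX2"),
                               c("miR-92a-3p", "miR-101-3p"), tab)
  expect_true(all(res3$n_targets == 0))
})

test_that("Venn partitions enumerate regions with percentages of the union", {
  v <- compare_pathway_sets(list(A = c("a", "b"), B = c("b", "c"),
                                 C = c("c", "d")))
  expect_equal(attr(v, "union_size"), 4)
  get <- function(region) v$count[v$region == region]
  expect_equal(get("A"), 1)
  expect_length(get("B"), 0)  # nothing exclusive to B
  expect_equal(get("C"), 1)
  expect_length(get("A&B&C"), 0)
  expect_equal(sum(v$count), 4)
  expect_equal(v$pct[v$region == "A"], 25)
  # identical sets collapse to one fully-shared region
  v2 <- compare_pathway_sets(list(X = letters[1:5], Y = letters[1:5]))
  expect_equal(v2$region, "X&Y")
  expect_equal(v2$pct, 100)
  expect_error(compare_pathway_sets(list(a = "x")), "between 2 and 4")
  expect_error(compare_pathway_sets(as.list(setNames(letters[1:5],
                                                     letters[1:5]))),
               "between 2 and 4")
  # property: region counts always sum to the union size
  set.seed(13)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) sample(letters, sample(3:12, 1)))
    names(sets) <- c("A", "B", "C")
    v3 <- compare_pathway_sets(sets)
    expect_equal(sum(v3$count), length(unique(unlist(sets))))
    expect_lt(abs(sum(v3$pct) - 100), 0.5)
  }
})

test_that("GMT collections load and workbook reads demand an existing file", {
  sets <- read_gmt(system.file("extdata", "genesets_toy.gmt",
                               package = "phenomir"))
  expect_true("NOTCH_SIGNALING" %in% names(sets))
  expect_true(all(lengths(sets) > 0))
  expect_true("NOTCH1" %in% sets$NOTCH_SIGNALING)
  expect_error(read_pathway_workbook("no/such/file.xlsx"), "not found")
})
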