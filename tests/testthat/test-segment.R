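test_that("blank or constant fields segment to zero objects", {
  b <- small_baseline()
  blank <- render_field(gt_cells(numeric(0), numeric(0)), b, noise = TRUE,
                        seed = 3)
  expect_equal(count_cells(segment_nuclei(blank$blue)), 0)
  const <- matrix(500, 64, 64)
  expect_equal(count_cells(segment_nuclei(const)), 0)
})

test_that("disjoint rendered nuclei are recovered with high overlap", {
  b <- baseline_params(shape = c(256L, 256L))
  xs <- c(60, 60, 190, 190); ys <- c(60, 190, 60, 190)
  cells <- gt_cells(x = xs, y = ys, nuc_r = 9, cell_r = 16)
  img <- render_field(cells, b, noise = FALSE)
  nuclei <- segment_nuclei(img$blue)
  expect_equal(count_cells(nuclei), 4)
  true_nuc <- img$blue == b$blue_nucleus
  for (i in seq_along(xs)) {
    lab <- nuclei[round(xs[i]), round(ys[i])]
    expect_gt(lab, 0)
    seg_i <- nuclei == lab
    # ground-truth pixels of this nucleus: true class within 2 radii
    d2 <- outer((seq_len(256) - xs[i])^2, (seq_len(256) - ys[i])^2, "+")
    truth_i <- true_nuc & d2 <= (2 * 9)^2
    iou <- sum(seg_i & truth_i) / sum(seg_i | truth_i)
    expect_gte(iou, 0.8)
  }
})

test_that("touching nuclei are split by the watershed", {
  b <- baseline_params(shape = c(128L, 128L))
  # centers 1.8 radii apart: overlap well under 30% of a radius
  cells <- gt_cells(x = c(55, 73), y = c(64, 64), nuc_r = 10, cell_r = 16)
  img <- render_field(cells, b, noise = FALSE)
  nuclei <- segment_nuclei(img$blue)
  expect_equal(count_cells(nuclei), 2)
})

test_that("cells contain their nuclei and nucleus-free cytoplasm is dropped", {
  b <- small_baseline()
  img <- render_field(gt_cells(x = 64, y = 64), b, noise = FALSE)
  nuclei <- segment_nuclei(img$blue)
  cells <- segment_cells(img$blue, nuclei)
  expect_equal(count_cells(cells), 1)
  expect_gt(sum(cells > 0), sum(nuclei > 0))
  expect_true(all(cells[nuclei > 0] == nuclei[nuclei > 0]))

  # add a cytoplasm-intensity blob with no nucleus: must not appear
  blue2 <- img$blue
  blue2[5:25, 100:120] <- b$blue_cyto
  nuclei2 <- segment_nuclei(blue2)
  cells2 <- segment_cells(blue2, nuclei2)
  expect_equal(count_cells(cells2), 1)
  expect_true(all(cells2[5:25, 100:120] == 0))

  expect_error(segment_cells(img$blue[1:50, ], nuclei), "shapes")
})

test_that("adjacent cells split near the midline between seeds", {
  b <- baseline_params(shape = c(160L, 160L))
  # symmetric pair with touching cytoplasm
  cells <- gt_cells(x = c(60, 100), y = c(80, 80), nuc_r = 9, cell_r = 22)
  img <- render_field(cells, b, noise = FALSE)
  seg <- segment_field(img)
  expect_equal(count_cells(seg$nuclei), 2)
  lab_a <- seg$cells[60, 80]
  lab_b <- seg$cells[100, 80]
  expect_true(lab_a > 0 && lab_b > 0 && lab_a != lab_b)
  boundary <- vapply(seq_len(160), function(cc) {
    col <- seg$cells[, cc]
    if (any(col == lab_a) && any(col == lab_b))
      (max(which(col == lab_a)) + min(which(col == lab_b))) / 2
    else NA_real_
  }, numeric(1))
  mid <- stats::median(boundary, na.rm = TRUE)
  expect_lt(abs(mid - 80), 2)
})

test_that("cytoplasm is the exact set difference and partitions the cell", {
  d <- screen_layout(n_mimics = 1, replicates = 1, sites_per_well = 1,
                     seed = 6, control_replicates = 1)
  b <- baseline_params(cells_per_field = 50)
  cells_gt <- sample_cells(d, default_effects(d), b, seed = 12)
  fc <- cells_gt[cells_gt$treatment == "mimic_01", ]
  img <- render_field(fc, b, noise = TRUE, seed = 4)
  seg <- segment_field(img)
  expect_gt(count_cells(seg$nuclei), 0)
  # audit: nucleus union cytoplasm = cell, intersection empty, per label
  expect_true(all((seg$nuclei > 0) + (seg$cytoplasm > 0) ==
                    (seg$cells > 0)))
  both <- seg$nuclei > 0 & seg$cytoplasm > 0
  expect_false(any(both))
  same <- seg$cytoplasm == 0 | seg$cytoplasm == seg$cells
  expect_true(all(same))

  # degenerate: nucleus fills the whole cell
  lab <- matrix(0L, 20, 20); lab[5:15, 5:15] <- 1L
  cyto <- derive_cytoplasm(lab, lab)
  expect_equal(sum(cyto), 0)
  expect_equal(attr(cyto, "empty_cytoplasm"), 1L)

  # violated containment errors
  nuc_bad <- lab
  nuc_bad[1, 1] <- 1L
  expect_error(derive_cytoplasm(lab, nuc_bad), "containment")
})

test_that("detected counts track planted counts within 5% under noise", {
  d <- screen_layout(n_mimics = 1, replicates = 1, sites_per_well = 2,
                     seed = 8, control_replicates = 1)
  b <- baseline_params()
  gt <- sample_cells(d, default_effects(d), b, seed = 21)
  fields <- unique(gt[gt$treatment %in% c("mimic_01", "miR-Ctr"),
                      c("plate", "well", "site")])
  true_n <- 0; det_n <- 0
  for (i in seq_len(nrow(fields))) {
    fc <- gt[gt$plate == fields$plate[i] & gt$well == fields$well[i] &
               gt$site == fields$site[i], ]
    img <- render_field(fc, b, noise = TRUE, seed = 100 + i)
    true_n <- true_n + nrow(fc)
    det_n <- det_n + count_cells(segment_nuclei(img$blue))
  }
  expect_lte(abs(det_n - true_n) / true_n, 0.05)
})
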