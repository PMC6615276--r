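#' Control treatments used on every plate
#'
#' The assay carries four control roles: a negative-control mimic with no
#' human targets (`miR-Ctr`), two differentiation controls (`atRA`,
#' `esiRNA-OCT4`) and a lethal transfection-efficiency control
#' (`siRNA-UBC`).
#' @return Named character vector mapping treatment name to role.
#' @export
control_roles <- function() {
  c("miR-Ctr" = "neg_control",
    "atRA" = "diff_control",
    "esiRNA-OCT4" = "diff_control",
    "siRNA-UBC" = "lethal_control")
}

#' Design a multiwell screen layout
#'
#' Lays out `n_mimics` mimic treatments in `replicates` wells each, plus the
#' four control roles, over as many 96-well plates as needed. All replicate
#' wells of one mimic sit on the same plate; every control appears on every
#' plate (in `control_replicates` wells) so per-plate normalization and QC
#' are always possible. Well positions are shuffled deterministically from
#' `seed`.
#'
#' @param n_mimics Number of mimic treatments (default 31).
#' @param replicates Wells per mimic (default 3).
#' @param sites_per_well Imaged fields per well (default 9).
#' @param seed Integer seed for the (deterministic) well shuffle.
#' @param mimics Optional character vector of mimic names
#'   (default `mimic_01` ... style names).
#' @param control_replicates Wells per control treatment per plate.
#' @param plate_capacity Wells per plate (96).
#' @param add_plates If `FALSE`, error instead of adding plates when the
#'   design does not fit.
#' @return A `screen_design` object: list with `wells` (data.frame of
#'   plate, well, treatment, replicate), `sites_per_well`, `roles`.
#' @export
screen_layout <- function(n_mimics = 31, replicates = 3, sites_per_well = 9,
                          seed = 1, mimics = NULL, control_replicates = 3,
                          plate_capacity = 96, add_plates = TRUE) {
  stopifnot(n_mimics >= 1, replicates >= 1, sites_per_well >= 1)
  ctrl <- control_roles()
  if (is.null(mimics)) mimics <- sprintf("mimic_%02d", seq_len(n_mimics))
  stopifnot(length(mimics) == n_mimics, !anyDuplicated(mimics))

  ctrl_wells_per_plate <- length(ctrl) * control_replicates
  mimics_per_plate <- (plate_capacity - ctrl_wells_per_plate) %/% replicates
  if (mimics_per_plate < 1)
    stop("plate capacity too small for controls plus one mimic")
  n_plates <- ceiling(n_mimics / mimics_per_plate)
  if (!add_plates && n_plates > 1 &&
      n_mimics * replicates + ctrl_wells_per_plate > plate_capacity)
    stop("design exceeds one plate and add_plates = FALSE")

  all_positions <- as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
  plates <- sprintf("P%d", seq_len(n_plates))

  rows <- list()
  mi <- 1L
  for (p in seq_len(n_plates)) {
    on_plate <- mimics[seq(mi, min(mi + mimics_per_plate - 1L, n_mimics))]
    mi <- mi + length(on_plate)
    trt <- c(rep(names(ctrl), each = control_replicates),
             rep(on_plate, each = replicates))
    rep_idx <- c(rep(seq_len(control_replicates), length(ctrl)),
                 rep(seq_len(replicates), length(on_plate)))
    pos <- with_seed(seed + p, sample(all_positions, length(trt)))
    rows[[p]] <- data.frame(plate = plates[p], well = pos, treatment = trt,
                            replicate = rep_idx, stringsAsFactors = FALSE)
  }
  wells <- do.call(rbind, rows)
  wells <- wells[order(wells$plate, wells$well), , drop = FALSE]
  rownames(wells) <- NULL

  roles <- c(ctrl, stats::setNames(rep("mimic", n_mimics), mimics))
  design <- list(wells = wells, sites_per_well = as.integer(sites_per_well),
                 plates = plates, roles = roles, seed = as.integer(seed))
  class(design) <- "screen_design"
  validate_design(design)
  design
}

validate_design <- function(design) {
  w <- design$wells
  if (anyDuplicated(paste(w$plate, w$well)))
    stop("duplicated well id within a plate")
  mim <- names(design$roles)[design$roles == "mimic"]
  cnt <- table(w$treatment[w$treatment %in% mim])
  reps <- unique(as.integer(cnt))
  if (length(mim) && length(reps) != 1)
    stop("mimics do not all have the same replicate count")
  neg <- names(design$roles)[design$roles == "neg_control"]
  for (p in design$plates)
    if (!any(w$treatment[w$plate == p] %in% neg))
      stop(sprintf("plate %s lacks a negative control well", p))
  invisible(design)
}

#' @export
print.screen_design <- function(x, ...) {
  cat(sprintf("screen_design: %d plate(s), %d wells, %d sites/well\n",
              length(x$plates), nrow(x$wells), x$sites_per_well))
  cat(sprintf("  treatments: %d mimics + %d controls\n",
              sum(x$roles == "mimic"), sum(x$roles != "mimic")))
  invisible(x)
}

#' Per-treatment phenotype effect profile
#'
#' Effects are dimensionless multipliers relative to the negative-control
#' baseline of 1. They scale, respectively, the expected cells per field,
#' nucleus and cell radius, nuclear boundary irregularity and elongation,
#' and the four marker levels (OCT4 and CCNB1 in nucleus and cytoplasm).
#'
#' @param treatment Treatment name.
#' @param count,nucleus_radius,cell_radius,irregularity,elongation Shape and
#'   abundance multipliers (> 0).
#' @param oct4_nuc,oct4_cyto,ccnb1_nuc,ccnb1_cyto Marker-level multipliers.
#' @return One-row data.frame.
#' @export
effect_profile <- function(treatment, count = 1, nucleus_radius = 1,
                           cell_radius = 1, irregularity = 1, elongation = 1,
                           oct4_nuc = 1, oct4_cyto = 1,
                           ccnb1_nuc = 1, ccnb1_cyto = 1) {
  v <- c(count = count, nucleus_radius = nucleus_radius,
         cell_radius = cell_radius, irregularity = irregularity,
         elongation = elongation, oct4_nuc = oct4_nuc, oct4_cyto = oct4_cyto,
         ccnb1_nuc = ccnb1_nuc, ccnb1_cyto = ccnb1_cyto)
  if (any(v <= 0)) stop("all effect multipliers must be > 0")
  data.frame(treatment = treatment, t(v), stringsAsFactors = FALSE)
}

#' Default effect profiles for a design
#'
#' Mimics and the negative control get all-ones profiles; the lethal control
#' kills 90% of cells (count multiplier 0.1) and the differentiation
#' controls halve OCT4 and CCNB1 levels.
#'
#' @param design A `screen_design`.
#' @return data.frame of effect profiles, one row per treatment.
#' @export
default_effects <- function(design) {
  rows <- lapply(names(design$roles), function(trt) {
    switch(design$roles[[trt]],
      lethal_control = effect_profile(trt, count = 0.1),
      diff_control = effect_profile(trt, oct4_nuc = 0.5, oct4_cyto = 0.5,
                                    ccnb1_nuc = 0.5, ccnb1_cyto = 0.5),
      effect_profile(trt))
  })
  do.call(rbind, rows)
}

#' Baseline generative parameters for the synthetic screen
#'
#' Defaults describe a desk-scale emulation of the assay: 512x512 px fields
#' at a nominal 10x magnification, a target of 100 cells per field, nuclei of
#' ~8 px and cells of ~14 px mean radius, and blue-channel intensity classes
#' (background < cytoplasm < nucleus) wide enough apart for three-class
#' thresholding. Marker levels are arbitrary 16-bit intensity units. A
#' small per-field size and intensity factor (`field_cv`, lognormal with
#' unit mean) emulates field-to-field heterogeneity in plating, staining
#' and focus.
#'
#' @param ... Overrides for any default element.
#' @return Named list of parameters.
#' @export
baseline_params <- function(...) {
  p <- list(
    cells_per_field = 100,
    nucleus_radius = 8, nucleus_radius_sdlog = 0.15,
    cell_radius = 14, cell_radius_sdlog = 0.12,
    min_cell_nucleus_ratio = 1.15,
    elongation = 1.3, elongation_sdlog = 0.10,
    irregularity = 0.2, irregularity_sdlog = 0.3,
    level_sdlog = 0.25,
    field_cv = 0.02,
    oct4_nuc = 6000, oct4_cyto = 2000,
    ccnb1_nuc = 3500, ccnb1_cyto = 2500,
    blue_background = 300, blue_cyto = 3000, blue_nucleus = 12000,
    marker_background = 50,
    shape = c(512L, 512L),
    pixel_size_um = 0.65,
    psf_sigma = 1, gaussian_sd = 50,
    overlap_factor = 0.9, max_retries = 200
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown baseline parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  p
}

# Lognormal draws with a prescribed arithmetic mean.
rlnorm_mean <- function(n, mean, sdlog) {
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Sample ground-truth cells for a single field.
sample_field_cells <- function(plate, well, site, treatment, eff, baseline, seed) {
  with_seed(seed, {
    n <- stats::rpois(1, baseline$cells_per_field * eff[["count"]])
    if (n == 0)
      return(empty_ground_truth())
    # field-to-field heterogeneity (plating, staining, focus): one size and
    # one intensity factor per field, unit mean
    size_f <- rlnorm_mean(1, 1, baseline$field_cv)
    int_f <- rlnorm_mean(1, 1, baseline$field_cv)
    nr <- size_f *
      rlnorm_mean(n, baseline$nucleus_radius * eff[["nucleus_radius"]],
                  baseline$nucleus_radius_sdlog)
    cr <- size_f *
      rlnorm_mean(n, baseline$cell_radius * eff[["cell_radius"]],
                  baseline$cell_radius_sdlog)
    cr <- pmax(cr, nr * baseline$min_cell_nucleus_ratio)
    el <- pmax(1, rlnorm_mean(n, baseline$elongation * eff[["elongation"]],
                              baseline$elongation_sdlog))
    theta <- stats::runif(n, 0, pi)
    amp <- pmin(0.35, rlnorm_mean(n, baseline$irregularity * eff[["irregularity"]],
                                  baseline$irregularity_sdlog))
    phase <- stats::runif(n, 0, 2 * pi)
    cell_a <- cr * sqrt(el); cell_b <- cr / sqrt(el)
    nuc_a <- nr * sqrt(el); nuc_b <- nr / sqrt(el)

    H <- baseline$shape[1]; W <- baseline$shape[2]
    rmax <- cell_a * (1 + amp)
    x <- numeric(n); y <- numeric(n); overlap <- logical(n)
    fac <- baseline$overlap_factor
    for (i in seq_len(n)) {
      placed <- FALSE
      for (k in seq_len(baseline$max_retries)) {
        px <- stats::runif(1, rmax[i] + 2, H - rmax[i] - 1)
        py <- stats::runif(1, rmax[i] + 2, W - rmax[i] - 1)
        if (i == 1 ||
            all((x[seq_len(i - 1)] - px)^2 + (y[seq_len(i - 1)] - py)^2 >
                (fac * (rmax[seq_len(i - 1)] + rmax[i]))^2)) {
          placed <- TRUE
          break
        }
      }
      x[i] <- px; y[i] <- py; overlap[i] <- !placed
    }

    lev <- function(base, key) {
      int_f * rlnorm_mean(n, base * eff[[key]], baseline$level_sdlog)
    }
    data.frame(
      plate = plate, well = well, site = as.integer(site),
      treatment = treatment, cell_id = seq_len(n),
      x = x, y = y,
      nuc_a = nuc_a, nuc_b = nuc_b, cell_a = cell_a, cell_b = cell_b,
      theta = theta, irregularity = amp, phase = phase,
      oct4_nuc = lev(baseline$oct4_nuc, "oct4_nuc"),
      oct4_cyto = lev(baseline$oct4_cyto, "oct4_cyto"),
      ccnb1_nuc = lev(baseline$ccnb1_nuc, "ccnb1_nuc"),
      ccnb1_cyto = lev(baseline$ccnb1_cyto, "ccnb1_cyto"),
      overlap = overlap, stringsAsFactors = FALSE)
  })
}

empty_ground_truth <- function() {
  data.frame(plate = character(), well = character(), site = integer(),
             treatment = character(), cell_id = integer(),
             x = numeric(), y = numeric(), nuc_a = numeric(), nuc_b = numeric(),
             cell_a = numeric(), cell_b = numeric(), theta = numeric(),
             irregularity = numeric(), phase = numeric(),
             oct4_nuc = numeric(), oct4_cyto = numeric(),
             ccnb1_nuc = numeric(), ccnb1_cyto = numeric(),
             overlap = logical(), stringsAsFactors = FALSE)
}

#' Sample ground-truth cells for a whole screen
#'
#' Per field, the cell count is Poisson with mean
#' `cells_per_field * count multiplier`; radii, elongation and marker levels
#' are lognormal with arithmetic means scaled by the treatment's
#' multipliers. Cell placement avoids overlaps by rejection sampling up to a
#' retry cap (cells placed past the cap are kept but flagged `overlap`).
#'
#' @param design A `screen_design`.
#' @param effects data.frame of effect profiles (see [effect_profile()]);
#'   every treatment in the design must have one row.
#' @param baseline Output of [baseline_params()].
#' @param seed Integer master seed; one sub-seed is derived per field.
#' @return data.frame of ground-truth cells, one row per cell.
#' @export
sample_cells <- function(design, effects, baseline = baseline_params(), seed = 1) {
  missing <- setdiff(design$wells$treatment, effects$treatment)
  if (length(missing))
    stop("no effect profile for treatment(s): ", paste(missing, collapse = ", "))
  fields <- expand_fields(design)
  seeds <- derive_seeds(seed, fields$key, salt = 101L)
  out <- vector("list", nrow(fields))
  for (i in seq_len(nrow(fields))) {
    eff <- effects[effects$treatment == fields$treatment[i], , drop = FALSE][1, ]
    out[[i]] <- sample_field_cells(fields$plate[i], fields$well[i],
                                   fields$site[i], fields$treatment[i],
                                   eff, baseline, seeds[[fields$key[i]]])
  }
  do.call(rbind, out)
}

expand_fields <- function(design) {
  w <- design$wells
  s <- design$sites_per_well
  f <- w[rep(seq_len(nrow(w)), each = s), c("plate", "well", "treatment")]
  f$site <- rep(seq_len(s), nrow(w))
  f$key <- field_key(f$plate, f$well, f$site)
  rownames(f) <- NULL
  f
}

# Paint `value[i]` inside each (possibly perturbed) ellipse on `img`.
paint_ellipses <- function(img, cells, a, b, value) {
  H <- nrow(img); W <- ncol(img)
  for (i in seq_len(nrow(cells))) {
    amp <- cells$irregularity[i]
    r <- max(a[i], b[i]) * (1 + abs(amp))
    x0 <- max(1L, floor(cells$x[i] - r)); x1 <- min(H, ceiling(cells$x[i] + r))
    y0 <- max(1L, floor(cells$y[i] - r)); y1 <- min(W, ceiling(cells$y[i] + r))
    if (x0 > x1 || y0 > y1) {
      warning(sprintf("cell %d of field %s falls outside the frame; skipped",
                      cells$cell_id[i],
                      field_key(cells$plate[i], cells$well[i], cells$site[i])))
      next
    }
    xs <- x0:x1; ys <- y0:y1
    dx <- matrix(xs - cells$x[i], length(xs), length(ys))
    dy <- matrix(ys - cells$y[i], length(xs), length(ys), byrow = TRUE)
    ct <- cos(cells$theta[i]); st <- sin(cells$theta[i])
    u <- (dx * ct + dy * st) / a[i]
    v <- (-dx * st + dy * ct) / b[i]
    rho <- sqrt(u^2 + v^2)
    inside <- rho <= 1 + amp * cos(3 * atan2(v, u) + cells$phase[i])
    sub <- img[xs, ys]
    sub[inside] <- value[i]
    img[xs, ys] <- sub
  }
  img
}

#' Render one field image from ground-truth cells
#'
#' The blue plane holds background, a medium constant inside each cell
#' ellipse and a high constant inside each nucleus ellipse; green (OCT4)
#' and red (CCNB1) planes hold each cell's true compartment levels painted
#' inside the matching ellipses. With `noise = TRUE` the planes are
#' Gaussian-smoothed (`psf_sigma`), given Poisson shot noise plus additive
#' Gaussian read noise (`gaussian_sd`), clipped to \[0, 65535\] and
#' quantized; with `noise = FALSE` the painted planes are only quantized.
#'
#' @param cells Ground-truth rows of a single field (may be empty).
#' @param baseline Output of [baseline_params()].
#' @param noise Apply the smoothing + noise model?
#' @param seed Seed for the noise draws.
#' @return A `field_image`: list of integer matrices `blue`, `green`, `red`
#'   plus `plate`, `well`, `site`, `pixel_size_um`.
#' @export
render_field <- function(cells, baseline = baseline_params(), noise = TRUE,
                         seed = 1) {
  key <- unique(field_key(cells$plate, cells$well, cells$site))
  if (length(key) > 1) stop("cells belong to more than one field")
  H <- baseline$shape[1]; W <- baseline$shape[2]
  blue <- matrix(baseline$blue_background, H, W)
  green <- matrix(baseline$marker_background, H, W)
  red <- matrix(baseline$marker_background, H, W)
  if (nrow(cells)) {
    blue <- paint_ellipses(blue, cells, cells$cell_a, cells$cell_b,
                           rep(baseline$blue_cyto, nrow(cells)))
    blue <- paint_ellipses(blue, cells, cells$nuc_a, cells$nuc_b,
                           rep(baseline$blue_nucleus, nrow(cells)))
    green <- paint_ellipses(green, cells, cells$cell_a, cells$cell_b, cells$oct4_cyto)
    green <- paint_ellipses(green, cells, cells$nuc_a, cells$nuc_b, cells$oct4_nuc)
    red <- paint_ellipses(red, cells, cells$cell_a, cells$cell_b, cells$ccnb1_cyto)
    red <- paint_ellipses(red, cells, cells$nuc_a, cells$nuc_b, cells$ccnb1_nuc)
  }
  planes <- list(blue = blue, green = green, red = red)
  if (noise) {
    planes <- with_seed(seed, lapply(planes, function(p) {
      if (baseline$psf_sigma > 0)
        p <- EBImage::gblur(p, sigma = baseline$psf_sigma)
      p <- stats::rpois(length(p), pmax(p, 0)) +
        stats::rnorm(length(p), 0, baseline$gaussian_sd)
      matrix(p, H, W)
    }))
  }
  planes <- lapply(planes, function(p) {
    storage.mode(p) <- "double"
    matrix(as.integer(pmin(pmax(round(p), 0), 65535)), H, W)
  })
  structure(c(planes,
              list(plate = if (nrow(cells)) cells$plate[1] else NA_character_,
                   well = if (nrow(cells)) cells$well[1] else NA_character_,
                   site = if (nrow(cells)) cells$site[1] else NA_integer_,
                   pixel_size_um = baseline$pixel_size_um)),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("field_image %s_%s_s%s: %dx%d px, 3 channels\n",
              x$plate, x$well, x$site, nrow(x$blue), ncol(x$blue)))
  invisible(x)
}

#' Simulate a screen to disk (or memory)
#'
#' Composes [sample_cells()] and [render_field()] over every field of the
#' design. With `dir` set, writes one 16-bit grayscale TIFF per channel
#' (`{plate}_{well}_s{site}_{channel}.tif`) plus `ground_truth.csv`; runs
#' are byte-reproducible from `seed`.
#'
#' @inheritParams sample_cells
#' @param dir Output directory (created if needed); `NULL` keeps images in
#'   memory (only sensible for small designs).
#' @param noise Apply the noise model (see [render_field()]).
#' @return list with `design`, `cells` (ground truth) and either `files`
#'   (data.frame of written paths) or `images` (list of `field_image`).
#' @export
simulate_screen <- function(design, effects = default_effects(design),
                            baseline = baseline_params(), seed = 1,
                            dir = NULL, noise = TRUE) {
  cells <- sample_cells(design, effects, baseline, seed)
  fields <- expand_fields(design)
  rseeds <- derive_seeds(seed, fields$key, salt = 202L)
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  images <- list(); files <- list()
  for (i in seq_len(nrow(fields))) {
    fc <- cells[cells$plate == fields$plate[i] & cells$well == fields$well[i] &
                  cells$site == fields$site[i], , drop = FALSE]
    img <- render_field(fc, baseline, noise = noise,
                        seed = rseeds[[fields$key[i]]])
    img$plate <- fields$plate[i]; img$well <- fields$well[i]
    img$site <- fields$site[i]
    if (is.null(dir)) {
      images[[fields$key[i]]] <- img
    } else {
      files[[fields$key[i]]] <- write_field_tiff(img, dir)
    }
  }
  out <- list(design = design, cells = cells)
  if (is.null(dir)) out$images <- images
  else {
    utils::write.csv(cells, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
    out$files <- do.call(rbind, files)
  }
  out
}

#' Write / read one field as per-channel 16-bit TIFFs
#'
#' @param img A `field_image`.
#' @param dir Directory for the three TIFF files.
#' @return `write_field_tiff`: data.frame of the paths written.
#' @export
write_field_tiff <- function(img, dir) {
  paths <- character(3)
  chans <- c("blue", "green", "red")
  for (j in seq_along(chans)) {
    ch <- chans[j]
    path <- file.path(dir, sprintf("%s_%s_s%d_%s.tif",
                                   img$plate, img$well, img$site, ch))
    tiff::writeTIFF(img[[ch]] / 65535, path, bits.per.sample = 16,
                    compression = "none")
    paths[j] <- path
  }
  data.frame(plate = img$plate, well = img$well, site = img$site,
             blue = paths[1], green = paths[2], red = paths[3],
             stringsAsFactors = FALSE)
}

#' @rdname write_field_tiff
#' @param dir Directory holding the TIFFs.
#' @param plate,well,site Field key.
#' @return `read_field_tiff`: the `field_image`.
#' @export
read_field_tiff <- function(dir, plate, well, site) {
  planes <- lapply(c("blue", "green", "red"), function(ch) {
    path <- file.path(dir, sprintf("%s_%s_s%d_%s.tif", plate, well,
                                   as.integer(site), ch))
    if (!file.exists(path)) stop("missing channel file: ", path)
    m <- tiff::readTIFF(path)
    matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  })
  structure(list(blue = planes[[1]], green = planes[[2]], red = planes[[3]],
                 plate = plate, well = well, site = as.integer(site),
                 pixel_size_um = NA_real_),
            class = "field_image")
}
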