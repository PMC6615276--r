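cell_feature_names <- function() {
  c("nucleus_area", "cell_area", "nucleus_perimeter", "cell_perimeter",
    "solidity_nucleus", "solidity_cell",
    "eccentricity_nucleus", "eccentricity_cell",
    "oct4_nuc_median", "oct4_cyto_median",
    "ccnb1_nuc_median", "ccnb1_cyto_median")
}

#' Default feature panel of the phenotypic profile
#'
#' Cell count, solidity, eccentricity (nucleus compartment by default),
#' nuclear/cellular area and perimeter, and nuclear/cytoplasmic OCT4 and
#' CCNB1 median intensities.
#' @return Character vector of feature names.
#' @export
profile_features <- function() {
  c("count", "solidity_cell", "eccentricity_nucleus",
    "nucleus_area", "cell_area", "nucleus_perimeter", "cell_perimeter",
    "oct4_nuc_median", "oct4_cyto_median",
    "ccnb1_nuc_median", "ccnb1_cyto_median")
}

#' Summarize cell records per imaged site
#'
#' One row per (plate, well, site): the cell count plus the median over
#' cells of every per-cell feature. With 3 replica wells and 9 sites each,
#' a treatment contributes 27 summaries per feature. Sites with zero cells
#' keep count 0 and `NA` medians, and are flagged.
#'
#' @param records Cell records from [measure_cells()] (treatment column
#'   required).
#' @param design Optional `screen_design` used to add rows for sites with
#'   no cells at all.
#' @return data.frame of site summaries.
#' @export
summarize_sites <- function(records, design = NULL) {
  if (nrow(records) && anyNA(records$treatment))
    stop("records lack treatment annotations")
  key <- interaction(records$plate, records$well, records$site, drop = TRUE)
  feats <- cell_feature_names()
  agg <- lapply(split(records, key), function(d) {
    if (length(unique(d$treatment)) > 1)
      stop(sprintf("site %s_%s_s%s carries conflicting treatment annotations",
                   d$plate[1], d$well[1], d$site[1]))
    out <- data.frame(plate = d$plate[1], well = d$well[1], site = d$site[1],
                      treatment = d$treatment[1], count = nrow(d),
                      stringsAsFactors = FALSE)
    for (f in feats) out[[f]] <- stats::median(d[[f]], na.rm = TRUE)
    out
  })
  res <- do.call(rbind, agg)
  if (!is.null(design)) {
    fields <- expand_fields(design)
    have <- if (is.null(res)) character() else
      field_key(res$plate, res$well, res$site)
    miss <- fields[!fields$key %in% have, , drop = FALSE]
    if (nrow(miss)) {
      extra <- data.frame(plate = miss$plate, well = miss$well,
                          site = miss$site, treatment = miss$treatment,
                          count = 0L, stringsAsFactors = FALSE)
      for (f in feats) extra[[f]] <- NA_real_
      res <- rbind(res, extra)
    }
  }
  if (is.null(res)) stop("no cell records and no design supplied")
  k <- paste(res$plate, res$well, res$site)
  if (anyDuplicated(k)) stop("duplicated site key in summaries")
  res <- res[order(res$plate, res$well, res$site), , drop = FALSE]
  rownames(res) <- NULL
  res$empty_site <- res$count == 0
  res
}

#' Percentage-of-control normalization
#'
#' Each site-level value becomes `100 * value / median(control values)`,
#' where the control median is taken over the negative-control sites of the
#' same plate, per feature. The count feature is normalized with the same
#' formula on site counts. Zero-celled sites contribute no morphology
#' values (their medians are `NA`) but do contribute count 0.
#'
#' @param summaries Site summaries from [summarize_sites()].
#' @param design The `screen_design` (identifies the negative control), or
#'   `control` a treatment name.
#' @param control Negative-control treatment name (overrides `design`).
#' @return data.frame shaped like `summaries`, values as POC.
#' @export
poc_normalize <- function(summaries, design = NULL, control = NULL) {
  if (is.null(control)) {
    if (is.null(design)) stop("supply `design` or `control`")
    control <- names(design$roles)[design$roles == "neg_control"][1]
  }
  feats <- c("count", cell_feature_names())
  out <- summaries
  for (p in unique(summaries$plate)) {
    on_plate <- summaries$plate == p
    ctrl <- summaries[on_plate & summaries$treatment == control, , drop = FALSE]
    if (nrow(ctrl) == 0)
      stop(sprintf("no %s sites on plate %s", control, p))
    for (f in feats) {
      m <- stats::median(ctrl[[f]], na.rm = TRUE)
      if (!is.finite(m) || m == 0)
        stop(sprintf("control median for feature %s on plate %s is %s",
                     f, p, if (is.finite(m)) "zero" else "undefined"))
      out[[f]][on_plate] <- 100 * summaries[[f]][on_plate] / m
    }
  }
  out
}

#' Build the multiparametric phenotypic profile
#'
#' Per treatment and feature, the median of the POC site values (27 values
#' for a triplicate treatment at 9 sites/well).
#'
#' @param poc POC site values from [poc_normalize()].
#' @param features Feature panel (default [profile_features()]).
#' @return A `phenotypic_profile`: numeric matrix, treatments x features,
#'   with attribute `provenance`.
#' @export
build_profile <- function(poc, features = profile_features()) {
  absent <- setdiff(features, names(poc))
  if (length(absent))
    stop("feature(s) absent from summaries: ", paste(absent, collapse = ", "))
  trts <- unique(poc$treatment)
  mat <- matrix(NA_real_, length(trts), length(features),
                dimnames = list(trts, features))
  for (t in trts) {
    d <- poc[poc$treatment == t, , drop = FALSE]
    for (f in features)
      mat[t, f] <- stats::median(d[[f]], na.rm = TRUE)
  }
  structure(mat,
            provenance = list(plates = unique(poc$plate),
                              n_sites = nrow(poc)),
            class = c("phenotypic_profile", "matrix", "array"))
}

#' @export
print.phenotypic_profile <- function(x, ...) {
  cat(sprintf("phenotypic_profile: %d treatments x %d features (POC)\n",
              nrow(x), ncol(x)))
  print(round(unclass(x), 1), ...)
  invisible(x)
}

#' Screen quality control
#'
#' Per plate: transfection efficiency
#' `1 - median(lethal-well site counts) / median(negative-control site
#' counts)` and, for each differentiation control, the OCT4 nuclear
#' knockdown `1 - POC/100` of its wells. Compared against thresholds
#' (default efficiency 0.85).
#'
#' @param summaries Site summaries from [summarize_sites()].
#' @param design The `screen_design`.
#' @param thresholds list with `efficiency` (default 0.85) and optional
#'   `knockdown`.
#' @return A `qc_report` data.frame, one row per plate and metric.
#' @export
qc_screen <- function(summaries, design,
                      thresholds = list(efficiency = 0.85, knockdown = 0.2)) {
  roles <- design$roles
  neg <- names(roles)[roles == "neg_control"]
  lethal <- names(roles)[roles == "lethal_control"]
  diffc <- names(roles)[roles == "diff_control"]
  rows <- list()
  for (p in unique(summaries$plate)) {
    d <- summaries[summaries$plate == p, , drop = FALSE]
    negc <- d$count[d$treatment %in% neg]
    if (length(lethal) && any(d$treatment %in% lethal) && length(negc)) {
      eff <- 1 - stats::median(d$count[d$treatment %in% lethal]) /
        stats::median(negc)
      rows[[length(rows) + 1]] <- data.frame(
        plate = p, metric = "transfection_efficiency", treatment = lethal[1],
        value = eff, threshold = thresholds$efficiency,
        pass = eff >= thresholds$efficiency, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1]] <- data.frame(
        plate = p, metric = "transfection_efficiency",
        treatment = NA_character_, value = NA_real_,
        threshold = thresholds$efficiency, pass = NA, stringsAsFactors = FALSE)
    }
    ctrl_med <- stats::median(d$oct4_nuc_median[d$treatment %in% neg],
                              na.rm = TRUE)
    for (dc in diffc) {
      v <- d$oct4_nuc_median[d$treatment == dc]
      kd <- if (length(v) && is.finite(ctrl_med) && ctrl_med > 0)
        1 - stats::median(100 * v / ctrl_med, na.rm = TRUE) / 100
      else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        plate = p, metric = "oct4_knockdown", treatment = dc, value = kd,
        threshold = thresholds$knockdown %||% NA_real_,
        pass = if (is.na(kd)) NA else kd >= (thresholds$knockdown %||% -Inf),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("qc_report", "data.frame")
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Screen QC report\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s %-24s %-12s %6s  %s\n", x$plate[i], x$metric[i],
                x$treatment[i],
                ifelse(is.na(x$value[i]), "NA", sprintf("%.3f", x$value[i])),
                ifelse(is.na(x$pass[i]), "unavailable",
                       ifelse(x$pass[i], "PASS", "FAIL"))))
  }
  invisible(x)
}
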