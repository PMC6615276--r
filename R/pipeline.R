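#' Assemble a screen run configuration
#'
#' A single configuration object (or YAML file) drives every stage of
#' [run_screen()]. Unset elements fall back to the defaults of the
#' underlying functions.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Master seed; recorded in the run manifest and every derived
#'   random draw.
#' @param n_mimics,replicates,sites_per_well Layout parameters
#'   (see [screen_layout()]).
#' @param mimics Optional mimic names.
#' @param effects `NULL` for [default_effects()], or a data.frame of
#'   [effect_profile()] rows, or a named list of multiplier lists
#'   (YAML-friendly), e.g. `list(mimic_01 = list(oct4_nuc = 1.5))`.
#' @param baseline Named list of [baseline_params()] overrides.
#' @param segmentation Named list of [segmentation_params()] overrides.
#' @param features Profile feature panel.
#' @param cluster_k,cluster_sub Cut specification (see [cut_profile_tree()]).
#' @param write_images Write per-field TIFFs during `simulate`?
#' @param targetscan,gene_sets Optional paths to a TargetScan-style table
#'   and a GMT collection enabling the `enrich` stage.
#' @param min_fraction Shared-target fraction (see [shared_targets()]).
#' @return A `screen_config` list.
#' @export
screen_config <- function(out_dir = tempfile("phenomir_run_"), seed = 1,
                          n_mimics = 31, replicates = 3, sites_per_well = 9,
                          mimics = NULL, effects = NULL, baseline = list(),
                          segmentation = list(),
                          features = profile_features(),
                          cluster_k = 2, cluster_sub = list(),
                          write_images = FALSE,
                          targetscan = NULL, gene_sets = NULL,
                          min_fraction = 1) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              n_mimics = n_mimics, replicates = replicates,
              sites_per_well = sites_per_well, mimics = mimics,
              effects = effects, baseline = baseline,
              segmentation = segmentation, features = features,
              cluster_k = cluster_k, cluster_sub = cluster_sub,
              write_images = write_images, targetscan = targetscan,
              gene_sets = gene_sets, min_fraction = min_fraction)
  class(cfg) <- "screen_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror [screen_config()] arguments.
#' @return A `screen_config`.
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(screen_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(screen_config, raw)
}

config_effects <- function(cfg, design) {
  eff <- cfg$effects
  if (is.null(eff)) return(default_effects(design))
  if (is.data.frame(eff)) {
    base <- default_effects(design)
    keep <- !base$treatment %in% eff$treatment
    return(rbind(base[keep, , drop = FALSE], eff[, names(base), drop = FALSE]))
  }
  base <- default_effects(design)
  for (trt in names(eff)) {
    row <- do.call(effect_profile, c(list(treatment = trt), eff[[trt]]))
    if (trt %in% base$treatment) base[base$treatment == trt, ] <- row
    else base <- rbind(base, row)
  }
  base
}

run_paths <- function(cfg) {
  d <- cfg$out_dir
  list(dir = d,
       images = file.path(d, "images"),
       ground_truth = file.path(d, "ground_truth.csv"),
       records = file.path(d, "cell_records.csv"),
       summaries = file.path(d, "site_summaries.csv"),
       poc = file.path(d, "site_poc.csv"),
       profile = file.path(d, "profile.csv"),
       qc_json = file.path(d, "qc_report.json"),
       qc_txt = file.path(d, "qc_report.txt"),
       clusters = file.path(d, "clusters.csv"),
       heatmap = file.path(d, "heatmap.png"),
       treeview = file.path(d, "profile"),
       enrichment = file.path(d, "enrichment.csv"),
       shared = file.path(d, "shared_targets.csv"),
       manifest = file.path(d, "manifest.json"))
}

need_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop(sprintf("missing artifact %s: run stage '%s' first",
                 basename(path), stage), call. = FALSE)
  path
}

config_digest <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg2 <- cfg
  cfg2$effects <- if (is.data.frame(cfg$effects))
    as.list(cfg$effects) else cfg$effects
  jsonlite::write_json(cfg2[order(names(cfg2))], tmp, auto_unbox = TRUE,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the screen analysis pipeline
#'
#' Executes the requested stages in order, writing each stage's artifacts
#' under the configured output directory:
#' \describe{
#'   \item{simulate}{layout + ground-truth cells (and TIFFs if requested)}
#'   \item{segment}{per-field rendering, segmentation, per-cell features}
#'   \item{profile}{site summaries, POC normalization, phenotypic profile,
#'     QC report}
#'   \item{cluster}{row/column trees, named cluster cut, TreeView export,
#'     heatmap PNG}
#'   \item{enrich}{shared predicted targets per cluster and gene-set
#'     enrichment (needs `targetscan` and `gene_sets` in the config)}
#'   \item{report}{run manifest (config digest, seed, version)}
#' }
#' Later stages re-load artifacts from disk when run in a fresh session,
#' erroring with the name of the stage to run first when one is missing.
#'
#' @param config A `screen_config` or path to a YAML config.
#' @param stages Subset of
#'   `c("simulate", "segment", "profile", "cluster", "enrich", "report")`.
#' @return Invisibly, a list of in-memory results of the executed stages.
#' @export
run_screen <- function(config,
                       stages = c("simulate", "segment", "profile",
                                  "cluster", "report")) {
  if (is.character(config)) config <- read_screen_config(config)
  stages <- match.arg(stages, c("simulate", "segment", "profile",
                                "cluster", "enrich", "report"),
                      several.ok = TRUE)
  p <- run_paths(config)
  if (!dir.exists(p$dir)) dir.create(p$dir, recursive = TRUE)
  state <- list(config = config)
  design <- screen_layout(n_mimics = config$n_mimics,
                          replicates = config$replicates,
                          sites_per_well = config$sites_per_well,
                          seed = config$seed, mimics = config$mimics)
  baseline <- do.call(baseline_params, config$baseline)
  segpar <- do.call(segmentation_params, config$segmentation)
  state$design <- design

  if ("simulate" %in% stages) {
    cells <- sample_cells(design, config_effects(config, design), baseline,
                          seed = config$seed)
    utils::write.csv(cells, p$ground_truth, row.names = FALSE)
    if (isTRUE(config$write_images)) {
      sim <- simulate_screen(design, config_effects(config, design),
                             baseline, seed = config$seed, dir = p$images)
    }
    state$cells <- cells
    message(sprintf("simulate: %d ground-truth cells over %d fields",
                    nrow(cells), nrow(expand_fields(design))))
  }

  if ("segment" %in% stages) {
    cells <- state$cells %||%
      utils::read.csv(need_artifact(p$ground_truth, "simulate"),
                      stringsAsFactors = FALSE)
    fields <- expand_fields(design)
    rseeds <- derive_seeds(config$seed, fields$key, salt = 202L)
    recs <- vector("list", nrow(fields))
    for (i in seq_len(nrow(fields))) {
      fc <- cells[cells$plate == fields$plate[i] &
                    cells$well == fields$well[i] &
                    cells$site == fields$site[i], , drop = FALSE]
      img <- render_field(fc, baseline, noise = TRUE,
                          seed = rseeds[[fields$key[i]]])
      seg <- segment_field(img, segpar)
      recs[[i]] <- measure_cells(seg$nuclei, seg$cells, seg$cytoplasm,
                                 img$green, img$red,
                                 meta = list(plate = fields$plate[i],
                                             well = fields$well[i],
                                             site = fields$site[i],
                                             treatment = fields$treatment[i]))
    }
    records <- do.call(rbind, recs)
    utils::write.csv(records, p$records, row.names = FALSE)
    state$records <- records
    message(sprintf("segment: %d cells measured", nrow(records)))
  }

  if ("profile" %in% stages) {
    records <- state$records %||%
      utils::read.csv(need_artifact(p$records, "segment"),
                      stringsAsFactors = FALSE)
    summaries <- summarize_sites(records, design)
    poc <- poc_normalize(summaries, design)
    profile <- build_profile(poc, config$features)
    qc <- qc_screen(summaries, design)
    utils::write.csv(summaries, p$summaries, row.names = FALSE)
    utils::write.csv(poc, p$poc, row.names = FALSE)
    utils::write.csv(data.frame(treatment = rownames(profile),
                                unclass(profile), check.names = FALSE),
                     p$profile, row.names = FALSE)
    jsonlite::write_json(as.data.frame(qc), p$qc_json, auto_unbox = TRUE,
                         digits = NA)
    writeLines(utils::capture.output(print(qc)), p$qc_txt)
    state$summaries <- summaries
    state$poc <- poc
    state$profile <- profile
    state$qc <- qc
    message("profile: built POC profile for ",
            nrow(profile), " treatments")
  }

  if ("cluster" %in% stages) {
    profile <- state$profile %||% read_profile_csv(
      need_artifact(p$profile, "profile"))
    mimics <- intersect(rownames(profile),
                        names(design$roles)[design$roles == "mimic"])
    sub <- profile[mimics, , drop = FALSE]
    row_tree <- profile_hclust(sub, axis = "rows")
    # feature correlations over treatments are only meaningful with >= 3 rows
    col_tree <- if (nrow(sub) >= 3) profile_hclust(sub, axis = "columns")
    assignment <- cut_profile_tree(row_tree, k = config$cluster_k,
                                   sub = config$cluster_sub)
    export_treeview(sub, row_tree, col_tree, p$treeview)
    plot_profile_heatmap(sub, row_tree, col_tree, p$heatmap)
    utils::write.csv(assignment, p$clusters, row.names = FALSE)
    state$row_tree <- row_tree
    state$col_tree <- col_tree
    state$clusters <- assignment
    message(sprintf("cluster: %d clusters over %d mimics",
                    length(unique(assignment$label)), nrow(assignment)))
  }

  if ("enrich" %in% stages) {
    if (is.null(config$targetscan) || is.null(config$gene_sets))
      stop("enrich stage needs `targetscan` and `gene_sets` in the config")
    clusters <- state$clusters %||%
      utils::read.csv(need_artifact(p$clusters, "cluster"),
                      stringsAsFactors = FALSE)
    table <- read_targetscan(config$targetscan)
    collection <- read_gmt(config$gene_sets)
    shared_rows <- list(); enr_rows <- list()
    for (lab in unique(clusters$label)) {
      mirs <- clusters$leaf[clusters$label == lab]
      genes <- tryCatch(shared_targets(mirs, table, config$min_fraction),
                        error = function(e) character())
      shared_rows[[lab]] <- data.frame(cluster = lab,
                                       n_shared = length(genes),
                                       genes = paste(genes, collapse = ";"),
                                       stringsAsFactors = FALSE)
      if (length(genes)) {
        e <- enrich_hyper(genes, collection)
        e$cluster <- lab
        enr_rows[[lab]] <- e
      }
    }
    utils::write.csv(do.call(rbind, shared_rows), p$shared, row.names = FALSE)
    if (length(enr_rows))
      utils::write.csv(do.call(rbind, enr_rows), p$enrichment,
                       row.names = FALSE)
    state$shared <- do.call(rbind, shared_rows)
    state$enrichment <- if (length(enr_rows)) do.call(rbind, enr_rows)
    message("enrich: processed ", length(shared_rows), " cluster(s)")
  }

  if ("report" %in% stages) {
    manifest <- list(package = "phenomir",
                     version = as.character(utils::packageVersion("phenomir")),
                     seed = config$seed,
                     config_md5 = config_digest(config),
                     stages = stages,
                     artifacts = basename(unlist(p[file.exists(unlist(p))])))
    jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, pretty = TRUE)
    state$manifest <- manifest
    message("report: manifest written")
  }

  invisible(state)
}

read_profile_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  structure(m, class = c("phenotypic_profile", "matrix", "array"))
}
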