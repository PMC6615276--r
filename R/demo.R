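#' Planted two-group demo screen configuration
#'
#' The package's reference recovery experiment: 12 mimic treatments in
#' triplicate at 9 sites/well, six with OCT4 and CCNB1 levels raised
#' (multipliers 1.4-1.6, two exactly at 1.5) and six with both markers
#' lowered (0.5-0.7). A correct pipeline separates the two groups at the
#' top-level 2-cut of the clustered phenotypic profile and recovers the
#' planted 1.5x treatments at an OCT4-nuclear percentage of control near
#' 150.
#'
#' @param seed Master seed.
#' @param out_dir Output directory for [run_screen()] artifacts.
#' @return A `screen_config`.
#' @export
two_group_screen_config <- function(seed = 1, out_dir = tempfile("demo_")) {
  up <- c(1.40, 1.45, 1.50, 1.50, 1.55, 1.60)
  down <- c(0.50, 0.55, 0.60, 0.60, 0.65, 0.70)
  mimics <- c(sprintf("up_%02d", seq_along(up)),
              sprintf("down_%02d", seq_along(down)))
  mult <- c(up, down)
  effects <- lapply(mult, function(m)
    list(oct4_nuc = m, oct4_cyto = m, ccnb1_nuc = m, ccnb1_cyto = m))
  names(effects) <- mimics
  screen_config(out_dir = out_dir, seed = seed, n_mimics = length(mimics),
                replicates = 3, sites_per_well = 9, mimics = mimics,
                effects = effects, cluster_k = 2)
}

#' Planted group of a demo-screen treatment
#'
#' @param treatments Treatment names from [two_group_screen_config()].
#' @return `"up"` or `"down"` per treatment.
#' @export
two_group_truth <- function(treatments) {
  ifelse(grepl("^up_", treatments), "up",
         ifelse(grepl("^down_", treatments), "down", NA_character_))
}
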