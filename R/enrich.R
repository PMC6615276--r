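#' Load a TargetScan-style prediction table
#'
#' Expects a tab-delimited file with at least the columns `miR_Family`,
#' `MiRBase_ID` (the mature member name), `Gene_Symbol` and `Species_ID`.
#' Rows are filtered to `species` (default human, 9606), gene symbols are
#' upper-cased and de-duplicated, and family membership is parsed from the
#' slash-separated family string (e.g. `miR-25-3p/32-5p/92-3p/363-3p/367-3p`)
#' so that a mature miR absent from `MiRBase_ID` can still resolve through
#' its seed family.
#'
#' @param path File path.
#' @param species Species taxon id kept (default `9606`).
#' @return A `target_table`: list with `targets` (mature name -> gene set),
#'   `family_targets` (family -> gene set) and `member_family`
#'   (mature name -> family).
#' @export
read_targetscan <- function(path, species = 9606) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(tab) <- gsub("[^A-Za-z0-9]+", "_", names(tab))
  required <- c("miR_Family", "MiRBase_ID", "Gene_Symbol", "Species_ID")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  tab <- tab[tab$Species_ID == species, , drop = FALSE]
  tab$Gene_Symbol <- toupper(tab$Gene_Symbol)
  fam_members <- lapply(unique(tab$miR_Family), parse_family_members)
  names(fam_members) <- unique(tab$miR_Family)
  member_family <- character()
  for (f in names(fam_members))
    member_family[fam_members[[f]]] <- f
  # members listed explicitly in MiRBase_ID also resolve to their family
  member_family[normalize_mir(tab$MiRBase_ID)] <- tab$miR_Family
  targets <- lapply(split(tab$Gene_Symbol, normalize_mir(tab$MiRBase_ID)),
                    function(g) sort(unique(g)))
  family_targets <- lapply(split(tab$Gene_Symbol, tab$miR_Family),
                           function(g) sort(unique(g)))
  structure(list(targets = targets, family_targets = family_targets,
                 member_family = member_family, species = species),
            class = "target_table")
}

# Strip species prefixes ("hsa-") and case-normalize the miR stem.
normalize_mir <- function(x) {
  x <- sub("^hsa-", "", x)
  sub("^mir", "miR", x, ignore.case = TRUE)
}

# "miR-25-3p/32-5p/92-3p/363-3p/367-3p" -> member mature names.
parse_family_members <- function(family) {
  parts <- strsplit(normalize_mir(family), "/", fixed = TRUE)[[1]]
  if (!length(parts)) return(character())
  prefix <- sub("^(let-|miR-).*", "\\1", parts[1])
  vapply(parts, function(p) {
    if (grepl("^(let-|miR-)", p)) p else paste0(prefix, p)
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.target_table <- function(x, ...) {
  cat(sprintf("target_table: %d mature miRs, %d families, species %s\n",
              length(x$targets), length(x$family_targets), x$species))
  invisible(x)
}

# Resolve one mature miR to its target gene set (exact name first, then
# family fallback with a message).
resolve_targets <- function(mir, table) {
  m <- normalize_mir(mir)
  if (m %in% names(table$targets)) return(table$targets[[m]])
  fam <- table$member_family[m]
  if (!is.na(fam) && fam %in% names(table$family_targets)) {
    message(sprintf("%s resolved via family %s", mir, fam))
    return(table$family_targets[[fam]])
  }
  stop("cannot resolve miR: ", mir)
}

#' Transcripts commonly targeted by a group of miRs
#'
#' Genes predicted as targets of at least `ceil(min_fraction * n)` of the
#' `n` queried miRs; the default (`min_fraction = 1`) is the strict
#' intersection, i.e. transcripts shared by every member of a phenotypic
#' cluster.
#'
#' @param mirs Character vector of mature miR names.
#' @param table A `target_table` from [read_targetscan()].
#' @param min_fraction Fraction of the group that must target a gene.
#' @return Sorted character vector of gene symbols.
#' @export
shared_targets <- function(mirs, table, min_fraction = 1) {
  stopifnot(length(mirs) >= 1, min_fraction > 0, min_fraction <= 1)
  sets <- lapply(mirs, resolve_targets, table = table)
  need <- ceiling(min_fraction * length(sets))
  counts <- table(unlist(lapply(sets, unique)))
  sort(names(counts)[counts >= need])
}

#' Read gene sets in GMT format
#'
#' @param path GMT file path.
#' @return Named list of character vectors (a gene-set collection).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, function(g) sort(unique(toupper(g))))
  if (any(lengths(sets) == 0)) stop("empty gene set in collection")
  if (anyDuplicated(names(sets))) stop("duplicated gene-set names")
  sets
}

#' Gene-set over-representation of a query gene set
#'
#' Upper-tail hypergeometric test per set: with universe size `N`, set size
#' `K`, query size `n` and overlap `k`, `p = P(X >= k)`. The EASE variant
#' (DAVID's conservative score) removes one overlapping gene, i.e. uses
#' `P(X >= k - 1 | K - 1 successes)`-style arithmetic by testing `k - 1`.
#' Benjamini-Hochberg FDR is computed across the collection.
#'
#' @param query Character vector of gene symbols.
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param universe Background gene symbols; defaults to the union of the
#'   collection's members.
#' @param method `"hypergeometric"` or `"ease"`.
#' @return data.frame sorted by p: set, overlap `k`, set size `K`, query
#'   size `n`, universe size `N`, `p`, BH `q`, overlapping genes.
#' @export
enrich_hyper <- function(query, collection,
                         universe = sort(unique(unlist(collection))),
                         method = c("hypergeometric", "ease")) {
  method <- match.arg(method)
  query <- unique(toupper(query))
  universe <- unique(toupper(universe))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped",
                    length(outside)))
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("empty query after universe filtering")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(s) {
    members <- intersect(collection[[s]], universe)
    K <- length(members)
    hit <- intersect(query, members)
    k <- length(hit)
    keff <- if (method == "ease") max(k - 1L, 0L) else k
    p <- if (keff == 0) 1 else
      stats::phyper(keff - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, k = k, K = K, n = n, N = N, p = p,
               genes = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), c("set", "k", "K", "n", "N", "p", "q", "genes")]
  rownames(out) <- NULL
  out
}

#' Count each miR's predicted targets within a gene list
#'
#' The pathway-membership query behind the Notch analysis: for every miR,
#' how many genes of `gene_list` it is predicted to target. Supports
#' threshold filtering downstream (e.g. miRs with more than 10 or fewer
#' than 5 targets in the list).
#'
#' @param gene_list Non-empty character vector of gene symbols.
#' @param mirs Mature miR names.
#' @param table A `target_table`.
#' @return data.frame: mir, n_targets, targets (";"-separated).
#' @export
mirs_targeting_genes <- function(gene_list, mirs, table) {
  if (!length(gene_list)) stop("gene list is empty")
  gene_list <- unique(toupper(gene_list))
  rows <- lapply(mirs, function(m) {
    hit <- intersect(resolve_targets(m, table), gene_list)
    data.frame(mir = m, n_targets = length(hit),
               targets = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Venn partition of 2-4 named sets
#'
#' Every non-empty region of the Venn diagram (exclusive and shared parts)
#' with its member names, count, and percentage of the union rounded to one
#' decimal — the arithmetic behind pathway-list comparisons.
#'
#' @param sets Named list of 2 to 4 character vectors.
#' @return A `venn_partition` data.frame: region (e.g. `"A&B"`), the member
#'   sets, count, pct, members.
#' @export
compare_pathway_sets <- function(sets) {
  m <- length(sets)
  if (m < 2 || m > 4) stop("need between 2 and 4 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  all_items <- sort(unique(unlist(sets)))
  if (!length(all_items)) stop("all sets are empty")
  memb <- vapply(sets, function(s) all_items %in% s, logical(length(all_items)))
  if (length(all_items) == 1) memb <- matrix(memb, nrow = 1,
                                             dimnames = list(NULL, names(sets)))
  sig <- apply(memb, 1, function(z) paste(names(sets)[z], collapse = "&"))
  rows <- lapply(split(all_items, sig), function(items) {
    data.frame(count = length(items),
               pct = round(100 * length(items) / length(all_items), 1),
               members = paste(items, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(region = rownames(out), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "union_size") <- length(all_items)
  class(out) <- c("venn_partition", "data.frame")
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("venn_partition: union of %d items\n", attr(x, "union_size")))
  print(as.data.frame(x)[, c("region", "count", "pct")], ...)
  invisible(x)
}

#' Read pathway lists from a supplementary Excel workbook
#'
#' Reads every sheet of an `.xlsx` workbook and returns each column as a
#' named character vector of pathway identifiers (empty cells dropped),
#' suitable as input to [compare_pathway_sets()]. Requires the `readxl`
#' package.
#'
#' @param path Workbook path.
#' @param sheets Optional sheet names (default: all).
#' @return Named list of character vectors (`<sheet>.<column>` names when
#'   the workbook has several sheets).
#' @export
read_pathway_workbook <- function(path, sheets = NULL) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("read_pathway_workbook requires the readxl package")
  if (!file.exists(path)) stop("workbook not found: ", path)
  if (is.null(sheets)) sheets <- readxl::excel_sheets(path)
  out <- list()
  for (s in sheets) {
    tab <- readxl::read_excel(path, sheet = s, col_types = "text")
    for (cn in names(tab)) {
      v <- tab[[cn]]
      v <- trimws(v[!is.na(v) & nzchar(trimws(v))])
      if (!length(v)) next
      nm <- if (length(sheets) > 1) paste(s, cn, sep = ".") else cn
      out[[nm]] <- unique(v)
    }
  }
  out
}
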