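# Over-representation analysis of gene lists against gene-set collections.

#' Map phosphosite ids to parent genes
#'
#' Site ids follow `gene_residuePosition` (e.g. `AKT2_S474`); the parent gene
#' is everything before the final `_S/T/Y<position>` token. Duplicates are
#' removed keeping the order of first occurrence.
#'
#' @param site_ids character vector
#' @export
map_sites_to_genes <- function(site_ids) {
  if (length(site_ids) == 0) return(character(0))
  ok <- grepl("^.+_[STY][0-9]+$", site_ids)
  if (any(!ok)) {
    stop("malformed site_id(s): ", paste(utils::head(site_ids[!ok]), collapse = ", "))
  }
  genes <- sub("_[STY][0-9]+$", "", site_ids)
  unique(genes)
}

#' Hypergeometric over-representation test
#'
#' For each gene set, tests whether the query list overlaps the set more than
#' expected under random draws from the universe: p = P(X >= k) for X
#' hypergeometric(N, K, n), where N is the universe size, K the set size
#' within the universe, n the query size and k the overlap. Benjamini-
#' Hochberg adjustment across sets.
#'
#' The recommended universe is every gene represented in the analyzed
#' (class-I filtered) site table, not the whole genome.
#'
#' @param query_genes character vector of query gene symbols
#' @param gene_sets a `gene_set_collection` (or named list of character
#'   vectors)
#' @param universe character vector of background gene symbols
#' @return data.frame per set: set, overlap (k), query_size (n), set_size
#'   (K), universe_size (N), p, fdr; sorted by p
#' @export
ora_test <- function(query_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(members)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, query_size = n, set_size = K,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
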