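## Weighted-LCA taxonomic binning of homolog sequences from reference hits,
## depth-corrected rank profiles, and gene/composition consensus bins.

UNASSIGNED <- "unassigned"

#' Weighted lowest-common-ancestor assignment for one query
#'
#' Implements score-weighted LCA placement of a homolog sequence from its
#' reference hits. Hits within `top_percent` percent of the best bit score
#' are retained; each votes for its full lineage with weight equal to its bit
#' score; the query is placed at the deepest node whose subtree accumulates
#' at least `weight_threshold` of the retained weight (the root always
#' qualifies).
#'
#' @param tree a [taxonomy_tree()]
#' @param hits data.frame with columns `taxon_id` and `bit_score` (one row
#'   per reference hit for this query); extra columns are ignored.
#' @param top_percent retain hits scoring at least
#'   `(1 - top_percent/100) * max(bit_score)`. Default 10.
#' @param weight_threshold subtree weight fraction a node must accumulate.
#'   Default 0.8. With a threshold above 0.5 the qualifying node at maximal
#'   depth is unique; at or below 0.5 ties are broken by larger accumulated
#'   weight, then by taxon id.
#' @return A taxon id, or `"unassigned"` for an empty hit table.
#' @references Placement rule follows the weighted-LCA reading used by
#'   MEGAN-style binning of protein homology hits.
#' @export
weighted_lca <- function(tree, hits, top_percent = 10, weight_threshold = 0.8) {
  check_number(top_percent, "top_percent", min = 0, max = 100)
  check_number(weight_threshold, "weight_threshold", min = 0, max = 1,
               strict_min = TRUE)
  if (is.null(hits) || nrow(hits) == 0L) return(UNASSIGNED)
  if (!all(c("taxon_id", "bit_score") %in% names(hits)))
    stop_arg("hits needs columns taxon_id, bit_score")
  if (any(!hits$taxon_id %in% names(tree$parent)))
    stop_arg("hit taxon not in tree: ",
             setdiff(hits$taxon_id, names(tree$parent))[1L])
  keep <- hits$bit_score >= (1 - top_percent / 100) * max(hits$bit_score)
  hits <- hits[keep, , drop = FALSE]
  total <- sum(hits$bit_score)
  acc <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(hits))) {
    for (id in tax_lineage(tree, hits$taxon_id[i])) {
      prev <- if (is.null(acc[[id]])) 0 else acc[[id]]
      acc[[id]] <- prev + hits$bit_score[i]
    }
  }
  ids <- ls(acc)
  w <- vapply(ids, function(id) acc[[id]], numeric(1))
  ok <- ids[w >= weight_threshold * total - 1e-12]
  if (!length(ok)) return(tree$nodes$taxon_id[is.na(tree$nodes$parent_id)])
  d <- tree$depth[match(ok, tree$nodes$taxon_id)]
  cand <- ok[d == max(d)]
  if (length(cand) > 1L) {
    cw <- w[match(cand, ids)]
    cand <- cand[order(-cw, cand)]
  }
  cand[1L]
}

#' Assign many queries by weighted LCA
#'
#' @inheritParams weighted_lca
#' @param hit_table data.frame of reference hits with a `query_id` column in
#'   addition to `taxon_id` and `bit_score`.
#' @return data.frame (`query_id`, `taxon_id`) with one row per query;
#'   queries without hits are absent (use [profile_at_rank()]'s
#'   `total_queries` bookkeeping for them).
#' @export
assign_taxonomy <- function(tree, hit_table, top_percent = 10,
                            weight_threshold = 0.8) {
  if (!all(c("query_id", "taxon_id", "bit_score") %in% names(hit_table)))
    stop_arg("hit_table needs query_id, taxon_id, bit_score")
  qs <- unique(hit_table$query_id)
  tax <- vapply(qs, function(q)
    weighted_lca(tree, hit_table[hit_table$query_id == q, , drop = FALSE],
                 top_percent, weight_threshold), "")
  data.frame(query_id = qs, taxon_id = unname(tax), stringsAsFactors = FALSE)
}

#' Depth-corrected taxonomic profile at a rank
#'
#' Accumulates the copy weight of each assigned query (1.0 for unassembled
#' sequences, scaffold read depth for assembled ones) at its assignment's
#' ancestor of the requested rank. Assignments shallower than `rank`
#' contribute to the `above_rank` mass, unassigned queries to `unassigned`;
#' total mass is conserved at every rank.
#'
#' @param tree a [taxonomy_tree()]
#' @param assignments data.frame (`query_id`, `taxon_id`) as returned by
#'   [assign_taxonomy()]; `taxon_id` may be `"unassigned"`.
#' @param weights named numeric: copy weight per query id. Queries present in
#'   `weights` but absent from `assignments` are counted as unassigned.
#' @param rank target rank (e.g. `"phylum"`).
#' @return Object of class `taxonomic_profile`: list with `rank`,
#'   `abundance` (named numeric per taxon at `rank`), `above_rank`,
#'   `unassigned`, `total`.
#' @export
profile_at_rank <- function(tree, assignments, weights, rank) {
  if (!rank %in% TAX_RANKS) stop_arg("unknown rank: ", rank)
  if (is.null(names(weights)) || any(weights < 0))
    stop_arg("weights must be a named non-negative vector")
  asg <- stats::setNames(assignments$taxon_id, assignments$query_id)
  abn <- new.env(hash = TRUE, parent = emptyenv())
  above <- 0
  unasg <- 0
  rk_num <- match(rank, TAX_RANKS)
  for (q in names(weights)) {
    tx <- if (q %in% names(asg)) asg[[q]] else UNASSIGNED
    if (identical(tx, UNASSIGNED)) {
      unasg <- unasg + weights[[q]]
      next
    }
    if (match(tree$rank[[tx]], TAX_RANKS) < rk_num) {
      above <- above + weights[[q]]
      next
    }
    anc <- tax_ancestor_at_rank(tree, tx, rank)
    prev <- if (is.null(abn[[anc]])) 0 else abn[[anc]]
    abn[[anc]] <- prev + weights[[q]]
  }
  ids <- sort(ls(abn))
  structure(list(
    rank = rank,
    abundance = stats::setNames(vapply(ids, function(i) abn[[i]], numeric(1)), ids),
    above_rank = above, unassigned = unasg,
    total = sum(weights)), class = "taxonomic_profile")
}

#' @export
print.taxonomic_profile <- function(x, ...) {
  cat("taxonomic_profile at rank", x$rank, "-", length(x$abundance),
      "taxa; total mass", format(x$total), "\n")
  invisible(x)
}

#' Consensus of a gene-wise and a composition-based scaffold assignment
#'
#' Returns the LCA of the two assignments; when one side is the
#' `"unassigned"` sentinel the other is returned unchanged.
#'
#' @inheritParams tax_lineage
#' @param gene_wise_taxon,composition_taxon taxon ids or `"unassigned"`.
#'   The composition-based label is an external input (its classifier is not
#'   part of this package).
#' @return A taxon id, or `"unassigned"` when both sides are unassigned.
#' @export
consensus_bin <- function(tree, gene_wise_taxon, composition_taxon) {
  a_un <- identical(gene_wise_taxon, UNASSIGNED)
  b_un <- identical(composition_taxon, UNASSIGNED)
  if (a_un && b_un) return(UNASSIGNED)
  if (a_un) return(composition_taxon)
  if (b_un) return(gene_wise_taxon)
  tax_lca(tree, c(gene_wise_taxon, composition_taxon))
}
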