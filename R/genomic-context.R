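## Gene-neighborhood profiling around marker hits on annotated scaffolds:
## windows measured in genes, domain-of-interest flags, co-occurrence
## summaries, and a domain-content similarity for scaffold comparison.

#' Extract the gene neighborhood of a marker gene
#'
#' Orders the scaffold's genes by coordinate and returns up to
#' `window_genes` genes on each side of the marker (offset 0), with a
#' presence flag per configured domain of interest.
#'
#' @param scaffold data.frame of one scaffold's genes with columns
#'   `gene_id`, `start`, `end`, `strand`, `domain_id` (comma-separated for
#'   multi-domain genes)
#' @param marker_gene `gene_id` of the marker (must be on the scaffold)
#' @param window_genes genes kept on each side (default 10)
#' @param targets named character vector of domains of interest (default
#'   [lipid_context_domains()])
#' @return Object of class `context_profile`: data.frame (`gene_id`,
#'   `strand`, `offset`, `domain_id`) with attributes `marker_gene`,
#'   `scaffold_id` and `flags` (named logical over `targets`).
#' @export
extract_context <- function(scaffold, marker_gene, window_genes = 10L,
                            targets = lipid_context_domains()) {
  req <- c("gene_id", "start", "end", "strand", "domain_id")
  if (!all(req %in% names(scaffold)))
    stop_arg("scaffold needs columns ", paste(req, collapse = ", "))
  check_number(window_genes, "window_genes", min = 0)
  g <- scaffold[order(scaffold$start), , drop = FALSE]
  at <- which(g$gene_id == marker_gene)
  if (length(at) != 1L)
    stop_arg("marker gene ", marker_gene, " not found (once) on scaffold")
  lo <- max(1L, at - window_genes)
  hi <- min(nrow(g), at + window_genes)
  win <- g[lo:hi, , drop = FALSE]
  win$offset <- (lo:hi) - at
  doms <- unlist(strsplit(win$domain_id[win$offset != 0L], ","))
  flags <- stats::setNames(unname(targets) %in% doms,
                           if (is.null(names(targets))) targets
                           else names(targets))
  out <- win[, c("gene_id", "strand", "offset", "domain_id")]
  rownames(out) <- NULL
  structure(out, class = c("context_profile", "data.frame"),
            marker_gene = marker_gene,
            scaffold_id = if ("scaffold_id" %in% names(g))
              g$scaffold_id[1L] else NA_character_,
            flags = flags)
}

#' Extract contexts for every marker gene of a study
#'
#' @param genes pooled gene table (e.g. `study_table(study, "genes")`) with a
#'   `scaffold_id` column
#' @param marker_domain domain marking the anchor genes (default
#'   the WS/DGAT marker, `"PF03007"`)
#' @inheritParams extract_context
#' @return List of `context_profile` objects, one per marker gene.
#' @export
extract_contexts <- function(genes, marker_domain = FAMILY_DOMAIN,
                             window_genes = 10L,
                             targets = lipid_context_domains()) {
  anchors <- genes[vapply(strsplit(genes$domain_id, ","),
                          function(d) marker_domain %in% d, TRUE), ,
                   drop = FALSE]
  lapply(seq_len(nrow(anchors)), function(i) {
    sc <- genes[genes$scaffold_id == anchors$scaffold_id[i], , drop = FALSE]
    extract_context(sc, anchors$gene_id[i], window_genes, targets)
  })
}

#' Domain co-occurrence over context profiles
#'
#' @param profiles list of [extract_context()] profiles (>= 1)
#' @param domain_set domains to summarize; default: the flag set of the
#'   first profile
#' @return data.frame (`domain`, `n_contexts_present`, `fraction`), the
#'   fraction of profiles whose window contains each domain.
#' @export
cooccurrence_summary <- function(profiles, domain_set = NULL) {
  if (!length(profiles)) stop_arg("need at least one context profile")
  if (is.null(domain_set)) domain_set <- names(attr(profiles[[1L]], "flags"))
  if (!length(domain_set)) stop_arg("empty domain set")
  counts <- vapply(domain_set, function(d) {
    sum(vapply(profiles, function(p) {
      fl <- attr(p, "flags")
      if (d %in% names(fl)) fl[[d]]
      else d %in% unlist(strsplit(p$domain_id[p$offset != 0L], ","))
    }, TRUE))
  }, 1L)
  data.frame(domain = domain_set, n_contexts_present = counts,
             fraction = counts / length(profiles),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Domain-content similarity of two scaffolds
#'
#' Jaccard index of the multisets of domain annotations on the two
#' scaffolds (multiset intersection over multiset union) — a
#' annotation-level stand-in for nucleotide synteny identity.
#'
#' @param scaffold_a,scaffold_b gene tables with a `domain_id` column
#' @return Similarity in `[0, 1]`; 0 (with a warning) when either scaffold
#'   has no annotated genes.
#' @export
domain_content_similarity <- function(scaffold_a, scaffold_b) {
  dom <- function(s) {
    d <- unlist(strsplit(s$domain_id, ","))
    d[!is.na(d) & nzchar(d)]
  }
  a <- dom(scaffold_a)
  b <- dom(scaffold_b)
  if (!length(a) || !length(b)) {
    warning("scaffold with no annotated genes; similarity defined as 0")
    return(0)
  }
  doms <- union(a, b)
  ca <- table(factor(a, levels = doms))
  cb <- table(factor(b, levels = doms))
  sum(pmin(ca, cb)) / sum(pmax(ca, cb))
}
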