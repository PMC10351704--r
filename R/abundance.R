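## Depth-corrected gene copy estimation, single-copy-gene normalization and
## per-genome census. An unassembled hit counts 1.0; an assembled hit counts
## its scaffold's read depth, approximating pre-assembly sequence abundance.

#' Attach sample/fraction/scaffold context to domain hits
#'
#' Joins a [scan_proteins()] (or [ingest_domain_table()]) hit table to a
#' protein record table by `protein_id`, picking up `sample_id`, `fraction`
#' and `scaffold_id` (and `gene` when present) so the hits can be fed to
#' [estimate_copies()].
#'
#' @param hits data.frame with a `protein_id` column
#' @param proteins data.frame with `protein_id`, `sample_id`, `fraction`,
#'   `scaffold_id` (e.g. the `proteins` table of a synthetic metagenome)
#' @return The hit table with the context columns appended.
#' @export
annotate_hits <- function(hits, proteins) {
  idx <- match(hits$protein_id, proteins$protein_id)
  if (anyNA(idx))
    stop_arg("hit protein(s) missing from the protein table: ",
             hits$protein_id[which(is.na(idx))[1L]])
  keep <- intersect(c("sample_id", "fraction", "scaffold_id", "gene",
                      "genome_id", "taxon_id", "weight"),
                    names(proteins))
  cbind(hits, proteins[idx, setdiff(keep, names(hits)), drop = FALSE],
        row.names = NULL)
}

#' Depth-corrected estimated gene copies
#'
#' Each unassembled hit contributes 1.0 copy; each assembled hit contributes
#' its scaffold's read depth. Totals are returned per sample (and per family
#' when a `family` column is present).
#'
#' @param hits data.frame with columns `sample_id`, `fraction`
#'   (`"assembled"`/`"unassembled"`) and `scaffold_id` (NA allowed for
#'   unassembled rows); an optional `family` column splits the totals.
#' @param scaffolds data.frame with `scaffold_id` and `read_depth` (> 0)
#' @param mode `"strict"` (default): an assembled hit whose scaffold has no
#'   depth is an error; `"lenient"`: it contributes 1.0 with a warning.
#' @return data.frame with one row per sample (x family):
#'   `copies_unassembled`, `copies_assembled_weighted`, `estimated_copies`.
#' @details Additive over disjoint hit subsets; scaling all depths by `c`
#'   scales the assembled component by exactly `c`.
#' @export
estimate_copies <- function(hits, scaffolds, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  req <- c("sample_id", "fraction")
  if (!all(req %in% names(hits)))
    stop_arg("hits needs columns ", paste(req, collapse = ", "))
  if (!all(hits$fraction %in% c("assembled", "unassembled")))
    stop_arg("fraction must be 'assembled' or 'unassembled'")
  fam <- if ("family" %in% names(hits)) hits$family else "all"
  w <- numeric(nrow(hits))
  un <- hits$fraction == "unassembled"
  w[un] <- 1
  if (any(!un)) {
    d <- scaffolds$read_depth[match(hits$scaffold_id[!un],
                                    scaffolds$scaffold_id)]
    if (anyNA(d)) {
      missing_sc <- unique(hits$scaffold_id[!un][is.na(d)])
      if (mode == "strict")
        stop_arg("no read depth for scaffold(s): ",
                 paste(utils::head(missing_sc, 3), collapse = ", "))
      warning("no read depth for ", length(missing_sc),
              " scaffold(s); assembled hits counted as 1.0")
      d[is.na(d)] <- 1
    }
    if (any(d <= 0)) stop_arg("read depths must be > 0")
    w[!un] <- d
  }
  key <- data.frame(sample_id = hits$sample_id, family = fam,
                    stringsAsFactors = FALSE)
  agg <- function(v) {
    if (!nrow(key)) return(numeric(0))
    tapply(v, paste(key$sample_id, key$family, sep = "\r"), sum)
  }
  tot_un <- agg(w * un)
  tot_as <- agg(w * !un)
  if (!length(tot_un))
    return(data.frame(sample_id = character(0), family = character(0),
                      copies_unassembled = numeric(0),
                      copies_assembled_weighted = numeric(0),
                      estimated_copies = numeric(0), stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(names(tot_un), "\r", fixed = TRUE))
  out <- data.frame(sample_id = parts[, 1], family = parts[, 2],
                    copies_unassembled = as.numeric(tot_un),
                    copies_assembled_weighted = as.numeric(tot_as),
                    stringsAsFactors = FALSE)
  out$estimated_copies <- out$copies_unassembled +
    out$copies_assembled_weighted
  rownames(out) <- NULL
  out[order(out$sample_id, out$family), , drop = FALSE]
}

#' Single-copy-gene normalization of a family estimate
#'
#' Divides the family's estimated copies by each panel gene's estimated
#' copies and summarizes the resulting per-genome-unit ratios by their mean,
#' standard deviation (n-1) and coefficient of variation.
#'
#' @param family_estimate estimated family copies in one sample (> 0 allowed
#'   to be 0)
#' @param panel_estimates named numeric vector of the panel genes' estimated
#'   copies; all must be > 0.
#' @param n_panel required panel size (default 12); set `NULL` to accept any
#'   size.
#' @return Object of class `abundance_estimate`: list with `ratios`
#'   (named, one per panel gene), `mean`, `sd`, `cv`.
#' @export
single_copy_ratios <- function(family_estimate, panel_estimates,
                               n_panel = 12L) {
  check_number(family_estimate, "family_estimate", min = 0)
  if (is.null(names(panel_estimates)))
    stop_arg("panel_estimates must be named by gene")
  if (!is.null(n_panel) && length(panel_estimates) != n_panel)
    stop_arg("panel must have exactly ", n_panel, " genes (got ",
             length(panel_estimates), ")")
  bad <- names(panel_estimates)[panel_estimates <= 0 |
                                  is.na(panel_estimates)]
  if (length(bad))
    stop_arg("non-positive panel estimate for gene(s): ",
             paste(bad, collapse = ", "))
  r <- family_estimate / panel_estimates
  m <- mean(r)
  s <- stats::sd(r)
  structure(list(ratios = r, mean = m, sd = s,
                 cv = if (m > 0) s / m else NA_real_),
            class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("abundance_estimate: ratio mean %.4g sd %.4g cv %.4g over %d panel genes\n",
              x$mean, x$sd, x$cv, length(x$ratios)))
  invisible(x)
}

#' Per-sample relative abundance summary
#'
#' Convenience wrapper around [estimate_copies()] + [single_copy_ratios()]:
#' computes, per sample, the family's estimated copies and its
#' single-copy-panel normalization.
#'
#' @param hits hit table with `sample_id`, `fraction`, `scaffold_id` and a
#'   `family` column naming the gene of each hit (the marker family plus the
#'   panel genes)
#' @param scaffolds scaffold depth table (see [estimate_copies()])
#' @param family_gene family label in the `family` column (default
#'   `"WSDGAT"`)
#' @param panel_genes panel labels (default `names(single_copy_panel())`)
#' @param mode passed to [estimate_copies()]
#' @return data.frame with one row per sample: `estimated_copies`,
#'   `ratio_mean`, `ratio_sd`, `ratio_cv`.
#' @export
relative_abundance <- function(hits, scaffolds, family_gene = FAMILY_GENE,
                               panel_genes = names(single_copy_panel()),
                               mode = "strict") {
  if (!"family" %in% names(hits)) stop_arg("hits needs a 'family' column")
  est <- estimate_copies(hits, scaffolds, mode)
  samples <- sort(unique(est$sample_id))
  rows <- lapply(samples, function(s) {
    e <- est[est$sample_id == s, , drop = FALSE]
    fam <- e$estimated_copies[e$family == family_gene]
    fam <- if (length(fam)) fam else 0
    pan <- stats::setNames(e$estimated_copies[match(panel_genes, e$family)],
                           panel_genes)
    pan[is.na(pan)] <- 0
    scr <- single_copy_ratios(fam, pan, n_panel = length(panel_genes))
    data.frame(sample_id = s, estimated_copies = fam,
               ratio_mean = scr$mean, ratio_sd = scr$sd, ratio_cv = scr$cv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Census of family copies per genome
#'
#' @param genome_hits data.frame with one row per detected copy, columns
#'   `genome_id` and `taxon_id`; genomes with zero copies must still be
#'   listed in `genomes` to enter the denominator.
#' @param genomes data.frame (`genome_id`, `taxon_id`) enumerating all
#'   censused genomes.
#' @param tree optional [taxonomy_tree()]; when given, taxa are validated
#'   and a summary rank can be requested.
#' @param rank optional rank for the per-taxon summary (requires `tree`).
#' @return List with `census` (data.frame `genome_id`, `taxon_id`,
#'   `n_copies`) and, when `rank` is given, `summary` (per taxon at `rank`:
#'   `n_genomes`, `fraction_with_copy`, `mean_copies_carriers`,
#'   `sd_copies_carriers`).
#' @export
genome_census <- function(genome_hits, genomes, tree = NULL, rank = NULL) {
  if (!all(c("genome_id", "taxon_id") %in% names(genomes)))
    stop_arg("genomes needs genome_id and taxon_id")
  if (nrow(genome_hits) &&
      !all(genome_hits$genome_id %in% genomes$genome_id))
    stop_arg("hits reference unknown genome(s)")
  if (!is.null(tree)) {
    unknown <- setdiff(genomes$taxon_id, names(tree$parent))
    if (length(unknown))
      stop_arg("unknown taxon label(s): ",
               paste(utils::head(unknown, 3), collapse = ", "))
  }
  tab <- table(factor(genome_hits$genome_id, levels = genomes$genome_id))
  census <- data.frame(genome_id = genomes$genome_id,
                       taxon_id = genomes$taxon_id,
                       n_copies = as.integer(tab),
                       stringsAsFactors = FALSE)
  out <- list(census = census)
  if (!is.null(rank)) {
    if (is.null(tree)) stop_arg("rank summary needs a taxonomy tree")
    grp <- vapply(census$taxon_id, function(t)
      tax_ancestor_at_rank(tree, t, rank), "")
    sp <- split(census$n_copies, grp)
    out$summary <- data.frame(
      taxon_id = names(sp),
      n_genomes = vapply(sp, length, 1L),
      fraction_with_copy = vapply(sp, function(v) mean(v >= 1L), 1),
      mean_copies_carriers = vapply(sp, function(v)
        if (any(v >= 1L)) mean(v[v >= 1L]) else NA_real_, 1),
      sd_copies_carriers = vapply(sp, function(v)
        if (sum(v >= 1L) > 1L) stats::sd(v[v >= 1L]) else NA_real_, 1),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}
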