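## De novo greedy identity clustering of homolog proteins into OPUs
## (operational protein units), the depth-corrected OPU x sample table, and
## the minimum-size filter.

#' Global pairwise identity of two protein sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and affine
#' gaps (open -10, extend -1) in score space; identity is the number of
#' identical aligned residues divided, by default, by the length of the
#' shorter sequence (the convention of greedy clustering tools), optionally
#' by the alignment length.
#'
#' @param a,b non-empty amino-acid strings
#' @param denominator `"shorter"` (default) or `"alignment"`
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, denominator = c("shorter", "alignment")) {
  denominator <- match.arg(denominator)
  if (!nzchar(a) || !nzchar(b)) stop_arg("empty sequence")
  aa <- aa_alphabet()
  mat <- matrix(0, 20, 20, dimnames = list(aa, aa))
  diag(mat) <- 1
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 1)
  n_id <- Biostrings::nmatch(pa)
  den <- switch(denominator,
                shorter = min(nchar(a), nchar(b)),
                alignment = Biostrings::nchar(Biostrings::alignedPattern(pa)))
  n_id / den
}

#' Greedy identity clustering into OPUs
#'
#' Sequences are sorted by length descending (ties broken by id ascending);
#' each sequence joins the first existing cluster whose representative it
#' matches at `cutoff` identity or better, otherwise it founds a new
#' cluster. Representatives are therefore the longest member of each
#' cluster. The procedure is deterministic and invariant to input order.
#'
#' @param seqs named character vector of protein sequences
#' @param cutoff identity threshold (default 0.8, the study value)
#' @param denominator passed to [pairwise_identity()]
#' @return Object of class `opu_set`: list with `opus` (data.frame
#'   `opu_id`, `representative_id`, `n_sequences`) and `members` (data.frame
#'   `seq_id`, `opu_id`, `identity_to_rep`).
#' @export
greedy_cluster <- function(seqs, cutoff = 0.8,
                           denominator = c("shorter", "alignment")) {
  denominator <- match.arg(denominator)
  check_number(cutoff, "cutoff", min = 0, max = 1)
  if (!length(seqs)) stop_arg("need at least one sequence")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop_arg("seqs must have unique names")
  if (any(!nzchar(seqs))) stop_arg("empty sequence")
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  ## identical sequences always land in the cluster of their first-sorted
  ## occurrence (earlier representatives that rejected the first occurrence
  ## reject its twins; later ones are scanned after it), so align each
  ## distinct sequence only once
  first_ix <- match(seqs, seqs)
  rep_id <- character(0)
  assign_opu <- integer(length(seqs))
  ident <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    if (first_ix[i] < i) {
      assign_opu[i] <- assign_opu[first_ix[i]]
      ident[i] <- ident[first_ix[i]]
      next
    }
    placed <- FALSE
    for (k in seq_along(rep_id)) {
      pid <- pairwise_identity(seqs[[i]], seqs[[rep_id[k]]], denominator)
      if (pid >= cutoff) {
        assign_opu[i] <- k
        ident[i] <- pid
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_id <- c(rep_id, names(seqs)[i])
      assign_opu[i] <- length(rep_id)
      ident[i] <- 1
    }
  }
  opu_ids <- sprintf("OPU_%04d", seq_along(rep_id))
  members <- data.frame(seq_id = names(seqs),
                        opu_id = opu_ids[assign_opu],
                        identity_to_rep = ident,
                        stringsAsFactors = FALSE)
  opus <- data.frame(opu_id = opu_ids, representative_id = rep_id,
                     n_sequences = as.integer(table(factor(assign_opu,
                       levels = seq_along(rep_id)))),
                     stringsAsFactors = FALSE)
  structure(list(opus = opus, members = members, cutoff = cutoff),
            class = "opu_set")
}

#' @export
print.opu_set <- function(x, ...) {
  cat("opu_set:", nrow(x$opus), "OPUs from", nrow(x$members),
      "sequences at identity cutoff", x$cutoff, "\n")
  invisible(x)
}

#' Depth-corrected OPU x sample abundance table
#'
#' Cell (OPU, sample) is the sum of the corrected weights (1.0 for
#' unassembled members, scaffold read depth for assembled ones) of that
#' OPU's members observed in that sample.
#'
#' @param opus an [greedy_cluster()] `opu_set`
#' @param weights data.frame with `seq_id`, `sample_id`, `weight`; every
#'   member must appear exactly once.
#' @return Object of class `opu_table`: list with `abundance` (matrix, OPUs
#'   x samples), and `meta` (data.frame `opu_id`, `representative_id`,
#'   `n_sequences`).
#' @export
opu_abundance <- function(opus, weights) {
  req <- c("seq_id", "sample_id", "weight")
  if (!all(req %in% names(weights)))
    stop_arg("weights needs columns ", paste(req, collapse = ", "))
  idx <- match(opus$members$seq_id, weights$seq_id)
  if (anyNA(idx))
    stop_arg("member without weight: ",
             opus$members$seq_id[which(is.na(idx))[1L]])
  w <- weights$weight[idx]
  if (any(w < 0 | is.na(w))) stop_arg("weights must be non-negative")
  samp <- sort(unique(weights$sample_id))
  mat <- matrix(0, nrow(opus$opus), length(samp),
                dimnames = list(opus$opus$opu_id, samp))
  agg <- tapply(w, list(factor(opus$members$opu_id,
                               levels = opus$opus$opu_id),
                        factor(weights$sample_id[idx], levels = samp)), sum)
  agg[is.na(agg)] <- 0
  mat[, ] <- agg
  structure(list(abundance = mat, meta = opus$opus), class = "opu_table")
}

#' @export
print.opu_table <- function(x, ...) {
  cat("opu_table:", nrow(x$abundance), "OPUs x", ncol(x$abundance),
      "samples; total corrected abundance", format(sum(x$abundance)), "\n")
  invisible(x)
}

#' Filter OPUs by raw member count
#'
#' Keeps OPUs containing at least `min_sequences` member sequences (the raw
#' count, not the corrected abundance), preserving row order. Idempotent.
#'
#' @param table an [opu_abundance()] `opu_table`
#' @param min_sequences inclusive threshold (default 10, the study value)
#' @return The filtered `opu_table`.
#' @export
filter_opus <- function(table, min_sequences = 10L) {
  check_number(min_sequences, "min_sequences", min = 0)
  keep <- table$meta$n_sequences >= min_sequences
  structure(list(abundance = table$abundance[keep, , drop = FALSE],
                 meta = table$meta[keep, , drop = FALSE]),
            class = "opu_table")
}

#' Community matrix view of an OPU table
#'
#' @param table an `opu_table`
#' @return Numeric matrix with samples as rows and OPUs as columns, the
#'   orientation expected by the community statistics functions.
#' @export
as_community_matrix <- function(table) {
  t(table$abundance)
}
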