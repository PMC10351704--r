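## Detection of marker-domain homologs in protein sets: an ungapped
## position-specific scoring matrix built from a seed alignment, an
## empirical Gumbel E-value calibration on background decoys, a window scan
## with the study's E-value cutoff, and an ingestion path for per-domain
## tabular output of external profile-search tools.

#' Build a log-odds profile from a seed alignment
#'
#' Columns with more than 50% gaps are dropped; each remaining column gets
#' per-residue scores `log2((count + A * 20 * bg) / (rows + A * 20) / bg)`
#' in bits, i.e. observed frequency with background-proportional pseudocounts
#' against the background.
#'
#' @param alignment aligned sequences of equal length: a character vector or
#'   `Biostrings::AAStringSet` (gap characters `-` or `.`), at least 2 rows.
#' @param background residue background frequencies (length 20, sums to 1);
#'   default uniform.
#' @param pseudocount pseudocount weight `A` (total added count `20 * A`);
#'   default 0.5.
#' @param domain_id label attached to hits from this profile
#' @return Object of class `profile_model`: scores matrix (`L` x 20, bits),
#'   background, and (after [calibrate_evalue()]) Gumbel location/scale.
#' @export
build_profile <- function(alignment, background = rep(1 / 20, 20),
                          pseudocount = 0.5, domain_id = FAMILY_DOMAIN) {
  if (inherits(alignment, "AAStringSet"))
    alignment <- as.character(alignment)
  if (length(alignment) < 2L)
    stop_arg("alignment needs at least 2 sequences")
  if (length(unique(nchar(alignment))) != 1L)
    stop_arg("ragged alignment: sequences have unequal aligned lengths")
  if (abs(sum(background) - 1) > 1e-9 || length(background) != 20L)
    stop_arg("background must be 20 frequencies summing to 1")
  rows <- length(alignment)
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  gapfrac <- colMeans(mat == "-" | mat == ".")
  keep <- gapfrac <= 0.5
  if (!any(keep)) stop_arg("all columns are majority-gap")
  mat <- mat[, keep, drop = FALSE]
  L <- ncol(mat)
  if (L < 10L) stop_arg("profile length must be >= 10 after gap filtering")
  aa <- aa_alphabet()
  scores <- matrix(0, L, 20, dimnames = list(NULL, aa))
  a_tot <- pseudocount * 20
  for (j in seq_len(L)) {
    counts <- table(factor(mat[, j], levels = aa))
    n_eff <- sum(counts)  # gaps in minority columns carry no count
    freq <- (as.numeric(counts) + pseudocount * 20 * background) /
      (n_eff + a_tot)
    scores[j, ] <- log2(freq / background)
  }
  structure(list(length = L, scores = scores, background = background,
                 pseudocount = pseudocount, domain_id = domain_id,
                 mu = NA_real_, beta = NA_real_, n_decoys = 0L),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat("profile_model", x$domain_id, "- length", x$length,
      if (is.na(x$beta)) "(uncalibrated)" else
        sprintf("(Gumbel mu=%.3f beta=%.3f, %d decoys)",
                x$mu, x$beta, x$n_decoys), "\n")
  invisible(x)
}

## best ungapped window score of an integer-coded sequence against the PSSM;
## ties go to the earliest offset
best_window <- function(x, scores) {
  L <- nrow(scores)
  m <- length(x) - L + 1L
  if (m < 1L) return(NULL)
  tot <- numeric(m)
  for (j in seq_len(L))
    tot <- tot + scores[j, ][x[j:(j + m - 1L)]]
  o <- which.max(tot)
  list(score = tot[o], start = o, end = o + L - 1L)
}

## maximum-likelihood Gumbel fit (location mu, scale beta)
fit_gumbel <- function(x) {
  if (stats::sd(x) < 1e-9)
    stop_arg("degenerate decoy score variance; cannot calibrate")
  xc <- x - mean(x)
  g <- function(beta) {
    lw <- -xc / beta
    w <- exp(lw - max(lw))  # stabilized weights
    beta - mean(xc) + sum(xc * w) / sum(w)
  }
  ## ML beta lies below the mean-centered moment bound; bracket generously
  lo <- 1e-6
  hi <- max(stats::sd(x) * 5, 1)
  while (g(hi) < 0) hi <- hi * 2
  beta <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  lw <- -xc / beta
  mx <- max(lw)
  mu <- mean(x) - beta * (mx + log(mean(exp(lw - mx))))
  c(mu = mu, beta = beta)
}

#' Calibrate profile E-values on background decoys
#'
#' Scores `n_decoys` i.i.d. background-sampled decoy proteins, fits a Gumbel
#' distribution to their best-window scores by maximum likelihood, and
#' stores it so that `E(s) = N_db * (1 - GumbelCDF(s))` for a database of
#' `N_db` proteins.
#'
#' @param profile a [build_profile()] result
#' @param decoy_lengths lengths of the decoys (recycled to `n_decoys`)
#' @param n_decoys number of decoys (>= 500)
#' @param seed integer RNG seed
#' @return The calibrated `profile_model`.
#' @export
calibrate_evalue <- function(profile, decoy_lengths = 300L, n_decoys = 1000L,
                             seed = 1L) {
  check_number(n_decoys, "n_decoys", min = 500)
  lens <- rep_len(as.integer(decoy_lengths), n_decoys)
  if (any(lens < profile$length))
    stop_arg("decoy_lengths must be >= profile length")
  scores <- with_seed(seed, {
    vapply(lens, function(n) {
      x <- sample.int(20L, n, replace = TRUE, prob = profile$background)
      best_window(x, profile$scores)$score
    }, numeric(1))
  }, stream = 21L)
  fit <- fit_gumbel(scores)
  profile$mu <- fit[["mu"]]
  profile$beta <- fit[["beta"]]
  profile$n_decoys <- as.integer(n_decoys)
  profile
}

gumbel_sf <- function(s, mu, beta) {
  ## numerically stable 1 - exp(-exp(-(s-mu)/beta))
  -expm1(-exp(-(s - mu) / beta))
}

#' Scan proteins for the marker domain
#'
#' Computes each protein's best ungapped window score against the calibrated
#' profile and reports a hit when its E-value (over the `n_db` scanned
#' proteins) is at or below `e_cutoff`. One best hit is retained per protein.
#' Proteins shorter than the profile are skipped with a message.
#'
#' @param proteins named character vector or `Biostrings::AAStringSet`
#' @param profile a calibrated `profile_model`
#' @param e_cutoff E-value cutoff (default `1e-5`, the study threshold)
#' @param n_db effective database size for E-values; defaults to the number
#'   of scanned proteins.
#' @return data.frame of domain hits: `protein_id`, `domain_id`,
#'   `bit_score`, `e_value`, `start`, `end` (1-based inclusive envelope).
#' @export
scan_proteins <- function(proteins, profile, e_cutoff = 1e-5, n_db = NULL) {
  if (inherits(proteins, "AAStringSet")) {
    nm <- names(proteins)
    proteins <- stats::setNames(as.character(proteins), nm)
  }
  if (is.na(profile$beta)) stop_arg("profile is not calibrated")
  if (length(proteins) && is.null(names(proteins)))
    stop_arg("proteins must be named")
  if (is.null(n_db)) n_db <- length(proteins)
  out <- vector("list", length(proteins))
  skipped <- 0L
  aa <- aa_alphabet()
  for (i in seq_along(proteins)) {
    x <- match(strsplit(toupper(proteins[[i]]), "")[[1]], aa)
    x[is.na(x)] <- 1L  # unknown residues scored as 'A'
    bw <- best_window(x, profile$scores)
    if (is.null(bw)) {
      skipped <- skipped + 1L
      next
    }
    e <- n_db * gumbel_sf(bw$score, profile$mu, profile$beta)
    if (e <= e_cutoff)
      out[[i]] <- data.frame(protein_id = names(proteins)[i],
                             domain_id = profile$domain_id,
                             bit_score = bw$score, e_value = e,
                             start = bw$start, end = bw$end,
                             stringsAsFactors = FALSE)
  }
  if (skipped)
    message(skipped, " protein(s) shorter than the profile were skipped")
  hits <- do.call(rbind, out)
  if (is.null(hits))
    hits <- data.frame(protein_id = character(0), domain_id = character(0),
                       bit_score = numeric(0), e_value = numeric(0),
                       start = integer(0), end = integer(0),
                       stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  hits
}

#' Write domain hits in the per-domain tabular dialect
#'
#' Whitespace-delimited table compatible with the per-domain tabular output
#' of common profile-search tools (23 columns, `#` comment header);
#' round-trips through [ingest_domain_table()].
#'
#' @param hits data.frame as returned by [scan_proteins()]
#' @param path output file
#' @param qlen profile length written into the query-length column
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(hits, path, qlen = NA_integer_) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# target name accession tlen query name accession qlen E-value score bias # of c-Evalue i-Evalue score bias from to from to from to acc description",
    "#"), con)
  if (nrow(hits)) {
    lines <- sprintf(
      "%s - %d %s - %d %.3g %.2f 0.0 1 1 %.3g %.3g %.2f 0.0 1 %d %d %d %d %d 0.99 -",
      hits$protein_id, hits$end, hits$domain_id,
      if (is.na(qlen)) hits$end - hits$start + 1L else qlen,
      hits$e_value, hits$bit_score, hits$e_value, hits$e_value,
      hits$bit_score, hits$end - hits$start + 1L,
      hits$start, hits$end, hits$start, hits$end)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Ingest a per-domain tabular hit file
#'
#' Parses the whitespace-delimited per-domain table written by common
#' profile-search tools (and by [write_domain_table()]): `#` lines are
#' comments; per row the target (protein) is column 1, the query (domain)
#' column 4, the independent per-domain E-value column 13, the domain bit
#' score column 14 and the envelope columns 20-21. Hits are filtered at
#' `e_cutoff` and reduced to the best-scoring hit per protein per domain.
#'
#' @param path input file
#' @param e_cutoff E-value filter (default `1e-5`)
#' @return data.frame as in [scan_proteins()], with an attribute
#'   `n_malformed` counting skipped unparsable lines.
#' @export
ingest_domain_table <- function(path, e_cutoff = 1e-5) {
  raw <- readLines(path)
  body <- raw[!grepl("^\\s*#", raw) & nzchar(trimws(raw))]
  if (!length(body)) stop_arg("no parsable lines in ", path)
  fields <- strsplit(trimws(body), "\\s+")
  parsed <- lapply(fields, function(f) {
    if (length(f) < 21L) return(NULL)
    ev <- suppressWarnings(as.numeric(f[13]))
    sc <- suppressWarnings(as.numeric(f[14]))
    st <- suppressWarnings(as.integer(f[20]))
    en <- suppressWarnings(as.integer(f[21]))
    if (anyNA(c(ev, sc, st, en)) || ev < 0 || st > en) return(NULL)
    data.frame(protein_id = f[1], domain_id = f[4], bit_score = sc,
               e_value = ev, start = st, end = en, stringsAsFactors = FALSE)
  })
  n_malformed <- sum(vapply(parsed, is.null, TRUE))
  hits <- do.call(rbind, parsed)
  if (is.null(hits)) stop_arg("no parsable lines in ", path)
  if (n_malformed)
    warning(n_malformed, " malformed line(s) skipped in ", path)
  hits <- hits[hits$e_value <= e_cutoff, , drop = FALSE]
  ## one best (max-score) hit per protein per domain
  key <- paste(hits$protein_id, hits$domain_id)
  hits <- hits[order(key, -hits$bit_score), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$protein_id, hits$domain_id)), ,
               drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "n_malformed") <- n_malformed
  hits
}
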