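## Synthetic metagenomes with planted ground truth: taxonomically structured
## genomes carrying known WS/DGAT-family copy numbers and exactly one copy of
## each single-copy panel gene, emitted as assembled scaffolds (with read
## depths) plus an unassembled remainder, together with truth tables that
## reconcile every emitted record.

FAMILY_GENE <- "WSDGAT"
FAMILY_DOMAIN <- "PF03007"

#' Default single-copy ribosomal-protein panel
#'
#' Twelve ribosomal-protein genes present in exactly one copy per genome,
#' used to express family abundance in copies-per-genome units. Names are
#' gene symbols, values the Pfam accession of the corresponding domain.
#' The membership is configurable wherever a panel argument is accepted.
#'
#' @return Named character vector of length 12.
#' @export
single_copy_panel <- function() {
  c(rpsB = "PF00318", rpsC = "PF00189", rpsE = "PF00333", rpsJ = "PF00338",
    rpsS = "PF00203", rplA = "PF00687", rplB = "PF00181", rplC = "PF00297",
    rplD = "PF00573", rplE = "PF00281", rplF = "PF00347", rplK = "PF00298")
}

#' Default lipid-metabolism context domains
#'
#' Pfam domains profiled in the gene neighborhood of WS/DGAT marker hits:
#' AGPAT acyltransferase (PF01553), HAD-like hydrolase (PF12710), acyl-CoA
#' synthetase (PF00501, PF13193) and the SCP-2 sterol transfer domain
#' (PF02036).
#'
#' @return Named character vector of Pfam accessions.
#' @export
lipid_context_domains <- function() {
  c(AGPAT = "PF01553", HAD = "PF12710", ACS = "PF00501",
    ACS_C = "PF13193", SCP2 = "PF02036")
}

#' Mean of the zero-truncated Poisson distribution
#'
#' @param lambda rate parameter (> 0)
#' @return `lambda / (1 - exp(-lambda))`.
#' @export
ztp_mean <- function(lambda) {
  check_number(lambda, "lambda", min = 0, strict_min = TRUE)
  lambda / (1 - exp(-lambda))
}

## inverse-CDF draw from the zero-truncated Poisson
rztpois <- function(n, lambda) {
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

#' Carrier prevalence needed for a target mean copies-per-genome
#'
#' Under the zero-inflated, zero-truncated-Poisson copy model the mean
#' copies per genome is `p * ztp_mean(lambda)`; this inverts that for `p`.
#'
#' @param rho target mean family copies per genome
#' @param lambda zero-truncated Poisson rate among carriers
#' @return Prevalence `p` in `[0, 1]`.
#' @export
prevalence_for_mean <- function(rho, lambda) {
  check_number(rho, "rho", min = 0)
  p <- rho / ztp_mean(lambda)
  if (p > 1 + 1e-12)
    stop_arg("rho = ", rho, " unreachable with lambda = ", lambda,
             " (max ", signif(ztp_mean(lambda), 4), ")")
  min(p, 1)
}

#' Default per-branch substitution fractions by rank
#'
#' Fraction of sites substituted along a branch leading into a node of each
#' rank. Terminal (species) branches are short and deeper branches long so
#' that expected within-genus identity sits near 0.9 while between-genus
#' identity falls well below the 0.8 OPU cutoff; see the methods vignette.
#'
#' @return Named numeric vector over the seven non-root ranks.
#' @export
default_branch_subs <- function() {
  c(domain = 0.12, phylum = 0.12, class = 0.12, order = 0.12,
    family = 0.12, genus = 0.16, species = 0.03)
}

## substitute a fraction `s` of sites with a uniform alternative residue;
## works on integer-coded sequences (1..20)
mutate_seq <- function(x, s) {
  if (s <= 0) return(x)
  hit <- which(stats::runif(length(x)) < s)
  if (length(hit)) {
    shift <- sample.int(19L, length(hit), replace = TRUE)
    x[hit] <- ((x[hit] - 1L + shift) %% 20L) + 1L
  }
  x
}

aa_encode <- function(s) match(strsplit(s, "")[[1]], aa_alphabet())
aa_decode <- function(x) paste(aa_alphabet()[x], collapse = "")

#' Random protein sequence
#'
#' Residues drawn i.i.d. from `freqs` (uniform by default). Uses the current
#' RNG stream.
#'
#' @param length sequence length
#' @param freqs background residue frequencies (length 20, summing to 1)
#' @return Single amino-acid string.
#' @export
random_protein <- function(length, freqs = rep(1 / 20, 20)) {
  paste(sample(aa_alphabet(), length, replace = TRUE, prob = freqs),
        collapse = "")
}

#' Evolve a family protein down a taxonomy
#'
#' Starting from `seed_protein` at the root, applies i.i.d. substitutions
#' (to a uniformly chosen alternative residue; no indels) along every branch
#' and returns the sequence at each species leaf. Expected pairwise identity
#' decays with the number of branches separating two leaves, which is what
#' makes identity-threshold clustering taxon-coherent.
#'
#' @param seed_protein ancestral amino-acid string (length >= 50)
#' @param tree a [taxonomy_tree()]
#' @param subs_per_site_per_branch per-branch substitution fraction: a single
#'   number, or a vector named by rank as in [default_branch_subs()].
#' @param seed integer RNG seed
#' @return Named character vector, one sequence per species taxon id.
#' @export
evolve_family_sequences <- function(seed_protein, tree,
                                    subs_per_site_per_branch = default_branch_subs(),
                                    seed = 1L) {
  if (!is.character(seed_protein) || length(seed_protein) != 1L ||
      nchar(seed_protein) < 50L)
    stop_arg("seed_protein must be a single sequence of length >= 50")
  rates <- subs_per_site_per_branch
  if (length(rates) == 1L && is.null(names(rates)))
    rates <- stats::setNames(rep(rates, 7), TAX_RANKS[-1L])
  if (any(rates < 0)) stop_arg("substitution rate must be >= 0")
  miss <- setdiff(TAX_RANKS[-1L], names(rates))
  if (length(miss)) stop_arg("missing branch rate for rank(s): ",
                             paste(miss, collapse = ", "))
  with_seed(seed, {
    nodes <- tree$nodes[order(tree$depth), , drop = FALSE]
    seqs <- new.env(hash = TRUE, parent = emptyenv())
    root <- nodes$taxon_id[1L]
    seqs[[root]] <- aa_encode(seed_protein)
    for (i in seq_len(nrow(nodes))[-1L]) {
      id <- nodes$taxon_id[i]
      seqs[[id]] <- mutate_seq(seqs[[nodes$parent_id[i]]],
                               rates[[nodes$rank[i]]])
    }
    sp <- sort(tax_species(tree))
    stats::setNames(vapply(sp, function(s) aa_decode(seqs[[s]]), ""), sp)
  }, stream = 11L)
}

#' Simulate genomes with planted family copy numbers
#'
#' Every species leaf of the taxonomy receives one genome. With probability
#' `prevalence` the genome carries the marker family, with a copy number
#' drawn from a zero-truncated Poisson(`lambda`); otherwise it carries zero
#' copies. Each genome carries exactly one copy of every panel gene. When
#' `seed_protein` is supplied, family copies get protein sequences evolved
#' along the taxonomy (plus small paralog divergence between copies of one
#' genome) and panel genes get unrelated random sequences; otherwise the
#' object is sequence-free, which is sufficient for abundance arithmetic.
#'
#' @param tree a [taxonomy_tree()] with at least one species
#' @param prevalence probability a genome carries the family, in `[0, 1]`
#' @param lambda zero-truncated Poisson rate among carriers (> 0)
#' @param seed integer RNG seed
#' @param seed_protein optional ancestral family protein
#' @param branch_subs per-branch substitution fractions
#'   (see [evolve_family_sequences()])
#' @param paralog_subs extra substitution fraction applied independently to
#'   each copy within a genome (default 0.01)
#' @param panel named character vector of panel genes (default
#'   [single_copy_panel()])
#' @param protein_length length of generated panel/decoy proteins
#' @return Object of class `synthetic_genomes`: a data.frame
#'   (`genome_id`, `taxon_id`, `family_copy_count`) with the panel, per-genome
#'   family copy sequences and panel sequences attached as attributes.
#' @export
simulate_genomes <- function(tree, prevalence, lambda, seed = 1L,
                             seed_protein = NULL,
                             branch_subs = default_branch_subs(),
                             paralog_subs = 0.01,
                             panel = single_copy_panel(),
                             protein_length = 200L) {
  check_number(prevalence, "prevalence", min = 0, max = 1)
  check_number(lambda, "lambda", min = 0, strict_min = TRUE)
  sp <- sort(tax_species(tree))
  if (!length(sp)) stop_arg("taxonomy has no species leaves")
  genomes <- with_seed(seed, {
    carrier <- stats::runif(length(sp)) < prevalence
    copies <- integer(length(sp))
    copies[carrier] <- rztpois(sum(carrier), lambda)
    data.frame(genome_id = paste0("G_", sp), taxon_id = sp,
               family_copy_count = copies, stringsAsFactors = FALSE)
  }, stream = 1L)
  family_seqs <- NULL
  panel_seqs <- NULL
  if (!is.null(seed_protein)) {
    leaf_seq <- evolve_family_sequences(seed_protein, tree, branch_subs, seed)
    family_seqs <- with_seed(seed, {
      lapply(seq_len(nrow(genomes)), function(i) {
        k <- genomes$family_copy_count[i]
        if (k == 0L) return(character(0))
        base <- aa_encode(leaf_seq[[genomes$taxon_id[i]]])
        vapply(seq_len(k), function(j)
          aa_decode(mutate_seq(base, paralog_subs)), "")
      })
    }, stream = 2L)
    names(family_seqs) <- genomes$genome_id
    panel_seqs <- with_seed(seed, {
      lapply(seq_len(nrow(genomes)), function(i)
        stats::setNames(vapply(names(panel), function(g)
          random_protein(protein_length), ""), names(panel)))
    }, stream = 3L)
    names(panel_seqs) <- genomes$genome_id
  }
  structure(genomes, class = c("synthetic_genomes", "data.frame"),
            panel = panel, family_seqs = family_seqs,
            panel_seqs = panel_seqs, seed = as.integer(seed))
}

#' Community design for one synthetic sample
#'
#' Records everything [simulate_metagenome()] needs for one sample: genome
#' relative abundances (drawn log-normal and normalized when not supplied),
#' the assembled fraction, the depth model and the RNG seed.
#'
#' @param sample_id sample label
#' @param genome_ids genomes present in the community
#' @param abundances optional non-negative weights (normalized to sum 1)
#' @param assembly_fraction probability a gene copy is assembled, in `[0, 1]`
#' @param depth_meanlog,depth_sdlog log-normal coverage model: genome
#'   coverage is `rlnorm(meanlog = depth_meanlog + log(abundance * n_genomes),
#'   sdlog = depth_sdlog)`, i.e. mean coverage ~ `exp(depth_meanlog)` scaled
#'   by relative abundance.
#' @param context_rate probability an assembled family gene gets an adjacent
#'   planted lipid-context gene
#' @param context_domains Pfam pool for planted context genes
#' @param genes_per_scaffold scaffold size in genes
#' @param seed integer RNG seed (recorded in the design)
#' @return Object of class `community_design`.
#' @export
community_design <- function(sample_id, genome_ids, abundances = NULL,
                             assembly_fraction = 0.8,
                             depth_meanlog = log(5), depth_sdlog = 0.4,
                             context_rate = 0.5,
                             context_domains = lipid_context_domains(),
                             genes_per_scaffold = 12L, seed = 1L) {
  check_number(assembly_fraction, "assembly_fraction", min = 0, max = 1)
  check_number(genes_per_scaffold, "genes_per_scaffold", min = 1)
  check_number(context_rate, "context_rate", min = 0, max = 1)
  if (is.null(abundances)) {
    abundances <- with_seed(seed, stats::rlnorm(length(genome_ids), 0, 1),
                            stream = 4L)
  }
  if (length(abundances) != length(genome_ids) || any(abundances < 0))
    stop_arg("abundances must be non-negative, one per genome")
  abundances <- abundances / sum(abundances)
  structure(list(sample_id = sample_id,
                 genome_ids = as.character(genome_ids),
                 abundances = abundances,
                 assembly_fraction = assembly_fraction,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 context_rate = context_rate,
                 context_domains = context_domains,
                 genes_per_scaffold = as.integer(genes_per_scaffold),
                 seed = as.integer(seed)),
            class = "community_design")
}

#' Simulate one sample of a synthetic metagenome
#'
#' Emits every gene copy of every community genome either onto an assembled
#' scaffold (probability `assembly_fraction`; the scaffold's read depth is
#' the genome's simulated coverage) or into the unassembled fraction, where
#' each copy yields `Poisson(coverage)` independent single-protein records so
#' that the expected contribution of the two routes to the depth-corrected
#' estimator is identical. Assembled family genes may get an adjacent planted
#' lipid-context gene. Truth tables are computed from the emitted records,
#' so conservation is exact by construction.
#'
#' @param genomes a [simulate_genomes()] object
#' @param design a [community_design()]; its abundances must sum to 1 within
#'   1e-9 and cover only genomes present in `genomes`.
#' @return Object of class `synthetic_metagenome`: list with `proteins`,
#'   `scaffolds`, `genes` (GFF-ready coordinates and domain annotations),
#'   `truth` (`sample_totals`, `per_protein`, `per_genome`) and `design`.
#' @export
simulate_metagenome <- function(genomes, design) {
  if (!inherits(design, "community_design")) stop_arg("design must be a community_design")
  if (abs(sum(design$abundances) - 1) > 1e-9)
    stop_arg("design abundances must sum to 1 (within 1e-9)")
  gi <- match(design$genome_ids, genomes$genome_id)
  if (anyNA(gi)) stop_arg("design names unknown genome(s)")
  panel <- attr(genomes, "panel")
  fam_seqs <- attr(genomes, "family_seqs")
  pan_seqs <- attr(genomes, "panel_seqs")
  sid <- design$sample_id
  with_seed(design$seed, {
    n_g <- length(gi)
    cov <- stats::rlnorm(n_g,
                         design$depth_meanlog + log(design$abundances * n_g),
                         design$depth_sdlog)
    cov <- round(cov, 4)
    fam_n <- genomes$family_copy_count[gi]
    n_panel <- length(panel)
    per_genome_copies <- fam_n + n_panel
    gidx <- rep(seq_len(n_g), per_genome_copies)
    gene <- unlist(lapply(seq_len(n_g), function(i)
      c(rep(FAMILY_GENE, fam_n[i]), names(panel))), use.names = FALSE)
    copy_ix <- unlist(lapply(seq_len(n_g), function(i)
      c(seq_len(fam_n[i]), rep(1L, n_panel))), use.names = FALSE)
    domain <- ifelse(gene == FAMILY_GENE, FAMILY_DOMAIN, unname(panel[gene]))
    copies <- data.frame(gidx = gidx, gene = gene, copy_ix = copy_ix,
                         domain = domain, stringsAsFactors = FALSE)
    copies$genome_id <- genomes$genome_id[gi][copies$gidx]
    copies$taxon_id <- genomes$taxon_id[gi][copies$gidx]
    copies$cov <- cov[copies$gidx]
    copies$assembled <- stats::runif(nrow(copies)) < design$assembly_fraction

    seq_of <- function(df) {
      if (is.null(fam_seqs)) return(rep(NA_character_, nrow(df)))
      vapply(seq_len(nrow(df)), function(i) {
        if (df$gene[i] == FAMILY_GENE)
          fam_seqs[[df$genome_id[i]]][df$copy_ix[i]]
        else pan_seqs[[df$genome_id[i]]][[df$gene[i]]]
      }, "")
    }

    ## ---- assembled fraction: units (gene + optional planted neighbor) ----
    asm <- copies[copies$assembled, , drop = FALSE]
    planted <- asm$gene == FAMILY_GENE &
      stats::runif(nrow(asm)) < design$context_rate
    ctx_dom <- rep(NA_character_, nrow(asm))
    if (any(planted))
      ctx_dom[planted] <- sample(unname(design$context_domains),
                                 sum(planted), replace = TRUE)
    if (nrow(asm)) {
      unit_ix <- stats::ave(seq_len(nrow(asm)), asm$gidx, FUN = seq_along)
      sc_ix <- (unit_ix - 1L) %/% design$genes_per_scaffold + 1L
      asm$scaffold_id <- paste0(sid, "|", asm$genome_id, "|sc", sc_ix)
    } else asm$scaffold_id <- character(0)

    ## expand units to gene rows (context gene directly after its marker)
    ord <- rep(seq_len(nrow(asm)), 1L + planted)
    is_ctx <- duplicated(ord)
    gff <- data.frame(
      scaffold_id = asm$scaffold_id[ord],
      gene = ifelse(is_ctx, "context", asm$gene[ord]),
      domain_id = ifelse(is_ctx, ctx_dom[ord], asm$domain[ord]),
      genome_id = asm$genome_id[ord],
      stringsAsFactors = FALSE)
    if (nrow(gff)) {
      o <- stats::ave(seq_len(nrow(gff)), gff$scaffold_id, FUN = seq_along)
      glen <- 600L
      gap <- 100L
      gff$start <- (o - 1L) * (glen + gap) + 1L
      gff$end <- gff$start + glen - 1L
      gff$strand <- sample(c("+", "-"), nrow(gff), replace = TRUE)
      gff$gene_id <- paste0(gff$scaffold_id, "_", o)
    } else {
      gff$start <- gff$end <- integer(0)
      gff$strand <- gff$gene_id <- character(0)
    }

    scaffolds <- if (nrow(gff)) {
      agg <- stats::aggregate(end ~ scaffold_id, gff, max)
      agg$length <- agg$end + 100L
      agg$end <- NULL
      agg$genome_id <- sub("\\|sc[0-9]+$", "",
                           sub("^[^|]*\\|", "", agg$scaffold_id))
      agg$sample_id <- sid
      agg$read_depth <- cov[match(agg$genome_id, genomes$genome_id[gi])]
      agg[order(agg$scaffold_id),
          c("scaffold_id", "sample_id", "genome_id", "length", "read_depth")]
    } else data.frame(scaffold_id = character(0), sample_id = character(0),
                      genome_id = character(0), length = integer(0),
                      read_depth = numeric(0), stringsAsFactors = FALSE)

    asm_prot <- gff[!is_ctx, , drop = FALSE]
    asm_src <- asm[ord[!is_ctx], , drop = FALSE]
    proteins_asm <- data.frame(
      protein_id = asm_prot$gene_id,
      sample_id = rep(sid, nrow(asm_prot)),
      genome_id = asm_src$genome_id, taxon_id = asm_src$taxon_id,
      gene = asm_src$gene, domain_id = asm_src$domain,
      fraction = rep("assembled", nrow(asm_prot)),
      scaffold_id = asm_prot$scaffold_id,
      weight = asm_src$cov, seq = seq_of(asm_src),
      stringsAsFactors = FALSE)

    ## ---- unassembled fraction: Poisson(coverage) records per copy ----
    un <- copies[!copies$assembled, , drop = FALSE]
    n_obs <- if (nrow(un)) stats::rpois(nrow(un), un$cov) else integer(0)
    rep_ix <- rep(seq_len(nrow(un)), n_obs)
    un_rows <- un[rep_ix, , drop = FALSE]
    proteins_un <- data.frame(
      protein_id = if (nrow(un_rows))
        paste0(sid, "|u", seq_len(nrow(un_rows))) else character(0),
      sample_id = rep(sid, nrow(un_rows)),
      genome_id = un_rows$genome_id, taxon_id = un_rows$taxon_id,
      gene = un_rows$gene, domain_id = un_rows$domain,
      fraction = rep("unassembled", nrow(un_rows)),
      scaffold_id = rep(NA_character_, nrow(un_rows)),
      weight = rep(1, nrow(un_rows)), seq = seq_of(un_rows),
      stringsAsFactors = FALSE)

    proteins <- rbind(proteins_asm, proteins_un)
    rownames(proteins) <- NULL

    totals <- stats::aggregate(weight ~ gene, proteins, sum)
    all_genes <- c(FAMILY_GENE, names(panel))
    totals <- data.frame(
      sample_id = sid, gene = all_genes,
      true_copies = totals$weight[match(all_genes, totals$gene)],
      stringsAsFactors = FALSE)
    totals$true_copies[is.na(totals$true_copies)] <- 0

    truth <- list(
      sample_totals = totals,
      per_protein = proteins[, c("protein_id", "sample_id", "genome_id",
                                 "taxon_id", "gene", "weight")],
      per_genome = data.frame(genome_id = genomes$genome_id[gi],
                              taxon_id = genomes$taxon_id[gi],
                              family_copies = fam_n,
                              coverage = cov, stringsAsFactors = FALSE))
    structure(list(proteins = proteins, scaffolds = scaffolds,
                   genes = gff[, c("scaffold_id", "gene_id", "start", "end",
                                   "strand", "domain_id", "gene", "genome_id")],
                   truth = truth, design = design),
              class = "synthetic_metagenome")
  }, stream = 5L)
}

#' @export
print.synthetic_metagenome <- function(x, ...) {
  cat("synthetic_metagenome sample", x$design$sample_id, "-",
      nrow(x$proteins), "protein records,", nrow(x$scaffolds), "scaffolds\n")
  invisible(x)
}

#' Simulate a multi-sample, grouped synthetic study
#'
#' Builds one [community_design()] per sample. Samples within a group share a
#' group-level base abundance profile (log-normal), jittered per sample, so
#' groups differ compositionally and community statistics have signal to
#' find.
#'
#' @param genomes a [simulate_genomes()] object
#' @param groups named integer vector: samples per group, e.g.
#'   `c(ANT = 3, ARG = 3)`
#' @param seed integer RNG seed
#' @param sample_sd log-scale per-sample jitter around the group profile
#' @param ... further arguments passed to [community_design()]
#' @return List of class `synthetic_study`: `samples` (named list of
#'   [simulate_metagenome()] results), `groups` (data.frame `sample_id`,
#'   `group`) and the genome set.
#' @export
simulate_study <- function(genomes, groups = c(ANT = 3L, ARG = 3L),
                           seed = 1L, sample_sd = 0.3, ...) {
  if (is.null(names(groups)) || any(groups < 1))
    stop_arg("groups must be a named vector of positive sample counts")
  n_g <- nrow(genomes)
  base <- with_seed(seed, {
    lapply(seq_along(groups), function(i) stats::rlnorm(n_g, 0, 1))
  }, stream = 6L)
  sims <- list()
  labels <- character(0)
  k <- 0L
  for (i in seq_along(groups)) {
    for (j in seq_len(groups[[i]])) {
      k <- k + 1L
      sid <- sprintf("%s%02d", names(groups)[i], j)
      ab <- with_seed(seed + 7919L * k,
                      base[[i]] * stats::rlnorm(n_g, 0, sample_sd))
      des <- community_design(sid, genomes$genome_id, abundances = ab,
                              seed = seed + 104729L * k, ...)
      sims[[sid]] <- simulate_metagenome(genomes, des)
      labels[sid] <- names(groups)[i]
    }
  }
  structure(list(samples = sims,
                 groups = data.frame(sample_id = names(labels),
                                     group = unname(labels),
                                     stringsAsFactors = FALSE),
                 genomes = genomes),
            class = "synthetic_study")
}

#' Pool per-sample tables of a synthetic study
#'
#' @param study a [simulate_study()] result
#' @param what one of `"proteins"`, `"scaffolds"`, `"genes"`,
#'   `"sample_totals"`
#' @return One data.frame across all samples.
#' @export
study_table <- function(study, what = c("proteins", "scaffolds", "genes",
                                        "sample_totals")) {
  what <- match.arg(what)
  pick <- function(s) switch(what, sample_totals = s$truth$sample_totals,
                             s[[what]])
  out <- do.call(rbind, lapply(study$samples, pick))
  rownames(out) <- NULL
  out
}

#' Write a synthetic metagenome to disk
#'
#' Emits assembled and unassembled protein FASTA, gene coordinates as GFF3,
#' per-scaffold read depths as TSV, the three truth tables as TSV and a JSON
#' run manifest carrying the seed and design parameters. Output is
#' byte-deterministic for a fixed design.
#'
#' @param sim a [simulate_metagenome()] result with sequences (the genome set
#'   must have been built with a `seed_protein`)
#' @param dir output directory (created if needed)
#' @return The directory path, invisibly.
#' @export
write_metagenome <- function(sim, dir) {
  if (anyNA(sim$proteins$seq))
    stop_arg("simulation has no sequences; rebuild genomes with a seed_protein")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wfa <- function(df, path) {
    x <- Biostrings::AAStringSet(stats::setNames(df$seq, df$protein_id))
    Biostrings::writeXStringSet(x, path)
  }
  wfa(sim$proteins[sim$proteins$fraction == "assembled", ],
      file.path(dir, "assembled.faa"))
  wfa(sim$proteins[sim$proteins$fraction == "unassembled", ],
      file.path(dir, "unassembled.faa"))
  g <- sim$genes
  gff <- c("##gff-version 3",
           sprintf("%s\tmetawax\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;domain=%s",
                   g$scaffold_id, g$start, g$end, g$strand, g$gene_id,
                   g$domain_id))
  writeLines(gff, file.path(dir, "genes.gff3"))
  wtsv <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  wtsv(sim$scaffolds[, c("scaffold_id", "read_depth")],
       file.path(dir, "depths.tsv"))
  wtsv(sim$truth$sample_totals, file.path(dir, "truth_sample_totals.tsv"))
  wtsv(sim$truth$per_protein, file.path(dir, "truth_per_protein.tsv"))
  wtsv(sim$truth$per_genome, file.path(dir, "truth_per_genome.tsv"))
  manifest <- list(sample_id = sim$design$sample_id,
                   seed = sim$design$seed,
                   assembly_fraction = sim$design$assembly_fraction,
                   depth_meanlog = sim$design$depth_meanlog,
                   depth_sdlog = sim$design$depth_sdlog,
                   context_rate = sim$design$context_rate,
                   genes_per_scaffold = sim$design$genes_per_scaffold,
                   n_genomes = length(sim$design$genome_ids))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a scaffold depth table
#'
#' @param path TSV with columns `scaffold_id` and `read_depth`
#' @return data.frame.
#' @export
read_scaffold_depths <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
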