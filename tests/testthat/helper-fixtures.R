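# Shared fixtures, built in code at test time.

# deterministic ancestral marker protein
fixture_seed_protein <- function(len = 200L, seed = 42L) {
  metawax:::with_seed(seed, random_protein(len))
}

# small 2-phylum taxonomy (64 species)
fixture_tree <- function() build_taxonomy(1, n_phyla = 2, children_per_node = 2)

# one-sample synthetic metagenome with sequences
fixture_sim <- function(seed = 3L, prevalence = 0.6, lambda = 2,
                        assembly_fraction = 0.8, ...) {
  tr <- fixture_tree()
  g <- simulate_genomes(tr, prevalence, lambda, seed = seed,
                        seed_protein = fixture_seed_protein())
  des <- community_design("S1", g$genome_id, seed = seed + 100,
                          assembly_fraction = assembly_fraction, ...)
  list(tree = tr, genomes = g, sim = simulate_metagenome(g, des))
}

# multi-sample grouped study, sequence-free (fast) unless asked otherwise
fixture_study <- function(seed = 7L, groups = c(ANT = 3L, ARG = 3L),
                          with_seqs = FALSE, n_phyla = 2L, ...) {
  tr <- build_taxonomy(1, n_phyla = n_phyla, children_per_node = 2)
  g <- simulate_genomes(tr, prevalence = 0.6, lambda = 2, seed = seed,
                        seed_protein = if (with_seqs) fixture_seed_protein())
  list(tree = tr, genomes = g,
       study = simulate_study(g, groups = groups, seed = seed, ...))
}

# calibrated toy profile + the alignment used to build it
fixture_profile <- function(len = 120L, n_decoys = 600L) {
  seedp <- fixture_seed_protein(len)
  aln <- metawax:::with_seed(2, vapply(1:8, function(i)
    aa_decode_test(mutate_test(aa_encode_test(seedp), 0.1)), ""))
  prof <- build_profile(aln)
  list(profile = calibrate_evalue(prof, decoy_lengths = 250,
                                  n_decoys = n_decoys, seed = 4),
       alignment = aln, seed_protein = seedp)
}

# thin test-side wrappers over internal coding helpers
aa_encode_test <- function(s) match(strsplit(s, "")[[1]], aa_alphabet())
aa_decode_test <- function(x) paste(aa_alphabet()[x], collapse = "")
mutate_test <- function(x, s) {
  hit <- which(stats::runif(length(x)) < s)
  if (length(hit)) {
    shift <- sample.int(19L, length(hit), replace = TRUE)
    x[hit] <- ((x[hit] - 1L + shift) %% 20L) + 1L
  }
  x
}

# hit table ready for estimate_copies(), taken from the truth annotations
truth_hits <- function(sim) {
  p <- sim$proteins
  data.frame(protein_id = p$protein_id, sample_id = p$sample_id,
             family = p$gene, fraction = p$fraction,
             scaffold_id = p$scaffold_id, stringsAsFactors = FALSE)
}
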