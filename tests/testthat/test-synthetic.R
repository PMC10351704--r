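test_that("copy-number model hits its degenerate cases", {
  tr <- fixture_tree()
  g0 <- simulate_genomes(tr, prevalence = 0, lambda = 3, seed = 1)
  expect_true(all(g0$family_copy_count == 0))
  g1 <- simulate_genomes(tr, prevalence = 1, lambda = 0.05, seed = 1)
  expect_true(all(g1$family_copy_count >= 1))  # zero truncation
  expect_error(simulate_genomes(tr, -0.1, 1), "prevalence")
  expect_error(simulate_genomes(tr, 0.5, 0), "lambda")
  empty <- taxonomy_tree(data.frame(taxon_id = "r", parent_id = NA,
                                    rank = "root", name = "r"))
  expect_error(simulate_genomes(empty, 0.5, 1), "species")
})

test_that("copy-number moments match the zero-truncated Poisson mixture", {
  tr <- build_taxonomy(1, n_phyla = 8, children_per_node = 3)  # 1944 species
  n <- length(tax_species(tr))
  expect_gte(n, 1000)
  p <- 0.6
  lam <- 3
  g <- simulate_genomes(tr, p, lam, seed = 21)
  carriers <- g$family_copy_count > 0
  # prevalence within 3 binomial SDs
  expect_lt(abs(mean(carriers) - p), 3 * sqrt(p * (1 - p) / n))
  # mean among carriers within 3 SEs of the ZTP mean
  m <- ztp_mean(lam)
  v <- m * (1 + lam - m)  # ZTP variance
  expect_lt(abs(mean(g$family_copy_count[carriers]) - m),
            3 * sqrt(v / sum(carriers)))
})

test_that("sequence evolution is identity-monotone in path length", {
  seedp <- fixture_seed_protein()
  tr <- fixture_tree()
  # rate 0: all sequences identical to the seed
  s0 <- evolve_family_sequences(seedp, tr, 0, seed = 1)
  expect_true(all(s0 == seedp))
  # same-genus pairs more similar than cross-phylum pairs
  sq <- evolve_family_sequences(seedp, tr, default_branch_subs(), seed = 2)
  sp <- names(sq)
  ident <- function(a, b) mean(aa_encode_test(a) == aa_encode_test(b))
  genus_of <- function(s) tax_ancestor_at_rank(tr, s, "genus")
  phylum_of <- function(s) tax_ancestor_at_rank(tr, s, "phylum")
  same_genus <- combn(sp, 2)[, apply(combn(sp, 2), 2, function(p)
    genus_of(p[1]) == genus_of(p[2]))]
  diff_phy <- combn(sp, 2)[, apply(combn(sp, 2), 2, function(p)
    phylum_of(p[1]) != phylum_of(p[2]))]
  wi <- mean(apply(same_genus, 2, function(p) ident(sq[p[1]], sq[p[2]])))
  bw <- mean(apply(diff_phy[, 1:50], 2, function(p) ident(sq[p[1]], sq[p[2]])))
  expect_gt(wi, 0.85)
  expect_lt(bw, 0.6)
  expect_gt(wi, bw)
  expect_error(evolve_family_sequences("SHORT", tr, 0.1), "length >= 50")
})

test_that("metagenome emission conserves truth totals exactly", {
  fx <- fixture_sim(seed = 3)
  sim <- fx$sim
  # independent recomputation of the per-sample totals from emitted records
  for (gene in unique(sim$truth$sample_totals$gene)) {
    rows <- sim$proteins[sim$proteins$gene == gene, ]
    asm <- rows$fraction == "assembled"
    depth <- sim$scaffolds$read_depth[match(rows$scaffold_id[asm],
                                            sim$scaffolds$scaffold_id)]
    expect_equal(sum(depth) + sum(!asm),
                 sim$truth$sample_totals$true_copies[
                   sim$truth$sample_totals$gene == gene],
                 info = gene)
  }
  # assembled record weights equal their scaffold depth
  asm <- sim$proteins[sim$proteins$fraction == "assembled", ]
  expect_equal(asm$weight,
               sim$scaffolds$read_depth[match(asm$scaffold_id,
                                              sim$scaffolds$scaffold_id)])
})

test_that("assembly_fraction = 1 leaves the unassembled fraction empty", {
  fx <- fixture_sim(seed = 5, assembly_fraction = 1)
  expect_equal(sum(fx$sim$proteins$fraction == "unassembled"), 0L)
  fx0 <- fixture_sim(seed = 5, assembly_fraction = 0)
  expect_equal(sum(fx0$sim$proteins$fraction == "assembled"), 0L)
  expect_equal(nrow(fx0$sim$scaffolds), 0L)
})

test_that("design validation rejects bad abundances", {
  g <- simulate_genomes(fixture_tree(), 0.5, 2, seed = 1)
  des <- community_design("S1", g$genome_id, seed = 1)
  des$abundances <- des$abundances * 2  # break normalization
  expect_error(simulate_metagenome(g, des), "sum to 1")
  expect_error(community_design("S1", g$genome_id,
                                abundances = rep(-1, nrow(g))),
               "non-negative")
})

test_that("same seed gives byte-identical fixture files", {
  dir1 <- tempfile()
  dir2 <- tempfile()
  fx <- fixture_sim(seed = 9)
  write_metagenome(fx$sim, dir1)
  fx2 <- fixture_sim(seed = 9)
  write_metagenome(fx2$sim, dir2)
  for (f in list.files(dir1)) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     info = f)
  }
  # and a different seed changes the content
  dir3 <- tempfile()
  write_metagenome(fixture_sim(seed = 10)$sim, dir3)
  expect_false(identical(unname(tools::md5sum(file.path(dir1, "depths.tsv"))),
                         unname(tools::md5sum(file.path(dir3, "depths.tsv")))))
})

test_that("emitted GFF3 is standard and consistent with the gene table", {
  fx <- fixture_sim(seed = 11)
  dir <- tempfile()
  write_metagenome(fx$sim, dir)
  gr <- rtracklayer::import(file.path(dir, "genes.gff3"))
  expect_equal(length(gr), nrow(fx$sim$genes))
  idx <- match(gr$ID, fx$sim$genes$gene_id)
  expect_false(anyNA(idx))
  expect_equal(GenomicRanges::start(gr), fx$sim$genes$start[idx])
  expect_equal(GenomicRanges::end(gr), fx$sim$genes$end[idx])
  # 1-based inclusive intervals within scaffold bounds
  sc_len <- fx$sim$scaffolds$length[match(fx$sim$genes$scaffold_id,
                                          fx$sim$scaffolds$scaffold_id)]
  expect_true(all(fx$sim$genes$start >= 1))
  expect_true(all(fx$sim$genes$end <= sc_len))
  # unassembled FASTA + assembled FASTA cover all protein records
  a <- Biostrings::readAAStringSet(file.path(dir, "assembled.faa"))
  u <- Biostrings::readAAStringSet(file.path(dir, "unassembled.faa"))
  expect_equal(length(a) + length(u), nrow(fx$sim$proteins))
})

test_that("grouped studies carry group structure and per-sample designs", {
  fx <- fixture_study(seed = 7, groups = c(ANT = 2L, ARG = 2L))
  st <- fx$study
  expect_equal(nrow(st$groups), 4L)
  expect_setequal(unique(st$groups$group), c("ANT", "ARG"))
  tot <- study_table(st, "sample_totals")
  expect_equal(sort(unique(tot$sample_id)), sort(st$groups$sample_id))
  # per-sample conservation holds in the pooled table too
  prot <- study_table(st, "proteins")
  agg <- stats::aggregate(weight ~ sample_id + gene, prot, sum)
  m <- merge(agg, tot, by = c("sample_id", "gene"))
  expect_equal(m$weight, m$true_copies)
})
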