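test_that("profile scores follow the log-odds construction", {
  # identical rows: consensus residue maximal in every column
  aln <- rep(strrep("ACDEFGHIKLMNPQRSTVWY", 3), 5)
  prof <- build_profile(aln)
  cons <- aa_encode_test(aln[1])
  for (j in seq_len(prof$length))
    expect_equal(which.max(prof$scores[j, ]), cons[j],
                 ignore_attr = TRUE)

  # uniform random columns, large n: columnwise scores shrink toward 0 bits
  big <- metawax:::with_seed(31, vapply(1:2000, function(i)
    random_protein(15), ""))
  p2 <- build_profile(big)
  expect_lt(max(abs(p2$scores)), 0.6)
  expect_lt(stats::median(abs(p2$scores)), 0.12)

  # 5-row toy alignment equals a hand-computed log-odds table
  toy <- c("AAAAACCCCC", "AAAAACCCCC", "AAAAACCCCC", "CAAAACCCCC",
           "AAAAACCCCA")
  p3 <- build_profile(toy)
  bg <- 1 / 20
  hand <- function(count) log2(((count + 0.5 * 20 * bg) / (5 + 0.5 * 20)) / bg)
  expect_equal(unname(p3$scores[1, "A"]), hand(4))
  expect_equal(unname(p3$scores[1, "C"]), hand(1))
  expect_equal(unname(p3$scores[1, "D"]), hand(0))
  expect_equal(unname(p3$scores[2, "A"]), hand(5))
  expect_equal(unname(p3$scores[10, "C"]), hand(4))

  expect_error(build_profile(c("AAA", "AAAA")), "ragged")
  expect_error(build_profile("AAAA"), "at least 2")
})

test_that("gap-heavy columns are dropped", {
  aln <- c("A-AAAAAAAAAA", "A-AAAAAAAAAA", "ACAAAAAAAAAA", "A-AAAAAAAAAA")
  prof <- build_profile(aln)
  expect_equal(prof$length, 11L)  # column 2 is 75% gaps
})

test_that("Gumbel calibration anchors the E-value tail", {
  fx <- fixture_profile()
  prof <- fx$profile
  expect_gt(prof$beta, 0)
  # E-value at the empirical (1 - k/n) decoy quantile ~ k * N_db / n, up to
  # tail sampling noise (k = 20 stabilizes the anchor)
  scores <- metawax:::with_seed(4, {
    vapply(rep(250L, 600L), function(n) {
      x <- sample.int(20L, n, replace = TRUE, prob = prof$background)
      metawax:::best_window(x, prof$scores)$score
    }, numeric(1))
  }, stream = 21L)
  q <- stats::quantile(scores, 1 - 20 / 600, type = 1)
  e_at_q <- 600 * metawax:::gumbel_sf(q, prof$mu, prof$beta)
  expect_gt(e_at_q, 10)
  expect_lt(e_at_q, 40)

  # degenerate variance (flat profile scores every decoy identically)
  flat <- prof
  flat$scores[, ] <- 0
  expect_error(calibrate_evalue(flat, 250, 500, seed = 1), "degenerate")
})

test_that("false-positive counts on fresh decoys match the calibrated Poisson rate", {
  fx <- fixture_profile()
  prof <- fx$profile
  covered <- 0L
  for (s in 1:10) {
    decoys <- metawax:::with_seed(100 + s, vapply(1:2000, function(i)
      random_protein(250), ""))
    names(decoys) <- paste0("d", 1:2000)
    hits <- scan_proteins(decoys, prof, e_cutoff = 1, n_db = 10000)
    # scaled: E<=1 over n_db 10000 scanning 2000 decoys -> Poisson(0.2)
    covered <- covered + (nrow(hits) <= 3)
  }
  expect_gte(covered, 9L)
})

test_that("scanning recovers planted family members and nothing else", {
  fx <- fixture_profile()
  tr <- fixture_tree()
  g <- simulate_genomes(tr, 0.6, 2, seed = 3,
                        seed_protein = fx$seed_protein)
  sim <- simulate_metagenome(g, community_design("S1", g$genome_id, seed = 103))
  prots <- stats::setNames(sim$proteins$seq, sim$proteins$protein_id)
  hits <- scan_proteins(prots, fx$profile)
  truth <- sim$proteins$protein_id[sim$proteins$gene == "WSDGAT"]
  sens <- mean(truth %in% hits$protein_id)
  spec <- 1 - sum(!hits$protein_id %in% truth) / (length(prots) - length(truth))
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
  # empty protein set
  expect_equal(nrow(scan_proteins(character(0), fx$profile)), 0L)
  # consensus self-match covers the full profile
  h1 <- scan_proteins(c(cons = fx$seed_protein), fx$profile, n_db = 1)
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$end - h1$start + 1L, fx$profile$length)
})

test_that("hit sets shrink monotonically with the cutoff and scores ignore trailing junk", {
  fx <- fixture_profile()
  prots <- metawax:::with_seed(51, {
    fam <- vapply(1:20, function(i)
      aa_decode_test(mutate_test(aa_encode_test(fx$seed_protein), 0.2)), "")
    dec <- vapply(1:50, function(i) random_protein(200), "")
    stats::setNames(c(fam, dec), paste0("s", 1:70))
  })
  h_loose <- scan_proteins(prots, fx$profile, e_cutoff = 1)
  h_std <- scan_proteins(prots, fx$profile, e_cutoff = 1e-5)
  h_tight <- scan_proteins(prots, fx$profile, e_cutoff = 1e-20)
  expect_true(all(h_std$protein_id %in% h_loose$protein_id))
  expect_true(all(h_tight$protein_id %in% h_std$protein_id))
  # appending residues that cannot improve the best window leaves scores be
  base <- scan_proteins(prots[1], fx$profile, e_cutoff = 1, n_db = 1)
  ext <- scan_proteins(stats::setNames(paste0(prots[1], strrep("A", 30)),
                                       names(prots)[1]),
                       fx$profile, e_cutoff = 1, n_db = 1)
  expect_gte(ext$bit_score, base$bit_score)  # extra windows can only help
  # proteins shorter than the profile are skipped, not an error
  expect_message(
    h <- scan_proteins(c(tiny = "ACDEF", ok = prots[[1]]), fx$profile,
                       e_cutoff = 1, n_db = 2),
    "skipped")
  expect_false("tiny" %in% h$protein_id)
})

test_that("domain tables round-trip and filter at the cutoff", {
  fx <- fixture_profile()
  prots <- metawax:::with_seed(52, {
    fam <- vapply(1:5, function(i)
      aa_decode_test(mutate_test(aa_encode_test(fx$seed_protein), 0.15)), "")
    stats::setNames(fam, paste0("q", 1:5))
  })
  hits <- scan_proteins(prots, fx$profile)
  path <- tempfile(fileext = ".domtbl")
  write_domain_table(hits, path, qlen = fx$profile$length)
  back <- ingest_domain_table(path, e_cutoff = 1e-5)
  expect_equal(back$protein_id, hits$protein_id)
  expect_equal(back$start, hits$start)
  expect_equal(back$end, hits$end)
  expect_equal(back$bit_score, hits$bit_score, tolerance = 1e-2)

  # explicit filter semantics
  tbl <- c("# comment",
           "p1 - 100 PF03007 - 50 1e-9 40 0 1 1 1e-9 1e-9 40 0 1 50 1 50 1 50 0.9 -",
           "p2 - 100 PF03007 - 50 1e-3 20 0 1 1 1e-3 1e-3 20 0 1 50 1 50 1 50 0.9 -",
           "p3 - 100 PF03007 - 50 1e-7 35 0 1 1 1e-7 1e-7 35 0 1 50 1 50 1 50 0.9 -")
  f <- tempfile()
  writeLines(tbl, f)
  kept <- ingest_domain_table(f, e_cutoff = 1e-5)
  expect_setequal(kept$protein_id, c("p1", "p3"))

  # comment-only file is a format error; malformed lines are counted
  f2 <- tempfile()
  writeLines(c("# a", "# b"), f2)
  expect_error(ingest_domain_table(f2), "no parsable lines")
  f3 <- tempfile()
  writeLines(c(tbl, "broken line"), f3)
  expect_warning(kept3 <- ingest_domain_table(f3, e_cutoff = 1), "malformed")
  expect_equal(attr(kept3, "n_malformed"), 1L)
  # best hit per protein per domain is retained
  f4 <- tempfile()
  writeLines(c(tbl[2], sub("40 0 1 50", "55 0 1 50",
                           sub("^p1", "p1", tbl[2]))), f4)
  best <- ingest_domain_table(f4, e_cutoff = 1)
  expect_equal(nrow(best), 1L)
  expect_equal(best$bit_score, 55)
})

test_that("ingestion parses genuine hmmer domain tables", {
  fx <- fixture_profile()
  dir <- tempfile()
  dir.create(dir)
  # alignment -> hmmbuild -> hmmsearch over planted + decoy proteins
  aln_fa <- file.path(dir, "seed.afa")
  writeLines(as.vector(rbind(paste0(">r", seq_along(fx$alignment)),
                             fx$alignment)), aln_fa)
  prots <- metawax:::with_seed(53, {
    fam <- vapply(1:6, function(i)
      aa_decode_test(mutate_test(aa_encode_test(fx$seed_protein), 0.2)), "")
    dec <- vapply(1:20, function(i) random_protein(220), "")
    stats::setNames(c(fam, dec), c(paste0("fam", 1:6), paste0("dec", 1:20)))
  })
  db <- file.path(dir, "db.faa")
  writeLines(as.vector(rbind(paste0(">", names(prots)), prots)), db)
  hmm <- file.path(dir, "seed.hmm")
  out <- file.path(dir, "hits.domtbl")
  r1 <- system2("hmmbuild", c("--amino", hmm, aln_fa), stdout = FALSE,
                stderr = FALSE)
  r2 <- system2("hmmsearch", c("--domtblout", out, hmm, db),
                stdout = FALSE, stderr = FALSE)
  expect_equal(r1, 0L)
  expect_equal(r2, 0L)
  hits <- ingest_domain_table(out, e_cutoff = 1e-5)
  expect_setequal(hits$protein_id, paste0("fam", 1:6))
  expect_true(all(hits$e_value <= 1e-5))
  expect_true(all(hits$start <= hits$end))
})
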