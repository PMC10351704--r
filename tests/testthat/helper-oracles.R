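# Independent oracles, implemented directly from first principles and kept
# separate from the package code paths they check.

# Needleman-Wunsch with affine gaps (open 10, extend 1 per gap position,
# first position charged open + extend), match +1 / mismatch 0. Returns the
# optimal score and the match count of one optimal traceback.
nw_affine_oracle <- function(a, b, open = 10, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap in B (consumes A)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap in A (consumes B)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- as.numeric(A[i - 1] == B[j - 1])
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, X[i, j - 1] - open - ext,
                     Y[i, j - 1] - ext)
    }
  }
  # traceback, preferring M then X then Y, counting matches
  i <- n + 1
  j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  score <- c(M[i, j], X[i, j], Y[i, j])[state]
  matches <- 0L
  while (i > 1 || j > 1) {
    if (state == 1L) {
      s <- as.numeric(A[i - 1] == B[j - 1])
      if (A[i - 1] == B[j - 1]) matches <- matches + 1L
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1
      j <- j - 1
    } else if (state == 2L) {
      prev <- c(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                Y[i - 1, j] - open - ext)
      state <- which.max(prev)
      i <- i - 1
    } else {
      prev <- c(M[i, j - 1] - open - ext, X[i, j - 1] - open - ext,
                Y[i, j - 1] - ext)
      state <- which.max(prev)
      j <- j - 1
    }
  }
  list(score = score, matches = matches)
}

# The greedy OPU procedure re-run verbatim on an exhaustively precomputed
# identity matrix.
greedy_oracle <- function(seqs, id_matrix, cutoff) {
  ord <- order(-nchar(seqs), names(seqs))
  ids <- names(seqs)[ord]
  reps <- character(0)
  assignment <- character(length(ids))
  names(assignment) <- ids
  for (s in ids) {
    hit <- NA_character_
    for (r in reps) {
      if (id_matrix[s, r] >= cutoff) {
        hit <- r
        break
      }
    }
    if (is.na(hit)) {
      reps <- c(reps, s)
      hit <- s
    }
    assignment[s] <- hit
  }
  assignment  # member -> representative id
}

# Brute-force weighted LCA: scan every tree node and test the threshold
# condition directly.
lca_oracle <- function(tree, hits, top_percent, threshold) {
  if (nrow(hits) == 0) return("unassigned")
  keep <- hits$bit_score >= (1 - top_percent / 100) * max(hits$bit_score)
  hits <- hits[keep, , drop = FALSE]
  total <- sum(hits$bit_score)
  lineages <- lapply(hits$taxon_id, function(t) tax_lineage(tree, t))
  nodes <- tree$nodes$taxon_id
  wt <- vapply(nodes, function(nd)
    sum(hits$bit_score[vapply(lineages, function(l) nd %in% l, TRUE)]),
    numeric(1))
  ok <- nodes[wt >= threshold * total - 1e-12]
  d <- tree$depth[match(ok, tree$nodes$taxon_id)]
  cand <- ok[d == max(d)]
  if (length(cand) > 1) {
    cw <- wt[match(cand, nodes)]
    cand <- cand[order(-cw, cand)]
  }
  cand[1]
}

# Exhaustive Mann-Whitney permutation null for tie-free data: distribution
# of U over all C(n1+n2, n1) assignments of the pooled values.
mw_enumeration_oracle <- function(x, y, alternative) {
  pool <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    xs <- pool[idx]
    ys <- pool[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  combos <- utils::combn(length(pool), n1)
  us <- apply(combos, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  p_ge <- mean(us >= u_obs - 1e-12)
  p_le <- mean(us <= u_obs + 1e-12)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Exhaustive Spearman permutation null (tie-free): iterative permutation
# generation, distinct from the package's recursive generator.
all_perms_iter <- function(n) {
  out <- matrix(1L, 1, 1)
  for (v in seq_len(n)[-1]) {
    grown <- vector("list", v)
    for (pos in seq_len(v)) {
      left <- if (pos > 1) out[, seq_len(pos - 1), drop = FALSE] else NULL
      right <- if (pos <= ncol(out)) out[, pos:ncol(out), drop = FALSE] else NULL
      grown[[pos]] <- cbind(left, v, right)
    }
    out <- do.call(rbind, grown)
  }
  out
}

spearman_enumeration_oracle <- function(x, y, alternative) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- all_perms_iter(n)
  rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  switch(alternative,
         greater = mean(rhos >= rho_obs - 1e-12),
         less = mean(rhos <= rho_obs + 1e-12),
         two.sided = mean(abs(rhos) >= abs(rho_obs) - 1e-12))
}

# Exhaustive two-group ANOSIM: statistic recomputed from scratch for every
# distinct assignment of group sizes (combn), p = fraction with R >= observed.
anosim_enumeration_oracle <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  lev <- unique(groups)
  stopifnot(length(lev) == 2)
  n1 <- sum(groups == lev[1])
  rk <- matrix(0, n, n)
  rk[lower.tri(rk)] <- rank(d[lower.tri(d)])
  rk <- rk + t(rk)
  stat <- function(members1) {
    g <- rep(lev[2], n)
    g[members1] <- lev[1]
    same <- outer(g, g, "==")
    lt <- lower.tri(rk)
    (mean(rk[lt & !same]) - mean(rk[lt & same])) / (n * (n - 1) / 4)
  }
  combos <- utils::combn(n, n1)
  rs <- apply(combos, 2, stat)
  r_obs <- stat(which(groups == lev[1]))
  list(R = r_obs, p = mean(rs >= r_obs - 1e-12))
}

# Independently coded Wilcoxon signed-rank normal deviate.
wsr_formula_oracle <- function(x, y) {
  d <- (x - y)[x - y != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie <- table(abs(d))
  s2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
  z <- (v - mu) / sqrt(s2)
  list(V = v, Z = z, p = 2 * stats::pnorm(-abs(z)))
}
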