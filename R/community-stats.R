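## Community statistics over the OPU table: Wisconsin double
## standardization, Bray-Curtis dissimilarity, NMDS (Kruskal stress-1 with
## monotone regression), ANOSIM, exact Mann-Whitney / Wilcoxon signed-rank /
## Spearman tests, and the ANCOM W statistic for differential OPUs.

test_result <- function(method, statistic, p_value, alternative = "two.sided",
                        ...) {
  structure(c(list(statistic = statistic, p.value = p_value,
                   method = method, alternative = alternative,
                   data.name = "community data"), list(...)),
            class = c("metawax_test", "htest"))
}

as_dissim_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop_arg("dissimilarity must be a square matrix or dist")
  if (max(abs(d - t(d))) > 1e-8) stop_arg("dissimilarity must be symmetric")
  if (any(d < -1e-12)) stop_arg("dissimilarities must be non-negative")
  d
}

lower_vec <- function(m) m[lower.tri(m)]

#' Wisconsin double standardization
#'
#' Divides each entry of a samples x species matrix by its species (column)
#' maximum and then by its sample (row) total, so that every column maximum
#' is 1 before the second step and every row afterwards sums to 1.
#'
#' @param x non-negative numeric matrix, samples as rows
#' @return Standardized matrix of the same shape.
#' @export
wisconsin <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop_arg("matrix must be non-negative")
  cmax <- apply(x, 2, max)
  zero <- cmax == 0
  if (any(zero)) {
    nm <- colnames(x)[zero]
    stop_arg("all-zero column(s): ",
             paste(utils::head(if (is.null(nm)) which(zero) else nm, 3),
                   collapse = ", "))
  }
  x <- sweep(x, 2, cmax, "/")
  rs <- rowSums(x)
  if (any(rs == 0)) stop_arg("all-zero row(s) after column standardization")
  sweep(x, 1, rs, "/")
}

#' Bray-Curtis dissimilarity
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over species; symmetric,
#' zero-diagonal, bounded in `[0, 1]`.
#'
#' @param x non-negative samples x species matrix
#' @return Symmetric dissimilarity matrix with the sample names.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop_arg("matrix must be non-negative")
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    denom <- sum(x[i, ] + x[j, ])
    if (denom == 0)
      stop_arg("Bray-Curtis undefined for two all-zero samples (rows ",
               i, ", ", j, ")")
    d[i, j] <- d[j, i] <- sum(abs(x[i, ] - x[j, ])) / denom
  }
  d
}

## weighted pool-adjacent-violators: isotonic (non-decreasing) fit of y
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  val <- y
  wt <- w
  idx <- rep(1L, n)  # block sizes
  b <- 0L
  for (i in seq_len(n)) {
    b <- b + 1L
    val[b] <- y[i]
    wt[b] <- w[i]
    idx[b] <- 1L
    while (b > 1L && val[b - 1L] > val[b]) {
      tw <- wt[b - 1L] + wt[b]
      val[b - 1L] <- (wt[b - 1L] * val[b - 1L] + wt[b] * val[b]) / tw
      wt[b - 1L] <- tw
      idx[b - 1L] <- idx[b - 1L] + idx[b]
      b <- b - 1L
    }
  }
  rep(val[seq_len(b)], idx[seq_len(b)])
}

## monotone regression of configuration distances on dissimilarity order,
## with tied dissimilarities pooled (averaged) into single blocks
monotone_fit <- function(dvec, distvec) {
  o <- order(dvec)
  ds <- dvec[o]
  ys <- distvec[o]
  grp <- cumsum(!duplicated(ds))
  gy <- tapply(ys, grp, mean)
  gw <- tapply(ys, grp, length)
  fit_g <- pava(as.numeric(gy), as.numeric(gw))
  fit <- fit_g[grp]
  out <- numeric(length(dvec))
  out[o] <- fit
  out
}

kruskal_stress <- function(distvec, dhat) {
  sqrt(sum((distvec - dhat)^2) / sum(distvec^2))
}

config_dist <- function(y) {
  as.matrix(stats::dist(y))
}

#' Nonmetric multidimensional scaling
#'
#' Minimizes Kruskal stress-1
#' `sqrt(sum((dhat - |y_i - y_j|)^2) / sum(|y_i - y_j|^2))`, alternating
#' monotone (pool-adjacent-violators, ties averaged) regression of the
#' configuration distances on the dissimilarities with gradient descent
#' steps under a backtracking line search, so the stress is non-increasing
#' within every start. The first start is the classical metric scaling
#' solution, the rest are random; the best start is reported.
#'
#' @param d dissimilarity matrix or `dist`
#' @param k embedding dimension (default 2)
#' @param n_starts number of initializations (default 20)
#' @param max_iter iterations per start (default 500)
#' @param tol stop a start when the stress improvement falls below this
#'   (default 1e-6)
#' @param seed integer RNG seed for the random starts
#' @return Object of class `nmds_fit`: `points` (n x k, centered at the
#'   origin), `stress`, `stress_trace` (per-iteration stress of the best
#'   start), `n_starts`, `best_start`, `converged`, `seed`.
#' @export
nmds <- function(d, k = 2L, n_starts = 20L, max_iter = 500L, tol = 1e-6,
                 seed = 1L) {
  d <- as_dissim_matrix(d)
  n <- nrow(d)
  if (n < k + 1L) stop_arg("need at least k + 1 points")
  dvec <- lower_vec(d)
  run_start <- function(y) {
    tr <- numeric(0)
    step <- 0.05 * max(dvec)
    dm <- config_dist(y)
    dm[dm < 1e-12] <- 1e-12
    dv <- lower_vec(dm)
    dhat <- monotone_fit(dvec, dv)
    s <- kruskal_stress(dv, dhat)
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      tr <- c(tr, s)
      ## gradient of stress wrt y at fixed dhat
      S <- sum((dv - dhat)^2)
      Tn <- sum(dv^2)
      if (S < 1e-24) {
        conv <- TRUE
        break
      }
      dhm <- matrix(0, n, n)
      dhm[lower.tri(dhm)] <- dhat
      dhm <- dhm + t(dhm)
      coef <- s * ((dm - dhm) / S - dm / Tn) / dm
      diag(coef) <- 0
      grad <- (y * rowSums(coef)) - coef %*% y
      grad <- 2 * grad
      gnorm <- sqrt(sum(grad^2))
      if (gnorm < 1e-14) {
        conv <- TRUE
        break
      }
      improved <- FALSE
      for (try in 1:30) {
        y2 <- y - step * grad / gnorm
        dm2 <- config_dist(y2)
        dm2[dm2 < 1e-12] <- 1e-12
        dv2 <- lower_vec(dm2)
        dhat2 <- monotone_fit(dvec, dv2)
        s2 <- kruskal_stress(dv2, dhat2)
        if (s2 <= s) {
          improved <- TRUE
          break
        }
        step <- step / 2
      }
      if (!improved) {
        conv <- TRUE
        break
      }
      delta <- s - s2
      y <- y2
      dm <- dm2
      dv <- dv2
      dhat <- dhat2
      s <- s2
      step <- step * 1.2
      if (delta < tol) {
        conv <- TRUE
        break
      }
    }
    list(y = y, stress = s, trace = c(tr, s), converged = conv)
  }
  best <- NULL
  best_i <- NA_integer_
  with_seed(seed, {
    for (i in seq_len(n_starts)) {
      y0 <- if (i == 1L) {
        cm <- suppressWarnings(stats::cmdscale(d, k = k))
        if (ncol(cm) < k) cbind(cm, matrix(stats::rnorm(n * (k - ncol(cm)),
                                                        sd = 1e-3), n))
        else cm
      } else matrix(stats::rnorm(n * k), n, k)
      res <- run_start(y0)
      if (is.null(best) || res$stress < best$stress) {
        best <- res
        best_i <- i
      }
    }
  }, stream = 31L)
  pts <- scale(best$y, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  dimnames(pts) <- list(rownames(d), paste0("NMDS", seq_len(k)))
  structure(list(points = pts, stress = best$stress,
                 stress_trace = best$trace, n_starts = n_starts,
                 best_start = best_i, converged = best$converged,
                 seed = seed),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("nmds_fit: %d points in %d dims, stress %.4g (best of %d starts)\n",
              nrow(x$points), ncol(x$points), x$stress, x$n_starts))
  invisible(x)
}

all_label_arrangements <- function(groups) {
  n <- length(groups)
  perm_all <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1))
    out <- NULL
    for (i in seq_along(v)) {
      rest <- perm_all(v[-i])
      out <- rbind(out, cbind(v[i], rest))
    }
    out
  }
  p <- perm_all(seq_len(n))
  lab <- matrix(groups[p], nrow(p))
  unique(lab)
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's rank-based statistic
#' `R = (mean rank between - mean rank within) / (n(n-1)/4)` over all
#' pairwise dissimilarities (midranks for ties), with a label-permutation
#' p-value `(1 + #[R_perm >= R_obs]) / (1 + n_perm)`, or exhaustive
#' enumeration of all distinct label arrangements when `exact = TRUE`.
#'
#' @param d dissimilarity matrix or `dist`
#' @param groups group label per sample; at least two groups of two
#' @param n_perm number of permutations (default 999)
#' @param seed integer RNG seed for the permutations
#' @param exact enumerate all distinct label arrangements (small n only)
#' @return A `metawax_test` (`htest`) with `statistic` R, `p.value`,
#'   `n_permutations` and `exact`.
#' @export
anosim <- function(d, groups, n_perm = 999L, seed = 1L, exact = FALSE) {
  d <- as_dissim_matrix(d)
  groups <- as.character(groups)
  n <- nrow(d)
  if (length(groups) != n) stop_arg("one group label per sample required")
  if (length(unique(groups)) < 2L || any(table(groups) < 2L))
    stop_arg("need >= 2 groups with >= 2 members each")
  r <- matrix(0, n, n)
  r[lower.tri(r)] <- rank(lower_vec(d))
  r <- r + t(r)
  stat <- function(g) {
    same <- outer(g, g, "==")
    within <- mean(r[lower.tri(r) & same])
    between <- mean(r[lower.tri(r) & !same])
    (between - within) / (n * (n - 1) / 4)
  }
  R_obs <- stat(groups)
  if (exact) {
    labs <- all_label_arrangements(groups)
    Rs <- apply(labs, 1, stat)
    p <- mean(Rs >= R_obs - 1e-12)
    return(test_result("ANOSIM (exact enumeration)", c(R = R_obs), p,
                       alternative = "greater",
                       n_permutations = nrow(labs), exact = TRUE))
  }
  b <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i)
      stat(sample(groups)) >= R_obs - 1e-12, TRUE))
  }, stream = 41L)
  p <- (1 + b) / (1 + n_perm)
  test_result("ANOSIM", c(R = R_obs), p, alternative = "greater",
              n_permutations = n_perm, exact = FALSE)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' U statistic with midranks; the p-value is exact (dynamic-programming null
#' distribution, via the U distribution function) when there are no ties and
#' `n1 + n2 <= exact_max_n`, otherwise a normal approximation with
#' tie-corrected variance (and continuity correction when `correct`).
#'
#' @param x,y the two samples (non-empty)
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`
#' @param exact_max_n use the exact null up to this total sample size
#' @param correct continuity correction in the normal approximation
#' @return A `metawax_test` (`htest`) with `statistic` U and `exact` flag.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater", "less"),
                         exact_max_n = 25L, correct = TRUE) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop_arg("both samples must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (n1 + n2) <= exact_max_n
  if (exact) {
    p <- switch(alternative,
      less = stats::pwilcox(U, n1, n2),
      greater = stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE),
      two.sided = {
        if (U > n1 * n2 / 2)
          min(1, 2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE))
        else min(1, 2 * stats::pwilcox(U, n1, n2))
      })
  } else {
    mu <- n1 * n2 / 2
    nt <- table(c(x, y))
    N <- n1 + n2
    v <- n1 * n2 / 12 * ((N + 1) - sum(nt^3 - nt) / (N * (N - 1)))
    if (v <= 0) {
      z <- 0
    } else {
      cc <- if (correct) switch(alternative,
        two.sided = sign(U - mu) * 0.5, greater = 0.5, less = -0.5) else 0
      z <- (U - mu - cc) / sqrt(v)
    }
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z))
    p <- min(1, p)
  }
  test_result("Mann-Whitney U", c(U = U), p, alternative, exact = exact,
              n = c(n1 = n1, n2 = n2))
}

#' Wilcoxon signed-rank test (normal approximation)
#'
#' Paired test on `x - y`; zero differences are dropped. The statistic is
#' the positive-rank sum V, reported with the tie-corrected normal deviate
#' `Z = (V - n(n+1)/4) / sd` without continuity correction and a two-sided
#' p-value.
#'
#' @param x,y paired vectors of equal length
#' @return A `metawax_test` (`htest`) with `statistic` c(V, Z).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop_arg("paired vectors must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) stop_arg("all differences are zero: no information")
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  nt <- table(abs(d))
  v <- n * (n + 1) * (2 * n + 1) / 24 - sum(nt^3 - nt) / 48
  z <- if (v > 0) (V - mu) / sqrt(v) else 0
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  test_result("Wilcoxon signed rank (normal approximation)",
              c(V = V, Z = z), p, "two.sided", n = n, exact = FALSE)
}

## all permutations of 1..n as a matrix (n! rows)
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- perm_matrix(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, n * m, n)
  for (i in seq_len(n)) {
    vals <- seq_len(n)[-i]
    rows <- ((i - 1L) * m + 1L):(i * m)
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(vals[sub], m)
  }
  out
}

#' Spearman rank correlation test
#'
#' Pearson correlation of midranks. With no ties and `n <= exact_max_n` the
#' p-value is exact by enumeration over all `n!` rank permutations;
#' otherwise it uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y equal-length vectors, `n >= 3`, neither constant
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#' @param exact_max_n exact-enumeration limit (default 9)
#' @return A `metawax_test` (`htest`) with `statistic` rho.
#' @export
spearman_test <- function(x, y,
                          alternative = c("two.sided", "greater", "less"),
                          exact_max_n = 9L) {
  alternative <- match.arg(alternative)
  n <- length(x)
  if (length(y) != n || n < 3L) stop_arg("need equal-length vectors, n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_arg("constant vector: correlation undefined")
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (!ties && n <= exact_max_n) {
    perms <- perm_matrix(n)
    base <- seq_len(n)
    rhos <- apply(perms, 1, function(p) stats::cor(base, p))
    p <- switch(alternative,
      two.sided = mean(abs(rhos) >= abs(rho) - 1e-12),
      greater = mean(rhos >= rho - 1e-12),
      less = mean(rhos <= rho + 1e-12))
    return(test_result("Spearman rank correlation (exact enumeration)",
                       c(rho = rho), p, alternative, exact = TRUE, n = n))
  }
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(tt), n - 2),
    greater = stats::pt(tt, n - 2, lower.tail = FALSE),
    less = stats::pt(tt, n - 2))
  test_result("Spearman rank correlation (t approximation)", c(rho = rho),
              min(1, p), alternative, exact = FALSE, n = n)
}

#' ANCOM W statistic for differential OPUs
#'
#' For each feature i, tests every additive log-ratio
#' `log((x_i + pseudocount) / (x_j + pseudocount))`, j != i, between the two
#' groups with the rank-sum test, applies Benjamini-Hochberg correction at
#' `alpha` within feature i, and counts the rejections as `W_i`. Feature i
#' is flagged as detected when `W_i >= detect_frac * (m - 1)`.
#'
#' @param x samples x features abundance matrix (at least 2 features)
#' @param groups two-level group label per sample, each group >= 3 samples
#' @param alpha per-feature BH level (default 0.05)
#' @param detect_frac detection cutoff as a fraction of `m - 1`
#'   (default 0.7)
#' @param pseudocount added before the log (default 1)
#' @return data.frame (`feature`, `W`, `detected`) in column order of `x`.
#' @export
ancom_w <- function(x, groups, alpha = 0.05, detect_frac = 0.7,
                    pseudocount = 1) {
  x <- as.matrix(x)
  m <- ncol(x)
  if (m < 2L) stop_arg("need at least 2 features")
  groups <- as.character(groups)
  if (length(groups) != nrow(x)) stop_arg("one group label per sample")
  lev <- unique(groups)
  if (length(lev) != 2L || any(table(groups) < 3L))
    stop_arg("need exactly two groups with >= 3 samples each")
  g1 <- groups == lev[1L]
  lx <- log(x + pseudocount)
  pmat <- matrix(NA_real_, m, m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    lr <- lx[, i] - lx[, j]
    pmat[i, j] <- pmat[j, i] <-
      mann_whitney(lr[g1], lr[!g1], "two.sided")$p.value
  }
  W <- vapply(seq_len(m), function(i) {
    padj <- stats::p.adjust(pmat[i, -i], method = "BH")
    sum(padj <= alpha)
  }, 1L)
  feature <- if (is.null(colnames(x))) paste0("feature_", seq_len(m))
             else colnames(x)
  data.frame(feature = feature, W = W,
             detected = W >= detect_frac * (m - 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}
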