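# Canonical correspondence analysis of cluster abundance matrices
# against environmental factors, with marginal permutation tests per
# factor.

# chi-square standardisation of a non-negative community matrix:
# Q_ij = (p_ij - r_i c_j) / sqrt(r_i c_j)
.chisq_standardise <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("community matrix must be non-negative")
  tot <- sum(Y)
  if (tot <= 0) stop("community matrix is all zero")
  r <- rowSums(Y) / tot
  c <- colSums(Y) / tot
  if (any(r == 0))
    stop(sprintf("sample '%s' has zero total abundance",
                 rownames(Y)[which(r == 0)[1]]))
  if (any(c == 0))
    stop(sprintf("cluster '%s' has zero total abundance",
                 colnames(Y)[which(c == 0)[1]]))
  P <- Y / tot
  Q <- (P - outer(r, c)) / sqrt(outer(r, c))
  list(Q = Q, r = r, c = c)
}

# dummy-code a predictor table: numeric columns pass through, factors
# and characters expand to treatment contrasts (first level reference)
.design_matrix <- function(X, n) {
  if (is.null(dim(X))) X <- data.frame(x = X)
  X <- as.data.frame(X, stringsAsFactors = FALSE)
  if (nrow(X) != n) stop("predictors and community matrix disagree on sample count")
  mm <- stats::model.matrix(~ ., data = X)
  mm[, -1, drop = FALSE]                 # drop intercept
}

#' Canonical correspondence analysis
#'
#' Constrained ordination relating a non-negative community matrix to
#' environmental predictors (ter Braak's algorithm): the community
#' matrix is chi-square standardised, its rows are projected onto the
#' predictor space by weighted least squares with row-mass weights, and
#' the fitted matrix is decomposed by SVD.  Eigenvalues are the squared
#' singular values; total inertia is the sum of squared standardised
#' entries; the pseudo-F statistic is
#' `(constrained/q) / (residual/(n - q - 1))` with `q` the rank of the
#' constraint matrix.
#'
#' @param Y samples x clusters matrix of non-negative abundances with
#'   positive row and column sums (rows are weighted by their mass, so
#'   counts and relative abundances give identical results up to row
#'   weighting).
#' @param X predictors: numeric vector, matrix or data frame;
#'   categorical columns are dummy-coded with first-level reference.
#'   Aliased (rank-deficient) columns are dropped with a warning.
#' @return An object of class `cca_result`: `eig` (descending
#'   constrained eigenvalues), `total_inertia`, `constrained_inertia`,
#'   `pseudo_F`, `rank`, `site_scores` (linear-combination scores),
#'   `species_scores` and `biplot_scores`.
#' @examples
#' Y <- matrix(rpois(24, 8) + 1, 6, 4)
#' cca_fit(Y, data.frame(ph = c(4, 5, 6, 7, 8, 4.5)))$eig
#' @export
cca_fit <- function(Y, X) {
  Y <- as.matrix(Y)
  st <- .chisq_standardise(Y)
  n <- nrow(Y)
  M <- .design_matrix(X, n)

  # weighted centring and projection, weights = row masses
  w <- st$r
  sw <- sqrt(w)
  ctr <- colSums(M * w)
  Mc <- sweep(M, 2L, ctr)            # weighted-centred predictors
  Z <- Mc * sw                        # rows scaled by sqrt(w)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    dropped <- colnames(Z)[qz$pivot[seq.int(qz$rank + 1L, ncol(Z))]]
    warning(sprintf("dropping aliased constraint column(s): %s",
                    paste(dropped, collapse = ", ")))
  }
  q <- qz$rank
  if (q == 0) {
    fit <- matrix(0, n, ncol(Y))
  } else {
    fit <- qr.fitted(qz, st$Q)
  }
  total <- sum(st$Q^2)
  constrained <- sum(fit^2)
  sv <- svd(fit)
  eig <- sv$d^2
  eig <- eig[eig > max(1e-12 * max(eig, 0), 1e-14)]
  k <- length(eig)
  resid <- total - constrained
  pseudo_F <- if (q > 0 && n - q - 1 > 0 && resid > 0)
    (constrained / q) / (resid / (n - q - 1)) else NA_real_

  site <- if (k) sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                         diag(sv$d[seq_len(k)], k), 1L, sw, "/") else
    matrix(0, n, 0)
  rownames(site) <- rownames(Y)
  species <- if (k) sweep(sv$v[, seq_len(k), drop = FALSE], 1L,
                          sqrt(st$c), "/") else matrix(0, ncol(Y), 0)
  rownames(species) <- colnames(Y)
  biplot <- if (k && q > 0) {
    sc <- scale(site, center = colSums(site * w), scale = FALSE)
    stats::cov.wt(cbind(Mc, sc), wt = w, cor = TRUE)$cor[
      seq_len(ncol(Mc)), ncol(Mc) + seq_len(k), drop = FALSE]
  } else matrix(0, ncol(M), 0)

  structure(list(eig = eig, total_inertia = total,
                 constrained_inertia = constrained,
                 pseudo_F = pseudo_F, rank = q,
                 site_scores = site, species_scores = species,
                 biplot_scores = biplot),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat("Canonical correspondence analysis\n")
  cat(sprintf("  total inertia:       %.6f\n", x$total_inertia))
  cat(sprintf("  constrained inertia: %.6f (%.1f%%)\n", x$constrained_inertia,
              100 * x$constrained_inertia / x$total_inertia))
  cat(sprintf("  pseudo-F:            %.4f (rank %d)\n", x$pseudo_F, x$rank))
  cat("  eigenvalues:", paste(signif(x$eig, 6), collapse = ", "), "\n")
  invisible(x)
}

# F statistic only, reusing a fixed standardisation; M is the raw
# (uncentred) design matrix for the permuted predictor
.cca_F <- function(st, M, n) {
  w <- st$r; sw <- sqrt(w)
  Mc <- sweep(M, 2L, colSums(M * w))
  qz <- qr(Mc * sw)
  q <- qz$rank
  if (q == 0) return(NA_real_)
  constrained <- sum(qr.fitted(qz, st$Q)^2)
  total <- sum(st$Q^2)
  resid <- total - constrained
  if (n - q - 1 <= 0 || resid <= 0) return(NA_real_)
  (constrained / q) / (resid / (n - q - 1))
}

#' Marginal permutation test of one environmental factor
#'
#' Tests a single factor against the community matrix: the observed
#' pseudo-F from `cca_fit(Y, x)` is compared with the distribution
#' obtained by permuting the sample rows of the factor (a categorical
#' factor is permuted as a block, keeping its dummy columns together).
#' The p-value is `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`, so its
#' floor is `1/(n_perm + 1)` (0.001 at the default 999 permutations).
#'
#' @param Y community matrix as in [cca_fit()].
#' @param x one factor: numeric vector or factor/character vector.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed making the permutation stream reproducible.
#' @param factor_name label for reporting.
#' @return An object of class `permutation_test`: `factor`,
#'   `F_observed`, `p_value`, `n_permutations`, `seed`.
#' @export
permutation_test <- function(Y, x, n_perm = 999L, seed = 1L,
                             factor_name = deparse(substitute(x))) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  Y <- as.matrix(Y)
  st <- .chisq_standardise(Y)
  n <- nrow(Y)
  M <- .design_matrix(x, n)
  F_obs <- .cca_F(st, M, n)
  if (is.na(F_obs)) {                   # constant factor: nothing to test
    return(structure(list(factor = factor_name, F_observed = NA_real_,
                          p_value = 1.0, n_permutations = as.integer(n_perm),
                          seed = as.integer(seed)),
                     class = "permutation_test"))
  }
  F_perm <- numeric(n_perm)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    F_perm[b] <- .cca_F(st, M[sample.int(n), , drop = FALSE], n)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  p <- (1 + sum(F_perm >= F_obs, na.rm = TRUE)) / (1 + n_perm)
  structure(list(factor = factor_name, F_observed = F_obs, p_value = p,
                 n_permutations = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("permutation test: %s  F = %.4f  p = %.4g (%d permutations, seed %d)\n",
              x$factor, x$F_observed, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

#' Screen environmental factors across identity thresholds
#'
#' Runs a marginal [permutation_test()] for every environmental factor
#' against the relative-abundance matrix at every identity threshold,
#' producing the factors x thresholds p-value table used to judge which
#' factors structure the community.
#'
#' @param matrices named list of `abundance_matrix` objects as from
#'   [build_matrices()].
#' @param env data frame of per-sample environmental factors, rows
#'   aligned with (or named by) the matrix samples.
#' @param factors which columns of `env` to test (default all).
#' @param n_perm,seed passed to [permutation_test()] (each factor x
#'   threshold combination uses an offset of `seed` so streams are
#'   independent but reproducible).
#' @param drop_unassigned exclude the `"unassigned"` column before
#'   normalising.
#' @return Data frame with one row per factor and one p-value column
#'   per threshold, plus a final row with the number of clusters
#'   observed at each threshold.
#' @export
niche_screen <- function(matrices, env, factors = names(env),
                         n_perm = 999L, seed = 1L,
                         drop_unassigned = TRUE) {
  stopifnot(length(matrices) > 0)
  pvals <- matrix(NA_real_, nrow = length(factors), ncol = length(matrices),
                  dimnames = list(factors, names(matrices)))
  ncl <- integer(length(matrices))
  for (j in seq_along(matrices)) {
    m <- matrices[[j]]
    rel <- relative_abundance(m, drop_unassigned = drop_unassigned)
    rel <- rel[, colSums(rel) > 0, drop = FALSE]
    ncl[j] <- ncol(rel)
    e <- env
    if (!is.null(rownames(m)) && all(rownames(m) %in% rownames(env)))
      e <- env[rownames(m), , drop = FALSE]
    for (i in seq_along(factors)) {
      pt <- permutation_test(rel, e[[factors[i]]], n_perm = n_perm,
                             seed = seed + 1000L * j + i,
                             factor_name = factors[i])
      pvals[i, j] <- pt$p_value
    }
  }
  out <- as.data.frame(pvals)
  out["n_clusters", ] <- ncl
  out
}
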