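#' SparCC configuration
#'
#' Parameters of the compositional correlation step: Dirichlet resampling
#' rounds, the strong-pair exclusion loop of the basis-variance solve,
#' permutation rounds for edge p-values, and the BH FDR gate for retained
#' edges (default 0.01, the network's edge threshold).
#'
#' @param n_resamples Dirichlet resampling rounds; the reported correlation is
#'   the element-wise median across rounds.
#' @param exclusion_threshold Pairs with |rho| above this are iteratively
#'   excluded from the basis system (sparsity assumption repair).
#' @param max_exclusions Maximum exclusion iterations per solve.
#' @param n_permutations Null rounds for permutation p-values.
#' @param edge_fdr BH FDR threshold for retaining network edges.
#' @param seed Integer seed for resampling and permutation.
#' @param method `"sparcc"` (default) or `"clr_pearson"`, a direct Pearson
#'   correlation of CLR-transformed counts for comparison.
#' @return A list of class `sparcc_config`.
#' @export
sparcc_config <- function(n_resamples = 20, exclusion_threshold = 0.1,
                          max_exclusions = 10, n_permutations = 100,
                          edge_fdr = 0.01, seed = 1L,
                          method = c("sparcc", "clr_pearson")) {
  method <- match.arg(method)
  stopifnot(n_resamples >= 1, exclusion_threshold > 0, max_exclusions >= 0,
            n_permutations >= 1, edge_fdr > 0, edge_fdr < 1)
  structure(list(n_resamples = n_resamples, exclusion_threshold = exclusion_threshold,
                 max_exclusions = max_exclusions, n_permutations = n_permutations,
                 edge_fdr = edge_fdr, seed = as.integer(seed), method = method),
            class = "sparcc_config")
}

# one SparCC estimate from one fraction matrix (species x samples)
sparcc_one <- function(frac, exclusion_threshold, max_exclusions) {
  D <- nrow(frac)
  L <- log(frac)
  C <- tcrossprod(L - rowMeans(L)) / (ncol(L) - 1)  # species covariance of log fractions
  v <- diag(C)
  Tm <- outer(v, v, "+") - 2 * C                    # variation matrix t_ij
  diag(Tm) <- 0

  # basis system: t_i = (D-2) omega_i + sum_j omega_j; exclusions knock single
  # pairs out of the sums
  M <- matrix(1, D, D); diag(M) <- D - 1
  inc <- matrix(TRUE, D, D); diag(inc) <- FALSE
  rho <- NULL
  for (iter in seq_len(max_exclusions + 1L)) {
    trow <- rowSums(Tm * inc)
    omega <- tryCatch(solve(M, trow), error = function(e) rep(mean(trow) / (2 * (D - 1)), D))
    omega <- pmax(omega, 1e-12)
    rho <- (outer(omega, omega, "+") - Tm) / (2 * sqrt(outer(omega, omega)))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    if (iter > max_exclusions) break
    cand <- abs(rho) * inc
    diag(cand) <- 0
    m <- max(cand)
    if (m <= exclusion_threshold) break
    ij <- which(cand == m, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    inc[i, j] <- inc[j, i] <- FALSE
    M[i, j] <- M[j, i] <- 0
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
  }
  rho
}

sparcc_once <- function(counts, cfg) {
  D <- nrow(counts); n <- ncol(counts)
  if (cfg$method == "clr_pearson") {
    lx <- log(counts + 1)
    clr <- sweep(lx, 2, colMeans(lx), "-")
    rho <- cor(t(clr))
    diag(rho) <- 1
    return(rho)
  }
  draws <- array(NA_real_, dim = c(D, D, cfg$n_resamples))
  for (r in seq_len(cfg$n_resamples)) {
    f <- matrix(rgamma(D * n, shape = as.vector(counts) + 1), D, n)
    f <- sweep(f, 2, colSums(f), "/")
    draws[, , r] <- sparcc_one(f, cfg$exclusion_threshold, cfg$max_exclusions)
  }
  rho <- apply(draws, c(1, 2), median)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(rownames(counts), rownames(counts))
  rho
}

#' SparCC compositional correlations
#'
#' Estimates correlations between underlying (basis) abundances from
#' compositional count data. Per resampling round, sample fractions are drawn
#' from Dirichlet(counts + 1), the log-ratio variation matrix
#' `t_ij = var(log(f_i/f_j))` is computed, basis variances are solved from
#' `sum_j t_ij = (D-2) omega_i + sum_j omega_j` under the sparsity assumption
#' (iteratively excluding the strongest pair above `exclusion_threshold`), and
#' `rho_ij = (omega_i + omega_j - t_ij) / (2 sqrt(omega_i omega_j))`. The
#' final estimate is the element-wise median across rounds, clipped to
#' `[-1, 1]`.
#'
#' @param counts Species x samples count matrix (>= 4 species, >= 10
#'   samples).
#' @param cfg A [sparcc_config()].
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sparcc_correlations <- function(counts, cfg = sparcc_config()) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 4) abort("SparCC basis system needs >= 4 species")
  if (ncol(counts) < 10) abort("SparCC needs >= 10 samples")
  if (any(counts < 0) || any(!is.finite(counts))) abort("counts must be finite and non-negative")
  if (max(counts) <= 1) abort("input does not look like counts (all entries <= 1)")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sparcc_once(counts, cfg)
}

#' Permutation p-values for SparCC correlations
#'
#' Each null round permutes every species' counts across samples
#' independently (destroying all between-species dependence while keeping
#' marginals) and recomputes the full SparCC estimate. Two-sided pseudo
#' p-values: `p_ij = (1 + #\{|rho_null| >= |rho_obs|\}) / (1 + n_permutations)`,
#' so the smallest attainable p is `1/(1 + n_permutations)`.
#'
#' @inheritParams sparcc_correlations
#' @param rho Observed correlation matrix; computed internally when `NULL`.
#' @return Symmetric matrix of p-values (diagonal `NA`).
#' @export
permutation_pvalues <- function(counts, cfg = sparcc_config(), rho = NULL) {
  counts <- as.matrix(counts)
  if (cfg$n_permutations < 20)
    warn("fewer than 20 permutation rounds: p-value granularity is coarse")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(rho)) rho <- sparcc_once(counts, cfg)
  D <- nrow(counts); n <- ncol(counts)
  exceed <- matrix(0L, D, D)
  for (b in seq_len(cfg$n_permutations)) {
    perm <- counts
    for (i in seq_len(D)) perm[i, ] <- perm[i, sample.int(n)]
    rho_null <- sparcc_once(perm, cfg)
    exceed <- exceed + (abs(rho_null) >= abs(rho))
  }
  p <- (1 + exceed) / (1 + cfg$n_permutations)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(rho)
  p
}
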