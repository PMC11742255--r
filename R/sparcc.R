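# SparCC-style inference of basis correlations from compositional count data.
#
# Read counts only carry relative information: correlations computed directly
# on fractions are biased by the closure. SparCC instead works from log-ratio
# variances t_ij = var(log(x_i/x_j)), which are invariant to per-sample
# scaling, and solves for the basis (absolute-abundance) variances w_i^2 under
# the assumption that the average correlation is weak (sparsity), using
#     t_ij = w_i^2 + w_j^2 - 2 rho_ij w_i w_j.
# Strongly correlated pairs violating the sparsity assumption are found and
# excluded iteratively, and the whole estimate is repeated on Dirichlet
# resamples of the fractions, taking the element-wise median.

#' Per-sample fraction matrix with pseudocount
#'
#' Converts counts to relative abundances after adding a pseudocount to every
#' cell (the conventional zero-handling for log-ratio methods).
#'
#' @param counts taxa x samples count matrix (or [otu_table()]).
#' @param pseudocount value added to every count before closure (default 1).
#' @return taxa x samples matrix of fractions; columns sum to 1.
#' @export
count_fractions <- function(counts, pseudocount = 1) {
  x <- unclass(counts) + pseudocount
  sweep(x, 2, colSums(x), "/")
}

#' Log-ratio variance matrix
#'
#' The matrix T with entries `t_ij = var(log(x_i / x_j))` across samples,
#' computed from per-sample fractions. Symmetric with a zero diagonal;
#' `t_ij = 0` exactly when taxa i and j are perfectly proportional.
#'
#' @param composition taxa x samples matrix of strictly positive fractions.
#' @return taxa x taxa variance matrix.
#' @examples
#' f <- count_fractions(matrix(rpois(40, 20), 4, 10))
#' log_ratio_variance_matrix(f)
#' @export
log_ratio_variance_matrix <- function(composition) {
  d <- nrow(composition)
  n <- ncol(composition)
  if (d < 2) stop("need at least 2 taxa")
  if (n < 4) stop("need at least 4 samples")
  if (any(composition <= 0)) stop("fractions must be strictly positive")
  lf <- log(composition)
  cv <- stats::cov(t(lf))
  v <- diag(cv)
  tm <- matrix(v, d, d) + matrix(v, d, d, byrow = TRUE) - 2 * cv
  tm[tm < 0] <- 0          # guard against roundoff
  diag(tm) <- 0
  dimnames(tm) <- dimnames(composition)[c(1, 1)]
  tm
}

#' Basis correlations from a log-ratio variance matrix
#'
#' Solves the sparsity-constrained linear system for the basis variances
#' (diagonal `D-1`, off-diagonal 1, right-hand side the row sums of T) and
#' converts them to correlations. Pairs whose estimated |rho| exceeds
#' `exclusion_threshold` are removed from the system one at a time — strongest
#' first — and the variances re-solved, for at most `max_exclusion_rounds`
#' rounds; this is what keeps single strong correlations from inflating the
#' variance estimates of their taxa.
#'
#' For exactly 3 uncorrelated taxa the solution reduces to the closed form
#' `w_i^2 = (t_ij + t_ik - t_jk) / 2`.
#'
#' @param tm log-ratio variance matrix from [log_ratio_variance_matrix()].
#' @param exclusion_threshold |rho| above which a pair is excluded from the
#'   variance system (default 0.1).
#' @param max_exclusion_rounds maximum number of excluded pairs (default 10).
#' @return List with `rho` (correlation matrix, clipped to \[-1, 1\], unit
#'   diagonal), `omega2` (basis variances) and `n_excluded`.
#' @export
basis_correlations <- function(tm, exclusion_threshold = 0.1,
                               max_exclusion_rounds = 10) {
  d <- nrow(tm)
  if (d < 3) stop("need at least 3 taxa: basis system underdetermined")
  m <- matrix(1, d, d)
  diag(m) <- d - 1
  excluded <- matrix(FALSE, d, d)
  t_eff <- tm

  solve_rho <- function() {
    v <- tryCatch(solve(m, rowSums(t_eff)), error = function(e) NULL)
    if (is.null(v)) return(NULL)
    vmin <- min(v[v > 0], 1e-12)
    v[v <= 0] <- vmin
    w <- sqrt(v)
    rho <- (matrix(v, d, d) + matrix(v, d, d, byrow = TRUE) - tm) /
      (2 * outer(w, w))
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    list(rho = rho, omega2 = v)
  }

  est <- solve_rho()
  if (is.null(est)) stop("basis variance system is singular")
  n_excluded <- 0
  for (round in seq_len(max_exclusion_rounds)) {
    cand <- abs(est$rho)
    cand[excluded] <- 0
    cand[lower.tri(cand, diag = TRUE)] <- 0
    mx <- which(cand == max(cand), arr.ind = TRUE)[1, ]
    if (cand[mx[1], mx[2]] <= exclusion_threshold) break
    i <- mx[1]; j <- mx[2]
    # a taxon involved in too many exclusions leaves the system ill-posed
    if (m[i, i] <= 2 || m[j, j] <= 2) break
    excluded[i, j] <- excluded[j, i] <- TRUE
    m[i, i] <- m[i, i] - 1
    m[j, j] <- m[j, j] - 1
    m[i, j] <- m[i, j] - 1
    m[j, i] <- m[j, i] - 1
    t_eff[i, j] <- t_eff[j, i] <- 0
    nxt <- solve_rho()
    if (is.null(nxt)) break
    est <- nxt
    n_excluded <- n_excluded + 1
  }
  dimnames(est$rho) <- dimnames(tm)
  list(rho = est$rho, omega2 = est$omega2, n_excluded = n_excluded)
}

# One Dirichlet resample of the fraction matrix: per sample, fractions drawn
# Dirichlet(counts + pseudocount), the posterior under a uniform prior.
dirichlet_fractions <- function(counts, pseudocount = 1) {
  x <- matrix(stats::rgamma(length(counts),
                            shape = as.numeric(counts) + pseudocount),
              nrow(counts), ncol(counts), dimnames = dimnames(counts))
  sweep(x, 2, colSums(x), "/")
}

#' SparCC correlation estimate for an OTU table
#'
#' Runs the basis-correlation solver on `n_iter` Dirichlet resamples of the
#' fraction matrix and returns the element-wise median, which damps the
#' sampling noise of low counts. Deterministic at a fixed seed.
#'
#' @param table taxa x samples count matrix or [otu_table()] (already
#'   prevalence-filtered).
#' @param n_iter number of Dirichlet resampling iterations (default 20).
#' @param exclusion_threshold,max_exclusion_rounds passed to
#'   [basis_correlations()].
#' @param pseudocount Dirichlet prior weight per cell (default 1).
#' @param seed integer seed.
#' @return List of class `sparcc_estimate`: `taxa`, `r_matrix` (symmetric,
#'   unit diagonal), `n_iterations`.
#' @examples
#' tb <- matrix(rpois(200, 50), 10, 20,
#'              dimnames = list(paste0("t", 1:10), paste0("s", 1:20)))
#' est <- sparcc(tb, n_iter = 5, seed = 1)
#' range(est$r_matrix)
#' @export
sparcc <- function(table, n_iter = 20, exclusion_threshold = 0.1,
                   max_exclusion_rounds = 10, pseudocount = 1, seed = 1L) {
  counts <- unclass(table)
  if (n_iter < 1) stop("n_iter must be at least 1")
  rhos <- with_seed(seed, {
    lapply(seq_len(n_iter), function(it) {
      f <- dirichlet_fractions(counts, pseudocount)
      basis_correlations(log_ratio_variance_matrix(f),
                         exclusion_threshold, max_exclusion_rounds)$rho
    })
  })
  r <- apply(simplify2array(rhos), c(1, 2), stats::median)
  r <- (r + t(r)) / 2    # medians are symmetric; enforce exactly
  diag(r) <- 1
  dimnames(r) <- dimnames(counts)[c(1, 1)]
  structure(list(taxa = rownames(counts) %||% as.character(seq_len(nrow(counts))),
                 r_matrix = r, n_iterations = n_iter,
                 exclusion_threshold = exclusion_threshold,
                 pseudocount = pseudocount),
            class = "sparcc_estimate")
}

#' Bootstrap pseudo P-values for SparCC correlations
#'
#' Builds a permutation null by independently shuffling each taxon's counts
#' across samples — destroying all between-taxon association while preserving
#' each taxon's marginal distribution — re-estimating the correlation matrix
#' on each of `B` such datasets, and counting how often the null |r| reaches
#' the observed |r|. The add-one rule keeps p-values in
#' `[1/(B+1), 1]`.
#'
#' @param table taxa x samples count matrix or [otu_table()].
#' @param observed_r observed correlation matrix (from [sparcc()]).
#' @param B number of bootstrap/permutation datasets (default 100).
#' @param n_iter Dirichlet iterations per null estimate (default 20, matching
#'   [sparcc()]).
#' @param exclusion_threshold,max_exclusion_rounds,pseudocount as in
#'   [sparcc()].
#' @param seed integer seed.
#' @return Symmetric matrix of two-sided pseudo p-values; diagonal 1.
#' @export
bootstrap_pseudo_p <- function(table, observed_r, B = 100, n_iter = 20,
                               exclusion_threshold = 0.1,
                               max_exclusion_rounds = 10, pseudocount = 1,
                               seed = 1L) {
  counts <- unclass(table)
  if (B < 1) stop("B must be at least 1")
  d <- nrow(counts)
  n <- ncol(counts)
  hits <- matrix(0, d, d)
  with_seed(seed, {
    for (b in seq_len(B)) {
      null_counts <- t(apply(counts, 1, sample, size = n))
      r_b <- sparcc(null_counts, n_iter = n_iter,
                    exclusion_threshold = exclusion_threshold,
                    max_exclusion_rounds = max_exclusion_rounds,
                    pseudocount = pseudocount,
                    seed = sample.int(2147483646, 1))$r_matrix
      hits <- hits + (abs(r_b) >= abs(observed_r))
    }
  })
  p <- (1 + hits) / (B + 1)
  p <- pmax(p, t(p))     # symmetrise conservatively
  diag(p) <- 1
  dimnames(p) <- dimnames(counts)[c(1, 1)]
  p
}
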