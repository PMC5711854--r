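# SparCC: basis-correlation inference for compositional count data.
# Per estimation iteration: draw component fractions from a Dirichlet
# posterior (counts + 1), form the log-ratio variation matrix
# T_ij = var(log(x_i/x_j)), solve the approximate linear system for the
# basis variances, convert to correlations, and iteratively exclude the
# strongest-correlated pair from the system; the reported matrix is the
# element-wise median over estimation iterations.

# variation matrix from a samples x OTUs fraction matrix:
# T_ij = var(log f_i) + var(log f_j) - 2 cov(log f_i, log f_j)
variation_matrix <- function(frac) {
  lf <- log(frac)
  C <- stats::cov(lf)
  v <- diag(C)
  outer(v, v, "+") - 2 * C
}

# one basis solve + exclusion loop on a variation matrix
sparcc_from_T <- function(Tm, n_exclusion_iter, exclusion_threshold) {
  p <- nrow(Tm)
  M <- matrix(1, p, p)
  diag(M) <- p - 1
  t_vec <- rowSums(Tm)
  excluded <- matrix(FALSE, p, p)

  basis_corr <- function() {
    omega <- tryCatch(solve(M, t_vec), error = function(e) NULL)
    if (is.null(omega)) return(NULL)
    omega <- pmax(omega, 1e-12)   # guard: negative basis variances degenerate
    r <- (outer(omega, omega, "+") - Tm) / (2 * sqrt(outer(omega, omega)))
    pmin(pmax(r, -1), 1)
  }

  r <- basis_corr()
  if (is.null(r)) stop("degenerate variation matrix: basis system singular")
  for (k in seq_len(n_exclusion_iter)) {
    ra <- abs(r)
    ra[excluded] <- -Inf
    diag(ra) <- -Inf
    m <- which.max(ra)
    if (ra[m] <= exclusion_threshold) break
    ij <- arrayInd(m, dim(ra))
    i <- ij[1]; j <- ij[2]
    # a component may leave the system entirely; keep it solvable
    if (M[i, i] <= 2 || M[j, j] <= 2) break
    t_vec[i] <- t_vec[i] - Tm[i, j]
    t_vec[j] <- t_vec[j] - Tm[i, j]
    M[i, j] <- M[i, j] - 1
    M[j, i] <- M[j, i] - 1
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    excluded[i, j] <- excluded[j, i] <- TRUE
    r2 <- basis_corr()
    if (is.null(r2)) break
    r <- r2
  }
  r
}

dirichlet_fractions <- function(counts) {
  g <- matrix(stats::rgamma(length(counts), shape = counts + 1),
              nrow(counts), ncol(counts))
  g / rowSums(g)
}

#' SparCC basis correlations from an OTU count table
#'
#' @param table an \code{otu_table} with at least 4 OTUs and 4 samples.
#' @param n_estimation_iter Dirichlet resampling iterations whose median is
#'   reported (published default 20).
#' @param n_exclusion_iter maximum strongly-correlated pairs excluded from
#'   the basis-variance system per iteration (published default 10).
#' @param exclusion_threshold |r| above which a pair is excluded
#'   (published default 0.1).
#' @param seed integer seed for the Dirichlet draws.
#' @return symmetric correlation matrix in [-1, 1] with unit diagonal,
#'   dimnames = OTU ids.
#' @export
sparcc <- function(table, n_estimation_iter = 20, n_exclusion_iter = 10,
                   exclusion_threshold = 0.1, seed = 1) {
  stopifnot(inherits(table, "otu_table"))
  p <- length(table$otu_ids)
  n <- length(table$sample_ids)
  if (p < 4) stop("SparCC needs at least 4 OTUs (got ", p, ")")
  if (n < 4) stop("SparCC needs at least 4 samples (got ", n, ")")
  rs <- withr::with_seed(seed, {
    lapply(seq_len(n_estimation_iter), function(it) {
      frac <- dirichlet_fractions(table$counts)
      Tm <- variation_matrix(frac)
      if (!all(is.finite(Tm))) stop("non-finite variation matrix")
      sparcc_from_T(Tm, n_exclusion_iter, exclusion_threshold)
    })
  })
  arr <- array(unlist(rs), dim = c(p, p, length(rs)))
  r <- apply(arr, c(1, 2), stats::median)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(table$otu_ids, table$otu_ids)
  r
}

#' Permutation p-values for SparCC correlations
#'
#' Each permutation shuffles every OTU's counts independently across samples
#' (destroying inter-OTU correlation while preserving marginals), recomputes
#' SparCC (with a reduced number of estimation iterations for tractability),
#' and the two-sided p-value is
#' \eqn{p_{ij} = (1 + \#\{|R^{perm}_{ij}| \ge |R^{obs}_{ij}|\}) / (n_{perm} + 1)}
#' (add-one smoothing so p = 0 never occurs). Permutation \code{k} shuffles
#' under seed \code{seed + k} and resamples under seed
#' \code{seed + n_perm + k}.
#'
#' @param table the same \code{otu_table} used for \code{r_obs}.
#' @param r_obs observed SparCC correlation matrix.
#' @param n_perm number of permutations (study setting: 1000).
#' @param seed integer seed.
#' @param perm_estimation_iter estimation iterations per permuted table.
#' @param n_exclusion_iter,exclusion_threshold passed to \code{\link{sparcc}}.
#' @return symmetric matrix of p-values in (0, 1], diagonal \code{NA}.
#' @export
permutation_pvalues <- function(table, r_obs, n_perm = 1000, seed = 1,
                                perm_estimation_iter = 5,
                                n_exclusion_iter = 10,
                                exclusion_threshold = 0.1) {
  stopifnot(inherits(table, "otu_table"), n_perm >= 1)
  p <- length(table$otu_ids)
  stopifnot(all(dim(r_obs) == p))
  abs_obs <- abs(r_obs)
  count <- matrix(0, p, p)
  for (k in seq_len(n_perm)) {
    perm <- withr::with_seed(seed + k,
      apply(table$counts, 2, sample))
    ptab <- otu_table(perm, sample_ids = table$sample_ids,
                      otu_ids = table$otu_ids)
    r_perm <- sparcc(ptab, n_estimation_iter = perm_estimation_iter,
                     n_exclusion_iter = n_exclusion_iter,
                     exclusion_threshold = exclusion_threshold,
                     seed = seed + n_perm + k)
    count <- count + (abs(r_perm) >= abs_obs)
  }
  pm <- (1 + count) / (n_perm + 1)
  pm <- (pm + t(pm)) / 2
  diag(pm) <- NA_real_
  dimnames(pm) <- dimnames(r_obs)
  pm
}
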