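# Negative-binomial differential testing: method-of-moments common
# dispersion and the exact conditional test for two groups of replicates.

#' Estimate a common NB dispersion by method of moments
#'
#' Counts are normalized to the mean library size; within each replicate
#' group the moment identity `Var = m + phi m^2` gives
#' `phi = sum(v_i - m_i) / sum(m_i^2 - v_i / r)` pooled over sites (the
#' denominator term corrects the bias of the squared sample mean), floored at
#' zero.
#'
#' @param counts Sites x replicates count matrix.
#' @param lib_sizes Library sizes (totals), one per column.
#' @param groups Optional factor assigning columns to conditions; moments are
#'   taken within groups.  Default: all columns form one group.
#' @param default_phi Returned (with a warning) when no group has >= 2
#'   replicates or the estimate is undefined.
#' @return Scalar dispersion estimate `phi >= 0`.
#' @export
estimate_dispersion <- function(counts, lib_sizes, groups = NULL,
                                default_phi = 0.1) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(lib_sizes))
  if (is.null(groups)) groups <- rep("g1", ncol(counts))
  groups <- as.factor(groups)
  ref <- mean(lib_sizes)
  y <- sweep(counts, 2L, ref / lib_sizes, "*")
  num <- 0; den <- 0; any_rep <- FALSE
  for (gname in levels(groups)) {
    j <- which(groups == gname)
    r <- length(j)
    if (r < 2L) next
    any_rep <- TRUE
    m <- rowMeans(y[, j, drop = FALSE])
    v <- apply(y[, j, drop = FALSE], 1L, stats::var)
    keep <- m > 0
    num <- num + sum(v[keep] - m[keep])
    den <- den + sum(m[keep]^2 - v[keep] / r)
  }
  if (!any_rep || den <= 0) {
    warning("no replication (or degenerate moments); returning default phi = ",
            default_phi)
    return(default_phi)
  }
  max(0, num / den)
}

# log pmf (unnormalized) of the conditional distribution of the pooled count
# of group A given the pooled total n, when both groups share a normalized
# mean: Dirichlet-multinomial with shapes r_a = n_a/phi, r_b = n_b/phi.
# phi = 0 degenerates to Binomial(n, n_a / (n_a + n_b)).
.nb_cond_logpmf <- function(n, r_a, r_b, phi) {
  k <- 0:n
  if (phi == 0) {
    stats::dbinom(k, n, r_a / (r_a + r_b), log = TRUE)
  } else {
    lgamma(k + r_a) - lgamma(k + 1) + lgamma(n - k + r_b) - lgamma(n - k + 1)
  }
}

#' Exact NB conditional test for differential counts
#'
#' Tests whether two groups of replicate counts share a normalized mean.
#' Counts are normalized to the mean library size and pooled within groups;
#' conditional on the pooled total, group A's count follows a
#' Dirichlet-multinomial with shapes `n_a/phi` and `n_b/phi` (Binomial for
#' `phi = 0`).  The two-sided p-value doubles the smaller tail (both tails
#' include the observed value), capped at 1.
#'
#' @param counts_a,counts_b Replicate count vectors.
#' @param lib_sizes_a,lib_sizes_b Library sizes parallel to the counts.
#' @param phi Common NB dispersion (>= 0).
#' @return p-value in (0, 1]; 1 when both pooled totals are zero.
#' @export
nb_exact_test <- function(counts_a, counts_b, lib_sizes_a, lib_sizes_b,
                          phi = 0) {
  stopifnot(all(counts_a >= 0), all(counts_b >= 0), phi >= 0)
  ref <- mean(c(lib_sizes_a, lib_sizes_b))
  ya <- round(sum(counts_a * ref / lib_sizes_a))
  yb <- round(sum(counts_b * ref / lib_sizes_b))
  .nb_exact_p(ya, yb, length(counts_a), length(counts_b), phi)
}

.nb_exact_p <- function(ya, yb, n_a, n_b, phi) {
  n <- ya + yb
  if (n == 0) return(1)
  lp <- if (phi > 0) .nb_cond_logpmf(n, n_a / phi, n_b / phi, phi)
        else .nb_cond_logpmf(n, n_a, n_b, 0)
  f <- exp(lp - max(lp))
  f <- f / sum(f)
  lower <- sum(f[1:(ya + 1)])
  upper <- sum(f[(ya + 1):(n + 1)])
  min(1, 2 * min(lower, upper))
}

# vectorized over sites: count matrices (sites x replicates)
.nb_exact_p_many <- function(mat_a, mat_b, lib_a, lib_b, phi) {
  ref <- mean(c(lib_a, lib_b))
  ya <- round(as.vector(mat_a %*% (ref / lib_a)))
  yb <- round(as.vector(mat_b %*% (ref / lib_b)))
  n_a <- ncol(mat_a); n_b <- ncol(mat_b)
  vapply(seq_along(ya), function(i) .nb_exact_p(ya[i], yb[i], n_a, n_b, phi),
         numeric(1L))
}
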