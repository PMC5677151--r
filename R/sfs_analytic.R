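# Analytic expected SFS under a single-population piecewise history.
#
# The engine rests on two classical results.  First, the expected per-site
# density of sites at derived count i in a sample of n chromosomes is
#
#   E[xi_i] = mu * sum_k k * E[T_k] * P(i | k),
#   P(i | k) = C(n-i-1, k-2) / C(n-1, k-1),
#
# where T_k is the total time during which the sample has k ancestral
# lineages.  Second, the number-of-lineages process is a pure-death chain
# whose occupancy probabilities in coalescent (rescaled) time tau have the
# closed form (a partial-fraction / spectral expansion)
#
#   P(K(tau) = k | K(0) = n) = sum_{j=k}^{n} rho_{jk} exp(-j(j-1) tau / 2).
#
# Under a piecewise history, tau(t) = integral_0^t dt' / (2 N(t')) is piecewise
# linear (constant epochs) or closed-form (exponential epochs), so
# E[T_k] = integral_0^inf P(K(tau(t)) = k) dt is computed exactly on constant
# epochs and by quadrature (rel.tol 1e-8) on exponential ones.

# Spectral coefficients rho_{jk} of the lineage-count occupancy, computed in
# log space: rising factorial k_(j-1), falling factorial n_[j], rising n_(j).
lineage_occupancy_coefs <- function(n, k) {
  j <- k:n
  lognum <- log(2 * j - 1) +
    (lgamma(k + j - 1) - lgamma(k)) +          # k_(j-1)
    (lfactorial(n) - lfactorial(n - j))        # n_[j]
  logden <- lfactorial(k) + lfactorial(j - k) +
    (lgamma(n + j) - lgamma(n))                # n_(j)
  sign <- (-1)^(j - k)
  list(j = j, coef = sign * exp(lognum - logden),
       rate = j * (j - 1) / 2)
}

# P(K(tau) = k) for a vector of tau values
lineage_occupancy_prob <- function(n, k, tau) {
  cf <- lineage_occupancy_coefs(n, k)
  drop(exp(-outer(tau, cf$rate)) %*% cf$coef)
}

# Cumulative coalescent intensity tau(t) at the epoch boundaries of a
# single-population demography, plus per-epoch descriptors.
coalescent_intensity <- function(demog) {
  st <- demography_steps(demog)
  K <- nrow(st)
  dtau <- numeric(K)
  for (i in seq_len(K)) {
    dt <- st$t1[i] - st$t0[i]
    if (st$N0[i] == st$N1[i]) {
      dtau[i] <- dt / (2 * st$N0[i])
    } else {
      beta <- log(st$N1[i] / st$N0[i]) / dt    # N(t) = N0 * exp(beta (t-t0))
      dtau[i] <- (1 - exp(-beta * dt)) / (2 * st$N0[i] * beta)
    }
  }
  dtau[K] <- Inf  # final epoch must reach tau = Inf (it is constant)
  list(steps = st, tau0 = cumsum(c(0, dtau[-K])), dtau = dtau)
}

#' Expected time spent at each lineage count under a piecewise history
#'
#' @param demog A single-population [piecewise_demography()] without events.
#' @param n Number of sampled chromosomes (>= 2).
#' @return Numeric vector `T[k]` for `k = 2..n` (named), in generations.
#'   Under constant size N, `T_k = 4N / (k (k-1))`.
#' @export
expected_branch_times <- function(demog, n) {
  if (!is_single_pop(demog))
    stop("unsupported feature: expected_branch_times requires a ",
         "single-population demography without events; use the Monte Carlo ",
         "engine (expected_sfs_montecarlo) for structured models",
         call. = FALSE)
  n <- as.integer(n)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  ci <- coalescent_intensity(demog)
  st <- ci$steps
  K <- nrow(st)
  Tk <- numeric(n - 1L)
  for (k in 2:n) {
    cf <- lineage_occupancy_coefs(n, k)
    tot <- 0
    for (i in seq_len(K)) {
      t0 <- st$t0[i]; t1 <- st$t1[i]
      tau0 <- ci$tau0[i]
      if (st$N0[i] == st$N1[i]) {
        # integral of P_k over tau, times 2N (dt = 2N dtau)
        tau1 <- tau0 + ci$dtau[i]
        e0 <- exp(-cf$rate * tau0)
        e1 <- if (is.finite(tau1)) exp(-cf$rate * tau1) else 0
        tot <- tot + 2 * st$N0[i] * sum(cf$coef * (e0 - e1) / cf$rate)
      } else {
        beta <- log(st$N1[i] / st$N0[i]) / (t1 - t0)
        tauf <- function(t)
          tau0 + (1 - exp(-beta * (t - t0))) / (2 * st$N0[i] * beta)
        ig <- stats::integrate(function(t)
          lineage_occupancy_prob(n, k, tauf(t)),
          lower = t0, upper = t1, rel.tol = 1e-8, abs.tol = 1e-10,
          subdivisions = 500L)
        tot <- tot + ig$value
      }
    }
    Tk[k - 1L] <- tot
  }
  stats::setNames(Tk, paste0("k", 2:n))
}

#' Analytic expected SFS under a single-population piecewise history
#'
#' Returns the expected per-site SNP density in each derived-allele
#' frequency class (kind `"persite"`): the classical coalescent identity
#' `E[xi_i] = mu * sum_k k E[T_k] P(i | k)` with
#' `P(i | k) = C(n-i-1, k-2) / C(n-1, k-1)`.  Deterministic; exact on
#' constant epochs, quadrature (rel.tol 1e-8) within exponential epochs.
#'
#' @param demog A single-population [piecewise_demography()] without events
#'   (multi-population input raises an unsupported-feature error directing
#'   to [expected_sfs_montecarlo()]).
#' @param n Number of sampled chromosomes (>= 2).
#' @return An unfolded `"persite"` [sfs_spectrum()].  Under constant size,
#'   proportions follow the neutral `1/i` law and `E[xi_1] = 4 N mu` for
#'   `n = 2`.
#' @export
expected_sfs_analytic <- function(demog, n) {
  n <- as.integer(n)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  Tk <- expected_branch_times(demog, n)
  k <- 2:n
  i <- seq_len(n - 1L)
  # P(branch subtends i | k lineages), rows i, cols k
  P <- outer(i, k, function(i, k)
    exp(lchoose(n - i - 1, k - 2) - lchoose(n - 1, k - 1)))
  xi <- demog$mutation_rate * drop(P %*% (k * Tk))
  sfs_spectrum(xi, n, "persite", folded = FALSE)
}
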