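# Independent oracles used to freeze expected values: brute-force
# enumeration and direct tabulation, kept free of the code paths they check.

# Distribution of the derived count among all C(n, m) subsamples of a site
# with i derived alleles among n chromosomes (exhaustive enumeration).
project_oracle <- function(i, n, m) {
  chroms <- c(rep(1L, i), rep(0L, n - i))
  subs <- utils::combn(n, m)
  counts <- apply(subs, 2L, function(ix) sum(chroms[ix]))
  vapply(seq_len(m - 1L), function(j) mean(counts == j), numeric(1))
}

# Mean pairwise Hamming distance per site across all C(n, 2) haplotype
# pairs of a 0/1 haplotype matrix (sites x haplotypes).
pairwise_pi_oracle <- function(hap, L) {
  n <- ncol(hap)
  tot <- 0
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
    tot <- tot + sum(hap[, a] != hap[, b])
  tot / choose(n, 2) / L
}

# Random haplotype matrix plus its consecutive-pairing dosage matrix.
random_hap_geno <- function(n_sites, n_dip, p = NULL) {
  n_hap <- 2L * n_dip
  repeat {
    hap <- matrix(rbinom(n_sites * n_hap, 1L,
                         if (is.null(p)) runif(1, 0.05, 0.95) else p),
                  n_sites, n_hap)
    ac <- rowSums(hap)
    if (all(ac > 0 & ac < n_hap)) break
  }
  dos <- hap[, seq(1L, n_hap, 2L), drop = FALSE] +
    hap[, seq(2L, n_hap, 2L), drop = FALSE]
  list(hap = hap, dos = dos)
}

# genotype_matrix wrapper around a dosage matrix on a single contig
as_gm <- function(dos, positions = NULL, L = NULL) {
  if (is.null(positions)) positions <- seq_len(nrow(dos)) * 10L
  if (is.null(L)) L <- max(positions) + 10L
  genotype_matrix(dos, positions = positions,
                  contig = rep("c1", nrow(dos)),
                  contig_lengths = c(c1 = L))
}

# simple two/three-epoch test demographies
two_epoch <- function(N_recent = 1e4, N_anc = 1e3, t = 1000,
                      mu = 1.25e-8) {
  piecewise_demography(list(epoch(0, t, c(pop1 = N_recent)),
                            epoch(t, Inf, c(pop1 = N_anc))),
                       mutation_rate = mu)
}
three_epoch <- function(mu = 1.25e-8) {
  piecewise_demography(list(epoch(0, 1000, c(pop1 = 1e4)),
                            epoch(1000, 3000, c(pop1 = 2e3)),
                            epoch(3000, Inf, c(pop1 = 8e3))),
                       mutation_rate = mu)
}
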