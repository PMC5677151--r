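# sfs_engine module: analytic engine, Monte Carlo engine, transforms

test_that("analytic SFS matches constant-size closed forms", {
  d <- constant_demography(1e4)
  Tk <- expected_branch_times(d, 10)
  k <- 2:10
  expect_equal(unname(Tk), 4e4 / (k * (k - 1)), tolerance = 1e-6)
  s4 <- expected_sfs_analytic(d, 4)
  expect_equal(as_proportions(s4)$values, c(6, 3, 2) / 11,
               tolerance = 1e-6)
  s2 <- expected_sfs_analytic(d, 2)
  expect_equal(s2$values, 4 * 1e4 * 1.25e-8, tolerance = 1e-6)
  # 1/i law at larger n
  s20 <- expected_sfs_analytic(d, 20)
  expect_equal(as_proportions(s20)$values,
               (1 / 1:19) / sum(1 / 1:19), tolerance = 1e-6)
  expect_error(expected_sfs_analytic(d, 1), "n must be")
  expect_error(
    expected_sfs_analytic(builtin_demography("three_pop_migration"), 10),
    "Monte Carlo|unsupported")
})

test_that("proportional analytic SFS is invariant to joint size/time scaling", {
  for (c_fac in c(0.3, 2, 7.5)) {
    d1 <- three_epoch()
    eps <- lapply(d1$epochs, function(e)
      epoch(e$t_start * c_fac, e$t_end * c_fac, e$size * c_fac))
    d2 <- piecewise_demography(eps, mutation_rate = d1$mutation_rate)
    p1 <- as_proportions(expected_sfs_analytic(d1, 12))$values
    p2 <- as_proportions(expected_sfs_analytic(d2, 12))$values
    expect_equal(p1, p2, tolerance = 1e-8)
  }
})

test_that("merging adjacent equal-size epochs is a no-op (n = 2)", {
  d1 <- two_epoch(1e4, 1e3, t = 2000)
  d2 <- piecewise_demography(list(
    epoch(0, 700, c(pop1 = 1e4)), epoch(700, 2000, c(pop1 = 1e4)),
    epoch(2000, 9000, c(pop1 = 1e3)), epoch(9000, Inf, c(pop1 = 1e3))))
  expect_equal(expected_sfs_analytic(d1, 2)$values,
               expected_sfs_analytic(d2, 2)$values, tolerance = 1e-9)
})

test_that("Monte Carlo engine agrees with the analytic engine", {
  d <- two_epoch()
  mc <- expected_sfs_montecarlo(d, c(pop1 = 10), n_reps = 3e4, seed = 7)
  an <- expected_sfs_analytic(d, 10)
  z <- (mc$values - an$values) / mc$se
  expect_true(all(abs(z) < 3))
  # identical seed, identical output
  mc2 <- expected_sfs_montecarlo(d, c(pop1 = 10), n_reps = 1000, seed = 5)
  mc3 <- expected_sfs_montecarlo(d, c(pop1 = 10), n_reps = 1000, seed = 5)
  expect_identical(mc2$values, mc3$values)
  expect_error(expected_sfs_montecarlo(d, c(nope = 10), n_reps = 10),
               "unknown|non-extant")
})

test_that("structured engine: symmetric isolated populations match", {
  # two populations with identical histories, joined only deep in time
  d <- piecewise_demography(
    list(epoch(0, 5e4, c(a = 5e3, b = 5e3)), epoch(5e4, Inf, c(a = 5e3))),
    events = list(split_event(5e4, derived = "b", ancestral = "a")))
  g <- simulate_genealogies(d, c(a = 6, b = 6), n_reps = 4000, seed = 11)
  se <- sqrt(g$a$se^2 + g$b$se^2)
  expect_true(all(abs(g$a$mean - g$b$mean) < 3 * se))
})

test_that("fold conserves mass and follows the definition", {
  s <- sfs_spectrum(c(5, 3, 2), 4, "counts")
  f <- fold(s)
  expect_equal(f$values, c(5 + 2, 3))
  expect_equal(sum(f$values), sum(s$values))
  expect_error(fold(f), "already folded")
  # odd n: floor(n/2) bins, no self-folding class
  s5 <- sfs_spectrum(c(4, 3, 2, 1), 5, "counts")
  expect_equal(fold(s5)$values, c(4 + 1, 3 + 2))
})

test_that("projection is expected hypergeometric down-sampling", {
  # one SNP at derived count 3 of n = 6 projected to m = 4, against the
  # exhaustive subsample enumeration oracle
  s <- sfs_spectrum(c(0, 0, 1, 0, 0), 6, "counts")
  pr <- project(s, 4)
  expect_equal(pr$values, project_oracle(3, 6, 4))
  expect_equal(pr$values, c(0.2, 0.6, 0.2))
  # m = n is the identity
  expect_identical(project(s, 6), s)
  expect_error(project(s, 7), "project up")
  # linearity: projection commutes with summation of spectra
  set.seed(3)
  a <- sfs_spectrum(runif(5), 6, "counts")
  b <- sfs_spectrum(runif(5), 6, "counts")
  ab <- sfs_spectrum(a$values + b$values, 6, "counts")
  expect_equal(project(ab, 4)$values,
               project(a, 4)$values + project(b, 4)$values)
  # mass lost only to monomorphic classes: project a full spectrum and
  # account for the lost mass explicitly
  set.seed(4)
  v <- runif(5)
  s6 <- sfs_spectrum(v, 6, "counts")
  lost <- sum(vapply(1:5, function(i)
    v[i] * (stats::dhyper(0, i, 6 - i, 4) + stats::dhyper(4, i, 6 - i, 4)),
    numeric(1)))
  expect_equal(sum(project(s6, 4)$values) + lost, sum(v))
})

test_that("marginalize_joint sums out other populations and drops ends", {
  # 2-population joint with a single entry at (1, 0)
  j <- array(0, dim = c(5, 7), dimnames = list(A = NULL, B = NULL))
  j[2, 1] <- 1  # count 1 in A, 0 in B
  mA <- marginalize_joint(j, "A")
  expect_equal(mA$values, c(1, 0, 0))
  expect_equal(mA$n, 4)
  mB <- marginalize_joint(j, "B")
  expect_equal(sum(mB$values), 0)  # B count is 0: dropped
  expect_error(marginalize_joint(j, "C"), "not an axis")
  # direct tabulation oracle on random per-site joint counts
  set.seed(9)
  nA <- 6; nB <- 4
  aA <- sample(0:nA, 200, replace = TRUE)
  aB <- sample(0:nB, 200, replace = TRUE)
  j2 <- array(0, dim = c(nA + 1, nB + 1), dimnames = list(A = NULL, B = NULL))
  for (s in 1:200) j2[aA[s] + 1, aB[s] + 1] <- j2[aA[s] + 1, aB[s] + 1] + 1
  expect_equal(marginalize_joint(j2, "A")$values,
               tabulate(aA[aA > 0 & aA < nA], nbins = nA - 1))
  expect_true(sum(marginalize_joint(j2, "A")$values) <= sum(j2))
})

test_that("singleton removal renormalizes the remaining bins", {
  s <- sfs_spectrum(c(0.5, 0.3, 0.2), 4, "proportions")
  expect_equal(drop_singletons_renormalize(s)$values, c(0, 0.6, 0.4))
  s0 <- sfs_spectrum(c(0, 0.6, 0.4), 4, "proportions")
  expect_equal(drop_singletons_renormalize(s0)$values, s0$values)
  all1 <- sfs_spectrum(c(1, 0, 0), 4, "proportions")
  expect_error(drop_singletons_renormalize(all1), "degenerate")
  expect_error(drop_singletons_renormalize(sfs_spectrum(c(1, 1, 1), 4,
                                                        "counts")),
               "proportional")
})

test_that("scale_to_counts applies theta = 4*N_Ai*mu*L", {
  sc <- scaling_params(1e4, 2.35e-8, 4.04e6)
  expect_equal(sc$theta, 3797.6)
  d <- constant_demography(1e4, mutation_rate = 2.35e-8)
  s <- expected_sfs_analytic(d, 20)
  cnt <- scale_to_counts(s, sc)
  expect_equal(cnt$kind, "counts")
  expect_equal(cnt$values, s$values * 4.04e6)
  # a relative (theta = 1) spectrum scales by theta itself
  rel <- sfs_spectrum(s$values / (4 * 1e4 * 2.35e-8), 20, "relative")
  expect_equal(scale_to_counts(rel, sc)$values, cnt$values,
               tolerance = 1e-12)
  zero <- scaling_params(1e4, 2.35e-8, 0)
  expect_equal(sum(scale_to_counts(s, zero)$values), 0)
  expect_error(scale_to_counts(cnt, sc), "persite|relative")
})

test_that("SFS text format round-trips and accepts bare vectors", {
  s <- sfs_spectrum(c(10, 5, 2.5, 1), 5, "counts")
  p <- tempfile(fileext = ".txt")
  write_sfs(s, p)
  s2 <- read_sfs(p)
  expect_equal(s2$values, s$values)
  expect_equal(s2$n, 5L)
  writeLines("12 7 3 1", p)
  bare <- read_sfs(p)
  expect_equal(bare$values, c(12, 7, 3, 1))
  expect_equal(bare$n, 5L)
})
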