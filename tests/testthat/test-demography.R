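# demography module: construction, parsing, conversion, editing

test_that("epoch and demography invariants are enforced", {
  expect_error(epoch(1000, 500, c(pop1 = 1e4)), "t_start < t_end")
  expect_error(epoch(0, Inf, c(pop1 = -5)), "positive")
  expect_error(piecewise_demography(list(epoch(0, 100, c(pop1 = 1e4)))),
               "unbounded")
  expect_error(piecewise_demography(list(
    epoch(0, 100, c(pop1 = 1e4)), epoch(200, Inf, c(pop1 = 1e4)))),
    "contiguous")
  m <- matrix(c(0, 2, 0, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(epoch(0, Inf, c(a = 1, b = 1), migration = m), "\\[0, 1\\]")
  expect_error(pulse_event(10, "a", "b", 1.5) |>
                 (\(ev) piecewise_demography(
                   list(epoch(0, Inf, c(a = 10, b = 10))),
                   events = list(ev)))(),
               "fraction")
})

test_that("epoch partition: every t >= 0 lies in exactly one epoch", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(1:5, 1)
    bounds <- sort(runif(k - 1, 1, 1e5))
    sizes <- runif(k, 100, 1e5)
    eps <- lapply(seq_len(k), function(i)
      epoch(c(0, bounds)[i], c(bounds, Inf)[i], c(pop1 = sizes[i])))
    d <- piecewise_demography(eps)
    ts <- c(0, runif(30, 0, 2e5), bounds)  # includes the boundaries
    idx <- epoch_index(d, ts)
    expect_true(all(idx >= 1 & idx <= k))
    for (j in seq_along(ts)) {
      e <- d$epochs[[idx[j]]]
      expect_true(ts[j] >= e$t_start && ts[j] < e$t_end)
    }
    expect_true(all(is.finite(size_at(d, ts))))
  }
})

test_that("parse_msmc_output applies the standard scaling", {
  tab <- data.frame(index = 0:2,
                    left_time_boundary = c(0, 1e-5, 5e-5),
                    right_time_boundary = c(1e-5, 5e-5, 1e-4),
                    lambda = c(1000, 500, 2000))
  mu <- 1.25e-8
  tr <- parse_msmc_output(tab, mu, generation_time = 30)
  expect_equal(tr$N[1], 1 / (2 * mu * 1000))  # 40,000 diploids
  expect_equal(tr$N[1], 40000)
  expect_equal(tr$t_left, tab$left_time_boundary / mu)
  expect_equal(tr$t_right[3], Inf)
  expect_identical(attr(tr, "generation_time"), 30)
  expect_error(parse_msmc_output(transform(tab, lambda = c(-1, 1, 1)), mu),
               "lambda")
  expect_error(parse_msmc_output(tab, -mu), "mu")
  bad <- tab; bad$left_time_boundary <- rev(bad$left_time_boundary)
  expect_error(parse_msmc_output(bad, mu), "nondecreasing")
})

test_that("MSMC table round-trip reproduces the trajectory", {
  tr <- size_trajectory(c(0, 800, 4000), c(800, 4000, Inf),
                        c(12000, 3000, 9000))
  mu <- 1.25e-8
  tab <- as_msmc_table(tr, mu)
  tr2 <- parse_msmc_output(tab, mu)
  expect_equal(tr2$t_left, tr$t_left)
  expect_equal(tr2$N, tr$N)
})

test_that("trajectory_to_stepwise passes steps through and refines functions", {
  tr <- size_trajectory(c(0, 1000), c(1000, Inf), c(1e4, 1e3))
  d <- trajectory_to_stepwise(tr, n_steps = 7)
  expect_length(d$epochs, 2)
  expect_equal(size_at(d, c(0, 999, 1000, 5e6)), c(1e4, 1e4, 1e3, 1e3))
  # exponential decline approximated on a geometric grid: doubling the
  # step count cannot worsen the maximum relative size error
  f <- function(t) 2e4 * exp(-t / 5e4)
  err <- function(n_steps) {
    d <- trajectory_to_stepwise(f, n_steps = n_steps, t_min = 10,
                                t_max = 2e5)
    tt <- exp(seq(log(10), log(2e5), length.out = 400))
    max(abs(size_at(d, tt) - f(tt)) / f(tt))
  }
  errs <- vapply(c(8, 16, 32, 64), err, numeric(1))
  expect_true(all(diff(errs) <= 0))
  expect_error(trajectory_to_stepwise(f, n_steps = 0), "n_steps")
})

test_that("average_trajectories takes the pointwise mean", {
  tr1 <- size_trajectory(c(0, 500), c(500, Inf), c(1000, 1000))
  tr3 <- size_trajectory(c(0, 500), c(500, Inf), c(3000, 3000))
  av <- average_trajectories(list(tr1, tr3))
  expect_true(all(abs(av$N - 2000) < 1e-9))
  same <- replicate(50, tr1, simplify = FALSE)
  av2 <- average_trajectories(same)
  expect_equal(popconcord:::trajectory_at(av2, c(0, 100, 499, 501, 1e6)),
               popconcord:::trajectory_at(tr1, c(0, 100, 499, 501, 1e6)))
  # log-scale averaging gives the geometric mean
  avg <- average_trajectories(list(tr1, tr3), scale = "log")
  expect_true(all(abs(avg$N - sqrt(1000 * 3000)) < 1e-9))
  expect_error(average_trajectories(list()), "at least one")
})

test_that("trim_model truncates, extends, and is idempotent", {
  d <- piecewise_demography(list(
    epoch(0, 1000, c(pop1 = 2e4)),
    epoch(1000, 5000, c(pop1 = 5e3)),
    epoch(5000, Inf, c(pop1 = 4e4))))
  # cutoff beyond all finite boundaries: unchanged
  expect_identical(trim_model(d, 6000), d)
  t1 <- trim_model(d, 3000)
  expect_length(t1$epochs, 2)
  expect_equal(t1$epochs[[2]]$t_end, Inf)
  expect_equal(size_at(t1, c(0, 999, 1500, 1e6)),
               c(2e4, 2e4, 5e3, 5e3))
  # never changes the size function on [0, t_max)
  tt <- seq(0, 2999, length.out = 50)
  expect_equal(size_at(t1, tt), size_at(d, tt))
  expect_identical(trim_model(t1, 3000), t1)
  # years are converted through the generation time (25 yr/gen default):
  # 225.5 KYA at 25 yr/gen = 9020 generations -> inside the oldest epoch
  expect_identical(trim_model(d, 225500, units = "years"), d)
  d30 <- piecewise_demography(d$epochs, generation_time = 30)
  t2 <- trim_model(d30, 225500, units = "years")  # 7516.7 generations
  expect_length(t2$epochs, 3)
  expect_equal(t2$epochs[[3]]$t_end, Inf)
})

test_that("set_ancestral_size replaces only the oldest epoch", {
  d <- two_epoch()
  d2 <- set_ancestral_size(d, 12300)
  expect_equal(size_at(d2, 1e6), 12300)
  expect_equal(size_at(d2, 0), size_at(d, 0))
  expect_equal(set_ancestral_size(d, 1e3)$epochs, d$epochs)
  expect_error(set_ancestral_size(d, -1), "positive")
})

test_that("rescale_mutation_rate preserves per-epoch 4*N*mu", {
  d <- two_epoch(mu = 1.25e-8)
  r <- rescale_mutation_rate(d, 2.5e-8)
  expect_equal(size_at(r, 0), 5e3)                # N halved
  expect_equal(r$epochs[[1]]$t_end, 500)          # t halved
  expect_equal(4 * size_at(r, 0) * r$mutation_rate,
               4 * size_at(d, 0) * d$mutation_rate)
  expect_equal(rescale_mutation_rate(d, d$mutation_rate)$epochs, d$epochs)
  # inverse composition is the identity to 1e-12 relative tolerance
  back <- rescale_mutation_rate(r, 1.25e-8)
  expect_equal(popconcord:::demography_steps(back), popconcord:::demography_steps(d),
               tolerance = 1e-12)
  expect_error(rescale_mutation_rate(d, 0), "positive")
})

test_that("ms emission and parsing round-trip the demography", {
  expect_identical(to_ms_command(constant_demography(5000)), "")
  d2 <- two_epoch(1e4, 2e4, t = 2 * 1e4)
  cmd <- to_ms_command(d2, N0 = 1e4)
  # a size step at 2*N0 generations sits at 0.5 in 4*N0-scaled time
  expect_match(cmd, "-en 0.5 1 2")
  expect_equal(popconcord:::demography_steps(parse_ms_command(cmd, N0 = 1e4)),
               popconcord:::demography_steps(d2))
  d3 <- builtin_demography("three_pop_migration")
  d3b <- parse_ms_command(to_ms_command(d3, N0 = 12000), N0 = 12000,
                          pop_labels = populations(d3))
  expect_equal(d3b$epochs, d3$epochs)
  expect_equal(d3b$events, d3$events)
  dp <- builtin_demography("archaic_pulse")
  dpb <- parse_ms_command(to_ms_command(dp, N0 = 1e4), N0 = 1e4,
                          pop_labels = populations(dp))
  expect_equal(dpb$epochs, dp$epochs)
  expect_equal(dpb$events, dp$events)
  # exponential epochs cannot be expressed in this dialect
  expect_error(to_ms_command(builtin_demography("growth")), "unsupported")
})

test_that("demography YAML/JSON round trips", {
  for (ext in c("yaml", "json")) {
    p <- tempfile(fileext = paste0(".", ext))
    d <- builtin_demography("three_pop_migration")
    write_demography(d, p)
    d2 <- read_demography(p)
    expect_equal(d2$epochs, d$epochs)
    expect_equal(length(d2$events), length(d$events))
    expect_equal(d2$mutation_rate, d$mutation_rate)
    g <- builtin_demography("growth")
    write_demography(g, p)
    expect_equal(read_demography(p)$epochs, g$epochs)
  }
})
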