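# Coalescent simulation of unlinked genealogies under piecewise histories
# with splits, migration, and pulse admixture; backend of the Monte Carlo
# SFS engine.  Single-population histories take a vectorized fast path
# (time-rescaled standard coalescent); structured models run an event-driven
# backward-in-time simulation.

# Invert the cumulative coalescent intensity: map tau values to generations.
invert_intensity <- function(ci, tau) {
  st <- ci$steps
  idx <- findInterval(tau, ci$tau0)
  idx[idx < 1L] <- 1L
  t0 <- st$t0[idx]; t1 <- st$t1[idx]
  N0 <- st$N0[idx]; N1 <- st$N1[idx]
  dtau <- tau - ci$tau0[idx]
  out <- t0 + 2 * N0 * dtau
  ex <- N0 != N1
  if (any(ex)) {
    beta <- log(N1[ex] / N0[ex]) / (t1[ex] - t0[ex])
    out[ex] <- t0[ex] - log(1 - 2 * N0[ex] * beta * dtau[ex]) / beta
  }
  out
}

# Fast path: single population, no events.  Coalescence times are drawn in
# rescaled time (level k lasts Exp(k(k-1)/2)), mapped back to generations
# through the inverse intensity; the exchangeable topology is sampled
# independently of the times.
sim_genealogies_single <- function(demog, n, n_reps, seed) {
  set.seed(seed)
  ci <- coalescent_intensity(demog)
  lev <- n:2
  lam <- lev * (lev - 1) / 2
  taus <- matrix(stats::rexp((n - 1L) * n_reps) / lam, n - 1L, n_reps)
  ctau <- apply(taus, 2L, cumsum)
  if (n == 2L) ctau <- matrix(ctau, 1L, n_reps)
  tt <- matrix(invert_intensity(ci, as.vector(ctau)), n - 1L, n_reps)
  dur <- rbind(tt[1L, , drop = FALSE], apply(tt, 2L, diff))
  if (n == 2L) dur <- tt
  s1 <- numeric(n - 1L)
  s2 <- numeric(n - 1L)
  tmrca1 <- 0; tmrca2 <- 0
  nb <- n - 1L
  for (r in seq_len(n_reps)) {
    desc <- rep(1L, n)
    acc <- numeric(nb)
    k <- n
    for (j in seq_len(n - 1L)) {
      acc <- acc + tabulate(desc[seq_len(k)], nbins = nb) * dur[j, r]
      pair <- sample.int(k, 2L)
      desc[pair[1L]] <- desc[pair[1L]] + desc[pair[2L]]
      desc[pair[2L]] <- desc[k]
      k <- k - 1L
    }
    s1 <- s1 + acc
    s2 <- s2 + acc * acc
    tm <- tt[n - 1L, r]
    tmrca1 <- tmrca1 + tm
    tmrca2 <- tmrca2 + tm * tm
  }
  res <- list(mean = s1 / n_reps,
              se = sqrt(pmax(s2 / n_reps - (s1 / n_reps)^2, 0) / n_reps),
              n = n, n_reps = n_reps,
              tmrca_mean = tmrca1 / n_reps,
              tmrca_se = sqrt(max(tmrca2 / n_reps - (tmrca1 / n_reps)^2, 0) /
                              n_reps))
  res
}

# Draw the waiting time to the next coalescence in one population from the
# current time, given the epoch's size profile; Inf if the drawn hazard is
# not reached within the epoch.
draw_coal_time <- function(k, e, pop, t_now) {
  if (k < 2L) return(Inf)
  ck <- k * (k - 1) / 2
  E <- stats::rexp(1)
  N0 <- e$size[[pop]]
  if (epoch_is_constant(e)) return(t_now + E * 2 * N0 / ck)
  beta <- log(e$end_size[[pop]] / N0) / (e$t_end - e$t_start)
  rhs <- exp(-beta * (t_now - e$t_start)) - 2 * N0 * beta * E / ck
  if (rhs <= 0) return(Inf)
  e$t_start - log(rhs) / beta
}

# Structured path: event-driven backward simulation for one replicate.
# `samples` is a named integer vector over focal populations; `acc` is a list
# of per-class accumulators updated in place via the returned value.
sim_genealogy_structured <- function(demog, samples) {
  pops_all <- populations(demog)
  focal <- names(samples)
  n_tot <- sum(samples)
  pop_of <- rep(match(focal, pops_all), samples)
  desc <- matrix(0L, n_tot, length(focal),
                 dimnames = list(NULL, focal))
  ix <- 0L
  for (f in seq_along(focal)) {
    desc[ix + seq_len(samples[f]), f] <- 1L
    ix <- ix + samples[f]
  }
  acc <- lapply(focal, function(f)
    numeric(max(samples[[f]] - 1L, 1L)))
  names(acc) <- focal
  ev_times <- vapply(demog$events, `[[`, numeric(1), "time")
  ev_ord <- order(ev_times)
  events <- demog$events[ev_ord]
  ev_times <- ev_times[ev_ord]
  ev_ptr <- 1L
  t <- 0
  alive <- rep(TRUE, n_tot)
  n_alive <- n_tot
  tmrca <- NA_real_
  while (n_alive > 1L) {
    ei <- epoch_index(demog, t)
    e <- demog$epochs[[ei]]
    next_break <- e$t_end
    if (ev_ptr <= length(events) && ev_times[ev_ptr] < next_break &&
        ev_times[ev_ptr] >= t)
      next_break <- ev_times[ev_ptr]
    here <- epoch_pops(e)
    idx_here <- match(here, pops_all)
    kp <- vapply(idx_here, function(p) sum(alive & pop_of == p), integer(1))
    bad <- setdiff(unique(pop_of[alive]), idx_here)
    if (length(bad))
      stop("lineages stranded in population(s) absent from epoch: ",
           paste(pops_all[bad], collapse = ", "), call. = FALSE)
    # candidate migration event (constant rates within an epoch)
    mig_rate <- 0
    if (!is.null(e$migration)) {
      rates_pq <- e$migration[here, here, drop = FALSE]
      diag(rates_pq) <- 0
      out_rates <- kp * rowSums(rates_pq)
      mig_rate <- sum(out_rates)
    }
    t_mig <- if (mig_rate > 0) t + stats::rexp(1, mig_rate) else Inf
    t_coal <- vapply(seq_along(here), function(pi)
      draw_coal_time(kp[pi], e, here[pi], t), numeric(1))
    t_next <- min(t_mig, t_coal, next_break)
    if (!is.finite(t_next))
      stop("remaining lineages can never coalesce under this demography ",
           "(isolated populations with no migration or merger)",
           call. = FALSE)
    dt <- t_next - t
    if (dt > 0) {
      for (f in focal) {
        nf <- samples[[f]]
        if (nf < 2L) next
        d <- desc[alive, f]
        d <- d[d >= 1L & d <= nf - 1L]
        if (length(d))
          acc[[f]] <- acc[[f]] + tabulate(d, nbins = nf - 1L) * dt
      }
    }
    t <- t_next
    if (t_next == next_break) {
      while (ev_ptr <= length(events) && ev_times[ev_ptr] <= t + 1e-12 &&
             ev_times[ev_ptr] >= next_break - 1e-12) {
        ev <- events[[ev_ptr]]
        if (ev$type == "split") {
          from <- match(ev$derived, pops_all)
          to <- match(ev$ancestral, pops_all)
          pop_of[alive & pop_of == from] <- to
        } else {
          from <- match(ev$dest, pops_all)
          to <- match(ev$source, pops_all)
          sel <- which(alive & pop_of == from)
          if (length(sel)) {
            mv <- sel[stats::runif(length(sel)) < ev$fraction]
            pop_of[mv] <- to
          }
        }
        ev_ptr <- ev_ptr + 1L
      }
      next
    }
    if (t_next == t_mig) {
      # choose (p, q) proportional to k_p * m[p, q], then a uniform lineage
      w <- kp * rates_pq
      pick <- sample.int(length(w), 1L, prob = as.vector(w))
      p_i <- (pick - 1L) %% length(here) + 1L
      q_i <- (pick - 1L) %/% length(here) + 1L
      cand <- which(alive & pop_of == idx_here[p_i])
      lin <- cand[sample.int(length(cand), 1L)]
      pop_of[lin] <- idx_here[q_i]
      next
    }
    # coalescence in the population whose candidate time fired
    pi <- which.min(t_coal)
    cand <- which(alive & pop_of == idx_here[pi])
    pair <- cand[sample.int(length(cand), 2L)]
    desc[pair[1L], ] <- desc[pair[1L], ] + desc[pair[2L], ]
    alive[pair[2L]] <- FALSE
    n_alive <- n_alive - 1L
    if (n_alive == 1L) tmrca <- t
  }
  list(acc = acc, tmrca = tmrca)
}

#' Simulate unlinked genealogies and accumulate subtending branch lengths
#'
#' Runs `n_reps` independent genealogies under `demog` and records, for each
#' focal population, the mean total branch length subtending each number of
#' sampled chromosomes (the branch-length SFS in generations).  Supports
#' splits, migration, pulse admixture, and constant or exponential epochs;
#' identical seeds give identical output.
#'
#' @param demog A [piecewise_demography()].
#' @param samples_per_pop Named integer vector: chromosomes sampled per
#'   population (a bare integer is allowed for single-population models).
#' @param n_reps Number of genealogies (>= 1).
#' @param seed Master seed (integer).
#' @return List with one element per focal population: `mean` and `se`
#'   vectors over classes `1..n_p - 1` (generations), plus `tmrca_mean`,
#'   `tmrca_se`, `n`, and `n_reps`.
#' @export
simulate_genealogies <- function(demog, samples_per_pop, n_reps,
                                 seed = 1L) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (is.null(names(samples_per_pop))) {
    labs <- populations(demog)
    if (length(samples_per_pop) == 1L && length(labs) >= 1L &&
        is_single_pop(demog)) {
      names(samples_per_pop) <- labs[1L]
    } else stop("samples_per_pop must be named by population", call. = FALSE)
  }
  pres <- epoch_pops(demog$epochs[[1L]])
  unknown <- setdiff(names(samples_per_pop), pres)
  if (length(unknown))
    stop("unknown or non-extant population(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  samples_per_pop <- vapply(samples_per_pop, as.integer, integer(1))
  if (is_single_pop(demog) && length(samples_per_pop) == 1L) {
    r <- sim_genealogies_single(demog, samples_per_pop[[1L]], n_reps, seed)
    out <- list(r)
    names(out) <- names(samples_per_pop)
    return(structure(out, class = "genealogy_sfs", n_reps = n_reps))
  }
  focal <- names(samples_per_pop)
  s1 <- lapply(focal, function(f) numeric(max(samples_per_pop[[f]] - 1L, 1L)))
  s2 <- s1
  names(s1) <- names(s2) <- focal
  tm1 <- 0; tm2 <- 0
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, r))
    g <- sim_genealogy_structured(demog, samples_per_pop)
    for (f in focal) {
      s1[[f]] <- s1[[f]] + g$acc[[f]]
      s2[[f]] <- s2[[f]] + g$acc[[f]]^2
    }
    tm1 <- tm1 + g$tmrca
    tm2 <- tm2 + g$tmrca^2
  }
  out <- lapply(focal, function(f) {
    m <- s1[[f]] / n_reps
    list(mean = m,
         se = sqrt(pmax(s2[[f]] / n_reps - m^2, 0) / n_reps),
         n = samples_per_pop[[f]], n_reps = n_reps,
         tmrca_mean = tm1 / n_reps,
         tmrca_se = sqrt(max(tm2 / n_reps - (tm1 / n_reps)^2, 0) / n_reps))
  })
  names(out) <- focal
  structure(out, class = "genealogy_sfs", n_reps = n_reps)
}

#' Monte Carlo expected SFS under an arbitrary piecewise demography
#'
#' Estimates the per-population marginal expected SFS as the mean subtending
#' branch length per frequency class times the mutation rate, with per-bin
#' Monte Carlo standard errors.  This is the engine of record for
#' multi-population models with migration; for single-population histories
#' it agrees with [expected_sfs_analytic()] within Monte Carlo error.
#'
#' @inheritParams simulate_genealogies
#' @return A single `"persite"` [sfs_spectrum()] when one population is
#'   sampled, otherwise a named list of spectra.
#' @export
expected_sfs_montecarlo <- function(demog, samples_per_pop, n_reps = 2e5,
                                    seed = 1L) {
  g <- simulate_genealogies(demog, samples_per_pop, n_reps, seed)
  mu <- demog$mutation_rate
  out <- lapply(g, function(r)
    sfs_spectrum(mu * r$mean, r$n, "persite", folded = FALSE,
                 se = mu * r$se))
  if (length(out) == 1L) out[[1L]] else out
}

#' Add a pulse-admixture event to a demography
#'
#' Returns a new demography with an instantaneous admixture pulse appended:
#' at `t` (backwards in time) each lineage of `dest_pop` traces to
#' `source_pop` with probability `f`.  The input is not modified.
#'
#' @param demog A [piecewise_demography()].
#' @param t Pulse time in generations before present.
#' @param source_pop Donor population.
#' @param dest_pop Recipient population.
#' @param f Admixture fraction in `[0, 1]`.
#' @return The augmented demography.
#' @export
add_pulse_admixture <- function(demog, t, source_pop, dest_pop, f) {
  if (!is.numeric(f) || f < 0 || f > 1)
    stop("admixture fraction f must lie in [0, 1]", call. = FALSE)
  demog$events <- c(demog$events,
                    list(pulse_event(t, source = source_pop,
                                     dest = dest_pop, fraction = f)))
  validate_demography(demog)
  demog
}
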