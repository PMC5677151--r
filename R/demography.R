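# Piecewise demographic histories: epochs of constant (or exponential) sizes
# on contiguous time intervals, optionally with splits, migration, and pulse
# admixture.  Time runs in generations before present, increasing into the
# past; sizes count diploid individuals.

#' Construct an epoch of a piecewise demography
#'
#' An epoch is a half-open time interval `[t_start, t_end)` (generations
#' before present) during which each extant population has either a constant
#' diploid size or a size interpolated exponentially between the value at
#' `t_start` and the value at `t_end`.
#'
#' @param t_start Recent edge of the epoch, in generations before present
#'   (>= 0).
#' @param t_end Old edge of the epoch (> `t_start`); `Inf` for the oldest
#'   epoch.
#' @param size Named numeric vector of diploid population sizes at `t_start`;
#'   names are population labels.  A bare unnamed scalar is taken as a single
#'   population labelled `"pop1"`.
#' @param end_size Optional named numeric vector of sizes at `t_end`.  When
#'   supplied (and different from `size`) the size changes exponentially
#'   within the epoch; `NULL` means constant size.  Not allowed for an
#'   unbounded epoch.
#' @param migration Optional square matrix of per-generation migration
#'   fractions with populations as dimnames: `migration[p, q]` is the
#'   probability per generation that a lineage currently in `p` traces its
#'   ancestry (backwards in time) to `q`.  Entries in `[0, 1]`, diagonal
#'   ignored.
#' @return An object of class `"epoch"`.
#' @export
epoch <- function(t_start, t_end, size, end_size = NULL, migration = NULL) {
  if (is.null(names(size))) {
    if (length(size) != 1L)
      stop("multi-population `size` must be named", call. = FALSE)
    names(size) <- "pop1"
  }
  if (!is.null(end_size) && is.null(names(end_size)))
    names(end_size) <- names(size)
  e <- structure(
    list(t_start = as.numeric(t_start), t_end = as.numeric(t_end),
         size = size, end_size = end_size, migration = migration),
    class = "epoch")
  validate_epoch(e)
  e
}

validate_epoch <- function(e) {
  if (e$t_start < 0) stop("epoch t_start must be >= 0", call. = FALSE)
  if (!(e$t_start < e$t_end)) stop("epoch requires t_start < t_end", call. = FALSE)
  if (any(!is.finite(e$size)) || any(e$size <= 0))
    stop("population sizes must be strictly positive and finite", call. = FALSE)
  if (!is.null(e$end_size)) {
    if (!is.finite(e$t_end))
      stop("an unbounded epoch cannot have exponential size change", call. = FALSE)
    if (!setequal(names(e$end_size), names(e$size)))
      stop("end_size labels must match size labels", call. = FALSE)
    if (any(e$end_size <= 0))
      stop("population sizes must be strictly positive", call. = FALSE)
  }
  if (!is.null(e$migration)) {
    m <- e$migration
    if (!is.matrix(m) || nrow(m) != ncol(m))
      stop("migration must be a square matrix", call. = FALSE)
    if (is.null(rownames(m)) || !setequal(rownames(m), names(e$size)))
      stop("migration dimnames must match population labels", call. = FALSE)
    if (any(m < 0) || any(m > 1))
      stop("migration entries must lie in [0, 1]", call. = FALSE)
  }
  invisible(e)
}

epoch_pops <- function(e) names(e$size)

#' Is the size constant within this epoch?
#' @noRd
epoch_is_constant <- function(e) {
  is.null(e$end_size) || isTRUE(all(e$end_size[names(e$size)] == e$size))
}

#' Construct a piecewise demographic history
#'
#' Epochs are listed from the present backwards and must tile `[0, Inf)`
#' contiguously.  Demographic events (population splits and pulse
#' admixtures) are instantaneous and interpreted backwards in time: at a
#' split, all lineages of the derived population move into the ancestral
#' population; at a pulse, each lineage of the recipient population moves to
#' the donor with probability `fraction`.
#'
#' @param epochs List of [epoch()] objects ordered from present to past.
#' @param events List of events created with [split_event()] or
#'   [pulse_event()].
#' @param mutation_rate Mutations per base pair per generation.
#' @param generation_time Years per generation (used only at input/output
#'   boundaries; all internal times are generations).
#' @param name Optional model label used in reports.
#' @return An object of class `"piecewise_demography"`.
#' @export
piecewise_demography <- function(epochs, events = list(),
                                 mutation_rate = 1.25e-8,
                                 generation_time = 25, name = NULL) {
  if (inherits(epochs, "epoch")) epochs <- list(epochs)
  if (length(epochs) < 1L) stop("at least one epoch is required", call. = FALSE)
  d <- structure(
    list(epochs = epochs, events = events,
         mutation_rate = as.numeric(mutation_rate),
         generation_time = as.numeric(generation_time),
         name = name),
    class = "piecewise_demography")
  validate_demography(d)
  d
}

validate_demography <- function(d) {
  eps <- d$epochs
  for (e in eps) validate_epoch(e)
  if (eps[[1L]]$t_start != 0)
    stop("first epoch must start at t = 0", call. = FALSE)
  K <- length(eps)
  if (is.finite(eps[[K]]$t_end))
    stop("oldest epoch must be unbounded (t_end = Inf)", call. = FALSE)
  if (K > 1L) {
    for (i in seq_len(K - 1L)) {
      if (is.infinite(eps[[i]]$t_end))
        stop("only the oldest epoch may be unbounded", call. = FALSE)
      if (eps[[i]]$t_end != eps[[i + 1L]]$t_start)
        stop("epochs must be contiguous and non-overlapping", call. = FALSE)
    }
  }
  if (d$mutation_rate <= 0) stop("mutation_rate must be > 0", call. = FALSE)
  if (d$generation_time <= 0) stop("generation_time must be > 0", call. = FALSE)
  for (ev in d$events) {
    if (!ev$type %in% c("split", "pulse"))
      stop("unknown event type: ", ev$type, call. = FALSE)
    if (ev$time < 0 || !is.finite(ev$time))
      stop("event time must be finite and >= 0", call. = FALSE)
    ei <- epoch_index(d, ev$time)
    have <- epoch_pops(d$epochs[[ei]])
    # an event at an epoch boundary acts on the lineages leaving the
    # younger epoch, so its populations may come from either side
    if (ei > 1L && d$epochs[[ei]]$t_start == ev$time)
      have <- union(have, epoch_pops(d$epochs[[ei - 1L]]))
    pops_needed <- if (ev$type == "split") c(ev$derived, ev$ancestral)
                   else c(ev$source, ev$dest)
    missing <- setdiff(pops_needed, have)
    if (length(missing))
      stop("event references population(s) absent from the epoch at its time: ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (ev$type == "pulse" && (ev$fraction < 0 || ev$fraction > 1))
      stop("pulse fraction must lie in [0, 1]", call. = FALSE)
  }
  invisible(d)
}

#' @rdname piecewise_demography
#' @param time Event time in generations before present.
#' @param derived,ancestral Population labels: backwards in time, lineages of
#'   `derived` move into `ancestral` at `time`.
#' @export
split_event <- function(time, derived, ancestral) {
  list(type = "split", time = as.numeric(time),
       derived = derived, ancestral = ancestral)
}

#' @rdname piecewise_demography
#' @param source Donor population of the admixture pulse.
#' @param dest Recipient population (its lineages trace to `source` with
#'   probability `fraction`, backwards in time).
#' @param fraction Admixture fraction in `[0, 1]`.
#' @export
pulse_event <- function(time, source, dest, fraction) {
  list(type = "pulse", time = as.numeric(time),
       source = source, dest = dest, fraction = as.numeric(fraction))
}

#' Index of the epoch containing time t
#'
#' Every `t >= 0` lies in exactly one epoch (`[t_start, t_end)` half-open).
#' @param demog A [piecewise_demography()].
#' @param t Time(s) in generations before present.
#' @return Integer vector of epoch indices.
#' @export
epoch_index <- function(demog, t) {
  bounds <- vapply(demog$epochs, function(e) e$t_start, numeric(1))
  idx <- findInterval(t, bounds)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  idx
}

#' Population size at time t
#'
#' @param demog A [piecewise_demography()].
#' @param t Numeric vector of times (generations before present).
#' @param pop Population label; may be omitted for single-population models.
#' @return Diploid size(s) at `t` (exponential interpolation within growth
#'   epochs).
#' @export
size_at <- function(demog, t, pop = NULL) {
  if (is.null(pop)) {
    labs <- epoch_pops(demog$epochs[[1L]])
    if (length(labs) != 1L)
      stop("`pop` must be given for multi-population demographies", call. = FALSE)
    pop <- labs
  }
  idx <- epoch_index(demog, t)
  vapply(seq_along(t), function(i) {
    e <- demog$epochs[[idx[i]]]
    if (!pop %in% epoch_pops(e))
      stop("population ", pop, " does not exist at t = ", t[i], call. = FALSE)
    N0 <- e$size[[pop]]
    if (epoch_is_constant(e)) return(N0)
    N1 <- e$end_size[[pop]]
    N0 * (N1 / N0)^((t[i] - e$t_start) / (e$t_end - e$t_start))
  }, numeric(1))
}

#' All population labels of a demography (union over epochs)
#' @param demog A [piecewise_demography()].
#' @export
populations <- function(demog) {
  unique(unlist(lapply(demog$epochs, epoch_pops)))
}

#' Is this a single-population history with no events?
#' @param demog A [piecewise_demography()].
#' @export
is_single_pop <- function(demog) {
  length(populations(demog)) == 1L && length(demog$events) == 0L
}

#' @export
print.piecewise_demography <- function(x, ...) {
  cat("Piecewise demography", if (!is.null(x$name)) paste0("'", x$name, "'"),
      "\n  populations:", paste(populations(x), collapse = ", "),
      "\n  mutation rate:", format(x$mutation_rate),
      "/bp/gen; generation time:", x$generation_time, "yr\n")
  for (e in x$epochs) {
    sz <- paste(sprintf("%s=%s", names(e$size), signif(e$size, 5)),
                collapse = ", ")
    grow <- if (!epoch_is_constant(e)) " (exponential)" else ""
    cat(sprintf("  [%s, %s) gen: %s%s\n", format(e$t_start), format(e$t_end),
                sz, grow))
  }
  if (length(x$events))
    for (ev in x$events)
      cat("  event:", ev$type, "at", ev$time, "gen\n")
  invisible(x)
}

#' Convenience constructor: constant-size single population
#' @param N Diploid size.
#' @inheritParams piecewise_demography
#' @export
constant_demography <- function(N, mutation_rate = 1.25e-8,
                                generation_time = 25, name = NULL) {
  piecewise_demography(list(epoch(0, Inf, c(pop1 = N))),
                       mutation_rate = mutation_rate,
                       generation_time = generation_time, name = name)
}

# ---------------------------------------------------------------------------
# Single-population step representation used by the SFS engine and the
# simulator fast path.

#' Steps of a single-population demography
#'
#' @param demog A single-population [piecewise_demography()].
#' @return Data frame with columns `t0`, `t1`, `N0`, `N1` (sizes at the two
#'   edges; `N0 == N1` for constant epochs).
#' @noRd
demography_steps <- function(demog) {
  labs <- populations(demog)
  if (length(labs) != 1L)
    stop("single-population demography required", call. = FALSE)
  p <- labs
  do.call(rbind, lapply(demog$epochs, function(e) {
    data.frame(t0 = e$t_start, t1 = e$t_end, N0 = e$size[[p]],
               N1 = if (epoch_is_constant(e)) e$size[[p]] else e$end_size[[p]])
  }))
}

# ---------------------------------------------------------------------------
# SizeTrajectory: raw single-population (time, size) step function, the form
# in which coalescent-HMM output (MSMC/PSMC-style) arrives.

#' Construct a single-population size trajectory (step function)
#'
#' @param t_left,t_right Step boundaries in generations before present;
#'   contiguous, last `t_right` must be `Inf`.
#' @param N Diploid size on each step (> 0).
#' @param units Provenance tag: `"physical"` (generations/diploids) or
#'   `"scaled"`.
#' @return Object of class `"size_trajectory"`, a data frame with attributes.
#' @export
size_trajectory <- function(t_left, t_right, N, units = c("physical", "scaled")) {
  units <- match.arg(units)
  if (length(t_left) != length(t_right) || length(t_left) != length(N))
    stop("t_left, t_right, N must have equal length", call. = FALSE)
  if (any(N <= 0)) stop("trajectory sizes must be > 0", call. = FALSE)
  if (t_left[1L] != 0) stop("trajectory must start at t = 0", call. = FALSE)
  if (is.finite(t_right[length(t_right)]))
    stop("last step must be unbounded (t_right = Inf)", call. = FALSE)
  if (length(t_left) > 1L &&
      any(t_right[-length(t_right)] != t_left[-1L]))
    stop("trajectory steps must be contiguous", call. = FALSE)
  structure(data.frame(t_left = t_left, t_right = t_right, N = N),
            class = c("size_trajectory", "data.frame"), units = units)
}

#' Evaluate a step trajectory at times t (left-hold interpolation)
#' @noRd
trajectory_at <- function(traj, t) {
  idx <- findInterval(t, traj$t_left)
  traj$N[pmax(idx, 1L)]
}

#' Parse MSMC-style scaled output into a physical-units size trajectory
#'
#' Coalescent-HMM output tables give per-interval scaled times and a scaled
#' coalescence rate `lambda`.  The standard conversion to physical units is
#' `t_generations = scaled_time / mu` and `N = 1 / (2 * mu * lambda)` diploid
#' individuals.
#'
#' @param table Data frame (or path to a whitespace-delimited file) with
#'   columns `index` (ignored), `left_time_boundary`, `right_time_boundary`,
#'   `lambda` (column names or the standard 4-column order).
#' @param mu Mutation rate per bp per generation used for the scaling.
#' @param generation_time Years per generation attached to the result for
#'   later conversion to calendar time.
#' @return A [size_trajectory()] in physical units with attributes `mu` and
#'   `generation_time`.
#' @export
parse_msmc_output <- function(table, mu, generation_time = 30) {
  if (is.character(table)) {
    table <- utils::read.table(table, header = TRUE, comment.char = "#")
  }
  if (!all(c("left_time_boundary", "right_time_boundary", "lambda") %in%
           names(table))) {
    if (ncol(table) < 4L)
      stop("MSMC table must have 4 columns", call. = FALSE)
    names(table)[1:4] <- c("index", "left_time_boundary",
                           "right_time_boundary", "lambda")
  }
  if (mu <= 0) stop("mu must be > 0", call. = FALSE)
  if (any(table$lambda <= 0))
    stop("lambda entries must be > 0", call. = FALSE)
  if (is.unsorted(table$left_time_boundary) ||
      any(table$right_time_boundary < table$left_time_boundary))
    stop("time boundaries must be nondecreasing", call. = FALSE)
  t_left <- table$left_time_boundary / mu
  t_right <- table$right_time_boundary / mu
  t_right[length(t_right)] <- Inf
  N <- 1 / (2 * mu * table$lambda)
  traj <- size_trajectory(t_left, t_right, N, units = "physical")
  attr(traj, "mu") <- mu
  attr(traj, "generation_time") <- generation_time
  if (traj$N[nrow(traj)] > 1e6)
    warning("oldest trajectory size exceeds 1e6 diploids; ",
            "check the scaling mutation rate", call. = FALSE)
  traj
}

#' Emit a scaled MSMC-style table from a physical-units trajectory
#'
#' Inverse of [parse_msmc_output()]; used to round-trip synthetic histories.
#'
#' @param traj A [size_trajectory()] in physical units.
#' @param mu Mutation rate per bp per generation.
#' @return Data frame with the standard 4 columns.
#' @export
as_msmc_table <- function(traj, mu) {
  if (mu <= 0) stop("mu must be > 0", call. = FALSE)
  right <- traj$t_right * mu
  right[length(right)] <- traj$t_left[length(right)] * mu * 4 # finite sentinel
  data.frame(index = seq_len(nrow(traj)) - 1L,
             left_time_boundary = traj$t_left * mu,
             right_time_boundary = right,
             lambda = 1 / (2 * mu * traj$N))
}

#' Convert a trajectory (step function or continuous) to a stepwise demography
#'
#' Already-stepwise inputs pass through unchanged (each step becomes a
#' constant epoch).  A continuous trajectory, given as a function of time in
#' generations, is discretized on a geometric time grid; each grid interval
#' takes the trajectory value at its geometric midpoint.
#'
#' @param x A [size_trajectory()] or a vectorized function `N(t)`.
#' @param n_steps Number of steps for function input (>= 1).
#' @param t_min,t_max Grid range (generations) for function input.  The
#'   interval `[0, t_min)` holds `N(0)`; `[t_max, Inf)` holds `N(t_max)`.
#' @param mutation_rate,generation_time Passed to the resulting demography
#'   (trajectory attributes take precedence when present).
#' @return A single-population [piecewise_demography()].
#' @export
trajectory_to_stepwise <- function(x, n_steps = 64, t_min = 10, t_max = 1e6,
                                   mutation_rate = 1.25e-8,
                                   generation_time = 30) {
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  if (inherits(x, "size_trajectory")) {
    mu <- attr(x, "mu") %||% mutation_rate
    gt <- attr(x, "generation_time") %||% generation_time
    eps <- lapply(seq_len(nrow(x)), function(i)
      epoch(x$t_left[i], x$t_right[i], c(pop1 = x$N[i])))
    return(piecewise_demography(eps, mutation_rate = mu,
                                generation_time = gt))
  }
  if (!is.function(x))
    stop("x must be a size_trajectory or a function N(t)", call. = FALSE)
  grid <- exp(seq(log(t_min), log(t_max), length.out = n_steps + 1L))
  lefts <- c(0, grid)
  rights <- c(grid, Inf)
  mids <- c(t_min / 2, sqrt(grid[-length(grid)] * grid[-1L]), t_max)
  # value on [0, t_min) is N at its midpoint; final epoch holds N(t_max)
  N <- vapply(mids, x, numeric(1))
  if (any(N <= 0)) stop("trajectory function returned nonpositive size",
                        call. = FALSE)
  eps <- lapply(seq_along(lefts), function(i)
    epoch(lefts[i], rights[i], c(pop1 = N[i])))
  piecewise_demography(eps, mutation_rate = mutation_rate,
                       generation_time = generation_time)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average several size trajectories on a common grid
#'
#' Replicate trajectories (e.g. independent coalescent-HMM runs) are
#' combined by the pointwise mean of sizes evaluated with left-hold step
#' interpolation on a geometric time grid.  The mean is arithmetic in
#' natural size by default; a log-scale (geometric) mean is available.
#'
#' @param trajectories List of [size_trajectory()] objects.
#' @param grid Optional increasing vector of grid times (generations,
#'   first entry 0).  Default: 0 plus a 64-point geometric grid spanning the
#'   finite step boundaries of the inputs.
#' @param scale `"natural"` (arithmetic mean, default) or `"log"`
#'   (geometric mean).
#' @return A [size_trajectory()] on the grid.
#' @export
average_trajectories <- function(trajectories, grid = NULL,
                                 scale = c("natural", "log")) {
  scale <- match.arg(scale)
  if (length(trajectories) < 1L)
    stop("at least one trajectory is required", call. = FALSE)
  for (tr in trajectories)
    if (!inherits(tr, "size_trajectory"))
      stop("inputs must be size_trajectory objects", call. = FALSE)
  if (is.null(grid)) {
    fin <- unlist(lapply(trajectories, function(tr)
      tr$t_left[tr$t_left > 0]))
    fin2 <- unlist(lapply(trajectories, function(tr)
      tr$t_right[is.finite(tr$t_right)]))
    lo <- min(c(fin, fin2, 10))
    hi <- max(c(fin, fin2, lo * 10))
    grid <- c(0, exp(seq(log(lo), log(hi), length.out = 64)))
  }
  if (grid[1L] != 0) grid <- c(0, grid)
  vals <- vapply(trajectories, function(tr) trajectory_at(tr, grid),
                 numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  N <- if (scale == "natural") rowMeans(vals) else exp(rowMeans(log(vals)))
  size_trajectory(grid, c(grid[-1L], Inf), N, units = "physical")
}

#' Trim ancient events from a single-population demography
#'
#' Epochs lying entirely beyond `t_max` are removed; an epoch straddling
#' `t_max` is truncated there and the oldest retained epoch is extended to
#' infinity at its own size.  If `t_max` is beyond every finite boundary the
#' input is returned unchanged.
#'
#' @param demog A single-population [piecewise_demography()].
#' @param t_max Cutoff, by default in generations.
#' @param units `"generations"` or `"years"` (converted with the model's
#'   generation time).
#' @return The trimmed demography.
#' @export
trim_model <- function(demog, t_max, units = c("generations", "years")) {
  units <- match.arg(units)
  if (t_max <= 0) stop("t_max must be > 0", call. = FALSE)
  if (length(populations(demog)) != 1L)
    stop("trim_model requires a single-population demography", call. = FALSE)
  if (units == "years") t_max <- t_max / demog$generation_time
  eps <- demog$epochs
  # cutoff at/inside the unbounded epoch: nothing to trim
  if (t_max >= eps[[length(eps)]]$t_start) return(demog)
  keep <- Filter(function(e) e$t_start < t_max, eps)
  last <- keep[[length(keep)]]
  p <- epoch_pops(last)
  if (!epoch_is_constant(last) && is.finite(last$t_end) && last$t_end > t_max) {
    # keep the exponential profile up to t_max, then hold its value there
    n_at <- last$size[[p]] *
      (last$end_size[[p]] / last$size[[p]])^((t_max - last$t_start) /
                                             (last$t_end - last$t_start))
    keep[[length(keep)]] <- epoch(last$t_start, t_max, last$size,
                                  end_size = stats::setNames(n_at, p),
                                  migration = last$migration)
    keep[[length(keep) + 1L]] <- epoch(t_max, Inf, stats::setNames(n_at, p))
  } else {
    keep[[length(keep)]] <- epoch(last$t_start, Inf, last$size,
                                  migration = last$migration)
  }
  piecewise_demography(keep, events = list(),
                       mutation_rate = demog$mutation_rate,
                       generation_time = demog$generation_time,
                       name = demog$name)
}

#' Replace the ancestral (oldest-epoch) population size
#'
#' @param demog A [piecewise_demography()].
#' @param N_A New diploid size for every population of the unbounded oldest
#'   epoch; all other epochs are untouched.
#' @return The adjusted demography.
#' @export
set_ancestral_size <- function(demog, N_A) {
  if (!is.numeric(N_A) || length(N_A) != 1L || N_A <= 0)
    stop("N_A must be a positive scalar", call. = FALSE)
  K <- length(demog$epochs)
  old <- demog$epochs[[K]]
  demog$epochs[[K]] <- epoch(old$t_start, old$t_end,
                             stats::setNames(rep(N_A, length(old$size)),
                                             names(old$size)),
                             migration = old$migration)
  validate_demography(demog)
  demog
}

#' Rescale a demography to a different mutation rate
#'
#' Coalescent-HMM histories are reported in units fixed by the mutation rate
#' used for scaling; re-expressing the same data under `mu_new` multiplies
#' every size and every time by `mu_old / mu_new`, leaving the per-site
#' population-scaled mutation rate (4 N mu) of every epoch invariant.
#'
#' @param demog A [piecewise_demography()].
#' @param mu_new New mutation rate (> 0).
#' @return The rescaled demography with `mutation_rate = mu_new`.
#' @export
rescale_mutation_rate <- function(demog, mu_new) {
  if (!is.numeric(mu_new) || length(mu_new) != 1L || mu_new <= 0)
    stop("mu_new must be a positive scalar", call. = FALSE)
  f <- demog$mutation_rate / mu_new
  demog$epochs <- lapply(demog$epochs, function(e) {
    epoch(e$t_start * f, e$t_end * f, e$size * f,
          end_size = if (is.null(e$end_size)) NULL else e$end_size * f,
          migration = e$migration)
  })
  demog$events <- lapply(demog$events, function(ev) {
    ev$time <- ev$time * f
    ev
  })
  demog$mutation_rate <- mu_new
  validate_demography(demog)
  demog
}
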