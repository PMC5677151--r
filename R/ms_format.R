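# Emission and parsing of demographies as ms-style command fragments.
# Conventions: times in units of 4*N0 generations, sizes relative to N0,
# migration entries as 4*N0*m.  Pulse admixture uses the standard
# `-es t dest p` + `-ej t <new> source` pairing with p = 1 - fraction.

#' Emit a demography as an ms-style command fragment
#'
#' Only constant-size epochs are supported (discretize exponential epochs
#' with [trajectory_to_stepwise()] first).  The fragment contains the
#' demography flags only (`-I/-n/-ma/-en/-ema/-ej/-es`); sample counts in
#' `-I` are taken from `samples` (zeros when omitted).
#'
#' @param demog A [piecewise_demography()] with constant-size epochs.
#' @param N0 Reference diploid size; defaults to the first population's size
#'   at t = 0.
#' @param samples Optional named integer vector of sample counts per
#'   population for the `-I` flag.
#' @return A single string; empty for a constant-size single population.
#' @export
to_ms_command <- function(demog, N0 = NULL, samples = NULL) {
  for (e in demog$epochs)
    if (!epoch_is_constant(e))
      stop("unsupported feature: exponential-growth epochs cannot be ",
           "emitted as ms flags; discretize with trajectory_to_stepwise()",
           call. = FALSE)
  pops <- populations(demog)
  npop <- length(pops)
  if (is.null(N0)) N0 <- demog$epochs[[1L]]$size[[1L]]
  fmt <- function(x) sprintf("%.17g", x)
  has_mig <- any(vapply(demog$epochs, function(e)
    !is.null(e$migration) && any(e$migration > 0), logical(1)))
  flags <- character(0)
  mig_mat <- function(e) {
    m <- matrix(0, npop, npop, dimnames = list(pops, pops))
    if (!is.null(e$migration)) {
      p <- rownames(e$migration)
      m[p, p] <- e$migration * 4 * N0
    }
    m
  }
  mig_entries <- function(m) {
    out <- character(0)
    for (i in seq_len(npop)) for (j in seq_len(npop))
      out <- c(out, if (i == j) "x" else fmt(m[i, j]))
    out
  }
  if (npop > 1L) {
    cnt <- rep(0L, npop)
    if (!is.null(samples)) cnt[match(names(samples), pops)] <- samples
    flags <- c(flags, "-I", npop, cnt)
    if (has_mig)
      flags <- c(flags, "-ma", mig_entries(mig_mat(demog$epochs[[1L]])))
  }
  e1 <- demog$epochs[[1L]]
  for (p in epoch_pops(e1)) {
    # a lone population at the reference size needs no flag at all
    if (npop == 1L && e1$size[[p]] == N0) next
    flags <- c(flags, "-n", match(p, pops), fmt(e1$size[[p]] / N0))
  }
  for (e in demog$epochs[-1L]) {
    tm <- fmt(e$t_start / (4 * N0))
    for (p in epoch_pops(e))
      flags <- c(flags, "-en", tm, match(p, pops), fmt(e$size[[p]] / N0))
    if (npop > 1L && has_mig)
      flags <- c(flags, "-ema", tm, npop, mig_entries(mig_mat(e)))
  }
  evs <- demog$events
  if (length(evs)) {
    evs <- evs[order(vapply(evs, `[[`, numeric(1), "time"))]
    extra <- npop
    for (ev in evs) {
      tm <- fmt(ev$time / (4 * N0))
      if (ev$type == "split") {
        flags <- c(flags, "-ej", tm, match(ev$derived, pops),
                   match(ev$ancestral, pops))
      } else {
        extra <- extra + 1L
        flags <- c(flags, "-es", tm, match(ev$dest, pops),
                   fmt(1 - ev$fraction),
                   "-ej", tm, extra, match(ev$source, pops))
      }
    }
  }
  paste(flags, collapse = " ")
}

#' Parse an ms-style command fragment back into a demography
#'
#' Inverse of [to_ms_command()]; handles the dialect that function emits
#' (`-I/-n/-ma/-en/-ema/-ej` and `-es` immediately followed by the matching
#' `-ej` that sends the new population to the admixture donor).
#'
#' @param cmd Command fragment string.
#' @param N0 Reference diploid size used for the scaling.
#' @param mutation_rate,generation_time Attached to the result.
#' @param pop_labels Optional character vector naming the populations in
#'   `-I` order (defaults to `pop1`, `pop2`, ...).
#' @return A [piecewise_demography()].
#' @export
parse_ms_command <- function(cmd, N0, mutation_rate = 1.25e-8,
                             generation_time = 25, pop_labels = NULL) {
  tok <- strsplit(trimws(cmd), "\\s+")[[1L]]
  if (length(tok) == 1L && tok == "") tok <- character(0)
  npop <- 1L
  i <- 1L  # index of the next unread token
  sizes0 <- list(); mig0 <- NULL
  en <- list(); ema <- list(); ej <- list(); es <- list()
  take <- function(k) { v <- tok[i - 1L + seq_len(k)]; i <<- i + k; v }
  read_mat <- function(n) {
    ent <- take(n * n)
    m <- matrix(0, n, n)
    ind <- 1L
    for (r in seq_len(n)) for (cc in seq_len(n)) {
      if (r != cc) m[r, cc] <- as.numeric(ent[ind])
      ind <- ind + 1L
    }
    m
  }
  while (i <= length(tok)) {
    flag <- take(1L)
    switch(flag,
      "-I" = { npop <- as.integer(take(1L)); take(npop) },
      "-ma" = { mig0 <- read_mat(npop) },
      "-n" = { v <- take(2L); sizes0[[v[1L]]] <- as.numeric(v[2L]) },
      "-en" = { en[[length(en) + 1L]] <- as.numeric(take(3L)) },
      "-ema" = { tm <- as.numeric(take(1L)); take(1L)  # npop
                 ema[[length(ema) + 1L]] <- list(t = tm, m = read_mat(npop)) },
      "-ej" = { ej[[length(ej) + 1L]] <- as.numeric(take(3L)) },
      "-es" = { es[[length(es) + 1L]] <- as.numeric(take(3L)) },
      stop("unsupported ms flag: ", flag, call. = FALSE)
    )
  }
  pops <- pop_labels %||% paste0("pop", seq_len(npop))
  # resolve -es: each creates a phantom population npop+1, npop+2, ... whose
  # matching -ej names the admixture donor
  pulses <- list()
  extra <- npop
  for (s in es) {
    extra <- extra + 1L
    donor_idx <- NULL
    keep <- list()
    for (e in ej) {
      if (is.null(donor_idx) && e[2L] == extra && e[1L] == s[1L])
        donor_idx <- e[3L]
      else keep[[length(keep) + 1L]] <- e
    }
    ej <- keep
    if (is.null(donor_idx))
      stop("-es without matching -ej for the new population", call. = FALSE)
    pulses[[length(pulses) + 1L]] <-
      pulse_event(s[1L] * 4 * N0, source = pops[donor_idx],
                  dest = pops[s[2L]], fraction = 1 - s[3L])
  }
  splits <- lapply(ej, function(e)
    split_event(e[1L] * 4 * N0, derived = pops[e[2L]],
                ancestral = pops[e[3L]]))
  # epoch boundaries come from -en/-ema times
  times <- sort(unique(c(0,
    vapply(en, `[[`, numeric(1), 1L),
    vapply(ema, function(x) x$t, numeric(1)))))
  eps <- list()
  for (k in seq_along(times)) {
    tm <- times[k]
    t0 <- tm * 4 * N0
    t1 <- if (k < length(times)) times[k + 1L] * 4 * N0 else Inf
    if (tm == 0) {
      keep_pops <- if (length(sizes0)) sort(as.integer(names(sizes0)))
                   else seq_len(npop)
      sz <- vapply(keep_pops, function(p) {
        x <- sizes0[[as.character(p)]]
        if (is.null(x)) 1 else x
      }, numeric(1)) * N0
      m <- mig0
    } else {
      here <- Filter(function(x) x[1L] == tm, en)
      idx <- vapply(here, function(x) as.integer(x[2L]), integer(1))
      o <- order(idx)
      keep_pops <- idx[o]
      sz <- vapply(here, function(x) x[3L], numeric(1))[o] * N0
      m <- NULL
      for (x in ema) if (x$t == tm) m <- x$m
    }
    if (!length(keep_pops)) next
    size <- stats::setNames(sz[seq_along(keep_pops)], pops[keep_pops])
    mig <- NULL
    if (!is.null(m) && any(m > 0)) {
      mig <- m[keep_pops, keep_pops, drop = FALSE] / (4 * N0)
      dimnames(mig) <- list(pops[keep_pops], pops[keep_pops])
    }
    eps[[length(eps) + 1L]] <- epoch(t0, t1, size, migration = mig)
  }
  events <- c(splits, pulses)
  if (length(events))
    events <- events[order(vapply(events, `[[`, numeric(1), "time"))]
  piecewise_demography(eps, events = events,
                       mutation_rate = mutation_rate,
                       generation_time = generation_time)
}
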