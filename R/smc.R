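# Sequential coalescent simulation of recombining sequence blocks under the
# SMC' approximation: the genealogy at the left end of a window is drawn
# from the standard coalescent; moving rightwards, recombination breakpoints
# arrive at rate r * (total branch length), a branch is detached at a
# uniformly chosen point and re-coalesces with the remaining tree --
# re-coalescence into the detached branch's original lineage is permitted
# (the SMC' refinement, which leaves the marginal tree at every position
# distributed as the standard coalescent).  Mutations are Poisson on
# branches under the infinite-sites model.

# Internal tree representation: arrays over 2n-1 nodes (leaves 1..n).
#   parent[v], time[v]; root has parent 0.
new_tree_from_coalescent <- function(demog, n) {
  ci <- coalescent_intensity(demog)
  lev <- n:2
  lam <- lev * (lev - 1) / 2
  tau <- cumsum(stats::rexp(n - 1L) / lam)
  tms <- invert_intensity(ci, tau)
  parent <- integer(2L * n - 1L)
  time <- numeric(2L * n - 1L)
  act <- seq_len(n)
  for (j in seq_len(n - 1L)) {
    v <- n + j
    time[v] <- tms[j]
    pair <- sample.int(length(act), 2L)
    parent[act[pair]] <- v
    act <- c(act[-pair], v)
  }
  list(parent = parent, time = time, n = n)
}

tree_root <- function(tr) which(tr$parent == 0L)

tree_branch_lengths <- function(tr) {
  len <- numeric(length(tr$parent))
  nz <- tr$parent != 0L
  len[nz] <- tr$time[tr$parent[nz]] - tr$time[nz]
  len
}

# leaves subtended by each node
tree_leaf_counts <- function(tr) {
  n <- tr$n
  cnt <- c(rep(1L, n), integer(n - 1L))
  ord <- order(tr$time[(n + 1L):(2L * n - 1L)]) + n
  for (v in c(seq_len(n), ord)) {
    p <- tr$parent[v]
    if (p > 0L) cnt[p] <- cnt[p] + cnt[v]
  }
  cnt
}

tree_leaf_sets <- function(tr) {
  n <- tr$n
  sets <- vector("list", 2L * n - 1L)
  for (v in seq_len(n)) sets[[v]] <- v
  ord <- order(tr$time[(n + 1L):(2L * n - 1L)]) + n
  for (v in c(seq_len(n), ord)) {
    p <- tr$parent[v]
    if (p > 0L) sets[[p]] <- c(sets[[p]], sets[[v]])
  }
  sets
}

# One SMC' transition: detach at a uniform point on the tree, re-coalesce.
# `nfun(t)` is the diploid size at time t; epochs via the demography.
smc_prime_transition <- function(tr, demog) {
  len <- tree_branch_lengths(tr)
  tot <- sum(len)
  # choose the branch (edge above `v`) proportional to length, cut uniform
  v <- sample.int(length(len), 1L, prob = len)
  u <- stats::runif(1, tr$time[v], tr$time[tr$parent[v]])
  p <- tr$parent[v]
  sib <- setdiff(which(tr$parent == p), v)
  gp <- tr$parent[p]
  # pruned tree: splice out p
  parent2 <- tr$parent
  parent2[sib] <- gp            # 0 if p was root -> sib becomes root
  parent2[v] <- 0L              # v's lineage is the floating one
  parent2[p] <- 0L
  pruned_nodes <- setdiff(seq_along(parent2), c(v, p))
  # also drop v's whole subtree from "available" lineages: available edges
  # are those of the pruned tree; v's subtree edges are below the cut and
  # not available, but they are still part of the final tree.
  sub <- v
  repeat {
    kids <- which(tr$parent %in% sub & !(seq_along(tr$parent) %in% sub))
    if (!length(kids)) break
    sub <- c(sub, kids)
  }
  avail_nodes <- setdiff(pruned_nodes, sub)
  a_par <- parent2[avail_nodes]
  a_top <- ifelse(a_par == 0L, Inf, tr$time[pmax(a_par, 1L)])
  a_bot <- tr$time[avail_nodes]
  # re-coalesce from time u: piecewise-constant number of available
  # lineages k(t); rate k(t) / (2 N(t)).  Walk intervals defined by node
  # times and epoch boundaries.
  cuts <- sort(unique(c(a_bot[a_bot > u], a_top[is.finite(a_top) & a_top > u],
                        vapply(demog$epochs, function(e) e$t_start, numeric(1)))))
  cuts <- cuts[cuts > u]
  t_now <- u
  repeat {
    t_hi <- if (length(cuts)) cuts[1L] else Inf
    k_av <- sum(a_bot <= t_now & a_top > t_now)
    e <- demog$epochs[[epoch_index(demog, t_now)]]
    pop <- epoch_pops(e)[1L]
    if (k_av > 0) {
      E <- stats::rexp(1)
      if (epoch_is_constant(e)) {
        t_c <- t_now + E * 2 * e$size[[pop]] / k_av
      } else {
        beta <- log(e$end_size[[pop]] / e$size[[pop]]) / (e$t_end - e$t_start)
        rhs <- exp(-beta * (t_now - e$t_start)) -
          2 * e$size[[pop]] * beta * E / k_av
        t_c <- if (rhs <= 0) Inf else e$t_start - log(rhs) / beta
      }
      if (t_c <= t_hi) { t_new <- t_c; break }
    }
    if (!is.finite(t_hi))
      stop("re-coalescence failed: no available lineage", call. = FALSE)
    t_now <- t_hi
    cuts <- cuts[-1L]
  }
  # choose the target edge among those crossing t_new
  crossing <- avail_nodes[a_bot <= t_new & a_top > t_new]
  w <- crossing[sample.int(length(crossing), 1L)]
  # reuse node p as the new internal node joining v and w at t_new
  parent2[p] <- parent2[w]
  parent2[w] <- p
  parent2[v] <- p
  time2 <- tr$time
  time2[p] <- t_new
  list(parent = parent2, time = time2, n = tr$n)
}

#' Simulate one recombining sequence block under the SMC' approximation
#'
#' @param demog A single-population [piecewise_demography()];
#'   multi-population models raise an unsupported-feature error directing to
#'   [simulate_genealogies()].
#' @param n_haplotypes Number of sampled chromosomes (>= 2).
#' @param L Block length in bp (>= 1).
#' @param r Recombination rate per bp per generation (>= 0).
#' @param mu Mutation rate per bp per generation; defaults to the
#'   demography's rate.
#' @param seed Integer seed; identical seeds give identical blocks.
#' @param id Block identifier stored in the result.
#' @return A `sim_block`: list with `id`, `L`, `r`, `positions` (1-based,
#'   strictly increasing), and `haplotypes` (0/1 incidence matrix, sites x
#'   haplotypes).
#' @export
simulate_window <- function(demog, n_haplotypes, L, r, mu = NULL,
                            seed = 1L, id = 1L) {
  if (n_haplotypes < 2) stop("n_haplotypes must be >= 2", call. = FALSE)
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  if (r < 0) stop("r must be >= 0", call. = FALSE)
  mu <- mu %||% demog$mutation_rate
  if (mu < 0) stop("mu must be >= 0", call. = FALSE)
  if (!is_single_pop(demog))
    stop("unsupported feature: the sequential SMC' engine supports ",
         "single-population histories only; use simulate_genealogies() ",
         "for structured models", call. = FALSE)
  set.seed(seed)
  n <- as.integer(n_haplotypes)
  pos_all <- integer(0)
  car_all <- list()
  tr <- new_tree_from_coalescent(demog, n)
  x <- 1            # current left coordinate (bp)
  while (x <= L) {
    tot <- sum(tree_branch_lengths(tr))
    seg <- if (r > 0) 1 + stats::rgeom(1, prob = -expm1(-r * tot)) else Inf
    seg_end <- min(x + seg - 1, L)  # tree holds for [x, seg_end]
    nbp <- seg_end - x + 1
    nmut <- stats::rpois(1, mu * nbp * tot)
    if (nmut > 0) {
      len <- tree_branch_lengths(tr)
      br <- sample.int(length(len), nmut, replace = TRUE, prob = len)
      pp <- x + sample.int(nbp, nmut, replace = TRUE) - 1L
      sets <- tree_leaf_sets(tr)
      for (m in seq_len(nmut)) {
        pos_all <- c(pos_all, pp[m])
        car_all[[length(car_all) + 1L]] <- sets[[br[m]]]
      }
    }
    x <- seg_end + 1
    if (x <= L) tr <- smc_prime_transition(tr, demog)
  }
  # infinite sites on an integer grid: drop repeat positions, sort
  if (length(pos_all)) {
    keep <- !duplicated(pos_all)
    pos_all <- pos_all[keep]
    car_all <- car_all[keep]
    o <- order(pos_all)
    pos_all <- pos_all[o]
    car_all <- car_all[o]
  }
  hap <- matrix(0L, nrow = length(pos_all), ncol = n)
  for (s in seq_along(car_all)) hap[s, car_all[[s]]] <- 1L
  structure(list(id = id, L = L, r = r, positions = pos_all,
                 haplotypes = hap, n_haplotypes = n),
            class = "sim_block")
}

#' Recombination-rate sampler configuration
#'
#' Stand-in for an empirical genome-wide recombination-rate distribution: a
#' truncated lognormal with median 1.1e-8 per bp per generation and log
#' standard deviation 0.7 by default.
#'
#' @param family Only `"lognormal"` (default) and `"fixed"` are provided.
#' @param meanlog,sdlog Lognormal parameters (natural log scale).
#' @param rate Fixed rate when `family = "fixed"`.
#' @param min,max Truncation bounds (resampling).
#' @return A `rate_sampler` configuration list.
#' @export
rate_sampler_config <- function(family = c("lognormal", "fixed"),
                                meanlog = log(1.1e-8), sdlog = 0.7,
                                rate = 1.1e-8, min = 0, max = 1e-6) {
  family <- match.arg(family)
  if (min < 0 || max <= min) stop("invalid truncation bounds", call. = FALSE)
  if (family == "fixed" && (rate < 0 || !is.finite(rate)))
    stop("fixed rate must be finite and >= 0", call. = FALSE)
  structure(list(family = family, meanlog = meanlog, sdlog = sdlog,
                 rate = rate, min = min, max = max),
            class = "rate_sampler")
}

sample_rate <- function(cfg) {
  if (cfg$family == "fixed") return(cfg$rate)
  for (i in 1:100) {
    x <- stats::rlnorm(1, cfg$meanlog, cfg$sdlog)
    if (x >= cfg$min && x <= cfg$max) return(x)
  }
  stop("rate sampler failed to draw within truncation bounds", call. = FALSE)
}

#' Simulate independent recombining blocks and diploid genotypes
#'
#' Blocks are mutually independent; each draws its own recombination rate
#' from `rate_sampler` and its own RNG stream from `(seed, block id)`, so
#' results do not depend on evaluation order.  Haplotypes are paired
#' consecutively (1+2, 3+4, ...) into diploid dosages.
#'
#' @param demog A single-population [piecewise_demography()].
#' @param n_diploids Number of diploid individuals (haplotypes = 2x).
#' @param n_blocks Number of independent blocks (>= 1).
#' @param L Block length in bp.
#' @param rate_sampler A [rate_sampler_config()].
#' @param mu Mutation rate per bp per generation; defaults to the
#'   demography's rate.
#' @param seed Master seed.
#' @return List with `blocks` (list of `sim_block`) and `genotypes`
#'   (a [genotype_matrix()] with one contig per block).
#' @export
simulate_blocks <- function(demog, n_diploids, n_blocks, L = 1e5,
                            rate_sampler = rate_sampler_config(),
                            mu = NULL, seed = 1L) {
  if (n_blocks < 1) stop("n_blocks must be >= 1", call. = FALSE)
  mu <- mu %||% demog$mutation_rate
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    sb <- derive_seed(seed, b)
    set.seed(sb)
    rr <- sample_rate(rate_sampler)
    if (rr < 0) stop("rate sampler yielded a negative rate", call. = FALSE)
    blocks[[b]] <- simulate_window(demog, 2L * n_diploids, L, rr, mu,
                                   seed = derive_seed(sb, 1L), id = b)
  }
  list(blocks = blocks, genotypes = blocks_to_genotypes(blocks))
}

#' Collapse simulated blocks into a diploid genotype matrix
#'
#' @param blocks List of `sim_block` objects.
#' @return A [genotype_matrix()]; contigs are named `block<id>`.
#' @export
blocks_to_genotypes <- function(blocks) {
  n_hap <- blocks[[1L]]$n_haplotypes
  n_ind <- n_hap %/% 2L
  dos <- do.call(rbind, lapply(blocks, function(b) {
    if (nrow(b$haplotypes) == 0L) return(matrix(0L, 0L, n_ind))
    b$haplotypes[, seq(1L, n_hap, 2L), drop = FALSE] +
      b$haplotypes[, seq(2L, n_hap, 2L), drop = FALSE]
  }))
  pos <- unlist(lapply(blocks, `[[`, "positions"))
  contig <- unlist(lapply(blocks, function(b)
    rep(paste0("block", b$id), length(b$positions))))
  lens <- stats::setNames(vapply(blocks, `[[`, numeric(1), "L"),
                          paste0("block", vapply(blocks, `[[`, numeric(1),
                                                 "id")))
  genotype_matrix(dos, positions = as.integer(pos),
                  contig = if (length(pos)) contig else character(0),
                  contig_lengths = lens)
}

#' Block manifest as a data frame
#' @param blocks List of `sim_block` objects.
#' @return Data frame with block id, length, recombination rate, site count.
#' @export
block_manifest <- function(blocks) {
  data.frame(block = vapply(blocks, `[[`, numeric(1), "id"),
             L = vapply(blocks, `[[`, numeric(1), "L"),
             r = vapply(blocks, `[[`, numeric(1), "r"),
             n_sites = vapply(blocks, function(b) length(b$positions),
                              numeric(1)))
}
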