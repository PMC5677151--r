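# Empirical data summaries: windowed expected heterozygosity (pi), genotype
# r^2 LD decay in fixed distance bins, and the empirical SFS -- computed
# from simulated blocks or VCF+BED input.

#' Construct a diploid genotype (dosage) matrix
#'
#' @param dosage Integer matrix in `{0, 1, 2}`, sites x individuals.
#' @param positions 1-based bp positions, strictly increasing within each
#'   contig.
#' @param contig Character vector of contig/block labels per site.
#' @param contig_lengths Named numeric vector: total length (bp) of each
#'   contig (used as the callable length when no mask is supplied).
#' @return Object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(dosage, positions, contig, contig_lengths) {
  dosage <- as.matrix(dosage)
  if (length(positions) != nrow(dosage) || length(contig) != nrow(dosage))
    stop("positions and contig must have one entry per site", call. = FALSE)
  if (any(!dosage %in% 0:2))
    stop("dosages must be 0, 1, or 2", call. = FALSE)
  for (ct in unique(contig)) {
    p <- positions[contig == ct]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within contig ", ct,
           call. = FALSE)
  }
  if (is.null(names(contig_lengths)))
    stop("contig_lengths must be named", call. = FALSE)
  structure(list(dosage = dosage, positions = as.numeric(positions),
                 contig = as.character(contig),
                 contig_lengths = contig_lengths),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d sites x %d individuals on %d contig(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(x$contig_lengths)))
  invisible(x)
}

n_individuals <- function(g) ncol(g$dosage)

# Callable length of [start, end] (1-based inclusive) given an optional BED
# mask (0-based half-open, converted at this boundary).
callable_length <- function(mask, ct, start, end) {
  if (is.null(mask)) return(end - start + 1)
  m <- mask[mask$contig == ct, , drop = FALSE]
  if (!nrow(m)) return(0)
  q <- IRanges::IRanges(start = start, end = end)
  r <- IRanges::IRanges(start = m$start + 1L, end = m$end)  # BED -> 1-based
  sum(IRanges::width(IRanges::intersect(r, q)))
}

#' Windowed expected heterozygosity (pi per site)
#'
#' Computes `pi = n/(n-1) * sum_i 2 p_i (1 - p_i) / L` in non-overlapping
#' fixed-width windows aligned to the contig start, where `p_i` is the
#' allele frequency at site i, `n = 2 x individuals`, and `L` is the
#' callable length of the window (window width without a mask, the
#' BED-mask intersection with one).  Windows with callable length 0 are
#' excluded (their count is reported in the `"dropped"` attribute).
#'
#' @param genotypes A [genotype_matrix()].
#' @param window_size Window width in bp (>= 1).
#' @param mask Optional BED-style data frame with columns `contig`, `start`
#'   (0-based), `end` (exclusive) of callable intervals.
#' @param min_callable_frac Windows whose callable fraction falls below this
#'   threshold are excluded (default 0: only L = 0 windows drop).
#' @return Data frame with `contig`, `start`, `end` (1-based inclusive),
#'   `L_callable`, `pi`.
#' @export
window_pi <- function(genotypes, window_size = 1e5, mask = NULL,
                      min_callable_frac = 0) {
  if (window_size < 1) stop("window_size must be >= 1", call. = FALSE)
  g <- genotypes
  n <- 2L * n_individuals(g)
  out <- list()
  dropped <- 0L
  for (ct in names(g$contig_lengths)) {
    len <- g$contig_lengths[[ct]]
    sel <- g$contig == ct
    pos <- g$positions[sel]
    dos <- g$dosage[sel, , drop = FALSE]
    if (!is.null(mask) && length(pos)) {
      # only sites inside callable intervals count towards heterozygosity
      m <- mask[mask$contig == ct, , drop = FALSE]
      keep <- rep(FALSE, length(pos))
      if (nrow(m)) {
        hits <- IRanges::findOverlaps(
          IRanges::IRanges(start = pos, width = 1L),
          IRanges::IRanges(start = m$start + 1L, end = m$end))
        keep[S4Vectors::queryHits(hits)] <- TRUE
      }
      pos <- pos[keep]
      dos <- dos[keep, , drop = FALSE]
    }
    starts <- seq(1, len, by = window_size)
    for (ws in starts) {
      we <- min(ws + window_size - 1, len)
      Lc <- callable_length(mask, ct, ws, we)
      if (Lc <= 0 || Lc < min_callable_frac * (we - ws + 1)) {
        dropped <- dropped + 1L
        next
      }
      in_w <- pos >= ws & pos <= we
      if (any(in_w)) {
        p <- rowSums(dos[in_w, , drop = FALSE]) / n
        het <- sum(2 * p * (1 - p))
        pi <- n / (n - 1) * het / Lc
      } else pi <- 0
      out[[length(out) + 1L]] <- data.frame(
        contig = ct, start = ws, end = we, L_callable = Lc, pi = pi)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(contig = character(0), start = numeric(0),
                         end = numeric(0), L_callable = numeric(0),
                         pi = numeric(0))
  attr(res, "dropped") <- dropped
  res
}

#' Summarize a window-pi table
#'
#' @param stats Data frame from [window_pi()] (>= 2 windows).
#' @return List with `mean`, `sd` (sample SD), `lower`/`upper`
#'   (mean -/+ 2 SD), `n_windows`, and the full `values` vector.
#' @export
pi_summary <- function(stats) {
  v <- stats$pi
  if (length(v) < 2)
    stop("insufficient data: pi_summary needs >= 2 windows", call. = FALSE)
  m <- mean(v); s <- stats::sd(v)
  list(mean = m, sd = s, lower = m - 2 * s, upper = m + 2 * s,
       n_windows = length(v), values = v)
}

#' Genotype r^2 LD decay in fixed distance bins
#'
#' Sites are filtered first -- singletons (minor allele count 1 among 2n
#' alleles) and invariant sites are removed -- then every within-contig pair
#' of retained sites closer than `max_dist` is assigned to a half-open
#' 1000-bp distance bin (`[0,1000)` ... `[50000,51000)` by default) and the
#' mean squared Pearson correlation of dosage vectors is reported per bin.
#' Pairs where either site has zero dosage variance are skipped.
#'
#' @param genotypes A [genotype_matrix()].
#' @param max_dist Maximum pair distance in bp (exclusive).
#' @param bin_width Bin width in bp.
#' @return Data frame with `bin` (1-based), `dist_lo`, `dist_hi`,
#'   `midpoint`, `mean_r2` (NA for empty bins), `n_pairs`.
#' @export
ld_decay <- function(genotypes, max_dist = 51000, bin_width = 1000) {
  g <- genotypes
  n_bins <- as.integer(ceiling(max_dist / bin_width))
  sum_r2 <- numeric(n_bins)
  n_pairs <- numeric(n_bins)
  n2 <- 2L * n_individuals(g)
  for (ct in unique(g$contig)) {
    sel <- g$contig == ct
    dos <- g$dosage[sel, , drop = FALSE]
    pos <- g$positions[sel]
    ac <- rowSums(dos)
    mac <- pmin(ac, n2 - ac)
    keep <- mac >= 2                     # drops singletons and invariant
    dos <- dos[keep, , drop = FALSE]
    pos <- pos[keep]
    S <- nrow(dos)
    if (S < 2) next
    # centered dosage rows for fast pairwise correlation
    cm <- dos - rowMeans(dos)
    ss <- rowSums(cm^2)
    for (i in seq_len(S - 1L)) {
      jmax <- i
      while (jmax < S && pos[jmax + 1L] - pos[i] < max_dist) jmax <- jmax + 1L
      if (jmax == i) next
      j <- (i + 1L):jmax
      ok <- ss[i] > 0 & ss[j] > 0
      if (!any(ok)) next
      j <- j[ok]
      r2 <- (cm[j, , drop = FALSE] %*% cm[i, ])^2 / (ss[i] * ss[j])
      b <- pmin(floor((pos[j] - pos[i]) / bin_width) + 1L, n_bins)
      for (u in seq_along(j)) {
        sum_r2[b[u]] <- sum_r2[b[u]] + r2[u]
        n_pairs[b[u]] <- n_pairs[b[u]] + 1
      }
    }
  }
  data.frame(bin = seq_len(n_bins),
             dist_lo = (seq_len(n_bins) - 1L) * bin_width,
             dist_hi = seq_len(n_bins) * bin_width,
             midpoint = (seq_len(n_bins) - 0.5) * bin_width,
             mean_r2 = ifelse(n_pairs > 0, sum_r2 / n_pairs, NA_real_),
             n_pairs = n_pairs)
}

#' Empirical site frequency spectrum of a genotype matrix
#'
#' Tabulates segregating sites by derived-allele count (unfolded; dosages
#' are taken as derived-allele dosages) or minor-allele count (folded).
#'
#' @param genotypes A [genotype_matrix()].
#' @param folded Tabulate minor-allele counts instead of derived counts.
#' @param proportions Return proportions instead of counts.
#' @return An [sfs_spectrum()].
#' @export
empirical_sfs <- function(genotypes, folded = FALSE, proportions = FALSE) {
  g <- genotypes
  n <- 2L * n_individuals(g)
  ac <- rowSums(g$dosage)
  ac <- ac[ac > 0 & ac < n]
  if (folded) {
    mac <- pmin(ac, n - ac)
    v <- tabulate(mac, nbins = n %/% 2L)
  } else {
    v <- tabulate(ac, nbins = n - 1L)
  }
  s <- sfs_spectrum(v, n, "counts", folded = folded)
  if (proportions) as_proportions(s) else s
}
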