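# Site frequency spectra: containers and transforms (scale, fold, project,
# marginalize, singleton handling) shared by the analytic and Monte Carlo
# engines and by the empirical summaries.

#' Construct a site frequency spectrum
#'
#' Unfolded spectra are indexed by derived-allele count `1..n-1`; folded
#' spectra by minor-allele count `1..floor(n/2)`.  Fixed (monomorphic)
#' classes are excluded everywhere.
#'
#' @param values Non-negative numeric vector of the appropriate length.
#' @param n Number of sampled chromosomes.
#' @param kind One of `"counts"` (SNP counts), `"proportions"` (sums to 1),
#'   `"persite"` (expected SNP density per site, i.e. mutation rate times
#'   expected subtending branch length), or `"relative"` (shape relative to
#'   theta = 1, as emitted by diffusion-based SFS software).
#' @param folded Logical.
#' @param se Optional per-bin Monte Carlo standard errors.
#' @return An object of class `"sfs_spectrum"`.
#' @export
sfs_spectrum <- function(values, n, kind = c("counts", "proportions",
                                             "persite", "relative"),
                         folded = FALSE, se = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  len <- if (folded) n %/% 2L else n - 1L
  if (length(values) != len)
    stop("expected ", len, " bins for n = ", n,
         if (folded) " (folded)" else " (unfolded)", call. = FALSE)
  if (any(values < -1e-12)) stop("SFS values must be >= 0", call. = FALSE)
  values <- pmax(values, 0)
  if (kind == "proportions" && abs(sum(values) - 1) > 1e-9)
    stop("proportions must sum to 1 (within 1e-9)", call. = FALSE)
  if (!is.null(se) && length(se) != len)
    stop("se must have one entry per bin", call. = FALSE)
  structure(list(values = as.numeric(values), n = n, kind = kind,
                 folded = folded, se = se),
            class = "sfs_spectrum")
}

#' @export
print.sfs_spectrum <- function(x, ...) {
  cat(sprintf("SFS (%s, %s), n = %d chromosomes, %d bins\n",
              x$kind, if (x$folded) "folded" else "unfolded", x$n,
              length(x$values)))
  print(signif(x$values, 5))
  invisible(x)
}

#' Convert a spectrum to proportions
#' @param sfs An [sfs_spectrum()].
#' @return The spectrum renormalized to sum to 1.
#' @export
as_proportions <- function(sfs) {
  tot <- sum(sfs$values)
  if (tot <= 0) stop("cannot normalize an all-zero spectrum", call. = FALSE)
  sfs_spectrum(sfs$values / tot, sfs$n, "proportions", sfs$folded)
}

#' Scaling parameters for absolute (count) spectra
#'
#' @param N_Ai Oldest ancestral diploid size of the model.
#' @param mu Mutation rate per bp per generation.
#' @param L Sequence length in bp.
#' @return List with the inputs and the derived `theta = 4 * N_Ai * mu * L`.
#' @export
scaling_params <- function(N_Ai, mu, L) {
  if (N_Ai <= 0 || mu <= 0 || L < 0)
    stop("scaling parameters must be positive (L >= 0)", call. = FALSE)
  list(N_Ai = N_Ai, mu = mu, L = L, theta = 4 * N_Ai * mu * L)
}

#' Scale a spectrum to absolute expected SNP counts
#'
#' A `"persite"` spectrum (expected SNP density per site, mutation rate
#' already applied) scales by the sequence length `L`; a `"relative"`
#' spectrum (shape at theta = 1) scales by `theta = 4 * N_Ai * mu * L`.
#'
#' @param sfs An [sfs_spectrum()] of kind `"persite"` or `"relative"`.
#' @param scaling A [scaling_params()] list.
#' @return A `"counts"` spectrum.
#' @export
scale_to_counts <- function(sfs, scaling) {
  fac <- switch(sfs$kind,
    persite = scaling$L,
    relative = scaling$theta,
    stop("scale_to_counts expects a 'persite' or 'relative' spectrum, got '",
         sfs$kind, "'", call. = FALSE))
  sfs_spectrum(sfs$values * fac, sfs$n, "counts", sfs$folded,
               se = if (is.null(sfs$se)) NULL else sfs$se * fac)
}

#' Fold an unfolded spectrum
#'
#' `F_j = xi_j + xi_(n-j)` for `j < n/2` and `F_(n/2) = xi_(n/2)` (n even);
#' total mass is conserved.
#'
#' @param sfs An unfolded [sfs_spectrum()].
#' @return The folded spectrum.
#' @export
fold <- function(sfs) {
  if (sfs$folded) stop("spectrum is already folded", call. = FALSE)
  n <- sfs$n
  half <- n %/% 2L
  v <- numeric(half)
  for (j in seq_len(half)) {
    v[j] <- if (j == n - j) sfs$values[j] else sfs$values[j] + sfs$values[n - j]
  }
  kind <- sfs$kind
  sfs_spectrum(v, n, kind, folded = TRUE)
}

#' Project a spectrum to a smaller sample size
#'
#' Expected hypergeometric down-sampling from `n` to `m` chromosomes; mass
#' falling into the monomorphic classes of the subsample is dropped
#' (proportions are renormalized afterwards so the kind's sum-to-one
#' invariant holds).
#'
#' @param sfs An unfolded [sfs_spectrum()] of kind `"counts"`,
#'   `"proportions"`, `"persite"` or `"relative"`.
#' @param m Target number of chromosomes, `2 <= m <= n`.
#' @return The spectrum at sample size `m`.
#' @export
project <- function(sfs, m) {
  if (sfs$folded) stop("project expects an unfolded spectrum", call. = FALSE)
  m <- as.integer(m)
  n <- sfs$n
  if (m > n) stop("cannot project up: m must be <= n", call. = FALSE)
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  if (m == n) return(sfs)
  out <- numeric(m - 1L)
  for (i in seq_len(n - 1L)) {
    j <- seq_len(m - 1L)
    # j derived among m drawn without replacement from i derived / n - i not
    w <- stats::dhyper(j, i, n - i, m)
    out <- out + sfs$values[i] * w
  }
  res <- sfs_spectrum(out, m, if (sfs$kind == "proportions") "counts"
                      else sfs$kind, folded = FALSE)
  if (sfs$kind == "proportions") res <- as_proportions(res)
  res
}

#' Marginal spectrum of one population from a joint SFS
#'
#' @param joint A multi-dimensional array of counts with one axis per
#'   population; axis `p` has length `n_p + 1` representing allele counts
#'   `0..n_p`, and `dimnames` name the populations.
#' @param pop Focal population label.
#' @return An unfolded `"counts"` [sfs_spectrum()] over classes
#'   `1..n_p - 1` (entries where the focal count is 0 or `n_p` are dropped).
#' @export
marginalize_joint <- function(joint, pop) {
  dn <- names(dimnames(joint))
  if (is.null(dn) || !pop %in% dn)
    stop("population '", pop, "' is not an axis of the joint SFS",
         call. = FALSE)
  ax <- match(pop, dn)
  marg <- apply(joint, ax, sum)
  n <- length(marg) - 1L
  sfs_spectrum(marg[2:n], n, "counts", folded = FALSE)
}

#' Zero out the singleton class and renormalize
#'
#' Low-coverage sequencing calls singletons unreliably; likelihood
#' comparisons are therefore also run with the singleton category removed
#' and the remaining bins rescaled to sum to 1.
#'
#' @param sfs A `"proportions"` [sfs_spectrum()].
#' @param drop_polarized_max For unfolded input, also zero the `n-1` class
#'   (derived-allele "singletons" of the ancestral allele).  Default FALSE.
#' @return The renormalized spectrum.
#' @export
drop_singletons_renormalize <- function(sfs, drop_polarized_max = FALSE) {
  if (sfs$kind != "proportions")
    stop("drop_singletons_renormalize expects a proportional spectrum",
         call. = FALSE)
  v <- sfs$values
  v[1L] <- 0
  if (drop_polarized_max && !sfs$folded) v[length(v)] <- 0
  if (sum(v) <= 0)
    stop("degenerate spectrum: all mass in the singleton class",
         call. = FALSE)
  sfs_spectrum(v / sum(v), sfs$n, "proportions", sfs$folded)
}

# ---------------------------------------------------------------------------
# Text format: one `#`-prefixed header line (n, folded, kind), then
# index<TAB>value rows.  The reader also accepts a bare vector of values.

#' Write a spectrum to the package text format
#' @param sfs An [sfs_spectrum()].
#' @param path Output path.
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d folded=%s kind=%s", sfs$n,
                     tolower(sfs$folded), sfs$kind), con)
  writeLines(sprintf("%d\t%.17g", seq_along(sfs$values), sfs$values), con)
  invisible(path)
}

#' Read a spectrum from the package text format (or a bare vector file)
#'
#' @param path Input path.  With the standard header, `n`/`folded`/`kind`
#'   are taken from it; a bare whitespace-separated vector is read as an
#'   unfolded count spectrum with `n = length + 1`.
#' @return An [sfs_spectrum()].
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  is_comment <- grepl("^#", lines)
  hdr_idx <- which(is_comment & grepl("n=\\d+", lines) &
                     grepl("kind=", lines))
  if (length(hdr_idx)) {
    h <- lines[hdr_idx[1L]]
    lines <- lines[!is_comment]
    n <- as.integer(sub(".*n=([0-9]+).*", "\\1", h))
    folded <- grepl("folded=true", h)
    kind <- sub(".*kind=([a-z]+).*", "\\1", h)
    parts <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
    vals <- as.numeric(parts[, 2L])[order(as.integer(parts[, 1L]))]
    sfs_spectrum(vals, n, kind, folded)
  } else {
    lines <- lines[!is_comment]
    vals <- as.numeric(unlist(strsplit(trimws(lines), "\\s+")))
    sfs_spectrum(vals, length(vals) + 1L, "counts", folded = FALSE)
  }
}
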