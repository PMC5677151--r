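# Scoring predicted spectra against an observed SFS: multinomial and
# Poisson log-likelihoods, the data-to-data reference, and ranked fit
# tables.

check_binning <- function(observed, model) {
  if (observed$n != model$n || observed$folded != model$folded)
    stop("observed and model spectra have mismatched binning (n or folded)",
         call. = FALSE)
}

#' Multinomial log-likelihood of an observed spectrum under model proportions
#'
#' `LL = sum_i x_i log p_i` (no multinomial coefficient, so the data-to-data
#' value is directly comparable across models; differences of LLs are
#' invariant to the convention either way).  Model bins with zero
#' probability but observations are floored at 1e-300 with a warning so
#' pathological models still rank (badly).
#'
#' @param observed A `"counts"` [sfs_spectrum()].
#' @param model A `"proportions"` [sfs_spectrum()] on the same binning.
#' @return The log-likelihood (scalar).
#' @export
multinomial_ll <- function(observed, model) {
  check_binning(observed, model)
  x <- observed$values
  p <- model$values
  if (model$kind != "proportions") p <- p / sum(p)
  bad <- p <= 0 & x > 0
  if (any(bad)) {
    warning("model assigns zero probability to ", sum(bad),
            " observed bin(s); flooring at 1e-300", call. = FALSE)
    p[bad] <- 1e-300
  }
  sum(x[x > 0] * log(p[x > 0]))
}

#' Poisson log-likelihood of observed counts under model expected counts
#'
#' `LL = sum_i [x_i log m_i - m_i - log Gamma(x_i + 1)]`.  The
#' `-log Gamma(x+1)` term is constant across models and kept so absolute
#' values match likelihood-theory references.
#'
#' @param observed A `"counts"` [sfs_spectrum()].
#' @param model A `"counts"` [sfs_spectrum()] of expected counts (> 0
#'   wherever observations exist).
#' @return The log-likelihood (scalar).
#' @export
poisson_ll <- function(observed, model) {
  check_binning(observed, model)
  x <- observed$values
  m <- model$values
  if (any(m < 0)) stop("negative expected count", call. = FALSE)
  if (any(m == 0 & x > 0)) {
    warning("model expects zero counts in ", sum(m == 0 & x > 0),
            " observed bin(s); flooring at 1e-300", call. = FALSE)
    m[m == 0 & x > 0] <- 1e-300
  }
  sum(ifelse(x > 0, x * log(m), 0) - m - lgamma(x + 1))
}

#' Best attainable ("data-to-data") log-likelihood of an observed spectrum
#'
#' The log-likelihood obtained by replacing the model's predictions with the
#' observed spectrum itself: `sum_i x_i log(x_i / X)` (multinomial, with
#' `0 log 0 = 0`) or the Poisson LL at `m = x`.
#'
#' @param observed A `"counts"` [sfs_spectrum()] with positive total.
#' @param family `"multinomial"` or `"poisson"`.
#' @return The log-likelihood (scalar).
#' @export
data_to_data_ll <- function(observed, family = c("multinomial", "poisson")) {
  family <- match.arg(family)
  x <- observed$values
  if (length(x) == 0L || sum(x) <= 0)
    stop("empty observed spectrum", call. = FALSE)
  if (family == "multinomial") {
    p <- x / sum(x)
    sum(x[x > 0] * log(p[x > 0]))
  } else {
    sum(ifelse(x > 0, x * log(x), 0) - x - lgamma(x + 1))
  }
}

#' Rank predicted spectra against an observed SFS
#'
#' Applies identical transforms (projection to a smaller sample size,
#' folding, singleton removal) to the observed spectrum and every model,
#' scores each model, and reports `LL`, `delta_LL = LL - LL(data-to-data)`,
#' and rank (best first; the data-to-data row has `delta_LL = 0` and is the
#' maximum by Gibbs' inequality).  Models that cannot be reconciled to the
#' observed binning are flagged `failed` and reported with `NA`.
#'
#' @param models Named list of [sfs_spectrum()] predictions (kinds
#'   `"proportions"`, `"persite"`, `"relative"`, or `"counts"`; for the
#'   multinomial family all are normalized to proportions; for the Poisson
#'   family models must be `"counts"`).
#' @param observed A `"counts"` [sfs_spectrum()].
#' @param family `"multinomial"` (default) or `"poisson"`.
#' @param drop_singletons Zero the singleton class and renormalize (both
#'   sides; multinomial only).
#' @param fold_spectra Fold both sides before scoring.
#' @param project_to Optionally project both sides down to this sample size
#'   before any folding.
#' @return A `data.frame` of class `"fit_table"`: model, LL, delta_LL, rank,
#'   failed; the first row is `"data-to-data"`.
#' @export
fit_table <- function(models, observed, family = c("multinomial", "poisson"),
                      drop_singletons = FALSE, fold_spectra = FALSE,
                      project_to = NULL) {
  family <- match.arg(family)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stop("models must be a named list", call. = FALSE)
  transform_counts <- function(s) {
    if (!is.null(project_to) && !s$folded && s$n > project_to)
      s <- project(s, project_to)
    if (fold_spectra && !s$folded) s <- fold(s)
    s
  }
  obs <- transform_counts(observed)
  obs_eff <- obs
  if (drop_singletons && family == "multinomial") {
    v <- obs$values
    v[1L] <- 0
    obs_eff <- sfs_spectrum(v, obs$n, "counts", obs$folded)
  }
  score_one <- function(m) {
    m <- transform_counts(m)
    if (m$n != obs$n || m$folded != obs$folded)
      return(NA_real_)
    if (family == "multinomial") {
      p <- as_proportions(m)
      if (drop_singletons) p <- drop_singletons_renormalize(p)
      multinomial_ll(obs_eff, p)
    } else {
      if (m$kind != "counts")
        stop("Poisson scoring requires count spectra; use scale_to_counts()",
             call. = FALSE)
      poisson_ll(obs_eff, m)
    }
  }
  ll <- vapply(names(models), function(nm) {
    tryCatch(score_one(models[[nm]]), error = function(e) NA_real_)
  }, numeric(1))
  dd <- if (family == "multinomial") data_to_data_ll(obs_eff, "multinomial")
        else data_to_data_ll(obs_eff, "poisson")
  res <- data.frame(model = c("data-to-data", names(models)),
                    LL = c(dd, ll),
                    delta_LL = c(0, ll - dd),
                    failed = c(FALSE, is.na(ll)),
                    stringsAsFactors = FALSE)
  ok <- !res$failed
  res$rank <- NA_integer_
  res$rank[ok] <- rank(-res$delta_LL[ok], ties.method = "first")
  res <- res[order(res$failed, -res$delta_LL), ]
  rownames(res) <- NULL
  class(res) <- c("fit_table", "data.frame")
  res
}

#' Write a fit table as TSV with a provenance header
#' @param ft A [fit_table()] result.
#' @param path Output path.
#' @param provenance Optional named character vector written as
#'   `# key=value` header lines.
#' @export
write_fit_table <- function(ft, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(provenance))
    writeLines(sprintf("# %s=%s", k, provenance[[k]]), con)
  utils::write.table(ft, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
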