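# Pipeline orchestration: built-in model families for fixtures, the
# fixture generator (demography configs plus a synthetic "observed" SFS),
# and the end-to-end comparison runner.

#' Built-in demography families for fixtures and tests
#'
#' Families: `"constant"` (N = 10,000), `"bottleneck"` (two-epoch: 10,000
#' diploids for the most recent 1,000 generations, ancestral 1,000),
#' `"growth"` (exponential growth from 1,000 to 20,000 over the last 500
#' generations), `"three_pop_migration"` (an out-of-Africa-shaped topology:
#' three extant populations exchanging migrants, joined by two ancient
#' splits), and `"archaic_pulse"` (the constant model with an isolated
#' archaic donor contributing a 3% pulse 1,500 generations ago).
#'
#' @param family Family name.
#' @param mutation_rate,generation_time Passed through.
#' @return A [piecewise_demography()].
#' @export
builtin_demography <- function(family = c("constant", "bottleneck", "growth",
                                          "three_pop_migration",
                                          "archaic_pulse"),
                               mutation_rate = 1.25e-8,
                               generation_time = 25) {
  family <- match.arg(family)
  mk <- function(eps, ev = list())
    piecewise_demography(eps, events = ev, mutation_rate = mutation_rate,
                         generation_time = generation_time, name = family)
  switch(family,
    constant = mk(list(epoch(0, Inf, c(pop1 = 1e4)))),
    bottleneck = mk(list(epoch(0, 1000, c(pop1 = 1e4)),
                         epoch(1000, Inf, c(pop1 = 1e3)))),
    growth = mk(list(epoch(0, 500, c(pop1 = 2e4),
                           end_size = c(pop1 = 1e3)),
                     epoch(500, Inf, c(pop1 = 1e3)))),
    three_pop_migration = {
      pops3 <- c("AFR", "EUR", "ASIA")
      mig <- matrix(3e-5, 3, 3, dimnames = list(pops3, pops3))
      diag(mig) <- 0
      mk(list(epoch(0, 1000, c(AFR = 12000, EUR = 10000, ASIA = 8000),
                    migration = mig),
              epoch(1000, 3000, c(AFR = 12000, EUR = 2000),
                    migration = matrix(c(0, 1e-4, 1e-4, 0), 2, 2,
                                       dimnames = list(c("AFR", "EUR"),
                                                       c("AFR", "EUR")))),
              epoch(3000, Inf, c(AFR = 7000))),
         ev = list(split_event(1000, derived = "ASIA", ancestral = "EUR"),
                   split_event(3000, derived = "EUR", ancestral = "AFR")))
    },
    archaic_pulse = mk(list(epoch(0, 16000, c(pop1 = 1e4, archaic = 2e3)),
                            epoch(16000, Inf, c(pop1 = 1e4))),
                       ev = list(
                         pulse_event(1500, source = "archaic",
                                     dest = "pop1", fraction = 0.03),
                         split_event(16000, derived = "archaic",
                                     ancestral = "pop1"))))
}

#' Generate a fixture: demography configs and a synthetic observed SFS
#'
#' Writes the generating model (and optionally decoy models) as YAML
#' configs plus a simulated "observed" SFS drawn multinomially from the
#' generating model's expected spectrum, so recovery experiments can assert
#' that the generating model ranks first.  The generating family is
#' recorded in the provenance header of every output.
#'
#' @param family A [builtin_demography()] family name.
#' @param seed Integer seed for the SFS draw.
#' @param dir Output directory (created if needed).
#' @param n_snps Total segregating sites in the synthetic observed SFS.
#' @param n_chrom Sampled chromosomes.
#' @param decoys Character vector of additional families to write as decoy
#'   models.
#' @return Invisibly, a list with paths (`model`, `decoys`, `observed_sfs`)
#'   and the drawn [sfs_spectrum()].
#' @export
generate_fixture <- function(family, seed = 1L, dir = tempdir(),
                             n_snps = 17446, n_chrom = 20,
                             decoys = character(0)) {
  demog <- builtin_demography(family)  # errors on unknown family
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model_path <- file.path(dir, paste0(family, ".yaml"))
  write_demography(demog, model_path)
  decoy_paths <- vapply(decoys, function(f) {
    p <- file.path(dir, paste0(f, ".yaml"))
    write_demography(builtin_demography(f), p)
    p
  }, character(1))
  exp_sfs <- model_expected_sfs(demog, n_chrom, seed = derive_seed(seed, 99L))
  p <- as_proportions(exp_sfs)$values
  set.seed(derive_seed(seed, 1L))
  counts <- as.vector(stats::rmultinom(1L, n_snps, p))
  obs <- sfs_spectrum(counts, n_chrom, "counts", folded = FALSE)
  sfs_path <- file.path(dir, "observed_sfs.txt")
  write_sfs(obs, sfs_path)
  prov <- c(sprintf("# generating_family=%s", family),
            sprintf("# seed=%d", as.integer(seed)),
            sprintf("# n_snps=%d", as.integer(n_snps)))
  txt <- readLines(sfs_path)
  writeLines(c(prov, txt), sfs_path)
  invisible(list(model = model_path, decoys = decoy_paths,
                 observed_sfs = sfs_path, observed = obs, demography = demog))
}

# Expected SFS for any model: analytic when single-population, Monte Carlo
# (first extant population) otherwise.
model_expected_sfs <- function(demog, n_chrom, n_reps = 2e4, seed = 1L) {
  if (is_single_pop(demog)) return(expected_sfs_analytic(demog, n_chrom))
  pop <- epoch_pops(demog$epochs[[1L]])[1L]
  samples <- stats::setNames(n_chrom, pop)
  expected_sfs_montecarlo(demog, samples, n_reps = n_reps, seed = seed)
}

#' Read an analysis config (YAML) for [run_compare()]
#'
#' Fields: `models` (list of `name:`/`path:` pairs), `observed_sfs` (path)
#' or `synthetic` (list with `family`, `n_snps`), `summaries` (character
#' subset of `sfs`, `heterozygosity`, `ld`), `simulation` (`n_blocks`, `L`,
#' `n_diploids`, `reps`), `transforms` (`fold`, `project_to`,
#' `drop_singletons`), `seed`, `output_dir`.
#'
#' @param path YAML config path.
#' @return The config list, validated.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$models) || !length(cfg$models))
    stop("config must list at least one model", call. = FALSE)
  for (m in cfg$models) {
    if (is.null(m$name) || is.null(m$path))
      stop("each model needs `name` and `path`", call. = FALSE)
    if (!file.exists(m$path))
      stop("model file does not exist: ", m$path, call. = FALSE)
  }
  if (!is.null(cfg$observed_sfs) && !file.exists(cfg$observed_sfs))
    stop("observed SFS file does not exist: ", cfg$observed_sfs,
         call. = FALSE)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$summaries <- cfg$summaries %||% "sfs"
  cfg$output_dir <- cfg$output_dir %||% tempdir()
  cfg
}

#' Run the full model-concordance comparison
#'
#' For every model in the config: predict the expected SFS (analytic or
#' Monte Carlo as appropriate) and, when requested, simulate blocks and
#' compute the heterozygosity distribution and LD decay; then score all
#' models against the observed SFS and write a ranked fit table.  Every
#' output carries a `# seed=` / `# config_hash=` provenance header.
#' Failure of one model is isolated to its rows/files.
#'
#' @param config A config list from [read_analysis_config()] or a path to a
#'   YAML config.
#' @return Invisibly, a list with `fit` (the [fit_table()]), `sfs`
#'   (per-model spectra), `pi` and `ld` (per-model summaries, when
#'   requested), and `output_dir`.
#' @export
run_compare <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  cfg <- config
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(yaml::as.yaml(cfg))
  prov <- c(seed = cfg$seed, config_hash = hash,
            version = as.character(utils::packageVersion("popconcord")))
  n_chrom <- 2L * as.integer(cfg$simulation$n_diploids %||% 10L)
  # observed spectrum
  obs <- if (!is.null(cfg$observed_sfs)) {
    read_sfs(cfg$observed_sfs)
  } else if (!is.null(cfg$synthetic)) {
    fx <- generate_fixture(cfg$synthetic$family %||% "bottleneck",
                           seed = cfg$seed,
                           dir = file.path(cfg$output_dir, "fixture"),
                           n_snps = cfg$synthetic$n_snps %||% 17446,
                           n_chrom = n_chrom)
    fx$observed
  } else stop("config needs `observed_sfs` or `synthetic`", call. = FALSE)
  demogs <- list()
  spectra <- list()
  pi_out <- list()
  ld_out <- list()
  for (m in cfg$models) {
    res <- tryCatch({
      d <- read_demography(m$path)
      s <- model_expected_sfs(d, obs$n,
                              n_reps = cfg$simulation$reps %||% 2e4,
                              seed = derive_seed(cfg$seed,
                                                 length(spectra) + 1L))
      list(d = d, s = s)
    }, error = function(e) {
      warning("model ", m$name, " failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) next
    demogs[[m$name]] <- res$d
    spectra[[m$name]] <- res$s
  }
  want <- cfg$summaries
  if (any(c("heterozygosity", "ld") %in% want)) {
    n_blocks <- as.integer(cfg$simulation$n_blocks %||% 200L)
    Lb <- as.numeric(cfg$simulation$L %||% 1e5)
    n_dip <- as.integer(cfg$simulation$n_diploids %||% 10L)
    for (nm in names(demogs)) {
      d <- demogs[[nm]]
      if (!is_single_pop(d)) next  # sequence simulation is single-population
      sim <- simulate_blocks(d, n_dip, n_blocks, L = Lb,
                             seed = derive_seed(cfg$seed, 1000L +
                                                  match(nm, names(demogs))))
      if ("heterozygosity" %in% want) {
        wp <- window_pi(sim$genotypes, window_size = Lb)
        pi_out[[nm]] <- pi_summary(wp)
        write_tsv_prov(wp, file.path(cfg$output_dir,
                                     paste0("pi_", nm, ".tsv")), prov)
      }
      if ("ld" %in% want) {
        ld <- ld_decay(sim$genotypes)
        ld_out[[nm]] <- ld
        write_tsv_prov(ld, file.path(cfg$output_dir,
                                     paste0("ld_", nm, ".tsv")), prov)
      }
    }
  }
  tr <- cfg$transforms %||% list()
  ft <- fit_table(spectra, obs,
                  family = "multinomial",
                  drop_singletons = isTRUE(tr$drop_singletons),
                  fold_spectra = isTRUE(tr$fold),
                  project_to = tr$project_to)
  write_fit_table(ft, file.path(cfg$output_dir, "fit_table.tsv"),
                  provenance = prov)
  for (nm in names(spectra))
    write_sfs(spectra[[nm]],
              file.path(cfg$output_dir, paste0("sfs_", nm, ".txt")))
  invisible(list(fit = ft, sfs = spectra, pi = pi_out, ld = ld_out,
                 output_dir = cfg$output_dir))
}

# TSV with `# key=value` provenance header lines
write_tsv_prov <- function(x, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(prov), prov), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
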