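# Reading and writing demographies as structured config files (YAML or
# JSON, chosen by file extension), plus a tiny provenance helper.

demography_to_list <- function(demog) {
  list(
    name = demog$name,
    mutation_rate = demog$mutation_rate,
    generation_time = demog$generation_time,
    epochs = lapply(demog$epochs, function(e) {
      out <- list(t_start = e$t_start,
                  t_end = if (is.finite(e$t_end)) e$t_end else "inf",
                  size = as.list(e$size))
      if (!is.null(e$end_size)) out$end_size <- as.list(e$end_size)
      if (!is.null(e$migration)) {
        out$migration <- list(populations = rownames(e$migration),
                              rates = apply(e$migration, 1L, as.list,
                                            simplify = FALSE))
      }
      out
    }),
    events = demog$events
  )
}

list_to_demography <- function(x) {
  eps <- lapply(x$epochs, function(e) {
    t_end <- if (identical(e$t_end, "inf")) Inf else as.numeric(e$t_end)
    mig <- NULL
    if (!is.null(e$migration)) {
      p <- unlist(e$migration$populations)
      mig <- matrix(0, length(p), length(p), dimnames = list(p, p))
      for (i in seq_along(p))
        mig[i, ] <- unlist(e$migration$rates[[i]])
    }
    epoch(as.numeric(e$t_start), t_end,
          size = unlist(e$size),
          end_size = if (is.null(e$end_size)) NULL else unlist(e$end_size),
          migration = mig)
  })
  evs <- lapply(x$events, function(ev) {
    ev$time <- as.numeric(ev$time)
    if (!is.null(ev$fraction)) ev$fraction <- as.numeric(ev$fraction)
    ev
  })
  piecewise_demography(eps, events = evs,
                       mutation_rate = as.numeric(x$mutation_rate),
                       generation_time = as.numeric(x$generation_time),
                       name = x$name)
}

#' Write a demography to a YAML or JSON config file
#' @param demog A [piecewise_demography()].
#' @param path Output path; `.json` selects JSON, anything else YAML.
#' @export
write_demography <- function(demog, path) {
  x <- demography_to_list(demog)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Read a demography from a YAML or JSON config file
#' @param path Input path (format by extension, as in
#'   [write_demography()]).
#' @return A [piecewise_demography()].
#' @export
read_demography <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
       else yaml::read_yaml(path)
  d <- list_to_demography(x)
  d
}

# Polynomial rolling hash of a character vector; used for config
# provenance stamps (not cryptographic).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
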