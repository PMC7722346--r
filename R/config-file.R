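# Plain "key: value" config files for the simulator, so the command-line
# interface needs no extra dependencies. Unknown keys are rejected.

#' Read a generator configuration from a key: value text file
#'
#' Recognized keys: the design counts `l, t, r, e`, `seed`,
#' `drought_yield_ratio`, `blocks_per_rep`, `n_checks`, `conditions`
#' (comma-separated), and per-trait overrides written as
#' `<trait>.<component>` (variance components from the generator's component
#' set) or `<trait>.mu_rainfed` / `<trait>.mu_drought` /
#' `<trait>.loading`. Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^:]+):(.*)$", lines))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) stop(path, ": malformed line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 2))
  vals <- trimws(vapply(kv, `[`, "", 3))
  top <- c("l", "t", "r", "e", "seed", "drought_yield_ratio",
           "blocks_per_rep", "n_checks", "conditions")
  cfg_args <- list()
  traits <- default_trait_params()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (k %in% top) {
      cfg_args[[k]] <- if (k == "conditions")
        trimws(strsplit(v, ",")[[1]]) else as.numeric(v)
    } else if (grepl(".", k, fixed = TRUE)) {
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      tr <- parts[1]; comp <- parts[2]
      if (!tr %in% names(traits))
        stop(path, ": unknown trait '", tr, "' in key '", k, "'")
      if (comp %in% gen_components) traits[[tr]]$vc[[comp]] <- as.numeric(v)
      else if (comp %in% c("mu_rainfed", "mu_drought", "loading"))
        traits[[tr]][[comp]] <- as.numeric(v)
      else stop(path, ": unknown component '", comp, "' in key '", k, "'")
    } else {
      stop(path, ": unknown key '", k, "'")
    }
  }
  cfg_args$traits <- traits
  do.call(generator_config, cfg_args)
}
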