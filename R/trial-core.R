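# Core containers for line x tester multi-environment trials: trait
# specifications, genotype roles, plot-level observations, and delimited I/O.

#' Trait specification
#'
#' Describes one measured trait: its units, the direction of merit, legal
#' bounds, and whether it is scored only under drought (as the stay-green
#' score is).
#'
#' @param name Trait identifier (column name in trial files).
#' @param units Free-text units, e.g. `"kg/ha"`.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param bounds Optional numeric `c(lo, hi)`; ordinal traits must have
#'   integer bounds.
#' @param scale `"continuous"` or `"ordinal"`.
#' @param drought_only Logical; trait recorded only on drought plots.
#' @return An object of class `trait_spec`.
#' @export
trait_spec <- function(name, units = "", direction = c("higher_better", "lower_better"),
                       bounds = NULL, scale = c("continuous", "ordinal"),
                       drought_only = FALSE) {
  direction <- match.arg(direction)
  scale <- match.arg(scale)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(bounds)) {
    stopifnot(is.numeric(bounds), length(bounds) == 2L, bounds[1] < bounds[2])
    if (scale == "ordinal" && any(bounds != round(bounds)))
      stop("ordinal trait '", name, "' must have integer bounds")
  } else if (scale == "ordinal") {
    stop("ordinal trait '", name, "' requires bounds")
  }
  structure(list(name = name, units = units, direction = direction,
                 bounds = bounds, scale = scale, drought_only = drought_only),
            class = "trait_spec")
}

#' Default trait set for extra-early maize testcross trials
#'
#' Grain yield (kg/ha), days to anthesis and silking, anthesis-silking
#' interval, ears per plant, plant and ear aspect (1-5, lower better),
#' and the 1-9 stay-green score recorded only under drought.
#'
#' @return Named list of [trait_spec()] objects.
#' @export
default_traits <- function() {
  specs <- list(
    trait_spec("yield", "kg/ha", "higher_better"),
    trait_spec("da", "days", "lower_better"),
    trait_spec("ds", "days", "lower_better"),
    trait_spec("asi", "days", "lower_better"),
    trait_spec("epp", "count", "higher_better", bounds = c(0, 5)),
    trait_spec("pasp", "score", "lower_better", bounds = c(1, 5), scale = "ordinal"),
    trait_spec("easp", "score", "lower_better", bounds = c(1, 5), scale = "ordinal"),
    trait_spec("sgc", "score", "lower_better", bounds = c(1, 9), scale = "ordinal",
               drought_only = TRUE)
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Canonical hybrid genotype id
#'
#' Hybrids are identified as `"<line>x<tester>"`, female x male order.
#'
#' @param line,tester Parent identifiers.
#' @return Character vector of genotype ids.
#' @export
hybrid_id <- function(line, tester) paste0(line, "x", tester)

key_columns <- c("environment", "condition", "replicate", "block")

validate_obs <- function(obs, traits, source = "data") {
  trait_names <- intersect(names(traits), names(obs))
  extra <- setdiff(names(obs), c(key_columns, "genotype", "line", "tester", "role",
                                 names(traits)))
  if (length(extra))
    stop(source, ": unknown trait column(s): ", paste(extra, collapse = ", "))
  bad_cond <- !obs$condition %in% c("drought", "rainfed")
  if (any(bad_cond))
    stop(source, ": invalid condition at row ", which(bad_cond)[1])
  for (tn in trait_names) {
    sp <- traits[[tn]]
    if (is.null(sp$bounds)) next
    v <- obs[[tn]]
    bad <- !is.na(v) & (v < sp$bounds[1] | v > sp$bounds[2])
    if (any(bad))
      stop(source, ": trait '", tn, "' out of bounds [", sp$bounds[1], ", ",
           sp$bounds[2], "] at row ", which(bad)[1], " (value ", v[which(bad)[1]], ")")
  }
  key <- paste(obs$environment, obs$replicate, obs$genotype, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(source, ": duplicate (environment, replicate, genotype) at row ", d,
         ": ", obs$environment[d], " / rep ", obs$replicate[d], " / ",
         obs$genotype[d])
  }
  invisible(trait_names)
}

derive_design <- function(obs) {
  hyb <- obs[obs$role == "hybrid", , drop = FALSE]
  lines <- sort(unique(hyb$line))
  testers <- sort(unique(hyb$tester))
  envs <- split(unique(obs[c("environment", "condition")])$environment,
                unique(obs[c("environment", "condition")])$condition)
  r <- max(obs$replicate)
  # balanced: every genotype present in every (environment, replicate) cell,
  # and every line x tester combination present
  cells <- table(obs$genotype, paste(obs$environment, obs$replicate))
  balanced_cells <- nrow(cells) > 0 && all(cells == 1)
  grid_full <- length(lines) == 0 ||
    all(outer(lines, testers, hybrid_id) %in% unique(hyb$genotype))
  list(l = length(lines), t = length(testers), r = r,
       e = vapply(envs, length, 0L),
       lines = lines, testers = testers,
       n_genotypes = length(unique(obs$genotype)),
       balanced = balanced_cells && grid_full)
}

new_trial_dataset <- function(obs, traits, source = "data") {
  stopifnot(is.data.frame(obs))
  miss <- setdiff(key_columns, names(obs))
  if (length(miss))
    stop(source, ": missing required column(s): ", paste(miss, collapse = ", "))
  obs$replicate <- as.integer(obs$replicate)
  if (any(is.na(obs$replicate) | obs$replicate < 1))
    stop(source, ": replicate must be a positive integer")
  validate_obs(obs, traits, source)
  structure(list(obs = obs, traits = traits, design = derive_design(obs)),
            class = "trial_dataset")
}

#' Read a plot-level trial file
#'
#' Long ("tidy") comma-separated layout: one row per plot, key columns
#' `environment, condition, replicate, block`, parent columns `line` and
#' `tester` for hybrids (the genotype id is canonicalized as
#' `"<line>x<tester>"`), a `genotype` column for check entries, and one
#' column per trait. Missing trait cells stay missing; they are never
#' imputed. Lines starting with `#` are comments.
#'
#' @param path File path.
#' @param traits Named list of [trait_spec()]; columns not in this list are
#'   rejected.
#' @return A `trial_dataset`: list with `obs` (validated data frame),
#'   `traits`, and `design` (counts `l`, `t`, `r`, `e` and a `balanced` flag).
#' @export
read_trial <- function(path, traits = default_traits()) {
  raw <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  for (col in c("genotype", "line", "tester"))
    if (!col %in% names(raw)) raw[[col]] <- ""
  raw$line[is.na(raw$line)] <- ""
  raw$tester[is.na(raw$tester)] <- ""
  raw$genotype[is.na(raw$genotype)] <- ""
  is_hyb <- nzchar(raw$line) & nzchar(raw$tester)
  is_chk <- !nzchar(raw$line) & !nzchar(raw$tester) & nzchar(raw$genotype)
  bad <- !(is_hyb | is_chk)
  if (any(bad))
    stop(path, ": row ", which(bad)[1],
         ": need either both line and tester (hybrid) or a genotype id (check)")
  raw$role <- ifelse(is_hyb, "hybrid", "check")
  raw$genotype[is_hyb] <- hybrid_id(raw$line[is_hyb], raw$tester[is_hyb])
  new_trial_dataset(raw, traits, source = path)
}

#' @export
print.trial_dataset <- function(x, ...) {
  d <- x$design
  cat("trial_dataset: ", nrow(x$obs), " plots, ", d$n_genotypes, " genotypes (",
      d$l, " lines x ", d$t, " testers), r = ", d$r, ", environments: ",
      paste(paste0(names(d$e), "=", d$e), collapse = ", "),
      if (d$balanced) ", balanced" else ", unbalanced", "\n", sep = "")
  cat("traits: ", paste(vapply(x$traits, `[[`, "", "name"), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a tabular pipeline result
#'
#' All tabular results (means tables, effect tables, index tables, ANOVA
#' tables, ...) serialize to comma-separated text with a stable column order
#' and round-trip through [read_table_file()] to 12 significant digits.
#'
#' @param x A data frame or a pipeline result with an `as.data.frame` method.
#' @param path Output file path.
#' @export
write_table <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], function(v) {
    s <- formatC(v, digits = 15, format = "g")
    s[is.na(v)] <- ""
    s
  })
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read back a table written by [write_table()]
#' @param path File path.
#' @return A data frame.
#' @export
read_table_file <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
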