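# Multi-trait base selection index for drought tolerance: traits are
# standardized to mean 0 / sd 1 over the indexed population, then combined as
# I = 2*z(yield) + z(EPP) - z(ASI) - z(PASP) - z(EASP) - z(SGC); positive
# values indicate tolerance. The stay-green term exists only under drought,
# so the rain-fed index omits it.

#' Standardize a trait vector
#'
#' `z = (x - mean) / sd` with the sample (n-1) standard deviation.
#'
#' @param x Numeric vector (length >= 2, non-constant).
#' @param trait Optional trait name for error messages.
#' @return Standardized vector with mean 0 and sd 1.
#' @export
standardize <- function(x, trait = NULL) {
  if (length(x) < 2) stop("need at least 2 genotypes to standardize",
                          if (!is.null(trait)) paste0(" '", trait, "'"))
  s <- stats::sd(x)
  if (is.na(s) || s == 0)
    stop("zero spread: cannot standardize trait",
         if (!is.null(trait)) paste0(" '", trait, "'") else "")
  (x - mean(x)) / s
}

index_weights <- function(condition) {
  w <- c(yield = 2, epp = 1, asi = -1, pasp = -1, easp = -1, sgc = -1)
  if (condition == "rainfed") w <- w[names(w) != "sgc"]
  w
}

#' Base drought-tolerance index
#'
#' Standardizes each component trait over the supplied population and
#' combines them; under drought
#' `I = 2 z_yield + z_epp - z_asi - z_pasp - z_easp - z_sgc`, under rain-fed
#' conditions the stay-green term is dropped (it is scored only on stressed
#' plots). Higher index = better. Ranks break ties by the yield z-score,
#' then genotype id.
#'
#' @param means Data frame of per-genotype condition means with a `genotype`
#'   column and the required trait columns.
#' @param condition `"drought"` or `"rainfed"`.
#' @return An `index_table` data frame: genotype, `z_<trait>` columns,
#'   `index`, `rank`, `selected` (all `"none"`).
#' @export
base_index <- function(means, condition = c("drought", "rainfed")) {
  condition <- match.arg(condition)
  stopifnot(is.data.frame(means), "genotype" %in% names(means))
  w <- index_weights(condition)
  missing_tr <- setdiff(names(w), names(means))
  if (length(missing_tr))
    stop("missing required trait column(s) for the ", condition, " index: ",
         paste(missing_tr, collapse = ", "))
  z <- vapply(names(w), function(tr) standardize(means[[tr]], tr),
              numeric(nrow(means)))
  idx <- as.vector(z %*% w)
  out <- data.frame(genotype = means$genotype, stringsAsFactors = FALSE)
  for (tr in names(w)) out[[paste0("z_", tr)]] <- z[, tr]
  out$index <- idx
  ord <- order(-out$index, -out$z_yield, out$genotype)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  out$selected <- "none"
  structure(out[order(out$rank), ], condition = condition,
            class = c("index_table", "data.frame"))
}

#' Flag the best and worst entries of an index table
#'
#' @param index An `index_table` from [base_index()].
#' @param n_best,n_worst Counts of entries to flag `"best"` / `"worst"`
#'   (defaults follow the 26 + 9 selection applied to the full trial).
#' @return The table with its `selected` column filled in.
#' @export
select_extremes <- function(index, n_best = 26, n_worst = 9) {
  stopifnot(inherits(index, "index_table"), n_best >= 0, n_worst >= 0)
  n <- nrow(index)
  if (n_best + n_worst > n)
    stop("n_best + n_worst (", n_best + n_worst, ") exceeds population size (",
         n, ")")
  index$selected <- "none"
  if (n_best > 0) index$selected[index$rank <= n_best] <- "best"
  if (n_worst > 0) index$selected[index$rank > n - n_worst] <- "worst"
  index
}
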