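# Genotype least-squares means, randomized-block ANOVA in the conventional
# multi-environment trial layout (E, Rep(E), Block(E x Rep), G, G x E, Error),
# variance components by the expected-mean-squares method of moments, hybrid-
# mean repeatability, coefficient of variation, and trait correlations.

subset_condition <- function(data, condition) {
  if (is.null(condition) || identical(condition, "across")) return(data$obs)
  data$obs[data$obs$condition == condition, , drop = FALSE]
}

# least-squares genotype means within one stratum: genotype + nuisance
# factors with sum-to-zero contrasts, so each genotype coefficient is its
# mean at the average nuisance level (equal to the arithmetic mean when the
# stratum is balanced)
ls_means_stratum <- function(df, trait) {
  df <- df[!is.na(df[[trait]]), , drop = FALSE]
  genos <- sort(unique(df$genotype))
  if (!nrow(df)) return(data.frame(genotype = character(), mean = numeric(),
                                   n = integer()))
  y <- df[[trait]]
  G <- factor(df$genotype, levels = genos)
  terms <- list()
  add_nuis <- function(f) {
    f <- droplevels(factor(f))
    if (nlevels(f) > 1) terms[[length(terms) + 1]] <<- f
    terms
  }
  terms <- add_nuis(df$environment)
  terms <- add_nuis(paste(df$environment, df$replicate))
  terms <- add_nuis(paste(df$environment, df$replicate, df$block))
  X <- vapply(genos, function(g) as.numeric(G == g), numeric(length(y)))
  if (!is.matrix(X)) X <- matrix(X, nrow = length(y))
  for (f in terms) {
    Cm <- stats::contr.sum(nlevels(f))
    X <- cbind(X, Cm[as.integer(f), , drop = FALSE])
  }
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients[seq_along(genos)]
  data.frame(genotype = genos, mean = unname(cf),
             n = as.integer(table(G)), stringsAsFactors = FALSE)
}

#' Least-squares genotype means
#'
#' Adjusted genotype means from an additive fixed-effect description
#' (genotype + environment + replicate within environment + incomplete block
#' within replicate). With balanced data these equal the arithmetic cell
#' means; with unbalanced data they are the usual normal-equations solution.
#' A genotype absent from a stratum gets a missing cell, never a fabricated
#' value; statistics use complete-case plots for the requested trait only.
#'
#' @param data A `trial_dataset`.
#' @param trait Trait name.
#' @param level `"per_condition"` (one mean per genotype and condition),
#'   `"per_environment"`, or `"across"` (all environments pooled).
#' @return A `means_table` data frame with columns `genotype`, `unit`,
#'   `mean`, `n` plus parent metadata (`line`, `tester`, `role`).
#' @export
ls_means <- function(data, trait, level = c("per_condition", "per_environment", "across")) {
  level <- match.arg(level)
  stopifnot(inherits(data, "trial_dataset"))
  if (!trait %in% names(data$obs)) stop("trait '", trait, "' not in dataset")
  obs <- data$obs
  units <- switch(level,
    per_condition = split(obs, obs$condition),
    per_environment = split(obs, obs$environment),
    across = list(across = obs))
  res <- lapply(names(units), function(u) {
    m <- ls_means_stratum(units[[u]], trait)
    # flag genotypes absent from this stratum as missing cells
    absent <- setdiff(unique(obs$genotype), m$genotype)
    if (length(absent))
      m <- rbind(m, data.frame(genotype = absent, mean = NA_real_, n = 0L))
    m$unit <- u
    m
  })
  out <- do.call(rbind, res)
  meta <- unique(obs[c("genotype", "line", "tester", "role")])
  out <- merge(out, meta, by = "genotype", sort = TRUE)
  out <- out[order(out$unit, out$genotype), c("genotype", "unit", "mean", "n",
                                              "line", "tester", "role")]
  rownames(out) <- NULL
  structure(out, trait = trait, level = level,
            class = c("means_table", "data.frame"))
}

#' Genotype x environment mean matrix
#'
#' Reshapes a `per_environment` means table into the genotype x environment
#' matrix consumed by the biplot functions.
#'
#' @param means A `means_table` at `per_environment` level.
#' @param genotypes Optional subset/order of genotypes.
#' @return Numeric matrix, genotypes in rows.
#' @export
means_matrix <- function(means, genotypes = NULL) {
  stopifnot(inherits(means, "means_table"))
  w <- stats::reshape(as.data.frame(means)[c("genotype", "unit", "mean")],
                      idvar = "genotype", timevar = "unit", direction = "wide")
  M <- as.matrix(w[, -1, drop = FALSE])
  rownames(M) <- w$genotype
  colnames(M) <- sub("^mean\\.", "", colnames(M))
  if (!is.null(genotypes)) M <- M[genotypes, , drop = FALSE]
  M[order(rownames(M)), order(colnames(M)), drop = FALSE]
}

check_balanced <- function(obs, trait, what = "analysis") {
  ok <- !is.na(obs[[trait]])
  obs <- obs[ok, , drop = FALSE]
  cells <- table(obs$genotype, paste(obs$environment, obs$replicate, sep = "/"))
  if (!all(cells == 1))
    stop(what, " requires a balanced design (every genotype in every ",
         "environment x replicate exactly once); found counts other than 1. ",
         "Use ls_means() for a stage-wise analysis of unbalanced data.")
  obs
}

#' Multi-environment trial ANOVA
#'
#' Sequential (Type I) decomposition over the conventional sources
#' Environment, Rep(E), Block(E x Rep), Genotype, G x E, Error for one
#' research condition or across conditions. F-tests follow the
#' random-environment convention: Genotype is tested against the G x E mean
#' square; G x E, blocks and reps against Error; Environment against Rep(E).
#' Balanced data only -- unbalanced data are refused with a pointer to
#' [ls_means()].
#'
#' @param data A `trial_dataset`.
#' @param trait Trait name.
#' @param scope `"drought"`, `"rainfed"`, or `"across"`.
#' @return An `anova_table` data frame (source, df, ss, mean_square, f_value,
#'   p_value) with attributes `grand_mean`, `r`, `e`, `g`.
#' @export
trial_anova <- function(data, trait, scope = c("drought", "rainfed", "across")) {
  scope <- match.arg(scope)
  stopifnot(inherits(data, "trial_dataset"))
  obs <- subset_condition(data, scope)
  if (!nrow(obs)) stop("no observations for scope '", scope, "'")
  obs <- check_balanced(obs, trait, "trial_anova")
  y <- obs[[trait]]
  env <- factor(obs$environment)
  e <- nlevels(env)
  g_f <- factor(obs$genotype)
  g <- nlevels(g_f)
  if (g < 2) stop("need at least 2 genotypes")
  rep_f <- factor(paste(obs$environment, obs$replicate, sep = "/"))
  r <- nlevels(rep_f) / e
  blk_f <- factor(paste(obs$environment, obs$replicate, obs$block, sep = "/"))
  has_blocks <- nlevels(blk_f) > nlevels(rep_f)

  gm <- mean(y)
  ss_tot <- sum((y - gm)^2)
  if (!has_blocks) {
    # closed-form balanced decomposition
    m_env <- tapply(y, env, mean)
    m_rep <- tapply(y, rep_f, mean)
    rep_env <- tapply(as.character(env), rep_f, `[`, 1)
    m_g <- tapply(y, g_f, mean)
    m_ge <- tapply(y, list(g_f, env), mean)
    ss_e <- g * r * sum((m_env - gm)^2)
    ss_rep <- g * sum((m_rep - m_env[rep_env])^2)
    ss_g <- e * r * sum((m_g - gm)^2)
    ss_ge <- r * sum((sweep(sweep(m_ge, 1, m_g), 2, m_env) + gm)^2)
    ss_blk <- 0
    df_blk <- 0
  } else {
    # sequential projections: E, Rep(E), Block, G, G x E
    X0 <- matrix(1, length(y))
    seq_ss <- function(X_prev, add) {
      X <- cbind(X_prev, add)
      fit <- stats::lm.fit(X, y)
      list(X = X, rss = sum(fit$residuals^2))
    }
    dm <- function(f) stats::model.matrix(~f)[, -1, drop = FALSE]
    rss0 <- sum((y - gm)^2)
    s1 <- seq_ss(X0, dm(env));          ss_e <- rss0 - s1$rss
    s2 <- seq_ss(s1$X, dm(rep_f));      ss_rep <- s1$rss - s2$rss
    s3 <- seq_ss(s2$X, dm(blk_f));      ss_blk <- s2$rss - s3$rss
    s4 <- seq_ss(s3$X, dm(g_f));        ss_g <- s3$rss - s4$rss
    s5 <- seq_ss(s4$X, dm(interaction(g_f, env))); ss_ge <- s4$rss - s5$rss
    df_blk <- nlevels(blk_f) - nlevels(rep_f)
  }
  df_e <- e - 1
  df_rep <- e * (r - 1)
  df_g <- g - 1
  df_ge <- (g - 1) * (e - 1)
  ss_err <- ss_tot - ss_e - ss_rep - ss_blk - ss_g - ss_ge
  df_err <- length(y) - 1 - df_e - df_rep - df_blk - df_g - df_ge
  src <- data.frame(
    source = c("E", "Rep(E)", "Block(ExRep)", "G", "GxE", "Error"),
    df = c(df_e, df_rep, df_blk, df_g, df_ge, df_err),
    ss = c(ss_e, ss_rep, ss_blk, ss_g, ss_ge, ss_err),
    stringsAsFactors = FALSE)
  src <- src[src$df >= 1, , drop = FALSE]
  src$mean_square <- src$ss / src$df
  ms <- function(s) src$mean_square[match(s, src$source)]
  dfof <- function(s) src$df[match(s, src$source)]
  fv <- pv <- rep(NA_real_, nrow(src))
  den <- list(E = "Rep(E)", `Rep(E)` = "Error", `Block(ExRep)` = "Error",
              G = "GxE", GxE = "Error")
  for (i in seq_len(nrow(src))) {
    s <- src$source[i]
    if (s == "Error" || is.null(den[[s]]) || is.na(ms(den[[s]]))) next
    fv[i] <- src$mean_square[i] / ms(den[[s]])
    pv[i] <- stats::pf(fv[i], src$df[i], dfof(den[[s]]), lower.tail = FALSE)
  }
  src$f_value <- fv
  src$p_value <- pv
  rownames(src) <- NULL
  structure(src, scope = scope, trait = trait, grand_mean = gm,
            r = r, e = e, g = g, class = c("anova_table", "data.frame"))
}

#' Variance components from an ANOVA table
#'
#' Expected-mean-squares method of moments for the balanced random-
#' environment layout: `sigma2_error = MS_Error`,
#' `sigma2_GE = (MS_GxE - MS_Error) / r`,
#' `sigma2_G = (MS_G - MS_GxE) / (r e)`. Negative solutions are truncated to
#' zero with a warning. Identical to REML for the balanced complete case.
#'
#' @param anova An `anova_table` containing G, GxE and Error rows.
#' @param r,e Replicates and environments; default from the table.
#' @return A `variance_components` list (`sigma2_G`, `sigma2_GE`,
#'   `sigma2_error`, `r`, `e`, `method`, `truncated`).
#' @export
variance_components <- function(anova, r = attr(anova, "r"), e = attr(anova, "e")) {
  need <- c("G", "GxE", "Error")
  miss <- setdiff(need, anova$source)
  if (length(miss)) stop("anova table lacks source row(s): ",
                         paste(miss, collapse = ", "))
  ms <- stats::setNames(anova$mean_square, anova$source)
  raw <- c(sigma2_G = (ms[["G"]] - ms[["GxE"]]) / (r * e),
           sigma2_GE = (ms[["GxE"]] - ms[["Error"]]) / r,
           sigma2_error = ms[["Error"]])
  trunc <- names(raw)[raw < 0]
  if (length(trunc))
    warning("negative variance component(s) truncated to zero: ",
            paste(trunc, collapse = ", "))
  out <- pmax(raw, 0)
  structure(list(sigma2_G = out[["sigma2_G"]], sigma2_GE = out[["sigma2_GE"]],
                 sigma2_error = out[["sigma2_error"]], r = r, e = e,
                 method = "ems_mom", truncated = trunc),
            class = "variance_components")
}

#' Hybrid-mean repeatability
#'
#' `R = sigma2_G / (sigma2_G + sigma2_GE / e + sigma2_error / (r e))`, the
#' proportion of entry-mean variance that is genotypic; 0 when the genotypic
#' variance is 0.
#'
#' @param vc A [variance_components()] result.
#' @return Number in \[0, 1\].
#' @export
repeatability <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  if (is.null(vc$r) || is.null(vc$e) || vc$r < 1 || vc$e < 1)
    stop("repeatability needs r >= 1 and e >= 1")
  if (vc$sigma2_G == 0) return(0)
  vc$sigma2_G / (vc$sigma2_G + vc$sigma2_GE / vc$e +
                 vc$sigma2_error / (vc$r * vc$e))
}

#' Coefficient of variation (%)
#'
#' `100 * sqrt(MS_Error) / grand_mean`.
#'
#' @param anova An `anova_table` with an Error row.
#' @param grand_mean Positive trial mean; defaults to the table's fitted
#'   grand mean.
#' @return CV in percent.
#' @export
cv_percent <- function(anova, grand_mean = attr(anova, "grand_mean")) {
  if (is.null(grand_mean) || is.na(grand_mean) || grand_mean <= 0)
    stop("grand_mean must be > 0")
  ms_err <- anova$mean_square[anova$source == "Error"]
  if (!length(ms_err)) stop("anova table lacks an Error row")
  100 * sqrt(ms_err) / grand_mean
}

#' Pearson correlations between trait means
#'
#' Correlations of genotype means within one research condition, as used for
#' descriptive trait-association tables. Zero-variance traits yield NA cells
#' with a warning.
#'
#' @param data A `trial_dataset`.
#' @param traits Character vector of trait names (>= 2).
#' @param condition `"drought"` or `"rainfed"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
trait_correlations <- function(data, traits, condition = "drought") {
  stopifnot(length(traits) >= 2)
  tabs <- lapply(traits, function(tr) {
    m <- ls_means(data, tr, "per_condition")
    m <- m[m$unit == condition, c("genotype", "mean")]
    names(m)[2] <- tr
    m
  })
  wide <- Reduce(function(a, b) merge(a, b, by = "genotype"), tabs)
  if (nrow(wide) < 3) stop("need at least 3 genotypes")
  X <- as.matrix(wide[, traits, drop = FALSE])
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning("zero-variance trait(s): ",
            paste(traits[which(sds == 0)], collapse = ", "))
  suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
}
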