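# Line x tester combining-ability analysis: GCA effects of lines (females)
# and testers (males), SCA effects of crosses, their mean squares and
# environment interactions, standard errors, significance, and the Baker
# proportion of additive (GCA) to total combining-ability variance.

# line x tester cell-mean matrix from a per_condition means table
lt_matrix <- function(means, condition = NULL) {
  stopifnot(inherits(means, "means_table"))
  df <- as.data.frame(means)
  if (!is.null(condition)) df <- df[df$unit == condition, , drop = FALSE]
  df <- df[df$role == "hybrid", , drop = FALSE]
  if (length(unique(df$unit)) > 1)
    stop("means span several units; pass condition= to pick one")
  lines <- sort(unique(df$line))
  testers <- sort(unique(df$tester))
  M <- matrix(NA_real_, length(lines), length(testers),
              dimnames = list(lines, testers))
  M[cbind(match(df$line, lines), match(df$tester, testers))] <- df$mean
  if (anyNA(M)) {
    idx <- which(is.na(M), arr.ind = TRUE)
    stop("incomplete line x tester grid; missing pair(s): ",
         paste(hybrid_id(lines[idx[, 1]], testers[idx[, 2]]), collapse = ", "))
  }
  M
}

#' General combining ability effects
#'
#' Line effect = line marginal mean - grand mean; tester effect = tester
#' marginal mean - grand mean, each computed from the complete balanced line
#' x tester grid of condition-level hybrid means. Both vectors sum to zero.
#'
#' @param means A `means_table` at `per_condition` level (hybrids), or a
#'   line x tester numeric matrix.
#' @param condition Condition to select when `means` covers several.
#' @return List with `line`, `tester` (named effect vectors), `grand_mean`,
#'   `l`, `t`.
#' @export
gca_effects <- function(means, condition = NULL) {
  M <- if (is.matrix(means)) means else lt_matrix(means, condition)
  if (anyNA(M)) stop("incomplete line x tester grid")
  gm <- mean(M)
  list(line = rowMeans(M) - gm, tester = colMeans(M) - gm,
       grand_mean = gm, l = nrow(M), t = ncol(M))
}

#' Specific combining ability effects
#'
#' `SCA_ij = cell mean - line mean - tester mean + grand mean`. Every row
#' and column of the returned matrix sums to zero.
#'
#' @inheritParams gca_effects
#' @return Numeric line x tester matrix of SCA effects.
#' @export
sca_effects <- function(means, condition = NULL) {
  M <- if (is.matrix(means)) means else lt_matrix(means, condition)
  if (anyNA(M)) stop("incomplete line x tester grid")
  gm <- mean(M)
  sweep(sweep(M, 1, rowMeans(M)), 2, colMeans(M)) + gm
}

#' Line x tester mean squares
#'
#' Partitions the hybrid variation of balanced plot-level data within one
#' research condition into GCA of lines, GCA of testers and SCA, with their
#' environment-interaction counterparts, using the orthogonal balanced
#' decomposition (`SS_GCA_LINE + SS_GCA_TESTER + SS_SCA = SS_Hybrid`
#' exactly). Incomplete-block variation, if present, is left in Error.
#' F-ratios follow the random-environment convention: each genetic term is
#' tested against its own environment interaction, interactions against
#' Error.
#'
#' @param data A `trial_dataset` (hybrid entries are used; checks ignored).
#' @param trait Trait name.
#' @param condition `"drought"` or `"rainfed"`.
#' @return A `ca_anova` data frame (source, df, ss, mean_square, f_value,
#'   p_value) with attributes `l`, `t`, `r`, `e`, `grand_mean`.
#' @export
ca_mean_squares <- function(data, trait, condition = "drought") {
  stopifnot(inherits(data, "trial_dataset"))
  obs <- subset_condition(data, condition)
  obs <- obs[obs$role == "hybrid" & !is.na(obs[[trait]]), , drop = FALSE]
  if (!nrow(obs)) stop("no hybrid observations for condition '", condition, "'")
  lines <- sort(unique(obs$line)); testers <- sort(unique(obs$tester))
  l <- length(lines); t_ <- length(testers)
  env <- sort(unique(obs$environment)); e <- length(env)
  r <- max(obs$replicate)
  cnt <- table(obs$line, obs$tester, obs$environment, obs$replicate)
  if (!all(cnt == 1))
    stop("ca_mean_squares requires balanced plot data ",
         "(every line x tester x environment x replicate exactly once)")
  y <- obs[[trait]]
  li <- factor(obs$line, lines); ti <- factor(obs$tester, testers)
  ei <- factor(obs$environment, env)
  gm <- mean(y)
  m_l <- tapply(y, li, mean); m_t <- tapply(y, ti, mean); m_e <- tapply(y, ei, mean)
  m_lt <- tapply(y, list(li, ti), mean)
  m_le <- tapply(y, list(li, ei), mean)
  m_te <- tapply(y, list(ti, ei), mean)
  m_lte <- tapply(y, list(li, ti, ei), mean)
  rep_f <- factor(paste(obs$environment, obs$replicate, sep = "/"))
  m_rep <- tapply(y, rep_f, mean)
  rep_env <- tapply(as.character(ei), rep_f, `[`, 1)

  dev_lt <- sweep(sweep(m_lt, 1, m_l), 2, m_t) + gm
  dev_le <- sweep(sweep(m_le, 1, m_l), 2, m_e) + gm
  dev_te <- sweep(sweep(m_te, 1, m_t), 2, m_e) + gm
  dev_lte <- m_lte
  for (kk in seq_len(e))
    dev_lte[, , kk] <- m_lte[, , kk] - dev_lt - dev_le[, kk] -
      outer(rep(1, l), dev_te[, kk]) - outer(m_l, rep(1, t_)) -
      outer(rep(1, l), m_t) - m_e[kk] + 2 * gm

  ss <- c(E = l * t_ * r * sum((m_e - gm)^2),
          `Rep(E)` = l * t_ * sum((m_rep - m_e[rep_env])^2),
          GCA_LINE = t_ * r * e * sum((m_l - gm)^2),
          GCA_TESTER = l * r * e * sum((m_t - gm)^2),
          SCA = r * e * sum(dev_lt^2),
          ExGCA_LINE = t_ * r * sum(dev_le^2),
          ExGCA_TESTER = l * r * sum(dev_te^2),
          ExSCA = r * sum(dev_lte^2))
  df <- c(E = e - 1, `Rep(E)` = e * (r - 1),
          GCA_LINE = l - 1, GCA_TESTER = t_ - 1, SCA = (l - 1) * (t_ - 1),
          ExGCA_LINE = (l - 1) * (e - 1), ExGCA_TESTER = (t_ - 1) * (e - 1),
          ExSCA = (l - 1) * (t_ - 1) * (e - 1))
  ss_tot <- sum((y - gm)^2)
  ss <- c(ss, Error = ss_tot - sum(ss))
  df <- c(df, Error = length(y) - 1 - sum(df))
  keep <- df >= 1
  out <- data.frame(source = names(ss)[keep], df = unname(df[keep]),
                    ss = unname(ss[keep]), stringsAsFactors = FALSE)
  out$mean_square <- out$ss / out$df
  den <- c(E = "Rep(E)", `Rep(E)` = "Error",
           GCA_LINE = "ExGCA_LINE", GCA_TESTER = "ExGCA_TESTER", SCA = "ExSCA",
           ExGCA_LINE = "Error", ExGCA_TESTER = "Error", ExSCA = "Error")
  out$f_value <- out$p_value <- NA_real_
  for (i in seq_len(nrow(out))) {
    dsrc <- den[out$source[i]]
    j <- match(dsrc, out$source)
    if (is.na(dsrc) || is.na(j)) next
    out$f_value[i] <- out$mean_square[i] / out$mean_square[j]
    out$p_value[i] <- stats::pf(out$f_value[i], out$df[i], out$df[j],
                                lower.tail = FALSE)
  }
  structure(out, l = l, t = t_, r = r, e = e, grand_mean = gm,
            trait = trait, condition = condition,
            class = c("ca_anova", "data.frame"))
}

ca_ms <- function(ms, source) {
  v <- ms$mean_square[match(source, ms$source)]
  if (is.na(v)) stop("mean-squares table lacks source '", source, "'")
  v
}

#' Baker's proportion of combining-ability variance
#'
#' Relative importance of additive (GCA) over non-additive (SCA) variation,
#' `2 sigma2_GCA / (2 sigma2_GCA + sigma2_SCA)`, with the variance
#' components solved from expected mean squares after subtracting the
#' corresponding environment-interaction mean squares (the interaction
#' correction of the Hung & Holland modification):
#' `sigma2_gca_line = (MS_L - MS_ExL)/(r t e)`,
#' `sigma2_gca_tester = (MS_T - MS_ExT)/(r l e)`,
#' `sigma2_sca = (MS_SCA - MS_ExSCA)/(r e)`, negatives truncated to zero,
#' and `2 sigma2_GCA` taken as the line + tester component sum. A value near
#' 1 indicates predominantly additive inheritance. `method = "baker_ms"`
#' gives the unmodified mean-square ratio
#' `(MS_L + MS_T) / (MS_L + MS_T + MS_SCA)`.
#'
#' @param ms A `ca_anova` table from [ca_mean_squares()].
#' @param design Optional list with `l`, `t`, `r`, `e`; defaults to the
#'   table's attributes.
#' @param method `"component_based"` (default) or `"baker_ms"`.
#' @return Proportion in \[0, 1\], or NA when all components are zero.
#' @export
baker_proportion <- function(ms, design = NULL,
                             method = c("component_based", "baker_ms")) {
  method <- match.arg(method)
  if (is.null(design))
    design <- list(l = attr(ms, "l"), t = attr(ms, "t"),
                   r = attr(ms, "r"), e = attr(ms, "e"))
  if (method == "baker_ms") {
    num <- ca_ms(ms, "GCA_LINE") + ca_ms(ms, "GCA_TESTER")
    den <- num + ca_ms(ms, "SCA")
    if (den == 0) return(NA_real_)
    return(min(max(num / den, 0), 1))
  }
  r <- design$r; e <- design$e; l <- design$l; t_ <- design$t
  s_line <- max((ca_ms(ms, "GCA_LINE") - ca_ms(ms, "ExGCA_LINE")) / (r * t_ * e), 0)
  s_test <- max((ca_ms(ms, "GCA_TESTER") - ca_ms(ms, "ExGCA_TESTER")) / (r * l * e), 0)
  s_sca <- max((ca_ms(ms, "SCA") - ca_ms(ms, "ExSCA")) / (r * e), 0)
  two_gca <- s_line + s_test
  if (two_gca + s_sca == 0) return(NA_real_)
  min(max(two_gca / (two_gca + s_sca), 0), 1)
}

#' Significance of combining-ability effects
#'
#' Two-sided t-test of effect / SE on the Error degrees of freedom, with the
#' usual star annotation (`*` at 0.05, `**` at 0.01).
#'
#' @param effects Numeric vector of effects.
#' @param se Positive standard error(s), length 1 or matching `effects`.
#' @param error_df Error degrees of freedom (>= 1).
#' @return Data frame with `effect`, `se`, `t`, `p`, `stars`.
#' @export
effect_significance <- function(effects, se, error_df) {
  if (any(se <= 0)) stop("se must be > 0")
  if (error_df < 1) stop("error_df must be >= 1")
  tval <- effects / se
  p <- 2 * stats::pt(-abs(tval), error_df)
  stars <- ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
  data.frame(effect = unname(effects), se = se, t = unname(tval),
             p = unname(p), stars = stars,
             row.names = names(effects) %||% NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full combining-ability analysis for one trait and condition
#'
#' Runs [ls_means()] at condition level, [gca_effects()], [sca_effects()],
#' [ca_mean_squares()] and [baker_proportion()], and attaches standard
#' errors and t-tests. Effect standard errors use the balanced line x
#' tester forms with `sigma2 = MS_Error`:
#' `Var(g_line) = sigma2 (l-1)/(l t r e)`,
#' `Var(g_tester) = sigma2 (t-1)/(l t r e)`,
#' `Var(sca) = sigma2 (l-1)(t-1)/(l t r e)`.
#'
#' @param data A `trial_dataset` with balanced plot-level hybrid data.
#' @param trait Trait name.
#' @param condition `"drought"` or `"rainfed"`.
#' @return A `combining_ability` object: lists `gca_line`, `gca_tester`,
#'   `sca` (with SEs, p, stars), the `mean_squares` table, and
#'   `baker_proportion`.
#' @export
combining_ability <- function(data, trait, condition = "drought") {
  means <- ls_means(data, trait, "per_condition")
  M <- lt_matrix(means, condition)
  g <- gca_effects(M)
  s <- sca_effects(M)
  ms <- ca_mean_squares(data, trait, condition)
  l <- g$l; t_ <- g$t
  r <- attr(ms, "r"); e <- attr(ms, "e")
  s2 <- ca_ms(ms, "Error")
  df_err <- ms$df[ms$source == "Error"]
  n <- l * t_ * r * e
  se_line <- sqrt(s2 * (l - 1) / n)
  se_test <- sqrt(s2 * (t_ - 1) / n)
  se_sca <- sqrt(s2 * (l - 1) * (t_ - 1) / n)
  sca_df <- data.frame(line = rep(rownames(s), ncol(s)),
                       tester = rep(colnames(s), each = nrow(s)),
                       stringsAsFactors = FALSE)
  sca_sig <- effect_significance(as.vector(s), se_sca, df_err)
  structure(list(
    trait = trait, condition = condition,
    gca_line = cbind(parent = rownames(s),
                     effect_significance(g$line, se_line, df_err)),
    gca_tester = cbind(parent = colnames(s),
                       effect_significance(g$tester, se_test, df_err)),
    sca = cbind(sca_df, sca_sig),
    grand_mean = g$grand_mean,
    mean_squares = ms,
    baker_proportion = baker_proportion(ms),
    design = list(l = l, t = t_, r = r, e = e, error_df = df_err)),
    class = "combining_ability")
}

#' @export
as.data.frame.combining_ability <- function(x, ...) {
  rbind(
    data.frame(parent = x$gca_line$parent, role = "line", trait = x$trait,
               effect = x$gca_line$effect, se = x$gca_line$se,
               p = x$gca_line$p, stars = x$gca_line$stars),
    data.frame(parent = x$gca_tester$parent, role = "tester", trait = x$trait,
               effect = x$gca_tester$effect, se = x$gca_tester$se,
               p = x$gca_tester$p, stars = x$gca_tester$stars),
    data.frame(parent = hybrid_id(x$sca$line, x$sca$tester), role = "sca",
               trait = x$trait, effect = x$sca$effect, se = x$sca$se,
               p = x$sca$p, stars = x$sca$stars))
}

#' @export
print.combining_ability <- function(x, ...) {
  cat("combining_ability:", x$trait, "/", x$condition, "\n")
  cat("  l =", x$design$l, " t =", x$design$t, " r =", x$design$r,
      " e =", x$design$e, "\n")
  cat("  Baker proportion (component-based):",
      format(x$baker_proportion, digits = 3), "\n")
  invisible(x)
}
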