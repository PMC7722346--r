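# Tester-defined heterotic grouping. A line joins the heterotic group of a
# tester with which it shows a significant NEGATIVE SCA effect (poor specific
# combination indicates shared background), provided it also shows a
# significant positive SCA with another tester and its testcross yield with
# some significant-positive tester clears that tester's grand mean by at
# least one standard error. Lines with no significant SCA pattern stay
# unclassified.

sig_levels <- c("ns", "p05", "p01")

#' Testcross summary table
#'
#' Holds, for every line x tester pair, the testcross mean yield, the SCA
#' effect and its significance flag, plus per-tester grand means and
#' standard errors -- either digitized from a published table or computed
#' from a [combining_ability()] result.
#'
#' @param mean_yield,sca Numeric line x tester matrices (shared dimnames).
#' @param sig Character matrix with entries `"ns"`, `"p05"`, `"p01"`.
#' @param tester_grand_mean Named vector of per-tester testcross grand means.
#' @param se_mean Named vector of standard errors of a tester mean (> 0).
#' @param sca_se Standard error of an SCA effect (> 0), length 1 or per
#'   tester.
#' @param sig_source `"digitized"` or `"computed"`.
#' @return A `testcross_table`.
#' @export
testcross_table <- function(mean_yield, sca, sig, tester_grand_mean, se_mean,
                            sca_se = NA_real_,
                            sig_source = c("digitized", "computed")) {
  sig_source <- match.arg(sig_source)
  stopifnot(is.matrix(mean_yield), is.matrix(sca),
            identical(dim(mean_yield), dim(sca)),
            identical(dim(mean_yield), dim(sig)))
  if (!all(sig[!is.na(sig)] %in% sig_levels))
    stop("sig entries must be one of: ", paste(sig_levels, collapse = ", "))
  testers <- colnames(mean_yield)
  stopifnot(all(testers %in% names(tester_grand_mean)),
            all(testers %in% names(se_mean)))
  if (any(se_mean[testers] <= 0)) stop("standard errors must be > 0")
  # each present pair must have all three of mean, sca, significance
  pres <- !is.na(mean_yield)
  if (any(pres & (is.na(sca) | is.na(sig))))
    stop("every present (line, tester) pair needs mean, sca and significance")
  structure(list(lines = rownames(mean_yield), testers = testers,
                 mean_yield = mean_yield, sca = sca, sig = sig,
                 tester_grand_mean = tester_grand_mean[testers],
                 se_mean = se_mean[testers], sca_se = sca_se,
                 sig_source = sig_source),
            class = "testcross_table")
}

#' Read a testcross file
#'
#' Long CSV with columns `line, tester, mean_yield, sca, sig`; rows whose
#' `line` is `"Mean"` carry the tester grand means, rows with `"SE"` the
#' standard error of a tester mean (`mean_yield` column) and of an SCA
#' effect (`sca` column).
#'
#' @param path File path.
#' @return A [testcross_table()].
#' @export
read_testcross <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("line", "tester", "mean_yield", "sca", "sig")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  special <- df$line %in% c("Mean", "SE")
  body <- df[!special, , drop = FALSE]
  lines <- unique(body$line); testers <- unique(df$tester)
  mk <- function(col, rows = body) {
    M <- matrix(NA_real_, length(lines), length(testers),
                dimnames = list(lines, testers))
    M[cbind(match(rows$line, lines), match(rows$tester, testers))] <- rows[[col]]
    M
  }
  mean_yield <- mk("mean_yield")
  sca <- mk("sca")
  sig <- matrix(NA_character_, length(lines), length(testers),
                dimnames = list(lines, testers))
  sig[cbind(match(body$line, lines), match(body$tester, testers))] <- body$sig
  mrow <- df[df$line == "Mean", , drop = FALSE]
  serow <- df[df$line == "SE", , drop = FALSE]
  if (!nrow(mrow) || !nrow(serow))
    stop(path, ": needs 'Mean' and 'SE' rows for the tester summaries")
  testcross_table(mean_yield, sca, sig,
                  stats::setNames(mrow$mean_yield, mrow$tester),
                  stats::setNames(serow$mean_yield, serow$tester),
                  sca_se = stats::setNames(serow$sca, serow$tester),
                  sig_source = "digitized")
}

#' Build a testcross table from a combining-ability result
#'
#' Uses the analysis' testcross means, SCA effects and their t-test
#' p-values; the standard error of a tester mean is `sqrt(MS_Error / (l r
#' e))`.
#'
#' @param ca A [combining_ability()] result.
#' @param means The condition-level `means_table` the analysis was run on.
#' @return A [testcross_table()] with `sig_source = "computed"`.
#' @export
as_testcross_table <- function(ca, means) {
  M <- lt_matrix(means, ca$condition)
  s <- ca$sca
  sca_m <- sig_m <- matrix(NA, nrow(M), ncol(M), dimnames = dimnames(M))
  sca_m[cbind(match(s$line, rownames(M)), match(s$tester, colnames(M)))] <- s$effect
  sig_chr <- ifelse(s$p < 0.01, "p01", ifelse(s$p < 0.05, "p05", "ns"))
  sig_m[cbind(match(s$line, rownames(M)), match(s$tester, colnames(M)))] <- sig_chr
  d <- ca$design
  s2 <- ca_ms(ca$mean_squares, "Error")
  se_mean <- stats::setNames(rep(sqrt(s2 / (d$l * d$r * d$e)), d$t), colnames(M))
  testcross_table(M, sca_m, sig_m,
                  tester_grand_mean = colMeans(M), se_mean = se_mean,
                  sca_se = unique(s$se)[1], sig_source = "computed")
}

is_significant <- function(sig, alpha) {
  if (alpha >= 0.05) sig %in% c("p05", "p01") else sig == "p01"
}

#' Classify lines into tester heterotic groups
#'
#' A line is classified into the group of the tester with which it has a
#' significant negative SCA effect if and only if (a) it has at least one
#' significant negative SCA, (b) a significant positive SCA with another
#' tester, and (c) its testcross mean yield with some significant-positive
#' tester is at least one standard error above that tester's grand mean.
#' With several significant negatives the most negative wins and the trace
#' notes the ambiguity. Lines with missing tester cells are judged on the
#' remaining testers (logged in the trace); lines with no significant SCA
#' stay unclassified.
#'
#' @param tc A [testcross_table()].
#' @param alpha Significance level, 0.05 (default) or 0.01. Tightening alpha
#'   never classifies more lines.
#' @return A `heterosis_assignment` data frame: `line`, `group`
#'   (tester id or `"unclassified"`), `rule_trace`.
#' @export
classify_lines <- function(tc, alpha = 0.05) {
  stopifnot(inherits(tc, "testcross_table"))
  res <- lapply(tc$lines, function(ln) {
    sca <- tc$sca[ln, ]
    sig <- tc$sig[ln, ]
    my <- tc$mean_yield[ln, ]
    present <- !is.na(sca) & !is.na(sig)
    notes <- character()
    if (any(!present))
      notes <- paste0("excluded tester(s) with missing cells: ",
                      paste(tc$testers[!present], collapse = ", "))
    signif <- present & is_significant(sig, alpha)
    neg <- signif & sca < 0
    pos <- signif & sca > 0
    if (!any(neg) || !any(pos)) {
      why <- if (!any(signif)) "no significant SCA effects"
             else if (!any(neg)) "no significant negative SCA"
             else "no significant positive SCA"
      return(data.frame(line = ln, group = "unclassified",
                        rule_trace = paste(c(why, notes), collapse = "; "),
                        stringsAsFactors = FALSE))
    }
    # yield gate: testcross with some significant-positive tester must clear
    # that tester's grand mean + 1 SE
    bars <- tc$tester_grand_mean + tc$se_mean
    pass <- pos & !is.na(my) & my >= bars
    if (!any(pass)) {
      return(data.frame(line = ln, group = "unclassified",
                        rule_trace = paste(c(paste0(
                          "yield gate failed: no significant-positive tester with mean >= grand mean + 1 SE (",
                          paste(sprintf("%s: %.0f < %.0f", tc$testers[pos],
                                        my[pos], bars[pos]), collapse = "; "), ")"),
                          notes), collapse = "; "),
                        stringsAsFactors = FALSE))
    }
    cand <- which(neg)
    pick <- cand[which.min(sca[cand])]
    trace <- sprintf(
      "significant negative SCA with %s (%.0f); significant positive SCA with %s; yield gate passed via %s (%.0f >= %.0f + %.0f)",
      tc$testers[pick], sca[pick],
      paste(tc$testers[pos], collapse = ", "),
      tc$testers[which(pass)[1]], my[which(pass)[1]],
      tc$tester_grand_mean[which(pass)[1]], tc$se_mean[which(pass)[1]])
    if (sum(neg) > 1)
      trace <- paste0(trace, "; ambiguous: several significant negatives (",
                      paste(tc$testers[neg], collapse = ", "),
                      "), most negative wins")
    if (length(notes)) trace <- paste(c(trace, notes), collapse = "; ")
    data.frame(line = ln, group = tc$testers[pick], rule_trace = trace,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  structure(out, alpha = alpha, class = c("heterosis_assignment", "data.frame"))
}

#' Heterotic group counts
#'
#' @param assign A [classify_lines()] result.
#' @return Named integer vector: one count per tester group present plus
#'   `unclassified`; counts sum to the number of lines.
#' @export
group_summary <- function(assign) {
  stopifnot(inherits(assign, "heterosis_assignment"))
  groups <- sort(unique(assign$group[assign$group != "unclassified"]))
  counts <- vapply(c(groups, "unclassified"),
                   function(g) sum(assign$group == g), 0L)
  counts
}
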