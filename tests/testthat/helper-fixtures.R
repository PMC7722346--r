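# Test fixtures built in code: toy trials, single-trait generator configs,
# and the packaged digitized tables.

extdata <- function(f) {
  p <- system.file("extdata", f, package = "ltmet")
  if (!nzchar(p)) p <- file.path("../../inst/extdata", f)
  p
}

# single-trait (yield) generator parameters
yield_params <- function(gl = 0, gt = 0, s = 0, gle = 0, se = 0,
                         env = 0, rep = 0, blk = 0, err = 0, mu = 3023) {
  list(yield = list(
    mu_rainfed = mu, mu_drought = NA,
    vc = c(gca_line = gl, gca_tester = gt, sca = s, gca_line_env = gle,
           sca_env = se, env = env, rep = rep, block = blk, error = err),
    loading = 1))
}

yield_config <- function(..., l = 4, t = 3, r = 2, e = 2, seed = 1,
                         conditions = "drought") {
  generator_config(l = l, t = t, r = r, e = e, traits = yield_params(...),
                   blocks_per_rep = 1, n_checks = 0,
                   conditions = conditions, seed = seed)
}

# hand-built balanced toy trial: values indexed [genotype, env, rep]
toy_trial <- function(values, conditions = "drought") {
  dn <- dimnames(values)
  rows <- expand.grid(g = seq_len(dim(values)[1]), e = seq_len(dim(values)[2]),
                      r = seq_len(dim(values)[3]))
  obs <- data.frame(environment = dn[[2]][rows$e], condition = conditions,
                    replicate = rows$r, block = 1,
                    genotype = dn[[1]][rows$g], line = "", tester = "",
                    role = "check",
                    yield = values[cbind(rows$g, rows$e, rows$r)],
                    stringsAsFactors = FALSE)
  ltmet:::new_trial_dataset(obs, default_traits()["yield"], "toy")
}

# line x tester toy with cell means given as an l x t matrix (one env, r reps,
# residuals zero unless noise supplied)
lt_toy <- function(M, r = 2, e = 1, noise = NULL, conditions = "drought") {
  lines <- rownames(M) %||% paste0("L", seq_len(nrow(M)))
  testers <- colnames(M) %||% paste0("T", seq_len(ncol(M)))
  rows <- expand.grid(i = seq_len(nrow(M)), j = seq_len(ncol(M)),
                      k = seq_len(e), rr = seq_len(r))
  y <- M[cbind(rows$i, rows$j)]
  if (!is.null(noise)) y <- y + noise
  obs <- data.frame(environment = paste0("E", rows$k), condition = conditions,
                    replicate = rows$rr, block = 1,
                    genotype = hybrid_id(lines[rows$i], testers[rows$j]),
                    line = lines[rows$i], tester = testers[rows$j],
                    role = "hybrid", yield = y, stringsAsFactors = FALSE)
  ltmet:::new_trial_dataset(obs, default_traits()["yield"], "lt_toy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a minimal trial CSV and return its path
write_trial_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

tiny_trial_df <- function(sgc_bad = FALSE, dup = FALSE, extra_col = FALSE) {
  rows <- expand.grid(environment = c("drought_E1", "drought_E2"),
                      replicate = 1:2, line = "A",
                      tester = c("T1", "T2"), stringsAsFactors = FALSE)
  df <- data.frame(environment = rows$environment, condition = "drought",
                   replicate = rows$replicate, block = 1,
                   line = rows$line, tester = rows$tester,
                   yield = 1000, sgc = 5, stringsAsFactors = FALSE)
  if (sgc_bad) df$sgc[3] <- 11
  if (dup) df$replicate[3] <- 1L  # same (env, rep, genotype) as row 1
  if (extra_col) df$mystery <- 1
  df
}

published_six <- c("TZEEI 71" = "TZEEI 63", "TZEEI 102" = "TZEEI 63",
                   "TZEEI 96" = "TZEEI 79", "TZEEI 97" = "TZEEI 95",
                   "TZEEI 99" = "TZEEI 95", "TZEEI 101" = "TZEEI 95")
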