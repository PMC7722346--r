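# Synthetic line x tester trial generator. Produces plot-level data with the
# random-effects structure the estimators assume -- additive GCA for lines and
# testers, SCA, environment / replicate / incomplete-block effects,
# genotype-by-environment interaction, and plot error -- together with the
# realized ground truth, so every downstream stage can be tested for recovery
# without any external data.

gen_components <- c("gca_line", "gca_tester", "sca", "gca_line_env", "sca_env",
                    "env", "rep", "block", "error")

default_trait_params <- function() {
  # mu_rainfed / mu_drought: condition-level grand means; variance components
  # loosely calibrated to the drought ANOVA of a 40 x 3 testcross trial.
  vc <- function(gl, gt, s, gle, se, env, rep, blk, err)
    c(gca_line = gl, gca_tester = gt, sca = s, gca_line_env = gle,
      sca_env = se, env = env, rep = rep, block = blk, error = err)
  list(
    yield = list(mu_rainfed = 3023, mu_drought = NA, # NA: set by drought_yield_ratio
                 vc = vc(3400, 78000, 57000, 12600, 59000, 2.5e5, 2000, 67000, 138000),
                 loading = 0.9),
    da    = list(mu_rainfed = 49.7, mu_drought = 51.9,
                 vc = vc(0.5, 0.2, 0.3, 0.25, 0.25, 5, 0.05, 0.05, 2.0),
                 loading = -0.65),
    asi   = list(mu_rainfed = 0.7, mu_drought = 3.8,
                 vc = vc(0.15, 0.05, 0.13, 0.25, 0.25, 2, 0.05, 0.2, 5.6),
                 loading = -0.65),
    epp   = list(mu_rainfed = 0.96, mu_drought = 0.7,
                 vc = vc(0.0015, 5e-04, 0.0013, 0.001, 0.001, 0.05, 5e-04, 0.002, 0.02),
                 loading = 0.8),
    pasp  = list(mu_rainfed = 2.5, mu_drought = 2.9,
                 vc = vc(0.015, 0.005, 0.013, 0.025, 0.025, 0.1, 0.005, 0.02, 0.2),
                 loading = -0.92),
    easp  = list(mu_rainfed = 3.0, mu_drought = 3.0,
                 vc = vc(0.015, 0.005, 0.013, 0.025, 0.025, 0.1, 0.005, 0.02, 0.2),
                 loading = -0.95),
    sgc   = list(mu_rainfed = NA, mu_drought = 4.1,
                 vc = vc(0.01, 0.004, 0.006, 0.025, 0.025, 1.5, 0.05, 0.03, 0.55),
                 loading = -0.59)
  )
}

#' Generator configuration
#'
#' Describes the simulated world: design counts, per-trait grand means and
#' variance components, the drought-to-rainfed yield ratio, and the latent
#' cross-trait correlation matrix. Defaults emulate the trial the package
#' targets: 40 lines crossed to 3 testers, 2 replicates, 3 environments per
#' condition, drought yield at 52.3 % of the rain-fed mean, and a one-factor
#' latent correlation structure linking yield with the secondary traits.
#'
#' @param l,t,r,e Lines, testers, replicates, environments per condition.
#' @param traits Per-trait parameter list as produced by the default; each
#'   entry holds `mu_rainfed`, `mu_drought`, a named variance-component
#'   vector, and a latent factor `loading`.
#' @param drought_yield_ratio Drought yield mean as a fraction of rain-fed.
#' @param trait_correlation Optional latent correlation matrix (unit
#'   diagonal, positive semi-definite); by default built from the one-factor
#'   loadings.
#' @param blocks_per_rep Incomplete blocks per replicate; `1` disables
#'   blocking. Default approximates a lattice (`ceiling(sqrt(n_genotypes))`).
#' @param n_checks Number of open-pollinated check entries appended.
#' @param drop_pairs Optional data frame (`line`, `tester`) of cells removed
#'   after generation, to exercise unbalanced-data guards.
#' @param conditions Conditions to simulate.
#' @param seed Master integer seed; per-component substreams are derived
#'   deterministically from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(l = 40, t = 3, r = 2, e = 3,
                             traits = default_trait_params(),
                             drought_yield_ratio = 0.523,
                             trait_correlation = NULL,
                             blocks_per_rep = NULL,
                             n_checks = 1,
                             drop_pairs = NULL,
                             conditions = c("drought", "rainfed"),
                             seed = 1) {
  if (l < 2 || t < 2) stop("need at least 2 lines and 2 testers")
  stopifnot(r >= 1, e >= 1, length(conditions) >= 1)
  if (!(drought_yield_ratio > 0 && drought_yield_ratio <= 1))
    stop("drought_yield_ratio must be in (0, 1]")
  k <- length(traits)
  for (tn in names(traits)) {
    v <- traits[[tn]]$vc
    if (any(v[gen_components] < 0)) stop("negative variance component for ", tn)
  }
  if (is.null(trait_correlation)) {
    lam <- vapply(traits, `[[`, 0, "loading")
    trait_correlation <- tcrossprod(lam)
    diag(trait_correlation) <- 1
    dimnames(trait_correlation) <- list(names(traits), names(traits))
  }
  C <- trait_correlation
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8)) ||
      any(abs(diag(C) - 1) > 1e-8) || min(eigen(C, symmetric = TRUE,
                                                only.values = TRUE)$values) < -1e-8)
    stop("trait_correlation must be symmetric PSD with unit diagonal")
  if (is.null(blocks_per_rep)) blocks_per_rep <- ceiling(sqrt(l * t + n_checks))
  structure(list(l = l, t = t, r = r, e = e, traits = traits,
                 drought_yield_ratio = drought_yield_ratio,
                 trait_correlation = C, blocks_per_rep = blocks_per_rep,
                 n_checks = n_checks, drop_pairs = drop_pairs,
                 conditions = conditions, seed = as.integer(seed)),
            class = "generator_config")
}

# deterministic substream seed (kept below 2^31)
substream <- function(master, id) {
  as.integer((as.numeric(master) * 1000003 + id * 7919) %% 2147483629 + 1)
}

# draw an n x k matrix of correlated effects; column j scaled to sd[j], then
# column-centered so realized effects sit on the estimators' constraint surface
draw_effects <- function(n, sds, chol_C, center = TRUE) {
  z <- matrix(stats::rnorm(n * ncol(chol_C)), n) %*% chol_C
  z <- sweep(z, 2, sds, `*`)
  if (center && n > 1) z <- sweep(z, 2, colMeans(z), `-`)
  z
}

#' Generate a synthetic line x tester trial
#'
#' Each plot value is built on a latent Gaussian scale as
#' `mu(condition) + env + rep(env) + block(env x rep) + g_line + g_tester +
#' sca + (line x env) + (sca x env) + error`; ordinal traits are then rounded
#' and clamped to their bounds, ears per plant is clamped at 0, days to
#' silking is derived as `da + asi`, the stay-green score exists only on
#' drought plots, and the drought yield mean is `drought_yield_ratio` times
#' the rain-fed mean. Genetic effects are shared across conditions and
#' environments; the same `(config, seed)` always reproduces the identical
#' dataset bit for bit.
#'
#' @param config A [generator_config()].
#' @return List with `data` (a `trial_dataset`) and `truth` (realized GCA and
#'   SCA effects per trait, nominal variance components, and the true Baker
#'   proportion per trait).
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cf <- config
  tn <- names(cf$traits)
  k <- length(tn)
  chol_C <- chol(cf$trait_correlation +
                 diag(1e-10, k)) # guard exact-singular one-factor matrices
  sdc <- function(comp) vapply(cf$traits, function(x) sqrt(x$vc[[comp]]), 0)

  set.seed(substream(cf$seed, 1))
  gl <- draw_effects(cf$l, sdc("gca_line"), chol_C)      # lines x traits
  set.seed(substream(cf$seed, 2))
  gt <- draw_effects(cf$t, sdc("gca_tester"), chol_C)    # testers x traits
  set.seed(substream(cf$seed, 3))
  sc <- draw_effects(cf$l * cf$t, sdc("sca"), chol_C)    # (line,tester) x traits
  # double-center SCA within each trait so rows and columns sum to zero
  for (j in seq_len(k)) {
    m <- matrix(sc[, j], cf$l, cf$t)
    m <- m - outer(rowMeans(m), rep(1, cf$t)) -
      outer(rep(1, cf$l), colMeans(m)) + mean(m)
    sc[, j] <- as.vector(m)
  }

  line_ids <- sprintf("L%03d", seq_len(cf$l))
  tester_ids <- sprintf("T%d", seq_len(cf$t))
  grid <- expand.grid(line = line_ids, tester = tester_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  hyb_ids <- hybrid_id(grid$line, grid$tester)
  check_ids <- if (cf$n_checks > 0) sprintf("CHECK-%d", seq_len(cf$n_checks)) else character()
  set.seed(substream(cf$seed, 11))
  g_chk <- draw_effects(max(cf$n_checks, 2),
                        sqrt(sdc("gca_line")^2 + sdc("gca_tester")^2 + sdc("sca")^2),
                        chol_C, center = FALSE)[seq_len(cf$n_checks), , drop = FALSE]

  n_geno <- length(hyb_ids) + length(check_ids)
  envs <- unlist(lapply(cf$conditions, function(cd)
    paste0(cd, "_E", seq_len(cf$e))))
  n_env <- length(envs)
  env_cond <- rep(cf$conditions, each = cf$e)

  set.seed(substream(cf$seed, 4))
  env_eff <- draw_effects(n_env, sdc("env"), chol_C)
  set.seed(substream(cf$seed, 5))
  rep_eff <- draw_effects(n_env * cf$r, sdc("rep"), chol_C)
  set.seed(substream(cf$seed, 8))
  glE <- draw_effects(cf$l * n_env, sdc("gca_line_env"), chol_C)
  set.seed(substream(cf$seed, 9))
  scE <- draw_effects(cf$l * cf$t * n_env, sdc("sca_env"), chol_C)

  # plot grid: every genotype in every env x rep
  plots <- expand.grid(geno_i = seq_len(n_geno), replicate = seq_len(cf$r),
                       env_i = seq_len(n_env),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_plots <- nrow(plots)
  geno_ids <- c(hyb_ids, check_ids)
  is_hyb <- plots$geno_i <= length(hyb_ids)
  li <- ifelse(is_hyb, match(grid$line[plots$geno_i], line_ids), NA)
  ti <- ifelse(is_hyb, match(grid$tester[plots$geno_i], tester_ids), NA)

  # incomplete blocks: random genotype grouping per env x rep
  set.seed(substream(cf$seed, 6))
  b <- cf$blocks_per_rep
  block_of <- integer(n_plots)
  for (ei in seq_len(n_env)) for (ri in seq_len(cf$r)) {
    idx <- which(plots$env_i == ei & plots$replicate == ri)
    perm <- sample(length(idx))
    block_of[idx[perm]] <- rep(seq_len(b), length.out = length(idx))
  }
  set.seed(substream(cf$seed, 7))
  blk_eff <- draw_effects(n_env * cf$r * b, sdc("block"), chol_C)
  set.seed(substream(cf$seed, 10))
  err <- draw_effects(n_plots, sdc("error"), chol_C, center = FALSE)

  mu <- matrix(NA_real_, length(cf$conditions), k,
               dimnames = list(cf$conditions, tn))
  for (j in tn) {
    if ("rainfed" %in% cf$conditions) mu["rainfed", j] <- cf$traits[[j]]$mu_rainfed
    if ("drought" %in% cf$conditions) {
      md <- cf$traits[[j]]$mu_drought
      if (j == "yield" || is.na(md))
        md <- if (j == "yield") cf$traits[[j]]$mu_rainfed * cf$drought_yield_ratio
              else cf$traits[[j]]$mu_rainfed
      mu["drought", j] <- md
    }
  }

  rep_idx <- (plots$env_i - 1L) * cf$r + plots$replicate
  blk_idx <- ((plots$env_i - 1L) * cf$r + (plots$replicate - 1L)) * b + block_of
  glE_idx <- ifelse(is_hyb, (plots$env_i - 1L) * cf$l + li, NA)
  scE_idx <- ifelse(is_hyb, (plots$env_i - 1L) * cf$l * cf$t +
                      (ti - 1L) * cf$l + li, NA)
  cond_i <- match(env_cond[plots$env_i], cf$conditions)

  val <- matrix(0, n_plots, k, dimnames = list(NULL, tn))
  for (j in seq_len(k)) {
    g <- numeric(n_plots)
    g[is_hyb] <- gl[li[is_hyb], j] + gt[ti[is_hyb], j] +
      sc[(ti[is_hyb] - 1L) * cf$l + li[is_hyb], j] +
      glE[glE_idx[is_hyb], j] + scE[scE_idx[is_hyb], j]
    if (any(!is_hyb)) g[!is_hyb] <- g_chk[plots$geno_i[!is_hyb] - length(hyb_ids), j]
    val[, j] <- mu[cond_i, j] + env_eff[plots$env_i, j] + rep_eff[rep_idx, j] +
      blk_eff[blk_idx, j] + g + err[, j]
  }

  tspecs <- default_traits()[c(tn, "ds")]
  tspecs <- tspecs[!vapply(tspecs, is.null, TRUE)]
  obs <- data.frame(environment = envs[plots$env_i],
                    condition = env_cond[plots$env_i],
                    replicate = plots$replicate, block = block_of,
                    genotype = geno_ids[plots$geno_i],
                    line = ifelse(is_hyb, grid$line[plots$geno_i], ""),
                    tester = ifelse(is_hyb, grid$tester[plots$geno_i], ""),
                    role = ifelse(is_hyb, "hybrid", "check"),
                    stringsAsFactors = FALSE)
  for (j in tn) {
    v <- val[, j]
    sp <- tspecs[[j]]
    if (!is.null(sp) && sp$scale == "ordinal")
      v <- pmin(pmax(round(v), sp$bounds[1]), sp$bounds[2])
    if (j == "epp") v <- pmax(v, 0)
    if (!is.null(sp) && sp$drought_only) v[obs$condition != "drought"] <- NA
    obs[[j]] <- v
  }
  if (all(c("da", "asi") %in% tn)) obs$ds <- obs$da + obs$asi

  if (!is.null(cf$drop_pairs)) {
    drop_geno <- hybrid_id(cf$drop_pairs$line, cf$drop_pairs$tester)
    obs <- obs[!obs$genotype %in% drop_geno, , drop = FALSE]
  }
  data <- new_trial_dataset(obs, tspecs, source = "generate_trial")

  vc_nom <- t(vapply(cf$traits, function(x) x$vc[gen_components],
                     numeric(length(gen_components))))
  baker_true <- apply(vc_nom, 1, function(v) {
    den <- v["gca_line"] + v["gca_tester"] + v["sca"]
    if (den == 0) NA_real_ else unname((v["gca_line"] + v["gca_tester"]) / den)
  })
  dimnames(gl) <- list(line_ids, tn); dimnames(gt) <- list(tester_ids, tn)
  sca_arr <- array(sc, dim = c(cf$l, cf$t, k),
                   dimnames = list(line_ids, tester_ids, tn))
  # realized hybrid-level components, on the latent scale, matching the
  # expected-mean-squares conventions of the genotype ANOVA: sigma2_G is the
  # sample variance of the l*t hybrid genetic effects; sigma2_GE the
  # doubly-centred interaction sum of squares over the hybrid x environment
  # grid divided by (g-1)(n_env-1) (all generated environments pooled)
  li_vec <- rep(seq_len(cf$l), cf$t)
  hyb_eff <- matrix(0, cf$l * cf$t, k)
  s2G <- s2GE <- stats::setNames(numeric(k), tn)
  for (j in seq_len(k)) {
    hyb_eff[, j] <- gl[li_vec, j] + gt[rep(seq_len(cf$t), each = cf$l), j] + sc[, j]
    D <- matrix(scE[, j], cf$l * cf$t, n_env) +
      matrix(glE[, j], cf$l, n_env)[li_vec, , drop = FALSE]
    D <- sweep(sweep(D, 1, rowMeans(D)), 2, colMeans(D)) + mean(D)
    s2G[j] <- stats::var(hyb_eff[, j])
    s2GE[j] <- if (n_env > 1)
      sum(D^2) / ((cf$l * cf$t - 1) * (n_env - 1)) else NA_real_
  }
  truth <- list(gca_line = gl, gca_tester = gt, sca = sca_arr,
                vc_nominal = vc_nom,
                vc_realized = rbind(gca_line = apply(gl, 2, stats::var),
                                    gca_tester = apply(gt, 2, stats::var),
                                    sca = apply(sc, 2, stats::var)),
                sigma2_G = s2G, sigma2_GE = s2GE,
                sigma2_error = stats::setNames(apply(err, 2, stats::var), tn),
                baker_true = baker_true, mu = mu)
  list(data = data, truth = truth)
}

#' Exact rank-2 genotype x environment means fixture
#'
#' Builds a genotype x environment matrix whose environment-centered form has
#' rank exactly 2, for use as an exact oracle in biplot tests: two principal
#' axes reconstruct it perfectly and the which-won-where winners equal the
#' per-environment column argmax.
#'
#' @param g,e Genotypes (>= 3) and environments (>= 3).
#' @param seed Integer seed.
#' @return Numeric `g x e` matrix with dimnames.
#' @export
make_rank2_means <- function(g, e, seed = 1) {
  stopifnot(g >= 3, e >= 3)
  set.seed(substream(seed, 42))
  repeat {
    A <- matrix(stats::rnorm(g * 2), g)
    A <- sweep(A, 2, colMeans(A), `-`)            # centered genotype factors
    B <- matrix(stats::rnorm(2 * e), 2)
    M <- A %*% B
    s <- svd(M)$d
    if (s[2] > 1e-6 * s[1]) break                 # genuine rank 2
  }
  M <- sweep(M, 2, stats::rnorm(e, mean = 10, sd = 2), `+`)  # env main effects
  dimnames(M) <- list(sprintf("G%02d", seq_len(g)), sprintf("E%02d", seq_len(e)))
  M
}
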