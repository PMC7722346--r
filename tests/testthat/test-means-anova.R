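test_that("balanced least-squares means equal arithmetic means", {
  v <- array(7, c(3, 2, 2), dimnames = list(paste0("g", 1:3), c("E1", "E2"), NULL))
  d <- toy_trial(v)
  m <- ls_means(d, "yield", "per_condition")
  expect_true(all(m$mean == 7))
  v2 <- array(c(10, 12), c(2, 2, 2),
              dimnames = list(c("g1", "g2"), c("E1", "E2"), NULL))
  d2 <- toy_trial(v2)
  m2 <- ls_means(d2, "yield", "per_condition")
  expect_equal(m2$mean[match(c("g1", "g2"), m2$genotype)],
               c(mean(v2[1, , ]), mean(v2[2, , ])))
  pe <- ls_means(d2, "yield", "per_environment")
  expect_equal(sort(unique(pe$unit)), c("E1", "E2"))
})

test_that("unbalanced least-squares means match an independent model fit", {
  set.seed(21)
  v <- array(rnorm(3 * 2 * 2, 100, 5), c(3, 2, 2),
             dimnames = list(paste0("g", 1:3), c("E1", "E2"), NULL))
  d <- toy_trial(v)
  d$obs <- d$obs[-5, ]  # delete one plot
  m <- ls_means(d, "yield", "per_condition")
  # oracle: treatment-contrast lm, prediction averaged over nuisance levels
  df <- d$obs
  fit <- lm(yield ~ 0 + genotype + environment +
              interaction(environment, replicate), data = df)
  grid <- expand.grid(genotype = sort(unique(df$genotype)),
                      environment = unique(df$environment),
                      replicate = unique(df$replicate),
                      stringsAsFactors = FALSE)
  pred <- predict(fit, grid)
  oracle <- tapply(pred, grid$genotype, mean)
  expect_equal(m$mean[match(names(oracle), m$genotype)], as.vector(oracle),
               tolerance = 1e-8)
})

test_that("missing cells are flagged, not fabricated", {
  v <- array(1:8, c(2, 2, 2), dimnames = list(c("g1", "g2"), c("E1", "E2"), NULL))
  d <- toy_trial(v)
  d$obs <- d$obs[!(d$obs$genotype == "g2" & d$obs$environment == "E2"), ]
  pe <- ls_means(d, "yield", "per_environment")
  cell <- pe[pe$genotype == "g2" & pe$unit == "E2", ]
  expect_true(is.na(cell$mean))
  expect_equal(cell$n, 0L)
})

test_that("constant data give zero mean squares for every non-Error source", {
  v <- array(5, c(4, 2, 2), dimnames = list(paste0("g", 1:4), c("E1", "E2"), NULL))
  an <- trial_anova(toy_trial(v), "yield", "drought")
  expect_true(all(an$mean_square == 0))
})

test_that("unbalanced data are refused with a pointer to ls_means", {
  sim <- generate_trial(yield_config(err = 1, seed = 2))
  sim$data$obs <- sim$data$obs[-1, ]
  expect_error(trial_anova(sim$data, "yield", "drought"), "ls_means")
})

test_that("sequential sums of squares are a complete decomposition", {
  # with incomplete blocks (lm path) and without (closed-form path)
  for (bpr in c(1, 3)) {
    cfg <- generator_config(l = 5, t = 3, r = 2, e = 2,
                            traits = yield_params(gl = 2, s = 1, gle = 0.5,
                                                  se = 0.5, env = 1, rep = 0.3,
                                                  blk = 0.5, err = 1),
                            blocks_per_rep = bpr, n_checks = 1,
                            conditions = "drought", seed = 8)
    sim <- generate_trial(cfg)
    an <- trial_anova(sim$data, "yield", "drought")
    y <- sim$data$obs$yield
    expect_equal(sum(an$ss), sum((y - mean(y))^2), tolerance = 1e-8)
    expect_true(all(an$df >= 1))
  }
})

test_that("the genotype F-test holds its size under the null", {
  # only plot error: p-values for G should be uniform
  n_sim <- 1000
  rej <- vapply(seq_len(n_sim), function(s) {
    sim <- generate_trial(yield_config(err = 1, l = 4, t = 3, r = 2, e = 2,
                                       seed = s))
    an <- trial_anova(sim$data, "yield", "drought")
    an$p_value[an$source == "G"] < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("mean squares match their expectations under the generative model", {
  # E[MS_G] = sigma2 + r sigma2_GE + r e sigma2_G (genotype-level components)
  cfg_ms <- function(s) yield_config(gl = 1.012766, gt = 0.506383,
                                     s = 1.012766, gle = 0.508547, se = 0.5,
                                     err = 4, l = 40, t = 3, r = 2, e = 3,
                                     seed = s)
  res <- vapply(1:60, function(s) {
    sim <- generate_trial(cfg_ms(s))
    an <- trial_anova(sim$data, "yield", "drought")
    ms <- setNames(an$mean_square, an$source)
    c(ms[["G"]], ms[["GxE"]], ms[["Error"]])
  }, c(0, 0, 0))
  r <- 2; e <- 3
  expect_equal(mean(res[1, ]), 4 + r * 1 + r * e * 2, tolerance = 0.10)
  expect_equal(mean(res[2, ]), 4 + r * 1, tolerance = 0.10)
  expect_equal(mean(res[3, ]), 4, tolerance = 0.10)
})

test_that("variance components follow the EMS arithmetic", {
  an <- structure(data.frame(source = c("G", "GxE", "Error"), df = c(9, 9, 20),
                             ss = NA, mean_square = c(46, 10, 4)),
                  class = c("anova_table", "data.frame"))
  vc <- variance_components(an, r = 2, e = 3)
  expect_equal(vc$sigma2_error, 4)
  expect_equal(vc$sigma2_GE, 3)
  expect_equal(vc$sigma2_G, 6)
  # equal mean squares -> zero genetic components
  an$mean_square <- c(4, 4, 4)
  vc0 <- variance_components(an, r = 2, e = 3)
  expect_equal(vc0$sigma2_G, 0)
  expect_equal(vc0$sigma2_GE, 0)
  # negative solutions truncate with a warning
  an$mean_square <- c(1, 5, 6)
  expect_warning(vct <- variance_components(an, r = 2, e = 3), "truncated")
  expect_equal(vct$sigma2_G, 0)
  an2 <- an[an$source != "GxE", ]
  expect_error(variance_components(an2, r = 2, e = 3), "GxE")
})

test_that("repeatability follows its formula and is monotone", {
  mk <- function(G, GE, err, r, e)
    structure(list(sigma2_G = G, sigma2_GE = GE, sigma2_error = err,
                   r = r, e = e), class = "variance_components")
  expect_equal(repeatability(mk(1, 0, 0, 2, 3)), 1)
  expect_equal(round(repeatability(mk(2, 3, 4, 2, 3)), 4), 0.5455)
  expect_equal(repeatability(mk(0, 3, 4, 2, 3)), 0)
  expect_error(repeatability(mk(1, 1, 1, 0, 3)), "r >= 1")
  set.seed(5)
  for (i in 1:50) {
    G <- runif(1, 0, 5); GE <- runif(1, 0, 5); err <- runif(1, 0, 5)
    r <- sample(2:4, 1); e <- sample(2:6, 1)
    R <- repeatability(mk(G, GE, err, r, e))
    expect_true(R >= 0 && R <= 1)
    expect_gte(repeatability(mk(G + 1, GE, err, r, e)), R)
    expect_gte(repeatability(mk(G, GE, err, r, e + 1)), R)
    expect_gte(repeatability(mk(G, GE, err, r + 1, e)), R)
  }
})

test_that("the coefficient of variation is consistent inside and out", {
  sim <- generate_trial(yield_config(gl = 2, s = 1, err = 3, seed = 6))
  an <- trial_anova(sim$data, "yield", "drought")
  cv <- cv_percent(an)
  # independent route: residual mean square from cell means
  o <- sim$data$obs
  cell <- ave(o$yield, o$genotype, o$environment)
  repm <- ave(o$yield, o$environment, o$replicate)
  envm <- ave(o$yield, o$environment)
  res <- o$yield - cell - repm + envm
  ms_err <- sum(res^2) / an$df[an$source == "Error"]
  expect_equal(cv, 100 * sqrt(ms_err) / mean(o$yield), tolerance = 1e-9)
  expect_error(cv_percent(an, grand_mean = 0), "> 0")
  # zero error -> zero CV
  an$mean_square[an$source == "Error"] <- 0
  expect_equal(cv_percent(an), 0)
  # plausibility against the published drought numbers
  expect_lt(abs(100 * sqrt(138176) / 1581 - 23.50), 0.1)
})

test_that("trait correlations recover the latent correlation", {
  tr2 <- list(
    yield = list(mu_rainfed = 3023, mu_drought = NA,
                 vc = c(gca_line = 1, gca_tester = 1, sca = 1,
                        gca_line_env = 0.2, sca_env = 0.2, env = 1,
                        rep = 0.1, block = 0, error = 0.5), loading = 1),
    asi = list(mu_rainfed = 0.7, mu_drought = 3.8,
               vc = c(gca_line = 1, gca_tester = 1, sca = 1,
                      gca_line_env = 0.2, sca_env = 0.2, env = 1,
                      rep = 0.1, block = 0, error = 0.5), loading = -0.6))
  est <- vapply(1:50, function(s) {
    cfg <- generator_config(l = 40, t = 3, r = 2, e = 3, traits = tr2,
                            blocks_per_rep = 1, n_checks = 0,
                            conditions = "drought", seed = s)
    sim <- generate_trial(cfg)
    trait_correlations(sim$data, c("yield", "asi"), "drought")[1, 2]
  }, 0)
  expect_lt(abs(mean(est) - (-0.6)), 0.1)
  # trivial cases
  v <- array(c(1, 2, 3, 1, 2, 3), c(3, 1, 2),
             dimnames = list(paste0("g", 1:3), "E1", NULL))
  d <- toy_trial(v)
  d$obs$asi <- 10 - 2 * d$obs$yield
  d$traits <- default_traits()[c("yield", "asi")]
  cm <- trait_correlations(d, c("yield", "asi"), "drought")
  expect_equal(diag(cm), c(yield = 1, asi = 1))
  expect_equal(cm[1, 2], -1)
})
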