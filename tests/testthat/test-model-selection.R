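test_that("AICc follows its closed form and limits", {
  expect_equal(aicc(-100, 3, 50), 206 + 24 / 46, tolerance = 1e-12)
  # k = 0: no correction
  expect_equal(aicc(-100, 0, 50), 200)
  # n -> Inf at fixed k: AICc -> AIC
  expect_equal(aicc(-100, 3, 1e9), 206, tolerance = 1e-6)
  expect_error(aicc(-100, 3, 4), "undefined")
})

test_that("intercept-only Poisson fit matches the analytic MLE", {
  d <- tibble::tibble(y = c(3L, 3L, 3L, 3L))
  fit <- fit_glm("y", character(0), d, family = "poisson", covariates = character(0))
  expect_equal(fit$coefficients$estimate, log(3), tolerance = 1e-8)
  expect_equal(fit$loglik, sum(dpois(rep(3, 4), 3, log = TRUE)), tolerance = 1e-8)
  expect_equal(fit$k, 1)
  expect_gte(fit$aicc, fit$aic)
})

test_that("gaussian family reduces to ordinary least squares", {
  set.seed(7)
  d <- tibble::tibble(x1 = rnorm(40), x2 = rnorm(40))
  d$y <- 1 + 2 * d$x1 - d$x2 + rnorm(40, 0, 0.5)
  fit <- fit_glm("y", c("x1", "x2"), d,
    family = "gaussian", covariates = character(0)
  )
  ols <- lm(y ~ x1 + x2, data = d)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-10)
  # and the pseudo-R2 convention equals classical adjusted R-squared
  expect_equal(
    adjusted_pseudo_r2(fit),
    summary(ols)$adj.r.squared,
    tolerance = 1e-10
  )
})

test_that("missing values and rank deficiency are hard errors", {
  d <- tibble::tibble(y = c(1L, 2L, 3L, 4L), x = c(1, 2, NA, 4))
  expect_error(
    fit_glm("y", "x", d, family = "poisson", covariates = character(0)),
    "missing values.*x"
  )
  d2 <- tibble::tibble(y = rpois(30, 3), a = rnorm(30))
  d2$b <- 2 * d2$a
  expect_error(
    fit_glm("y", c("a", "b"), d2, family = "poisson", covariates = character(0)),
    "collinear"
  )
})

test_that("NB parameter recovery on data simulated from a known NB GLM", {
  set.seed(300)
  n <- 2000
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  truth <- c(`(Intercept)` = 1.2, x1 = -0.3, x2 = 0.15)
  mu <- exp(truth[1] + truth[2] * d$x1 + truth[3] * d$x2)
  d$y <- rnbinom(n, size = 1.5, mu = mu)
  fit <- fit_glm("y", c("x1", "x2"), d,
    family = "negative_binomial",
    covariates = character(0)
  )
  cf <- fit$coefficients
  for (i in seq_along(truth)) {
    expect_lt(abs(cf$estimate[i] - truth[i]) / cf$se[i], 3)
  }
  expect_equal(fit$theta, 1.5, tolerance = 0.2)
})

test_that("dredge enumerates all 2^m subsets with the covariates fixed", {
  d <- cached_analysis_table("mid", 400, 19)
  cands <- c("ak_freq_dom", "ak_var_nd", "sk_dwell_b2")
  tbl <- dredge_subsets(d, "paltea6", cands, family = "negative_binomial")
  expect_equal(nrow(tbl), 8)
  expect_equal(sum(tbl$is_null), 1)
  # every candidate appears in exactly half the subsets
  for (f in cands) {
    expect_equal(sum(grepl(f, tbl$features)), 4)
  }
  # the table is ranked: deltas start at 0 and never decrease
  expect_equal(tbl$delta_aicc[1], 0)
  expect_true(all(diff(tbl$delta_aicc[tbl$converged]) >= 0))
  # every fitted model carries the five fixed covariates
  fit1 <- best_fit(tbl)
  expect_true(all(c(
    "age_years", "sexmale", "hads_depression", "hads_anxiety"
  ) %in% fit1$coefficients$term))
})

test_that("dredge ranking matches independent per-subset refits", {
  d <- cached_analysis_table("mid", 400, 19)
  cands <- c("ak_freq_dom", "ak_var_nd", "sk_freq_b1")
  tbl <- dredge_subsets(d, "paltea6", cands, family = "negative_binomial")
  # brute force: refit every subset from scratch with MASS::glm.nb
  covs <- paste(default_covariates(), collapse = " + ")
  ref <- lapply(0:7, function(mask) {
    feats <- cands[bitwAnd(mask, c(1L, 2L, 4L)) > 0]
    rhs <- paste(c(covs, feats), collapse = " + ")
    m <- suppressWarnings(MASS::glm.nb(as.formula(paste("paltea6 ~", rhs)), data = d))
    ll <- logLik(m)
    k <- attr(ll, "df")
    data.frame(
      features = paste(sort(feats), collapse = "+"),
      aicc_ref = -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (nobs(m) - k - 1)
    )
  })
  ref <- do.call(rbind, ref)
  ref <- ref[order(ref$aicc_ref), ]
  expect_equal(tbl$features, ref$features)
  expect_equal(tbl$aicc, ref$aicc_ref, tolerance = 1e-6)
})

test_that("hypothesis evaluation applies the delta-AICc > 2 rule", {
  d <- cached_analysis_table("mid", 400, 19)
  # pure-noise candidates: the null model must sit in the equivalence set
  set.seed(11)
  d$noise1 <- rnorm(nrow(d))
  d$noise2 <- rnorm(nrow(d))
  tbl0 <- dredge_subsets(d, "swmbe6", c("noise1", "noise2"),
    family = "negative_binomial"
  )
  hyp0 <- evaluate_hypothesis(tbl0)
  expect_false(hyp0$improvement)
  expect_gte(hyp0$null_delta_aicc, 0)
  # injected-signal candidates push the null model out of the set
  # (n chosen for adequate power: detection z per feature ~ 3)
  d_big <- cached_analysis_table("sig", 1000, 23)
  tbl1 <- dredge_subsets(d_big, "paltea6",
    c("sk_freq_b1", "ak_freq_dom", "ak_var_nd"),
    family = "negative_binomial"
  )
  hyp1 <- evaluate_hypothesis(tbl1)
  expect_true(hyp1$improvement)
  expect_gt(hyp1$null_delta_aicc, 2)
  expect_false(hyp1$null_in_equivalence_set)
})

test_that("family selection prefers NB for overdispersed counts and Poisson otherwise", {
  d <- cached_analysis_table("mid", 400, 19)
  # paltea6 is generated negative-binomial (theta = 1): NB must win
  ch_nb <- select_family(d, "paltea6")
  expect_equal(ch_nb$family, "negative_binomial")
  expect_gt(ch_nb$aicc_poisson - ch_nb$aicc_negative_binomial, 2)
  # swms is generated Poisson: NB cannot beat it by more than 2
  ch_pois <- select_family(d, "swms")
  expect_equal(ch_pois$family, "poisson")
  expect_false(ch_pois$fallback)
})

test_that("a degenerate outcome triggers the recorded gaussian fallback", {
  d <- cached_analysis_table("mid", 400, 19)
  d$flat <- 0L # zero-variance count: the NB null cannot be fitted
  ch <- select_family(d, "flat")
  expect_equal(ch$family, "gaussian")
  expect_true(ch$fallback)
  expect_match(ch$reason, "did not converge")
})

test_that("incident rate ratios exponentiate coefficients with their bounds", {
  d <- cached_analysis_table("mid", 400, 19)
  fit <- fit_glm("paltea6", "ak_freq_dom", d, family = "negative_binomial")
  irr <- incident_rate_ratios(fit)
  expect_equal(irr$irr, exp(fit$coefficients$estimate), tolerance = 1e-12)
  expect_true(all(irr$conf_low < irr$irr & irr$irr < irr$conf_high))
  # the injected negative frequency effect shows up as IRR < 1
  expect_lt(irr$irr[irr$term == "ak_freq_dom"], 1)
  # undefined on the identity link
  gfit <- fit_glm("paltea6", "ak_freq_dom", d, family = "gaussian")
  expect_error(incident_rate_ratios(gfit), "gaussian")
})

test_that("adjusted pseudo-R2 is zero for the null fit and grows with signal", {
  d <- cached_analysis_table("mid", 400, 19)
  null_fit <- fit_glm("paltea6", character(0), d, family = "negative_binomial")
  expect_equal(adjusted_pseudo_r2(null_fit, null_fit), 0)
  full_fit <- fit_glm("paltea6", c("ak_freq_dom", "ak_var_nd"), d,
    family = "negative_binomial"
  )
  expect_gt(adjusted_pseudo_r2(full_fit), 0)
  expect_lt(adjusted_pseudo_r2(full_fit), 1)
})
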