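test_that("composite literacy is a centred z-score average", {
  lit <- tibble::tibble(participant = paste0("P", 1:5),
                        spelling = c(30, 25, 35, 28, 32),
                        vocabulary = c(38, 30, 34, 31, 37))
  out <- composite_literacy(lit)
  # spreadsheet-style oracle
  zs <- (lit$spelling - mean(lit$spelling)) / sd(lit$spelling)
  zv <- (lit$vocabulary - mean(lit$vocabulary)) / sd(lit$vocabulary)
  expect_equal(out$composite, (zs + zv) / 2)
  expect_equal(mean(out$composite), 0, tolerance = 1e-12)
  # mirrored two-participant case gives symmetric composites
  two <- composite_literacy(tibble::tibble(participant = c("A", "B"),
                                           spelling = c(20, 30),
                                           vocabulary = c(25, 35)))
  expect_equal(two$composite, -rev(two$composite))
  # missing score excludes the participant with a warning
  lit$vocabulary[2] <- NA
  expect_warning(out2 <- composite_literacy(lit), "P2")
  expect_equal(nrow(out2), 4L)
})

test_that("one-sample t test against 1 matches the direct formula", {
  x <- c(1.28, 1.61, 1.90, 2.86, 1.44, 1.02)
  res <- ttest_vs_one(x)
  t_hand <- (mean(x) - 1) / (sd(x) / sqrt(length(x)))
  expect_equal(res$t, t_hand)
  expect_equal(res$df, length(x) - 1)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df = length(x) - 1))
  expect_equal(ttest_vs_one(c(1, 1.0001, 0.9999, 1))$t, 0, tolerance = 1e-6)
  expect_error(ttest_vs_one(rep(1, 5)), "variance")
})

test_that("diversity LMM recovers a known negative consistency effect", {
  d <- simulate_diversity_data(seed = 101)
  m <- fit_diversity_lmm(d)
  fe <- m$fixed_effects
  b <- fe[fe$term == "consistency", ]
  expect_lt(b$estimate, 0)
  expect_lt(b$p, 0.01)
  # Satterthwaite df are fractional and positive
  expect_gt(b$df, 0)
  expect_false(b$df == round(b$df) && b$df == nrow(d) - 4)
  expect_true(all(fe$se > 0))
  expect_lte(m$r2_marginal, m$r2_conditional)
})

test_that("diversity LMM estimates are near zero under null effects", {
  d <- simulate_diversity_data(
    beta = c(intercept = 0.4, consistency = 0, literacy = 0, interaction = 0),
    seed = 102)
  m <- fit_diversity_lmm(d)
  fe <- m$fixed_effects
  expect_lt(max(abs(fe$estimate[fe$term != "(Intercept)"])), 0.1)
  expect_lt(m$r2_marginal, 0.05)
})

test_that("grouping factors with fewer than 2 levels fail loudly", {
  d <- simulate_diversity_data(seed = 1)
  d$participant <- "P01"
  expect_error(fit_diversity_lmm(d), "fewer than 2 levels")
})

test_that("novelty GLMM recovers session and consistency effects", {
  d <- simulate_novelty_data(seed = 103)
  m <- fit_novelty_glmm(d)
  fe <- m$fixed_effects
  expect_lt(fe$estimate[fe$term == "session_c"], 0)
  expect_lt(fe$p[fe$term == "session_c"], 0.001)
  expect_lt(fe$estimate[fe$term == "consistency"], 0)
  # Wald z tests: no df
  expect_true(all(is.na(fe$df)))
  # both theoretical and delta R2 are reported for the binomial family
  expect_true(all(c("r2_marginal_delta", "r2_conditional_delta") %in% names(m$r2)))
  expect_lte(m$r2$r2_marginal_delta, m$r2$r2_conditional_delta)
})

test_that("intercept-only novelty at 50% gives a near-zero logit intercept", {
  d <- simulate_novelty_data(
    beta = c(intercept = 0, session = 0, consistency = 0, literacy = 0,
             session_consistency = 0, session_literacy = 0,
             consistency_literacy = 0),
    sd_participant = 0.05, sd_item = 0.05, seed = 104)
  m <- fit_novelty_glmm(d)
  expect_lt(abs(m$fixed_effects$estimate[1]), 0.15)
})

test_that("distance LMM recovers a shrinking-distance slope and is symmetric", {
  d <- simulate_distance_data(seed = 105)
  m <- fit_distance_lmm(d)
  b <- m$fixed_effects[m$fixed_effects$term == "session_z", ]
  expect_lt(b$estimate, 0)
  expect_lt(b$p, 0.001)
  # swapping pair labels leaves the fixed effect unchanged
  swapped <- d
  swapped$participant_a <- d$participant_b
  swapped$participant_b <- d$participant_a
  m2 <- fit_distance_lmm(swapped)
  expect_equal(m2$fixed_effects$estimate, m$fixed_effects$estimate,
               tolerance = 1e-6)
})

test_that("constant distances give a near-zero slope", {
  d <- simulate_distance_data(beta = c(intercept = 0.6, session = 0),
                              seed = 106)
  m <- fit_distance_lmm(d)
  b <- m$fixed_effects[m$fixed_effects$term == "session_z", ]
  expect_lt(abs(b$estimate), 3 * b$se + 0.01)
})

test_that("trajectory extraction recovers a positive intercept-slope link", {
  d <- simulate_trajectory_data(rho = 0.6, seed = 107)
  tr <- fit_trajectories(d)
  expect_equal(nrow(tr$trajectories), 300L)
  expect_gt(tr$cor_intercept_slope, 0)
  expect_true(tr$r_defined)
})

test_that("flat trajectories are flagged as having no defined correlation", {
  d <- tidyr::expand_grid(item = sprintf("I%d", 1:20), session = 1:4)
  d$pronunciation <- "p"
  d$frequency <- 5
  tr <- suppressWarnings(fit_trajectories(d))
  expect_false(tr$r_defined)
  expect_true(is.na(tr$cor_intercept_slope))
})

test_that("r2 components match independent arithmetic on a fixture", {
  d <- simulate_diversity_data(seed = 108)
  fit <- lmerTest::lmer(diversity ~ consistency + (1 | item) + (1 | participant),
                        data = d)
  r2 <- r2_mixed(fit)
  # independent arithmetic: var of fixed predictions, sum of intercept
  # variances, residual variance
  b <- lme4::fixef(fit)
  vf <- var(b[1] + b[2] * d$consistency)
  vc <- as.data.frame(lme4::VarCorr(fit))
  vr <- sum(vc$vcov[is.na(vc$var2) & vc$grp != "Residual"])
  ve <- vc$vcov[vc$grp == "Residual"]
  expect_equal(r2$r2_marginal, vf / (vf + vr + ve), tolerance = 1e-10)
  expect_equal(r2$r2_conditional, (vf + vr) / (vf + vr + ve), tolerance = 1e-10)
  expect_gte(r2$r2_marginal, 0)
  expect_lte(r2$r2_conditional, 1)
})

test_that("with negligible random variance, marginal R2 approaches classical R2", {
  set.seed(109)
  n <- 400
  d <- tibble::tibble(g = rep(sprintf("G%d", 1:20), each = n / 20),
                      x = rnorm(n))
  d$y <- 1 + 0.5 * d$x + rnorm(n)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(y ~ x + (1 | g), data = d)))
  r2 <- r2_mixed(fit)
  ols <- summary(lm(y ~ x, data = d))$r.squared
  expect_equal(r2$r2_marginal, ols, tolerance = 0.02)
  expect_equal(r2$r2_marginal, r2$r2_conditional, tolerance = 0.02)
})

test_that("semi-partial R2 isolates a term's variance share", {
  d <- simulate_diversity_data(seed = 110)
  m <- fit_diversity_lmm(d)
  sp_cons <- semipartial_r2(m, "consistency")
  sp_lit <- semipartial_r2(m, "literacy")
  # the only nonzero effect carries essentially the whole marginal R2
  expect_lt(sp_cons$r2_full - sp_cons$semipartial_r2, 0.02)
  expect_gt(sp_cons$semipartial_r2, 0.1)
  expect_lt(abs(sp_lit$semipartial_r2), 0.02)
  expect_error(semipartial_r2(m, "not_a_term"), "not a fixed-effect term")
})

test_that("additive effects give approximately additive semi-partials", {
  d <- simulate_diversity_data(
    beta = c(intercept = 0.4, consistency = -0.15, literacy = 0.1,
             interaction = 0),
    seed = 111)
  m <- fit_diversity_lmm(d)
  sp_c <- semipartial_r2(m, "consistency")$semipartial_r2
  sp_l <- semipartial_r2(m, "literacy")$semipartial_r2
  full <- r2_mixed(suppressWarnings(
    lmerTest::lmer(formula(m$fit), data = d, REML = FALSE)))$r2_marginal
  expect_equal(sp_c + sp_l, full, tolerance = 0.05)
})

test_that("centring a covariate changes only the intercept in the linear model", {
  d <- simulate_diversity_data(
    beta = c(intercept = 0.4, consistency = -0.15, literacy = 0,
             interaction = 0), seed = 112)
  m1 <- fit_diversity_lmm(d)
  d2 <- d
  d2$consistency <- d$consistency + 2   # de-centre
  m2 <- fit_diversity_lmm(d2)
  # interaction-free slope unchanged; intercept shifts by -2 * slope
  b1 <- setNames(m1$fixed_effects$estimate, m1$fixed_effects$term)
  b2 <- setNames(m2$fixed_effects$estimate, m2$fixed_effects$term)
  expect_equal(unname(b1["consistency"]), unname(b2["consistency"]),
               tolerance = 1e-4)
})
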