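#' Marginal and conditional R-squared for mixed models
#'
#' Variance-decomposition R-squared for `lmer`/`glmer` fits. The marginal
#' value is the variance of the fixed-effect predictions divided by the total
#' of fixed, random and residual variances; the conditional value adds the
#' random-effect variances to the numerator. Random-slope terms contribute
#' the mean observation-level variance `diag(Z S Z')` of their estimated
#' covariance `S`, so models with random slopes are handled exactly rather
#' than by summing raw variance components.
#'
#' For binomial (logit) models the residual slot is the distribution-specific
#' observation-level variance, computed two ways: the theoretical logistic
#' variance `pi^2 / 3`, and the delta-method value `1 / (p * (1 - p))`
#' evaluated at the mean fitted probability. Both pairs are returned; the
#' theoretical pair populates `r2_marginal` / `r2_conditional`.
#'
#' @param fit A fitted `merMod` / `lmerModLmerTest` object, or an
#'   `nwv_model`.
#' @return List with `r2_marginal`, `r2_conditional`, the variance pieces
#'   (`var_fixed`, `var_random`, `var_residual`), and for binomial fits also
#'   `r2_marginal_delta`, `r2_conditional_delta`.
#' @export
r2_mixed <- function(fit) {
  if (inherits(fit, "nwv_model")) fit <- fit$fit
  stopifnot(inherits(fit, "merMod"))
  beta <- lme4::fixef(fit)
  X <- lme4::getME(fit, "X")
  var_f <- stats::var(as.vector(X %*% beta))

  mf <- stats::model.frame(fit)
  vc <- lme4::VarCorr(fit)
  var_r <- 0
  for (g in seq_along(vc)) {
    S <- as.matrix(vc[[g]])
    terms_g <- rownames(S)
    Z <- vapply(terms_g, function(tm) {
      if (tm == "(Intercept)") rep(1, nrow(mf))
      else eval(str2lang(tm), envir = mf)
    }, numeric(nrow(mf)))
    Z <- matrix(Z, nrow = nrow(mf))
    var_r <- var_r + mean(rowSums((Z %*% S) * Z))
  }

  is_binomial <- isGLMM(fit)
  if (!is_binomial) {
    var_e <- stats::sigma(fit)^2
    tot <- var_f + var_r + var_e
    return(list(r2_marginal = var_f / tot,
                r2_conditional = (var_f + var_r) / tot,
                var_fixed = var_f, var_random = var_r, var_residual = var_e))
  }
  if (stats::family(fit)$family != "binomial" ||
      stats::family(fit)$link != "logit") {
    stop("r2_mixed supports gaussian and binomial(logit) fits")
  }
  var_e_theo <- pi^2 / 3
  pbar <- mean(stats::fitted(fit))
  var_e_delta <- 1 / (pbar * (1 - pbar))
  tot_t <- var_f + var_r + var_e_theo
  tot_d <- var_f + var_r + var_e_delta
  list(r2_marginal = var_f / tot_t,
       r2_conditional = (var_f + var_r) / tot_t,
       r2_marginal_delta = var_f / tot_d,
       r2_conditional_delta = (var_f + var_r) / tot_d,
       var_fixed = var_f, var_random = var_r,
       var_residual = var_e_theo, var_residual_delta = var_e_delta)
}

isGLMM <- function(fit) methods::is(fit, "glmerMod")

# Remove a fixed-effect term (and every interaction containing it) from a
# merMod formula, keeping the random-effects part intact.
reduce_formula <- function(fit, term) {
  ff <- stats::formula(fit)
  tt <- stats::terms(lme4::nobars(ff))
  labs <- attr(tt, "term.labels")
  involves <- vapply(strsplit(labs, ":", fixed = TRUE),
                     function(x) term %in% x, logical(1))
  if (!any(involves)) stop("'", term, "' is not a fixed-effect term of the model")
  keep <- labs[!involves]
  bars <- lme4::findbars(ff)
  re_txt <- vapply(bars, function(b) paste0("(", deparse1(b), ")"), character(1))
  rhs <- paste(c(if (length(keep)) keep else "1", re_txt), collapse = " + ")
  stats::as.formula(paste(deparse1(ff[[2]]), "~", rhs),
                    env = environment(ff))
}

#' Semi-partial R-squared of one fixed effect
#'
#' The share of variance uniquely attributable to a fixed-effect term:
#' the drop in marginal R-squared when the term (together with every
#' interaction that contains it) is removed and the model refit on the same
#' data. For binomial fits the theoretical marginal R-squared is used.
#'
#' @param model An `nwv_model` (from one of the `fit_*` functions).
#' @param term Name of a fixed-effect main term, e.g. `"session_c"`.
#' @return List with `semipartial_r2`, `r2_full`, `r2_reduced`, and
#'   `reduced_ok` (`FALSE` when the reduced fit emitted convergence
#'   warnings, in which case the value should be treated with caution).
#' @export
semipartial_r2 <- function(model, term) {
  stopifnot(inherits(model, "nwv_model"))
  fit <- model$fit
  red_ff <- reduce_formula(fit, term)
  dat <- stats::model.frame(fit)
  ok <- TRUE
  red <- withCallingHandlers({
    suppressMessages(
      if (isGLMM(fit)) {
        lme4::glmer(red_ff, data = dat, family = stats::binomial())
      } else {
        lmerTest::lmer(red_ff, data = dat, REML = FALSE)
      })
  }, warning = function(w) {
    if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) ok <<- FALSE
    invokeRestart("muffleWarning")
  })
  full_fit <- if (!isGLMM(fit) && lme4::isREML(fit)) {
    suppressMessages(suppressWarnings(
      lmerTest::lmer(stats::formula(fit), data = dat, REML = FALSE)))
  } else {
    fit
  }
  r2_full <- r2_mixed(full_fit)$r2_marginal
  r2_red <- r2_mixed(red)$r2_marginal
  list(semipartial_r2 = r2_full - r2_red,
       r2_full = r2_full, r2_reduced = r2_red, reduced_ok = ok)
}
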