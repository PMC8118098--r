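#' Composite literacy score
#'
#' Averages within-sample standardised (z-scored) spelling and vocabulary
#' scores into a single literacy measure, avoiding the multicollinearity of
#' entering two correlated tests as separate predictors. Participants missing
#' either score are excluded with a warning. The composite is centred near
#' zero by construction.
#'
#' @param literacy Data frame with columns `participant`, `spelling`,
#'   `vocabulary` (raw test scores).
#' @return Tibble: `participant`, `spelling`, `vocabulary`, `composite`.
#' @export
composite_literacy <- function(literacy) {
  stopifnot(all(c("participant", "spelling", "vocabulary") %in% names(literacy)))
  literacy <- tibble::as_tibble(literacy)
  miss <- is.na(literacy$spelling) | is.na(literacy$vocabulary)
  if (any(miss)) {
    warning("excluding participant(s) with missing scores: ",
            paste(literacy$participant[miss], collapse = ", "))
    literacy <- literacy[!miss, ]
  }
  if (nrow(literacy) < 2L) stop("need at least two complete participants")
  z <- function(x) (x - mean(x)) / stats::sd(x)
  literacy$composite <- (z(literacy$spelling) + z(literacy$vocabulary)) / 2
  literacy
}

#' One-sample t test of mean distinct-pronunciation counts against 1
#'
#' A unit (participant or item) whose responses never vary has a mean
#' distinct-pronunciation count of exactly 1, so the test asks whether
#' responses vary across sessions at all.
#'
#' @param means Numeric vector of per-unit mean distinct counts.
#' @return List with `t`, `df` (`length(means) - 1`), `p` (two-sided),
#'   `mean`.
#' @export
ttest_vs_one <- function(means) {
  stopifnot(length(means) >= 2)
  if (stats::sd(means) == 0) stop("zero variance: t statistic undefined")
  tt <- stats::t.test(means, mu = 1)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = unname(tt$estimate))
}

# ---------------------------------------------------------------------------
# model_result container

new_model_result <- function(fit, formula_used, fallback, family,
                             r2 = NULL) {
  fe <- extract_fixed_effects(fit)
  vc <- extract_varcomp(fit)
  if (is.null(r2)) r2 <- r2_mixed(fit)
  structure(list(
    formula = deparse1(formula_used),
    fixed_effects = fe,
    variance_components = vc,
    r2_marginal = r2$r2_marginal,
    r2_conditional = r2$r2_conditional,
    r2 = r2,
    converged = TRUE,
    fallback_applied = fallback,
    singular = lme4::isSingular(fit),
    family = family,
    fit = fit
  ), class = "nwv_model")
}

#' @export
print.nwv_model <- function(x, digits = 3, ...) {
  cat("<nwv_model> ", x$family, " mixed model\n  ", x$formula, "\n", sep = "")
  if (!is.null(x$fallback_applied)) {
    cat("  random-effects fallback applied: ", x$fallback_applied, "\n", sep = "")
  }
  if (isTRUE(x$singular)) cat("  note: singular fit (a variance component is ~0)\n")
  print(as.data.frame(x$fixed_effects), digits = digits)
  cat(sprintf("  R2 marginal = %.3f, conditional = %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

extract_fixed_effects <- function(fit) {
  sm <- summary(fit)$coefficients
  df <- tibble::tibble(term = rownames(sm),
                       estimate = sm[, "Estimate"],
                       se = sm[, "Std. Error"])
  if ("df" %in% colnames(sm)) {                       # lmerTest: Satterthwaite
    df$statistic <- sm[, "t value"]
    df$df <- sm[, "df"]
    df$p <- sm[, "Pr(>|t|)"]
  } else if ("z value" %in% colnames(sm)) {           # glmer: Wald z
    df$statistic <- sm[, "z value"]
    df$df <- NA_real_
    df$p <- sm[, "Pr(>|z|)"]
  } else {
    df$statistic <- sm[, "t value"]
    df$df <- NA_real_
    df$p <- NA_real_
  }
  df
}

extract_varcomp <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  tibble::tibble(group = vc$grp, term1 = vc$var1, term2 = vc$var2,
                 variance = vc$vcov, sd = vc$sdcor)
}

# Fit a mixed model trying progressively simpler random-effects structures.
# `formulas` is an ordered list; the first formula that fits without error or
# convergence warning wins. A merely singular fit is accepted (a variance
# component estimated at zero is not a convergence failure) but flagged.
fit_with_fallback <- function(formulas, labels, data, family = "gaussian",
                              reml = TRUE) {
  last_err <- NULL
  for (k in seq_along(formulas)) {
    fit <- NULL
    bad <- FALSE
    withCallingHandlers({
      fit <- tryCatch({
        if (family == "gaussian") {
          lmerTest::lmer(formulas[[k]], data = data, REML = reml)
        } else {
          lme4::glmer(formulas[[k]], data = data, family = stats::binomial())
        }
      }, error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      })
    }, warning = function(w) {
      if (grepl("converge|Hessian|pwrssUpdate", conditionMessage(w),
                ignore.case = TRUE)) bad <<- TRUE
      invokeRestart("muffleWarning")
    }, message = function(m) {
      if (grepl("boundary|singular", conditionMessage(m))) {
        invokeRestart("muffleMessage")
      }
    })
    if (!is.null(fit) && !bad) {
      conv_msgs <- fit@optinfo$conv$lme4$messages
      if (!is.null(conv_msgs) &&
          any(grepl("failed to converge", conv_msgs, ignore.case = TRUE))) {
        next
      }
      fallback <- if (k == 1L) NULL else labels[[k]]
      return(list(fit = fit, formula = formulas[[k]], fallback = fallback))
    }
  }
  stop("no random-effects structure converged",
       if (!is.null(last_err)) paste0(" (last error: ", last_err, ")"))
}

check_grouping <- function(data, vars) {
  for (v in vars) {
    if (length(unique(data[[v]])) < 2L) {
      stop("grouping factor '", v, "' has fewer than 2 levels")
    }
  }
}

#' Mixed model of response diversity
#'
#' Fits `diversity ~ consistency * literacy + (1 | item) +
#' (1 + consistency | participant)` by REML with Satterthwaite degrees of
#' freedom. When the maximal structure fails to converge the ladder drops the
#' intercept-slope correlation, then the random slope; the fallback used is
#' recorded in the result.
#'
#' @param data Data frame with columns `participant`, `item`, `diversity`,
#'   `consistency` (centred item covariate), `literacy` (centred participant
#'   covariate).
#' @return An object of class `nwv_model`.
#' @export
fit_diversity_lmm <- function(data) {
  stopifnot(all(c("participant", "item", "diversity", "consistency",
                  "literacy") %in% names(data)))
  data <- stats::na.omit(tibble::as_tibble(
    data[c("participant", "item", "diversity", "consistency", "literacy")]))
  check_grouping(data, c("participant", "item"))
  forms <- list(
    diversity ~ consistency * literacy + (1 | item) + (1 + consistency | participant),
    diversity ~ consistency * literacy + (1 | item) + (1 + consistency || participant),
    diversity ~ consistency * literacy + (1 | item) + (1 | participant))
  labels <- c(NA, "dropped random intercept-slope correlation",
              "dropped random slope for consistency")
  res <- fit_with_fallback(forms, labels, data, family = "gaussian")
  new_model_result(res$fit, res$formula, res$fallback, "gaussian")
}

#' Binomial mixed model of novel-pronunciation use
#'
#' Fits a logit GLMM (Laplace approximation):
#' `novel ~ session_c * consistency + session_c * literacy +
#' consistency * literacy + (1 | participant) + (1 | item)`, with Wald z
#' tests. `session` is treated as numeric and centred internally
#' (`session_c`).
#'
#' @param data Data frame with columns `participant`, `item`, `session`,
#'   `novel` (0/1), `consistency`, `literacy`.
#' @return An object of class `nwv_model`. Its `r2` element carries both the
#'   theoretical (`pi^2/3`) and delta-method observation-level variances.
#' @export
fit_novelty_glmm <- function(data) {
  stopifnot(all(c("participant", "item", "session", "novel", "consistency",
                  "literacy") %in% names(data)))
  data <- stats::na.omit(tibble::as_tibble(
    data[c("participant", "item", "session", "novel", "consistency",
           "literacy")]))
  if (!all(data$novel %in% c(0, 1))) stop("'novel' must be binary 0/1")
  check_grouping(data, c("participant", "item"))
  data$session_c <- data$session - mean(data$session)
  for (v in c("session_c", "consistency", "literacy")) {
    tab <- table(data[[v]] > stats::median(data[[v]]), data$novel)
    if (any(dim(tab) == 1L)) next
    if (any(tab == 0)) {
      stop("complete separation risk on predictor '", v, "'")
    }
  }
  forms <- list(
    novel ~ session_c * consistency + session_c * literacy +
      consistency * literacy + (1 | participant) + (1 | item))
  res <- fit_with_fallback(forms, list(NA), data, family = "binomial")
  new_model_result(res$fit, res$formula, res$fallback, "binomial")
}

#' Mixed model of inter-participant distances across sessions
#'
#' Fits `distance ~ session_z + (1 + session_z | participant_a) +
#' (1 + session_z | participant_b)`: two crossed random factors, one per pair
#' member, with random slopes for (standardised) session. The same fallback
#' ladder as [fit_diversity_lmm()] applies to both random terms jointly.
#'
#' @param data Data frame with columns `session`, `participant_a`,
#'   `participant_b`, `distance` (e.g. from [gower_distances()]).
#' @return An object of class `nwv_model`.
#' @export
fit_distance_lmm <- function(data) {
  stopifnot(all(c("session", "participant_a", "participant_b", "distance")
                %in% names(data)))
  data <- stats::na.omit(tibble::as_tibble(
    data[c("session", "participant_a", "participant_b", "distance")]))
  check_grouping(data, c("participant_a", "participant_b"))
  data$session_z <- as.numeric(scale(data$session))
  forms <- list(
    distance ~ session_z + (1 + session_z | participant_a) + (1 + session_z | participant_b),
    distance ~ session_z + (1 + session_z || participant_a) + (1 + session_z || participant_b),
    distance ~ session_z + (1 | participant_a) + (1 | participant_b))
  labels <- c(NA, "dropped random intercept-slope correlations",
              "dropped random slopes for session")
  res <- fit_with_fallback(forms, labels, data, family = "gaussian")
  new_model_result(res$fit, res$formula, res$fallback, "gaussian")
}

#' Random intercept and slope trajectories of pronunciation frequencies
#'
#' Fits `frequency_c ~ 1 + (1 + session | pronunciation)` where the grouping
#' unit is each (item, pronunciation) combination and `frequency_c` is the
#' centred headcount, then extracts the conditional modes of the random
#' intercepts and slopes. The intercepts order pronunciations by overall
#' popularity; the slopes capture session-to-session change in their use. The
#' Pearson correlation between them summarises whether popular pronunciations
#' spread while rare ones drop out. Pronunciations observed in few sessions
#' are retained and shrunk towards the population, never dropped.
#'
#' @param freqs Tibble from [pronunciation_frequencies()] (columns `item`,
#'   `pronunciation`, `session`, `frequency`).
#' @param center_frequency Centre the frequency after zero-filling (default
#'   `TRUE`).
#' @return List of class `nwv_trajectories`: `trajectories` (tibble: item,
#'   pronunciation, intercept, slope), `cor_intercept_slope`, `n`, `p`
#'   (correlation test), `r_defined` (FALSE when slopes are all ~0), and the
#'   underlying `fit`.
#' @export
fit_trajectories <- function(freqs, center_frequency = TRUE) {
  stopifnot(all(c("item", "pronunciation", "session", "frequency")
                %in% names(freqs)))
  d <- tibble::as_tibble(freqs)
  d$pron_id <- interaction(d$item, d$pronunciation, drop = TRUE, sep = "\r")
  d$frequency_c <- if (center_frequency) d$frequency - mean(d$frequency) else d$frequency
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(frequency_c ~ 1 + (1 + session | pron_id), data = d))),
    error = function(e)  # degenerate (e.g. constant) data: plain lme4 fit
      suppressMessages(suppressWarnings(
        lme4::lmer(frequency_c ~ 1 + (1 + session | pron_id), data = d))))
  re <- lme4::ranef(fit)$pron_id
  ids <- strsplit(rownames(re), "\r", fixed = TRUE)
  traj <- tibble::tibble(
    item = vapply(ids, `[`, character(1), 1),
    pronunciation = vapply(ids, `[`, character(1), 2),
    intercept = re[["(Intercept)"]],
    slope = re[["session"]])
  r_defined <- stats::sd(traj$slope) > 1e-8 && stats::sd(traj$intercept) > 1e-8
  if (r_defined) {
    ct <- stats::cor.test(traj$intercept, traj$slope)
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    r <- NA_real_; p <- NA_real_
  }
  structure(list(trajectories = traj, cor_intercept_slope = r,
                 n = nrow(traj), p = p, r_defined = r_defined, fit = fit),
            class = "nwv_trajectories")
}

#' @export
print.nwv_trajectories <- function(x, ...) {
  cat("<nwv_trajectories> ", x$n, " pronunciations\n", sep = "")
  if (x$r_defined) {
    cat(sprintf("  intercept-slope r = %.3f (N = %d, p = %.3g)\n",
                x$cor_intercept_slope, x$n, x$p))
  } else {
    cat("  intercept-slope correlation undefined (no slope variance)\n")
  }
  invisible(x)
}
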