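# Model-level data generators with known coefficients, used to score
# parameter recovery of each fitting stage at the study's design size.
# Strong-effect defaults are sized so the focal effect is detected with
# near-certain power at 22 participants x 50 items x 5 sessions; null
# settings zero every fixed effect for type-I calibration.

#' Simulate response-diversity data from a known linear mixed model
#'
#' `diversity = b0 + b_c * consistency + b_l * literacy +
#' b_cl * consistency * literacy + u_item + u0_participant +
#' u1_participant * consistency + e`.
#'
#' @param n_participants,n_items Design size.
#' @param beta Named vector `c(intercept, consistency, literacy,
#'   interaction)`.
#' @param sd_item,sd_participant,sd_slope,sigma Standard deviations of the
#'   random item intercept, random participant intercept, random participant
#'   slope for consistency, and the residual.
#' @param seed Integer seed.
#' @return Tibble ready for [fit_diversity_lmm()], with the generating
#'   values attached as attribute `"truth"`.
#' @export
simulate_diversity_data <- function(n_participants = 22, n_items = 50,
                                    beta = c(intercept = 0.4, consistency = -0.15,
                                             literacy = 0, interaction = 0),
                                    sd_item = 0.1, sd_participant = 0.15,
                                    sd_slope = 0.05, sigma = 0.3, seed = 1) {
  set.seed(seed)
  pid <- sprintf("P%02d", seq_len(n_participants))
  iid <- sprintf("I%02d", seq_len(n_items))
  cons <- stats::rnorm(n_items); cons <- cons - mean(cons)
  lit <- stats::rnorm(n_participants); lit <- lit - mean(lit)
  u_i <- stats::rnorm(n_items, 0, sd_item)
  u_p <- stats::rnorm(n_participants, 0, sd_participant)
  u_s <- stats::rnorm(n_participants, 0, sd_slope)
  d <- tidyr::expand_grid(p = seq_len(n_participants), i = seq_len(n_items))
  d$diversity <- beta[["intercept"]] +
    beta[["consistency"]] * cons[d$i] + beta[["literacy"]] * lit[d$p] +
    beta[["interaction"]] * cons[d$i] * lit[d$p] +
    u_i[d$i] + u_p[d$p] + u_s[d$p] * cons[d$i] +
    stats::rnorm(nrow(d), 0, sigma)
  out <- tibble::tibble(participant = pid[d$p], item = iid[d$i],
                        consistency = cons[d$i], literacy = lit[d$p],
                        diversity = d$diversity)
  attr(out, "truth") <- list(beta = beta)
  out
}

#' Simulate novel-pronunciation data from a known binomial GLMM
#'
#' Bernoulli outcomes with
#' `logit(p) = b0 + b_s * session_c + b_c * consistency + b_l * literacy +
#' two-way interactions + u_participant + u_item`, over sessions 2..5.
#'
#' @param n_participants,n_items,n_sessions Design size (sessions 2 to
#'   `n_sessions` are coded).
#' @param beta Named vector `c(intercept, session, consistency, literacy,
#'   session_consistency, session_literacy, consistency_literacy)`.
#' @param sd_participant,sd_item Random-intercept standard deviations.
#' @param seed Integer seed.
#' @return Tibble ready for [fit_novelty_glmm()], truth attached.
#' @export
simulate_novelty_data <- function(n_participants = 22, n_items = 50,
                                  n_sessions = 5,
                                  beta = c(intercept = -1.2, session = -0.8,
                                           consistency = -0.4, literacy = 0,
                                           session_consistency = 0,
                                           session_literacy = 0,
                                           consistency_literacy = 0),
                                  sd_participant = 0.3, sd_item = 0.3,
                                  seed = 1) {
  set.seed(seed)
  pid <- sprintf("P%02d", seq_len(n_participants))
  iid <- sprintf("I%02d", seq_len(n_items))
  cons <- stats::rnorm(n_items); cons <- cons - mean(cons)
  lit <- stats::rnorm(n_participants); lit <- lit - mean(lit)
  u_p <- stats::rnorm(n_participants, 0, sd_participant)
  u_i <- stats::rnorm(n_items, 0, sd_item)
  d <- tidyr::expand_grid(p = seq_len(n_participants), i = seq_len(n_items),
                          session = 2:n_sessions)
  sc <- d$session - mean(d$session)
  eta <- beta[["intercept"]] + beta[["session"]] * sc +
    beta[["consistency"]] * cons[d$i] + beta[["literacy"]] * lit[d$p] +
    beta[["session_consistency"]] * sc * cons[d$i] +
    beta[["session_literacy"]] * sc * lit[d$p] +
    beta[["consistency_literacy"]] * cons[d$i] * lit[d$p] +
    u_p[d$p] + u_i[d$i]
  out <- tibble::tibble(participant = pid[d$p], item = iid[d$i],
                        session = d$session, consistency = cons[d$i],
                        literacy = lit[d$p],
                        novel = stats::rbinom(nrow(d), 1, stats::plogis(eta)))
  attr(out, "truth") <- list(beta = beta)
  out
}

#' Simulate inter-participant distance data from a known mixed model
#'
#' All unordered pairs of participants per session (the final session
#' missing `dropout` participants), with
#' `distance = b0 + b_s * session_z + u0_a + u1_a * session_z + u0_b +
#' u1_b * session_z + e`.
#'
#' @param n_participants,n_sessions,dropout Design size.
#' @param beta Named vector `c(intercept, session)` on the standardised
#'   session scale.
#' @param sd_intercept,sd_slope,sigma Random-effect and residual standard
#'   deviations (shared by both pair members).
#' @param seed Integer seed.
#' @return Tibble ready for [fit_distance_lmm()], truth attached.
#' @export
simulate_distance_data <- function(n_participants = 22, n_sessions = 5,
                                   dropout = 2,
                                   beta = c(intercept = 0.6, session = -0.03),
                                   sd_intercept = 0.05, sd_slope = 0.01,
                                   sigma = 0.08, seed = 1) {
  set.seed(seed)
  pid <- sprintf("P%02d", seq_len(n_participants))
  u0 <- stats::rnorm(n_participants, 0, sd_intercept)
  u1 <- stats::rnorm(n_participants, 0, sd_slope)
  dropped <- if (dropout > 0) sample(seq_len(n_participants), dropout) else integer(0)
  rows <- lapply(seq_len(n_sessions), function(s) {
    present <- if (s == n_sessions) setdiff(seq_len(n_participants), dropped)
               else seq_len(n_participants)
    pairs <- utils::combn(present, 2)
    tibble::tibble(session = s, a = pairs[1, ], b = pairs[2, ])
  })
  d <- dplyr::bind_rows(rows)
  sz <- as.numeric(scale(d$session))
  d$distance <- beta[["intercept"]] + beta[["session"]] * sz +
    u0[d$a] + u1[d$a] * sz + u0[d$b] + u1[d$b] * sz +
    stats::rnorm(nrow(d), 0, sigma)
  out <- tibble::tibble(session = d$session, participant_a = pid[d$a],
                        participant_b = pid[d$b], distance = d$distance)
  attr(out, "truth") <- list(beta = beta)
  out
}

#' Simulate pronunciation-frequency trajectories with a known
#' intercept-slope correlation
#'
#' Each pronunciation draws a (intercept, slope) pair from a bivariate
#' normal with correlation `rho`; its frequency at session `t` is
#' `intercept + slope * t + e`. Positive `rho` makes popular pronunciations
#' gain users over sessions while rare ones lose them.
#'
#' @param n_pronunciations Number of (item, pronunciation) units.
#' @param n_sessions Sessions retained (default 4).
#' @param rho True intercept-slope correlation.
#' @param sd_intercept,sd_slope,sigma Scale parameters.
#' @param seed Integer seed.
#' @return Tibble ready for [fit_trajectories()], truth attached.
#' @export
simulate_trajectory_data <- function(n_pronunciations = 300, n_sessions = 4,
                                     rho = 0.6, sd_intercept = 0.8,
                                     sd_slope = 0.08, sigma = 0.3, seed = 1) {
  set.seed(seed)
  z1 <- stats::rnorm(n_pronunciations)
  z2 <- stats::rnorm(n_pronunciations)
  int <- sd_intercept * z1
  slo <- sd_slope * (rho * z1 + sqrt(1 - rho^2) * z2)
  d <- tidyr::expand_grid(k = seq_len(n_pronunciations),
                          session = seq_len(n_sessions))
  d$frequency <- int[d$k] + slo[d$k] * d$session + stats::rnorm(nrow(d), 0, sigma)
  out <- tibble::tibble(item = sprintf("I%03d", d$k),
                        pronunciation = sprintf("pron%03d", d$k),
                        session = d$session, frequency = d$frequency)
  attr(out, "truth") <- list(rho = rho)
  out
}

null_beta <- function(beta) {
  beta[setdiff(names(beta), "intercept")] <- 0
  beta
}

# focal terms whose sign recovery is scored per stage
FOCAL_TERMS <- list(
  diversity = "consistency",
  novelty = c("session_c", "consistency"),
  distance = "session_z",
  trajectory = "cor_intercept_slope"
)

# map model terms to the names used in the generators' beta vectors
TERM_TO_TRUTH <- c(
  consistency = "consistency", literacy = "literacy",
  "consistency:literacy" = "consistency_literacy",
  session_c = "session", "session_c:consistency" = "session_consistency",
  "session_c:literacy" = "session_literacy", session_z = "session"
)

run_one_replicate <- function(stage, effect, seed) {
  strong <- effect == "strong"
  if (stage == "trajectory") {
    rho <- if (strong) 0.6 else 0
    dat <- simulate_trajectory_data(rho = rho, seed = seed)
    res <- fit_trajectories(dat, center_frequency = TRUE)
    ct <- stats::cor.test(res$trajectories$intercept, res$trajectories$slope)
    return(tibble::tibble(
      stage = stage, term = "cor_intercept_slope",
      estimate = res$cor_intercept_slope, se = NA_real_, p = res$p,
      true = rho,
      ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2]))
  }
  sim <- switch(stage,
    diversity = function(b, s) simulate_diversity_data(beta = b, seed = s),
    novelty = function(b, s) simulate_novelty_data(beta = b, seed = s),
    distance = function(b, s) simulate_distance_data(beta = b, seed = s))
  fitter <- switch(stage,
    diversity = fit_diversity_lmm,
    novelty = fit_novelty_glmm,
    distance = fit_distance_lmm)
  beta <- eval(formals(switch(stage,
    diversity = simulate_diversity_data,
    novelty = simulate_novelty_data,
    distance = simulate_distance_data))$beta)
  if (!strong) beta <- null_beta(beta)
  dat <- sim(beta, seed)
  fe <- fitter(dat)$fixed_effects
  fe <- fe[fe$term != "(Intercept)", ]
  truth_name <- TERM_TO_TRUTH[fe$term]
  crit <- ifelse(is.na(fe$df), stats::qnorm(0.975), stats::qt(0.975, fe$df))
  tibble::tibble(
    stage = stage, term = fe$term, estimate = fe$estimate, se = fe$se,
    p = fe$p, true = unname(beta[truth_name]),
    ci_lo = fe$estimate - crit * fe$se,
    ci_hi = fe$estimate + crit * fe$se)
}

#' Parameter-recovery suite for the model stages
#'
#' Repeatedly simulates data with known coefficients at the study design
#' size (22 participants, 50 items, 5 sessions), fits the corresponding
#' model stage, and scores recovery. Under `effect = "strong"` the focal
#' effects are large enough that their signs should be recovered essentially
#' always; under `effect = "null"` every fixed effect is zero and the
#' rejection rate at `p < .05` calibrates type-I error. A replicate whose
#' fit fails is recorded with its error message rather than aborting the
#' suite.
#'
#' @param stages Subset of `c("diversity", "novelty", "distance",
#'   "trajectory")`.
#' @param effect `"strong"` or `"null"`.
#' @param n_replicates Replicates per stage (default 25).
#' @param seed Base seed; replicate `r` uses `seed * 1000 + r`.
#' @return Tibble with one row per stage x replicate x fixed term:
#'   `estimate`, `se`, `p`, `true`, `ci_lo`, `ci_hi`, plus
#'   `sign_correct` (focal nonzero effects only), `ci_covered`,
#'   `focal`, `error`.
#' @export
recovery_suite <- function(stages = c("diversity", "novelty", "distance",
                                      "trajectory"),
                           effect = c("strong", "null"),
                           n_replicates = 25, seed = 1) {
  effect <- match.arg(effect)
  stages <- match.arg(stages, several.ok = TRUE)
  out <- list()
  for (stage in stages) {
    for (r in seq_len(n_replicates)) {
      rep_seed <- seed * 1000L + r
      res <- tryCatch(run_one_replicate(stage, effect, rep_seed),
                      error = function(e) {
                        tibble::tibble(stage = stage, term = NA_character_,
                                       estimate = NA_real_, se = NA_real_,
                                       p = NA_real_, true = NA_real_,
                                       ci_lo = NA_real_, ci_hi = NA_real_,
                                       error = conditionMessage(e))
                      })
      if (!"error" %in% names(res)) res$error <- NA_character_
      res$replicate <- r
      out[[length(out) + 1L]] <- res
    }
  }
  res <- dplyr::bind_rows(out)
  res$focal <- mapply(function(s, tm) tm %in% FOCAL_TERMS[[s]],
                      res$stage, res$term)
  res$sign_correct <- ifelse(res$focal & !is.na(res$true) & res$true != 0,
                             sign(res$estimate) == sign(res$true), NA)
  res$ci_covered <- res$true >= res$ci_lo & res$true <= res$ci_hi
  res
}

#' Summarise a recovery-suite run
#'
#' @param results Tibble from [recovery_suite()].
#' @return Tibble per stage: sign-recovery rate over focal terms, CI
#'   coverage, bias and RMSE of focal estimates, rejection rate of true-null
#'   terms at `p < .05`, and number of failed replicates.
#' @export
summarise_recovery <- function(results) {
  results |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(
      n_failed = dplyr::n_distinct(.data$replicate[!is.na(.data$error)]),
      sign_recovery = mean(.data$sign_correct[.data$focal], na.rm = TRUE),
      ci_coverage = mean(.data$ci_covered, na.rm = TRUE),
      bias = mean((.data$estimate - .data$true)[.data$focal], na.rm = TRUE),
      rmse = sqrt(mean(((.data$estimate - .data$true)^2)[.data$focal], na.rm = TRUE)),
      type1 = mean(.data$p[!is.na(.data$true) & .data$true == 0] < 0.05,
                   na.rm = TRUE),
      .groups = "drop")
}
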