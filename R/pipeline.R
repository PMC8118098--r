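#' Assemble and validate a pipeline configuration
#'
#' @param lexicon,rules,nonwords Paths to the syllabified lexicon TSV,
#'   grapheme rule CSV and nonword list (one per line).
#' @param responses Path to the response CSV.
#' @param overrides Optional path to a syllabification override CSV.
#' @param literacy Optional path to a literacy CSV (`participant`,
#'   `spelling`, `vocabulary`); without it the models involving literacy are
#'   skipped.
#' @param out_dir Output directory.
#' @param weighting GPC weighting, `"types"` or `"tokens"`.
#' @param transform,eps Consistency covariate transform, see
#'   [score_nonwords()].
#' @param drop_last_session_freqs Exclude the final session from
#'   pronunciation frequencies (default `TRUE`).
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(lexicon, rules, nonwords, responses,
                            overrides = NULL, literacy = NULL,
                            out_dir = "nonwordvar-out",
                            weighting = "types", transform = "log",
                            eps = 0.01, drop_last_session_freqs = TRUE,
                            seed = 1L) {
  cfg <- list(lexicon = lexicon, rules = rules, nonwords = nonwords,
              responses = responses, overrides = overrides,
              literacy = literacy, out_dir = out_dir, weighting = weighting,
              transform = transform, eps = eps,
              drop_last_session_freqs = drop_last_session_freqs,
              seed = as.integer(seed))
  for (f in c("lexicon", "rules", "nonwords", "responses")) {
    if (!file.exists(cfg[[f]])) stop("input file for '", f, "' not found: ", cfg[[f]])
  }
  for (f in c("overrides", "literacy")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("input file for '", f, "' not found: ", cfg[[f]])
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of
#'   [pipeline_config()]. Relative paths are resolved against the YAML
#'   file's directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is needed to read YAML configs")
  }
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("lexicon", "rules", "nonwords", "responses", "overrides",
              "literacy")) {
    if (!is.null(raw[[f]]) && !grepl("^(/|[A-Za-z]:)", raw[[f]])) {
      raw[[f]] <- file.path(base, raw[[f]])
    }
  }
  do.call(pipeline_config, raw)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(cfg)[order(names(unclass(cfg)))], tmp)
  unname(tools::md5sum(tmp))
}

model_result_json <- function(x) {
  list(formula = x$formula,
       fixed_effects = x$fixed_effects,
       variance_components = x$variance_components,
       r2_marginal = x$r2_marginal,
       r2_conditional = x$r2_conditional,
       fallback_applied = if (is.null(x$fallback_applied)) NULL else x$fallback_applied,
       singular = x$singular)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: GPC extraction from the lexicon, nonword consistency
#' scoring, response statistics (distinct counts, diversity, novelty,
#' per-session Gower distances, pronunciation frequencies), and the model
#' stages (one-sample t tests of distinct counts against 1; diversity LMM;
#' novelty GLMM; distance LMM; frequency-trajectory random effects). Every
#' table is written as a tidy CSV under `out_dir`, the model results as
#' `models.json`, and a run manifest (`manifest.json`) records package
#' version, seed, config hash and any random-effects fallbacks. The literacy
#' models require a literacy file; without one the diversity and novelty
#' models set the literacy covariate to zero and record that in the
#' manifest.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @return Invisibly, a list of the in-memory results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  notes <- character(0)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  # gpc
  gpc <- stage("gpc", {
    lex <- read_lexicon(config$lexicon)
    rules <- read_grapheme_rules(config$rules)
    build_gpc_table(lex, rules, weighting = config$weighting)
  })
  write_gpc_table(gpc, file.path(out, "gpc.csv"))

  # score
  consistency <- stage("score", {
    nonwords <- readLines(config$nonwords, encoding = "UTF-8")
    nonwords <- trimws(nonwords[trimws(nonwords) != ""])
    ov <- if (!is.null(config$overrides)) read_syllable_overrides(config$overrides)
    score_nonwords(nonwords, gpc, overrides = ov,
                   transform = config$transform, eps = config$eps)
  })
  readr::write_csv(consistency, file.path(out, "consistency.csv"))

  # stats
  stats_out <- stage("stats", {
    resp <- read_responses(config$responses)
    list(responses = resp,
         diversity = diversity_table(resp),
         novelty = novelty_table(resp),
         distances = gower_distances(resp),
         frequencies = pronunciation_frequencies(
           resp, drop_last_session = config$drop_last_session_freqs))
  })
  for (nm in c("diversity", "novelty", "distances", "frequencies")) {
    readr::write_csv(stats_out[[nm]], file.path(out, paste0(nm, ".csv")))
  }

  # literacy
  lit <- NULL
  if (!is.null(config$literacy)) {
    lit <- stage("literacy", {
      df <- readr::read_csv(config$literacy, col_types = readr::cols(
        participant = "c", spelling = "d", vocabulary = "d"),
        progress = FALSE)
      composite_literacy(df)
    })
    readr::write_csv(lit, file.path(out, "literacy.csv"))
  } else {
    notes <- c(notes, "no literacy file: literacy covariate fixed at 0")
  }

  # fit
  models <- stage("fit", {
    div <- stats_out$diversity |>
      dplyr::left_join(consistency[c("nonword", "covariate")],
                       by = c(item = "nonword")) |>
      dplyr::rename(consistency = "covariate")
    lit_map <- if (is.null(lit)) NULL else setNames(lit$composite, lit$participant)
    add_lit <- function(d) {
      d$literacy <- if (is.null(lit_map)) 0 else unname(lit_map[d$participant])
      d
    }
    div <- add_lit(div)
    nov <- add_lit(
      stats_out$novelty |>
        dplyr::left_join(consistency[c("nonword", "covariate")],
                         by = c(item = "nonword")) |>
        dplyr::rename(consistency = "covariate"))
    by_participant <- stats_out$diversity |>
      dplyr::group_by(.data$participant) |>
      dplyr::summarise(m = mean(.data$n_distinct))
    by_item <- stats_out$diversity |>
      dplyr::group_by(.data$item) |>
      dplyr::summarise(m = mean(.data$n_distinct))
    traj <- fit_trajectories(stats_out$frequencies)
    list(
      distinct_counts = list(
        by_participant = ttest_vs_one(by_participant$m),
        by_item = ttest_vs_one(by_item$m)),
      diversity = fit_diversity_lmm(div),
      novelty = fit_novelty_glmm(nov),
      distance = fit_distance_lmm(stats_out$distances),
      trajectories = traj)
  })

  fallbacks <- Filter(Negate(is.null), lapply(
    models[c("diversity", "novelty", "distance")],
    function(m) m$fallback_applied))
  manifest <- list(
    package = "nonwordvar",
    version = as.character(utils::packageVersion("nonwordvar")),
    r_version = R.version.string,
    seed = config$seed,
    config_hash = config_hash(config),
    n_syllables_used = gpc$n_syllables_used,
    n_syllables_discarded = gpc$n_syllables_discarded,
    fallbacks = fallbacks,
    notes = notes,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(
    list(distinct_counts = models$distinct_counts,
         diversity = model_result_json(models$diversity),
         novelty = model_result_json(models$novelty),
         distance = model_result_json(models$distance),
         trajectories = list(
           cor_intercept_slope = models$trajectories$cor_intercept_slope,
           n = models$trajectories$n, p = models$trajectories$p)),
    file.path(out, "models.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(list(gpc = gpc, consistency = consistency, stats = stats_out,
                 literacy = lit, models = models, manifest = manifest))
}
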