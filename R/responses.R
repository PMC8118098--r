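# IPA stress marks: primary (U+02C8), secondary (U+02CC), and their ASCII
# stand-ins sometimes used in transcriptions.
STRESS_MARKS <- "[ˈˌ']"

#' Normalise a phonemic transcription
#'
#' Strips lexical-stress marks, trims whitespace, and applies Unicode NFC so
#' that composed and decomposed encodings of the same IPA string compare
#' equal. Equality of normalised strings defines "same pronunciation"
#' throughout the package.
#'
#' @param raw Character vector of transcriptions.
#' @return Character vector of normalised pronunciations.
#' @export
normalize_transcription <- function(raw) {
  out <- stringi::stri_trans_nfc(raw)
  out <- stringr::str_remove_all(out, STRESS_MARKS)
  out <- stringr::str_trim(out)
  if (any(!is.na(out) & out == "")) {
    stop("transcription empty after normalisation")
  }
  out
}

#' Read and validate a response table
#'
#' CSV columns: `participant`, `session` (integer), `item`, `pronunciation`
#' (IPA, UTF-8). Pronunciations are normalised with
#' [normalize_transcription()]. Rows with a missing or empty pronunciation
#' (non-responses) are dropped with a message by default. Validation enforces
#' uniqueness of (participant, session, item) and that each participant's
#' sessions form a contiguous block 1..s_max (dropping out of later sessions
#' is allowed; gaps are not).
#'
#' @param path CSV path.
#' @param on_missing `"drop"` (default) or `"error"` for empty/NA
#'   pronunciations.
#' @return Tibble with columns `participant`, `session`, `item`,
#'   `pronunciation`.
#' @export
read_responses <- function(path, on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  df <- readr::read_csv(path, col_types = readr::cols(
    participant = "c", session = "i", item = "c", pronunciation = "c"),
    progress = FALSE)
  miss <- is.na(df$pronunciation) | stringr::str_trim(df$pronunciation) == ""
  if (any(miss)) {
    if (on_missing == "error") stop(sum(miss), " missing pronunciations")
    message("dropping ", sum(miss), " rows with missing pronunciations")
    df <- df[!miss, ]
  }
  df$pronunciation <- normalize_transcription(df$pronunciation)
  validate_responses(df)
}

#' Validate an in-memory response table
#'
#' @param df Data frame with columns `participant`, `session`, `item`,
#'   `pronunciation`.
#' @return The table as a tibble, sorted by participant, item, session.
#' @export
validate_responses <- function(df) {
  required <- c("participant", "session", "item", "pronunciation")
  stopifnot(all(required %in% names(df)))
  df <- tibble::as_tibble(df[required])
  df$session <- as.integer(df$session)
  if (anyDuplicated(df[c("participant", "session", "item")])) {
    stop("duplicate (participant, session, item) rows")
  }
  bad <- df |>
    dplyr::distinct(.data$participant, .data$session) |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      ok = setequal(.data$session, seq_len(max(.data$session))),
      .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop("sessions are not a contiguous 1..s_max block for participant(s): ",
         paste(bad$participant, collapse = ", "))
  }
  dplyr::arrange(df, .data$participant, .data$item, .data$session)
}

#' Number of distinct pronunciations across sessions
#'
#' @param pronunciations Character vector: one participant's responses to one
#'   item, one element per session.
#' @return Integer between 1 and the number of sessions.
#' @export
count_distinct <- function(pronunciations) {
  stopifnot(length(pronunciations) >= 1)
  length(unique(pronunciations))
}

#' Response diversity of one participant-item series
#'
#' Shannon entropy (nats) of the empirical distribution of pronunciations
#' over sessions: `sum(-p_i * log(p_i))` where `p_i` is the proportion of
#' sessions in which pronunciation `i` was used. Zero when the response never
#' changes; `log(n_sessions)` when every session's response is distinct.
#'
#' @inheritParams count_distinct
#' @return Entropy in nats.
#' @export
response_diversity <- function(pronunciations) {
  stopifnot(length(pronunciations) >= 1)
  shannon_entropy(table(pronunciations) / length(pronunciations))
}

#' Per participant-item variability summary
#'
#' @param records Validated response table (see [validate_responses()]).
#' @return Tibble with one row per (participant, item): `n_sessions`,
#'   `n_distinct`, `diversity` (nats).
#' @export
diversity_table <- function(records) {
  records |>
    dplyr::group_by(.data$participant, .data$item) |>
    dplyr::summarise(n_sessions = dplyr::n(),
                     n_distinct = count_distinct(.data$pronunciation),
                     diversity = response_diversity(.data$pronunciation),
                     .groups = "drop")
}

#' Code novel pronunciations for one session-ordered series
#'
#' A session's response is novel (1) when the participant had not used that
#' pronunciation for that item in any earlier session, and old (0) otherwise.
#' Session 1 is never coded. The flags sum to `n_distinct - 1`.
#'
#' @param pronunciations Character vector ordered by session, sessions
#'   `1..length(pronunciations)` contiguous.
#' @return Integer vector of length `length(pronunciations) - 1` (sessions 2
#'   onwards).
#' @export
code_novelty <- function(pronunciations) {
  n <- length(pronunciations)
  stopifnot(n >= 1)
  if (n == 1L) return(integer(0))
  vapply(2:n, function(s) {
    as.integer(!pronunciations[s] %in% pronunciations[seq_len(s - 1L)])
  }, integer(1))
}

#' Novel-pronunciation table for all participants and items
#'
#' @param records Validated response table.
#' @return Tibble with one row per (participant, item, session >= 2):
#'   column `novel` is 1 for a pronunciation not used in any earlier session.
#' @export
novelty_table <- function(records) {
  records |>
    dplyr::arrange(.data$participant, .data$item, .data$session) |>
    dplyr::group_by(.data$participant, .data$item) |>
    dplyr::group_modify(function(d, key) {
      if (!identical(d$session, seq_len(nrow(d)))) {
        stop("sessions for participant ", key$participant, ", item ",
             key$item, " are not contiguous from 1")
      }
      if (nrow(d) == 1L) return(tibble::tibble(session = integer(0),
                                               novel = integer(0)))
      tibble::tibble(session = d$session[-1],
                     novel = code_novelty(d$pronunciation))
    }) |>
    dplyr::ungroup()
}

#' Per-session Gower distances between participants' response sets
#'
#' For each session the response table is cast into a participants-by-items
#' matrix of categorical pronunciations, and the Gower dissimilarity between
#' every two rows is computed with [cluster::daisy()]. For purely categorical
#' data this is the proportion of mismatching items among the items both
#' participants responded to; items missing for either member of a pair are
#' excluded (standard Gower handling) and the number of mutually answered
#' items is recorded. Participants with no responses in a session are omitted
#' (with a warning when they responded in other sessions but contribute no
#' usable items here).
#'
#' @param records Validated response table.
#' @return Tibble of all unordered pairs per session: `session`,
#'   `participant_a`, `participant_b`, `distance` in `[0, 1]`,
#'   `n_items_compared`.
#' @export
gower_distances <- function(records) {
  sessions <- sort(unique(records$session))
  out <- lapply(sessions, function(s) {
    d <- records[records$session == s, ]
    wide <- tidyr::pivot_wider(d[c("participant", "item", "pronunciation")],
                               names_from = "item",
                               values_from = "pronunciation")
    parts <- wide$participant
    m <- as.data.frame(lapply(wide[-1], factor), check.names = FALSE)
    rownames(m) <- parts
    n_resp <- rowSums(!is.na(m))
    if (any(n_resp == 0L)) {
      warning("session ", s, ": excluding participant(s) with no responses: ",
              paste(parts[n_resp == 0L], collapse = ", "))
      m <- m[n_resp > 0L, , drop = FALSE]
      parts <- parts[n_resp > 0L]
    }
    if (length(parts) < 2L) return(NULL)
    dd <- as.matrix(cluster::daisy(m, metric = "gower", warnBin = FALSE,
                                   warnAsym = FALSE, warnConst = FALSE))
    shared <- (!is.na(as.matrix(m))) %*% t(!is.na(as.matrix(m)) * 1)
    idx <- which(upper.tri(dd), arr.ind = TRUE)
    tibble::tibble(session = s,
                   participant_a = parts[idx[, 1]],
                   participant_b = parts[idx[, 2]],
                   distance = dd[idx],
                   n_items_compared = as.integer(shared[idx]))
  })
  dplyr::bind_rows(out)
}

#' Pronunciation frequencies per item and session
#'
#' Counts how many participants used each pronunciation of each item in each
#' session. Any pronunciation observed in some session of an item is
#' zero-filled in the sessions of that item where nobody used it, so
#' frequency trajectories are complete. The final session can be excluded
#' (the default), since fewer participants may have attended it and raw
#' headcounts would be biased downwards.
#'
#' @param records Validated response table.
#' @param drop_last_session Exclude the highest session number (default
#'   `TRUE`).
#' @return Tibble: `item`, `pronunciation`, `session`, `frequency`.
#' @export
pronunciation_frequencies <- function(records, drop_last_session = TRUE) {
  if (drop_last_session) {
    records <- records[records$session < max(records$session), ]
  }
  counts <- dplyr::count(records, .data$item, .data$pronunciation,
                         .data$session, name = "frequency")
  grid <- tidyr::expand_grid(
    dplyr::distinct(counts, .data$item, .data$pronunciation),
    session = sort(unique(records$session)))
  out <- dplyr::left_join(grid, counts,
                          by = c("item", "pronunciation", "session"))
  out$frequency[is.na(out$frequency)] <- 0L
  dplyr::arrange(out, .data$item, .data$pronunciation, .data$session)
}
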