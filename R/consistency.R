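# Legal English onset clusters used by the fallback syllabifier. Single
# consonants are always legal onsets and need not be listed.
LEGAL_ONSETS <- c(
  "BL", "BR", "CH", "CL", "CR", "DR", "DW", "FL", "FR", "GL", "GR", "GN",
  "KN", "PH", "PL", "PR", "QU", "SC", "SH", "SK", "SL", "SM", "SN", "SP",
  "SQ", "ST", "SW", "TH", "TR", "TW", "WH", "WR", "SCR", "SHR", "SPL",
  "SPR", "SQU", "STR", "THR", "CHR", "PHR", "SCH"
)

is_legal_onset <- function(cluster) {
  nchar(cluster) <= 1L || cluster %in% LEGAL_ONSETS
}

#' Split a nonword into syllables
#'
#' Manual syllabifications supplied via `overrides` are authoritative (they
#' play the role of hand-parsed item lists). Otherwise a rule-based fallback
#' applies: vowel letters (A, E, I, O, U, and Y when not adjacent to another
#' vowel letter) are grouped into maximal runs; between two vowel groups the
#' intervening consonant cluster is split so that the onset donated to the
#' following syllable is the longest legal English onset (onset
#' maximisation). A word with a single vowel group is returned whole.
#'
#' @param nonword Alphabetic string.
#' @param overrides Optional named character vector or data frame
#'   (columns `nonword`, `syllabification`, `-`-separated) of manual splits.
#' @return Character vector of syllables whose concatenation equals
#'   `toupper(nonword)`.
#' @examples
#' syllabify_nonword("BAMP")
#' syllabify_nonword("BUDGORD")
#' syllabify_nonword("BLISPLE", overrides = c(BLISPLE = "BLI-SPLE"))
#' @export
syllabify_nonword <- function(nonword, overrides = NULL) {
  nonword <- toupper(trimws(nonword))
  if (is.na(nonword) || !grepl("^[A-Z]+$", nonword)) {
    stop("nonword must be a nonempty alphabetic string, got '", nonword, "'")
  }
  ov <- normalize_overrides(overrides)
  if (!is.null(ov) && nonword %in% names(ov)) {
    syls <- strsplit(ov[[nonword]], "-", fixed = TRUE)[[1]]
    if (paste(syls, collapse = "") != nonword) {
      stop("override for '", nonword, "' does not spell the nonword")
    }
    return(syls)
  }

  letters_ <- strsplit(nonword, "")[[1]]
  is_vowel <- letters_ %in% c("A", "E", "I", "O", "U")
  # Y is vocalic unless adjacent to a vowel letter (MYST vs YARN, PLAY)
  for (i in which(letters_ == "Y")) {
    left <- if (i > 1L) is_vowel[i - 1L] else FALSE
    right <- if (i < length(letters_)) letters_[i + 1L] %in% c("A", "E", "I", "O", "U") else FALSE
    is_vowel[i] <- !(left || right)
  }
  groups <- rle(is_vowel)
  ends <- cumsum(groups$lengths)
  starts <- ends - groups$lengths + 1L
  v_idx <- which(groups$values)
  if (length(v_idx) <= 1L) return(nonword)

  # boundary inside each consonant run between two vowel groups
  cuts <- integer(0)
  for (k in seq_len(length(v_idx) - 1L)) {
    run <- v_idx[k] + 1L
    if (run > length(groups$values) || groups$values[run]) {
      # adjacent vowel groups cannot occur (maximal runs); defensive
      cuts <- c(cuts, ends[v_idx[k]])
      next
    }
    c_start <- starts[run]
    c_end <- ends[run]
    cluster <- substr(nonword, c_start, c_end)
    len <- nchar(cluster)
    onset_len <- 0L
    for (L in seq(min(len, 3L), 0L)) {
      if (L == 0L || is_legal_onset(substr(cluster, len - L + 1L, len))) {
        onset_len <- L
        break
      }
    }
    cuts <- c(cuts, c_end - onset_len)
  }
  bounds <- c(0L, cuts, nchar(nonword))
  vapply(seq_len(length(bounds) - 1L),
         function(i) substr(nonword, bounds[i] + 1L, bounds[i + 1L]),
         character(1))
}

normalize_overrides <- function(overrides) {
  if (is.null(overrides)) return(NULL)
  if (is.data.frame(overrides)) {
    stopifnot(all(c("nonword", "syllabification") %in% names(overrides)))
    ov <- toupper(overrides$syllabification)
    names(ov) <- toupper(overrides$nonword)
    return(as.list(ov))
  }
  out <- as.list(toupper(unlist(overrides)))
  names(out) <- toupper(names(overrides))
  out
}

#' Read a syllabification override file
#'
#' CSV with columns `nonword` and `syllabification` (`-`-separated).
#'
#' @param path CSV path.
#' @return Tibble usable as the `overrides` argument of
#'   [syllabify_nonword()] and [item_consistency()].
#' @export
read_syllable_overrides <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  stopifnot(all(c("nonword", "syllabification") %in% names(df)))
  tibble::as_tibble(df)
}

# Entropy of one matched rule under a GPC table, with fallback to the
# grapheme's unconditioned rule. Returns list(entropy, provenance) or NULL.
lookup_entropy <- function(ent, grapheme, position_class, context_set) {
  hit <- ent[ent$grapheme == grapheme & ent$position_class == position_class &
               ent$context_set == context_set, ]
  if (nrow(hit) > 0) {
    return(list(entropy = hit$entropy[1], provenance = "exact"))
  }
  hit <- ent[ent$grapheme == grapheme & ent$position_class == "any" &
               ent$context_set == "", ]
  if (nrow(hit) > 0) {
    return(list(entropy = hit$entropy[1], provenance = "fallback"))
  }
  NULL
}

#' Spelling-sound consistency of one nonword
#'
#' The nonword is syllabified ([syllabify_nonword()]), each syllable is parsed
#' into graphemes under the GPC table's rule inventory, and each grapheme
#' receives the pronunciation entropy of its matched rule (falling back to the
#' grapheme's unconditioned rule when the matched rule was never observed in
#' the lexicon; a grapheme with no entry at all is an error). Grapheme
#' entropies are averaged within each syllable; the primary measure is the
#' entropy of the most inconsistent syllable, multiplied by -1 so that higher
#' values mean more predictable spelling-sound mappings.
#'
#' Alternative aggregations (negated likewise) are returned for the
#' metric-selection step: mean/sum/max over all graphemes, and mean/sum of the
#' per-syllable means.
#'
#' @param nonword Alphabetic string.
#' @param table A `gpc_table` (see [build_gpc_table()]).
#' @param overrides Optional manual syllabifications, see
#'   [syllabify_nonword()].
#' @return A one-row tibble: `nonword`, `syllables` (`-`-separated), `raw`
#'   (negated entropy of the most inconsistent syllable, `<= 0`),
#'   `n_fallback` (graphemes scored via the unconditioned fallback), and the
#'   alternative metrics `gr_mean`, `gr_sum`, `gr_max`, `syl_mean`,
#'   `syl_sum`.
#' @export
item_consistency <- function(nonword, table, overrides = NULL) {
  stopifnot(inherits(table, "gpc_table"))
  syls <- syllabify_nonword(nonword, overrides)
  ent <- gpc_entropies(table)
  n_syl <- length(syls)
  syl_means <- numeric(n_syl)
  all_h <- numeric(0)
  n_fallback <- 0L
  for (i in seq_len(n_syl)) {
    parse <- parse_syllable(syls[i], table$rules, i, n_syl)
    h <- numeric(nrow(parse))
    for (j in seq_len(nrow(parse))) {
      hit <- lookup_entropy(ent, parse$grapheme[j], parse$position_class[j],
                            parse$context_set[j])
      if (is.null(hit)) {
        stop("no GPC record (nor unconditioned fallback) for grapheme '",
             parse$grapheme[j], "' in '", toupper(nonword), "'")
      }
      if (hit$provenance == "fallback") n_fallback <- n_fallback + 1L
      h[j] <- hit$entropy
    }
    syl_means[i] <- mean(h)
    all_h <- c(all_h, h)
  }
  tibble::tibble(
    nonword = toupper(nonword),
    syllables = paste(syls, collapse = "-"),
    raw = -max(syl_means),
    n_fallback = n_fallback,
    gr_mean = -mean(all_h),
    gr_sum = -sum(all_h),
    gr_max = -max(all_h),
    syl_mean = -mean(syl_means),
    syl_sum = -sum(syl_means)
  )
}

#' Score a set of nonwords and build the model covariate
#'
#' Applies [item_consistency()] to each nonword and adds the covariate used in
#' the mixed models. The negated raw metric is nonpositive, so it has no real
#' logarithm; the log transform is therefore applied to the magnitude:
#' `covariate = -log(H_maxsyll + eps)` centred over the scored item set, which
#' preserves the sign convention (higher = more consistent). Set
#' `transform = "identity"` to centre the raw negated metric instead.
#'
#' @param nonwords Character vector of nonwords.
#' @param table A `gpc_table`.
#' @param overrides Optional manual syllabifications.
#' @param transform `"log"` (default) or `"identity"`.
#' @param eps Offset inside the logarithm, default 0.01.
#' @return Tibble with one row per nonword: the [item_consistency()] columns
#'   plus `covariate` (centred over these items).
#' @export
score_nonwords <- function(nonwords, table, overrides = NULL,
                           transform = c("log", "identity"), eps = 0.01) {
  transform <- match.arg(transform)
  stopifnot(length(nonwords) > 0)
  out <- dplyr::bind_rows(
    lapply(nonwords, item_consistency, table = table, overrides = overrides))
  h_max <- -out$raw
  cov_raw <- switch(transform,
                    log = -log(h_max + eps),
                    identity = out$raw)
  out$covariate <- cov_raw - mean(cov_raw)
  out
}

#' Select the consistency metric most correlated with a dependent variable
#'
#' Reproduces the metric-selection step: among candidate consistency metrics,
#' pick the one whose absolute Pearson correlation with the dependent variable
#' is largest. Zero-variance candidates are excluded with a warning; ties are
#' broken by the declared candidate order.
#'
#' @param candidates Named list (or data frame) of equal-length numeric
#'   vectors.
#' @param dv Numeric vector, same length.
#' @return Name of the winning candidate, with the correlations attached as
#'   attribute `"correlations"`.
#' @export
select_metric <- function(candidates, dv) {
  candidates <- as.list(candidates)
  stopifnot(length(candidates) > 0, !is.null(names(candidates)))
  lens <- lengths(candidates)
  if (any(lens != length(dv))) stop("candidate lengths must match dv")
  r <- vapply(candidates, function(x) {
    if (stats::sd(x) == 0 || stats::sd(dv) == 0) NA_real_ else stats::cor(x, dv)
  }, numeric(1))
  if (anyNA(r)) {
    warning("excluding zero-variance candidate(s): ",
            paste(names(r)[is.na(r)], collapse = ", "))
  }
  if (all(is.na(r))) stop("no candidate with nonzero variance")
  best <- names(r)[which.max(abs(r))]  # which.max takes the first on ties
  structure(best, correlations = r)
}
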