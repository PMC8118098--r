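#' @importFrom rlang .data
#' @importFrom stats var sd cor median setNames
#' @importFrom utils head tail
NULL

#' Shannon entropy of a discrete distribution (nats)
#'
#' Computes `sum(-p * log(p))` over the positive entries of `p`. Probabilities
#' are renormalised defensively; zero entries contribute nothing (the
#' `p * log p -> 0` limit).
#'
#' @param p Numeric vector of nonnegative weights (need not sum to one).
#' @return Entropy in nats, a single nonnegative number. Zero iff at most one
#'   positive entry; maximal (`log(k)`) iff the `k` positive entries are
#'   uniform.
#' @examples
#' shannon_entropy(c(0.5, 0.5))   # log(2)
#' shannon_entropy(c(1, 0, 0))    # 0
#' @export
shannon_entropy <- function(p) {
  stopifnot(is.numeric(p), all(is.finite(p)), all(p >= 0))
  p <- p[p > 0]
  if (length(p) == 0L) stop("entropy of an empty distribution is undefined")
  p <- p / sum(p)
  -sum(p * log(p)) + 0   # "+ 0" normalises IEEE negative zero
}

POSITION_CLASSES <- c("any", "word_initial", "word_final",
                      "syllable_initial", "syllable_final")

#' Read a grapheme rule inventory
#'
#' The inventory is a CSV with columns `grapheme`, `position_class` (one of
#' `any`, `word_initial`, `word_final`, `syllable_initial`, `syllable_final`)
#' and `context_set` (letters separated by `|` that the *following* letter
#' must belong to, or empty for no context condition). File order is
#' meaningful: it breaks ties between equally specific rules.
#'
#' A default inventory covering the single letters A-Z plus common English
#' multi-letter graphemes ships with the package; see
#' `system.file("extdata", "english_graphemes.csv", package = "nonwordvar")`.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `grapheme`, `position_class`, `context_set`
#'   and `rule_id` (file order).
#' @export
read_grapheme_rules <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  required <- c("grapheme", "position_class", "context_set")
  if (!all(required %in% names(df))) {
    stop("rule inventory must have columns: ", paste(required, collapse = ", "))
  }
  as_grapheme_rules(df[required])
}

#' Validate a data frame of grapheme rules
#'
#' @param df Data frame with columns `grapheme`, `position_class`,
#'   `context_set`.
#' @return The validated rule tibble with a `rule_id` column.
#' @export
as_grapheme_rules <- function(df) {
  df <- tibble::as_tibble(df)
  df$grapheme <- toupper(trimws(df$grapheme))
  df$position_class[is.na(df$position_class) | df$position_class == ""] <- "any"
  df$context_set[is.na(df$context_set)] <- ""
  df$context_set <- toupper(gsub(" ", "", df$context_set))
  if (any(df$grapheme == "")) stop("empty grapheme in rule inventory")
  bad <- setdiff(unique(df$position_class), POSITION_CLASSES)
  if (length(bad) > 0) {
    stop("unknown position_class: ", paste(bad, collapse = ", "))
  }
  df$rule_id <- seq_len(nrow(df))
  df
}

#' Default English grapheme inventory
#'
#' @return Rule tibble parsed from the packaged CSV.
#' @export
default_grapheme_rules <- function() {
  read_grapheme_rules(system.file("extdata", "english_graphemes.csv",
                                  package = "nonwordvar"))
}

# Position classes that hold for a grapheme spanning [first, last] letters of
# syllable `syl` out of `n_syl`, when the grapheme is the `g`th of `n_g` in its
# syllable.
applicable_positions <- function(is_first, is_last, syl, n_syl) {
  out <- "any"
  if (is_first) {
    out <- c(out, "syllable_initial")
    if (syl == 1L) out <- c(out, "word_initial")
  }
  if (is_last) {
    out <- c(out, "syllable_final")
    if (syl == n_syl) out <- c(out, "word_final")
  }
  out
}

#' Parse one syllable into graphemes
#'
#' Segmentation is greedy leftmost-longest match over the grapheme strings in
#' the inventory. Each segmented grapheme is then assigned the most specific
#' applicable rule: rules with a context condition (membership of the next
#' letter in `context_set`) beat position-specific rules, which beat
#' unconditioned rules; remaining ties are broken by inventory file order.
#' Context is evaluated within the syllable only, so a syllable-final grapheme
#' never matches a context rule.
#'
#' @param orth Orthographic syllable (letters only).
#' @param rules Rule inventory, see [read_grapheme_rules()].
#' @param syllable_index Position of this syllable in its word (1-based).
#' @param n_syllables Number of syllables in the word.
#' @return Tibble with one row per grapheme: `grapheme`, `position_class`,
#'   `context_set`, `rule_id`. Concatenating `grapheme` reproduces `orth`.
#' @export
parse_syllable <- function(orth, rules, syllable_index = 1L, n_syllables = 1L) {
  orth <- toupper(orth)
  if (is.na(orth) || nchar(orth) == 0L) stop("empty syllable")
  glyphs <- unique(rules$grapheme)
  by_len <- split(glyphs, nchar(glyphs))
  lens <- sort(as.integer(names(by_len)), decreasing = TRUE)

  # greedy leftmost-longest segmentation
  segs <- character(0)
  pos <- 1L
  n <- nchar(orth)
  while (pos <= n) {
    hit <- NA_character_
    for (L in lens) {
      if (pos + L - 1L > n) next
      cand <- substr(orth, pos, pos + L - 1L)
      if (cand %in% by_len[[as.character(L)]]) {
        hit <- cand
        break
      }
    }
    if (is.na(hit)) {
      stop(sprintf("cannot parse syllable '%s': no grapheme matches at position %d ('%s')",
                   orth, pos, substr(orth, pos, pos)))
    }
    segs <- c(segs, hit)
    pos <- pos + nchar(hit)
  }

  n_g <- length(segs)
  out <- vector("list", n_g)
  cum_end <- cumsum(nchar(segs))
  for (j in seq_len(n_g)) {
    g <- segs[j]
    next_letter <- if (cum_end[j] < n) substr(orth, cum_end[j] + 1L, cum_end[j] + 1L) else ""
    pc <- applicable_positions(j == 1L, j == n_g, syllable_index, n_syllables)
    cand <- rules[rules$grapheme == g, , drop = FALSE]
    ctx_ok <- cand$context_set == "" |
      (next_letter != "" &
         vapply(strsplit(cand$context_set, "|", fixed = TRUE),
                function(s) next_letter %in% s, logical(1)))
    pos_ok <- cand$position_class %in% pc
    cand <- cand[ctx_ok & pos_ok, , drop = FALSE]
    # most specific first: context > position > any; then file order
    ord <- order(cand$context_set == "", cand$position_class == "any", cand$rule_id)
    out[[j]] <- cand[ord[1L], c("grapheme", "position_class", "context_set", "rule_id")]
  }
  dplyr::bind_rows(out)
}

#' Read a syllabified phonemic lexicon
#'
#' TSV columns: `word`; `syl_orth` (orthographic syllables separated by `-`);
#' `syl_phon` (phonemic syllables separated by `-`, phoneme codes within a
#' syllable separated by `.`); optional `freq` (token weight, default 1).
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `word`, `syl_orth`, `syl_phon`, `freq`.
#' @export
read_lexicon <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  required <- c("word", "syl_orth", "syl_phon")
  if (!all(required %in% names(df))) {
    stop("lexicon must have columns: ", paste(required, collapse = ", "))
  }
  df$freq <- if ("freq" %in% names(df)) as.numeric(df$freq) else 1
  df$freq[is.na(df$freq)] <- 1
  validate_lexicon(df)
  tibble::as_tibble(df[c("word", "syl_orth", "syl_phon", "freq")])
}

validate_lexicon <- function(df) {
  so <- strsplit(df$syl_orth, "-", fixed = TRUE)
  sp <- strsplit(df$syl_phon, "-", fixed = TRUE)
  n_mismatch <- sum(lengths(so) != lengths(sp))
  if (n_mismatch > 0) {
    stop(n_mismatch, " lexicon entries have differing numbers of orthographic and phonemic syllables")
  }
  if (any(lengths(so) == 0L) ||
      any(vapply(so, function(x) any(x == ""), logical(1))) ||
      any(vapply(sp, function(x) any(x == ""), logical(1)))) {
    stop("lexicon contains empty syllables")
  }
  invisible(df)
}

#' Keep the alignable syllables of one lexicon entry
#'
#' A syllable is alignable when its grapheme parse has exactly as many
#' graphemes as the syllable has phoneme codes, so each grapheme pairs
#' positionally with one phoneme. Non-alignable syllables are dropped and
#' counted, never treated as errors.
#'
#' @param word,syl_orth,syl_phon One lexicon entry (see [read_lexicon()]).
#' @param rules Grapheme rule inventory.
#' @return List with `aligned` (tibble: grapheme, position_class, context_set,
#'   rule_id, phoneme, one row per aligned grapheme) and counts `n_used`,
#'   `n_discarded`.
#' @export
filter_alignable <- function(word, syl_orth, syl_phon, rules) {
  orth_syls <- strsplit(syl_orth, "-", fixed = TRUE)[[1]]
  phon_syls <- strsplit(syl_phon, "-", fixed = TRUE)[[1]]
  stopifnot(length(orth_syls) == length(phon_syls))
  n_syl <- length(orth_syls)
  used <- 0L
  discarded <- 0L
  keep <- vector("list", n_syl)
  for (i in seq_len(n_syl)) {
    parse <- tryCatch(parse_syllable(orth_syls[i], rules, i, n_syl),
                      error = function(e) NULL)
    phonemes <- strsplit(phon_syls[i], ".", fixed = TRUE)[[1]]
    if (!is.null(parse) && nrow(parse) == length(phonemes)) {
      parse$phoneme <- phonemes
      keep[[i]] <- parse
      used <- used + 1L
    } else {
      discarded <- discarded + 1L
    }
  }
  list(aligned = dplyr::bind_rows(keep), n_used = used, n_discarded = discarded)
}

#' Build a grapheme-phoneme correspondence table from a lexicon
#'
#' Parses every alignable syllable of every lexicon entry, tallies
#' (rule, phoneme) correspondences, converts tallies to relative frequencies
#' within each rule (the frequency of the correspondence divided by the
#' frequency of the grapheme rule), and attaches the Shannon entropy (nats) of
#' each rule's pronunciation distribution.
#'
#' @param lexicon Tibble from [read_lexicon()] (columns `word`, `syl_orth`,
#'   `syl_phon`, `freq`).
#' @param rules Grapheme rule inventory.
#' @param weighting `"types"` (default): each unique entry — the combination
#'   of word, syllabification and pronunciation — counts once, so homographs
#'   with distinct pronunciations contribute one count each and duplicated
#'   rows are collapsed. `"tokens"`: entries weighted by their `freq` column.
#' @return An object of class `gpc_table`: a list with `records` (tibble:
#'   grapheme, position_class, context_set, phoneme, count, rel_freq,
#'   entropy), `rules`, `n_syllables_used`, `n_syllables_discarded`,
#'   `weighting`.
#' @export
build_gpc_table <- function(lexicon, rules, weighting = c("types", "tokens")) {
  weighting <- match.arg(weighting)
  if (nrow(lexicon) == 0L) stop("empty lexicon")
  if (weighting == "types") {
    lexicon <- dplyr::distinct(lexicon, .data$word, .data$syl_orth, .data$syl_phon)
    lexicon$freq <- 1
  }

  # memoise syllable parses: synthetic and natural lexicons reuse syllables
  cache <- new.env(parent = emptyenv())
  used <- 0L
  discarded <- 0L
  rows <- vector("list", nrow(lexicon))
  for (r in seq_len(nrow(lexicon))) {
    orth_syls <- strsplit(lexicon$syl_orth[r], "-", fixed = TRUE)[[1]]
    phon_syls <- strsplit(lexicon$syl_phon[r], "-", fixed = TRUE)[[1]]
    if (length(orth_syls) != length(phon_syls)) {
      stop("entry '", lexicon$word[r], "': syllable count mismatch")
    }
    n_syl <- length(orth_syls)
    w <- lexicon$freq[r]
    entry_rows <- vector("list", n_syl)
    for (i in seq_len(n_syl)) {
      key <- paste(orth_syls[i],
                   if (i == 1L) "I" else "i",
                   if (i == n_syl) "F" else "f", sep = "\r")
      parse <- cache[[key]]
      if (is.null(parse)) {
        parse <- tryCatch(parse_syllable(orth_syls[i], rules, i, n_syl),
                          error = function(e) "unparseable")
        cache[[key]] <- parse
      }
      phonemes <- strsplit(phon_syls[i], ".", fixed = TRUE)[[1]]
      if (!is.character(parse) && nrow(parse) == length(phonemes)) {
        parse$phoneme <- phonemes
        parse$count <- w
        entry_rows[[i]] <- parse
        used <- used + 1L
      } else {
        discarded <- discarded + 1L
      }
    }
    rows[[r]] <- dplyr::bind_rows(entry_rows)
  }
  tall <- dplyr::bind_rows(rows)
  if (nrow(tall) == 0L) stop("no alignable syllables in lexicon")

  records <- tall |>
    dplyr::group_by(.data$grapheme, .data$position_class, .data$context_set,
                    .data$phoneme) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop_last") |>
    dplyr::mutate(rel_freq = .data$count / sum(.data$count),
                  entropy = shannon_entropy(.data$rel_freq)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$grapheme, .data$position_class, .data$context_set,
                   dplyr::desc(.data$count), .data$phoneme)

  structure(list(records = records, rules = rules,
                 n_syllables_used = used, n_syllables_discarded = discarded,
                 weighting = weighting),
            class = "gpc_table")
}

#' @export
print.gpc_table <- function(x, ...) {
  n_rules <- nrow(dplyr::distinct(x$records, .data$grapheme,
                                  .data$position_class, .data$context_set))
  cat("<gpc_table> ", n_rules, " grapheme rules, ",
      nrow(x$records), " correspondences (", x$weighting, " weighting)\n",
      "  syllables used: ", x$n_syllables_used,
      ", discarded: ", x$n_syllables_discarded, "\n", sep = "")
  print(utils::head(x$records, 10))
  invisible(x)
}

#' Per-rule entropies of a GPC table
#'
#' @param table A `gpc_table`.
#' @return Tibble with one row per rule: `grapheme`, `position_class`,
#'   `context_set`, `n_phonemes`, `entropy` (nats).
#' @export
gpc_entropies <- function(table) {
  stopifnot(inherits(table, "gpc_table"))
  table$records |>
    dplyr::group_by(.data$grapheme, .data$position_class, .data$context_set) |>
    dplyr::summarise(n_phonemes = dplyr::n(),
                     entropy = .data$entropy[1], .groups = "drop")
}

#' Write / read a GPC table as CSV
#'
#' The CSV carries the correspondence records plus the rule inventory and
#' syllable counters in commented header lines, so a round trip reproduces the
#' `gpc_table` object.
#'
#' @param table A `gpc_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gpc_table <- function(table, path) {
  stopifnot(inherits(table, "gpc_table"))
  meta <- sprintf("# n_syllables_used=%d n_syllables_discarded=%d weighting=%s",
                  table$n_syllables_used, table$n_syllables_discarded,
                  table$weighting)
  rules_line <- paste0("# rules=", jsonlite::toJSON(
    table$rules[c("grapheme", "position_class", "context_set")]))
  body <- readr::format_csv(table$records)
  writeLines(c(meta, rules_line, sub("\n$", "", body)),
             file(path, encoding = "UTF-8"))
  invisible(path)
}

#' @rdname write_gpc_table
#' @export
read_gpc_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- lines[1]
  used <- as.integer(sub(".*n_syllables_used=(\\d+).*", "\\1", meta))
  discarded <- as.integer(sub(".*n_syllables_discarded=(\\d+).*", "\\1", meta))
  weighting <- sub(".*weighting=(\\w+).*", "\\1", meta)
  rules <- as_grapheme_rules(
    jsonlite::fromJSON(sub("^# rules=", "", lines[2])))
  records <- readr::read_csv(
    I(paste(lines[-(1:2)], collapse = "\n")),
    col_types = readr::cols(
      grapheme = "c", position_class = "c", context_set = "c",
      phoneme = "c", count = "d", rel_freq = "d", entropy = "d"),
    progress = FALSE)
  records$context_set[is.na(records$context_set)] <- ""
  structure(list(records = records, rules = rules,
                 n_syllables_used = used, n_syllables_discarded = discarded,
                 weighting = weighting),
            class = "gpc_table")
}
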