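# In-code fixtures: tiny rule inventories, lexicons and response tables.

# rule inventory from a compact spec: "G", "G:pos", "G:pos:set"
make_rules <- function(...) {
  specs <- c(...)
  parts <- strsplit(specs, ":", fixed = TRUE)
  as_grapheme_rules(tibble::tibble(
    grapheme = vapply(parts, `[`, character(1), 1),
    position_class = vapply(parts, function(p) {
      if (length(p) >= 2 && p[2] != "") p[2] else "any"
    }, character(1)),
    context_set = vapply(parts, function(p) {
      if (length(p) >= 3) p[3] else ""
    }, character(1))))
}

single_letter_rules <- function() {
  as_grapheme_rules(tibble::tibble(grapheme = LETTERS,
                                   position_class = "any", context_set = ""))
}

make_lex <- function(word, syl_orth, syl_phon, freq = 1) {
  tibble::tibble(word = word, syl_orth = syl_orth, syl_phon = syl_phon,
                 freq = freq)
}

# one participant's responses to one item, one string per session
make_series <- function(prons, participant = "P01", item = "ITEM") {
  tibble::tibble(participant = participant,
                 session = seq_along(prons),
                 item = item, pronunciation = prons)
}

# naive Gower oracle: mean mismatch proportion over mutually non-missing items
naive_gower <- function(m) {
  n <- nrow(m)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    out[i, j] <- mean(m[i, ok] != m[j, ok])
  }
  out
}

# nested-loop GPC tally oracle: counts per (grapheme, position, context,
# phoneme) over alignable syllables, no grouping machinery
naive_gpc_counts <- function(lexicon, rules) {
  acc <- list()
  for (r in seq_len(nrow(lexicon))) {
    so <- strsplit(lexicon$syl_orth[r], "-", fixed = TRUE)[[1]]
    sp <- strsplit(lexicon$syl_phon[r], "-", fixed = TRUE)[[1]]
    for (i in seq_along(so)) {
      parse <- tryCatch(parse_syllable(so[i], rules, i, length(so)),
                        error = function(e) NULL)
      ph <- strsplit(sp[i], ".", fixed = TRUE)[[1]]
      if (is.null(parse) || nrow(parse) != length(ph)) next
      for (j in seq_len(nrow(parse))) {
        key <- paste(parse$grapheme[j], parse$position_class[j],
                     parse$context_set[j], ph[j], sep = "\r")
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + 1
      }
    }
  }
  acc
}
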