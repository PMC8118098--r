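test_that("shannon_entropy matches closed forms", {
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2))
  # hand evaluation: -(0.9 ln 0.9 + 0.1 ln 0.1) = 0.3250829...
  expect_equal(shannon_entropy(c(0.9, 0.1)), 0.325083, tolerance = 1e-6)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(1 / 4, 4)), log(4))
})

test_that("entropy is maximal iff uniform and bounded by log(k)", {
  set.seed(42)
  for (k in 2:6) {
    p <- rgamma(k, 1); p <- p / sum(p)
    h <- shannon_entropy(p)
    expect_lte(h, log(k) + 1e-12)
    expect_gte(h, 0)
    if (max(abs(p - 1 / k)) > 1e-3) expect_lt(h, log(k))
  }
})

test_that("context rule wins for C before Y; final Y gets its position rule", {
  rules <- make_rules("C", "Y", "Y:syllable_final", "C::E|I|Y")
  p <- parse_syllable("CY", rules)
  expect_equal(p$grapheme, c("C", "Y"))
  expect_equal(p$context_set[1], "E|I|Y")
  expect_equal(p$position_class[2], "syllable_final")
  # no context rule fires when the next letter is outside the set
  p2 <- parse_syllable("CO", make_rules("C", "O", "C::E|I|Y"))
  expect_equal(p2$context_set[1], "")
})

test_that("single-letter word-initial syllable takes the word_initial rule", {
  rules <- make_rules("A:word_initial", "A")
  p <- parse_syllable("A", rules, syllable_index = 1, n_syllables = 2)
  expect_equal(p$position_class, "word_initial")
  # not word-initial in a later syllable
  p2 <- parse_syllable("A", rules, syllable_index = 2, n_syllables = 2)
  expect_equal(p2$position_class, "any")
})

test_that("greedy segmentation equals leftmost-longest over all parses", {
  rules <- make_rules("C", "H", "I", "P", "S", "CH", "SH", "HI")
  glyphs <- unique(rules$grapheme)
  # enumeration oracle: all segmentations, then pick leftmost-longest
  all_parses <- function(s) {
    if (nchar(s) == 0) return(list(character(0)))
    out <- list()
    for (g in glyphs) {
      if (startsWith(s, g)) {
        for (rest in all_parses(substr(s, nchar(g) + 1, nchar(s)))) {
          out[[length(out) + 1]] <- c(g, rest)
        }
      }
    }
    out
  }
  leftmost_longest <- function(parses) {
    best <- parses[[1]]
    for (p in parses[-1]) {
      for (k in seq_len(min(length(p), length(best)))) {
        if (nchar(p[k]) != nchar(best[k])) {
          if (nchar(p[k]) > nchar(best[k])) best <- p
          break
        }
      }
    }
    best
  }
  for (w in c("CHIP", "SHIP", "CHIPS", "PHIS", "CHI", "SCHIP")) {
    w_ok <- tryCatch(parse_syllable(w, rules)$grapheme, error = function(e) NULL)
    cand <- all_parses(w)
    if (length(cand) == 0) {
      expect_null(w_ok)
    } else {
      expect_equal(w_ok, leftmost_longest(cand), info = w)
    }
  }
})

test_that("unparseable syllables are rejected with the offending position", {
  rules <- make_rules("A", "B")
  expect_error(parse_syllable("ABC", rules), "position 3")
})

test_that("filter_alignable keeps 1:1 grapheme-phoneme syllables only", {
  rules <- make_rules("B", "A", "M", "P", "CH")
  ok <- filter_alignable("BAM", "BAM", "b.a.m", rules)
  expect_equal(ok$n_used, 1L)
  expect_equal(ok$n_discarded, 0L)
  expect_equal(ok$aligned$phoneme, c("b", "a", "m"))
  # 4 graphemes vs 3 phonemes: dropped, counted
  bad <- filter_alignable("BAMP", "BAMP", "b.a.m", rules)
  expect_equal(bad$n_used, 0L)
  expect_equal(bad$n_discarded, 1L)
  # digraph consumed as one grapheme aligns 3 phonemes to CHAM
  dig <- filter_alignable("CHAM", "CHAM", "tS.a.m", rules)
  expect_equal(dig$aligned$grapheme, c("CH", "A", "M"))
})

test_that("gpc table entropies follow the pronunciation distributions", {
  rules <- make_rules("G", "A", "B")
  # G always -> g : entropy 0
  lex1 <- make_lex(c("GA", "GAB"), c("GA", "GAB"), c("g.a", "g.a.b"))
  t1 <- build_gpc_table(lex1, rules)
  e1 <- gpc_entropies(t1)
  expect_equal(e1$entropy[e1$grapheme == "G"], 0)
  # G -> g / dZ at 50/50 : entropy log 2
  lex2 <- make_lex(c("GA", "GB"), c("GA", "GB"), c("g.a", "dZ.b"))
  e2 <- gpc_entropies(build_gpc_table(lex2, rules))
  expect_equal(e2$entropy[e2$grapheme == "G"], log(2))
  # 9:1 split: hand-computed 0.325083
  lex3 <- make_lex(sprintf("G%d", 1:10), rep("GA", 10),
                   c(rep("g.a", 9), "dZ.a"))
  e3 <- gpc_entropies(build_gpc_table(lex3, rules))
  expect_equal(e3$entropy[e3$grapheme == "G"], 0.325083, tolerance = 1e-6)
})

test_that("relative frequencies sum to 1 within every rule", {
  lx <- make_lexicon(n_words = 80, seed = 11)
  tab <- build_gpc_table(lx$lexicon, lx$rules)
  sums <- tapply(tab$records$rel_freq,
                 paste(tab$records$grapheme, tab$records$position_class,
                       tab$records$context_set),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("gpc table is invariant to lexicon row order", {
  lx <- make_lexicon(n_words = 60, seed = 12)
  t1 <- build_gpc_table(lx$lexicon, lx$rules)
  set.seed(1)
  t2 <- build_gpc_table(lx$lexicon[sample(nrow(lx$lexicon)), ], lx$rules)
  expect_equal(t1$records, t2$records)
  expect_equal(t1$n_syllables_used, t2$n_syllables_used)
})

test_that("duplicate entries do not change type-weighted frequencies", {
  rules <- make_rules("G", "A", "B")
  lex <- make_lex(c("GA", "GB"), c("GA", "GB"), c("g.a", "dZ.b"))
  t1 <- build_gpc_table(lex, rules, weighting = "types")
  t2 <- build_gpc_table(rbind(lex, lex[1, ]), rules, weighting = "types")
  expect_equal(t1$records, t2$records)
  # but token weighting counts the frequency column
  lex$freq <- c(3, 1)
  t3 <- build_gpc_table(lex, rules, weighting = "tokens")
  g <- t3$records[t3$records$grapheme == "G", ]
  expect_equal(g$rel_freq[g$phoneme == "g"], 0.75)
})

test_that("tallies equal a naive nested-loop oracle on small lexicons", {
  for (seed in 1:3) {
    lx <- make_lexicon(n_words = 10, seed = seed)
    tab <- build_gpc_table(lx$lexicon, lx$rules)
    oracle <- naive_gpc_counts(lx$lexicon, lx$rules)
    rec <- tab$records
    keys <- paste(rec$grapheme, rec$position_class, rec$context_set,
                  rec$phoneme, sep = "\r")
    expect_setequal(keys, names(oracle))
    expect_equal(rec$count, unname(unlist(oracle[keys])))
  }
})

test_that("empty post-filter lexicon is an explicit failure", {
  rules <- make_rules("A", "B")
  lex <- make_lex("AB", "AB", "a.b.c")   # never alignable
  expect_error(build_gpc_table(lex, rules), "no alignable")
})

test_that("a gpc table round-trips through CSV", {
  lx <- make_lexicon(n_words = 40, seed = 5)
  tab <- build_gpc_table(lx$lexicon, lx$rules)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gpc_table(tab, path)
  back <- read_gpc_table(path)
  expect_equal(back$records, tab$records)
  expect_equal(back$n_syllables_used, tab$n_syllables_used)
  expect_equal(back$n_syllables_discarded, tab$n_syllables_discarded)
  # and the reloaded table scores nonwords identically
  expect_equal(item_consistency("BAMP", back), item_consistency("BAMP", tab))
})
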