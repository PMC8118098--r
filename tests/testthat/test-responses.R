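test_that("transcription normalisation strips stress and unifies encodings", {
  expect_equal(normalize_transcription("ˈbɛbəl"), "bɛbəl")
  expect_equal(normalize_transcription("bɛbəl "), "bɛbəl")
  # composed vs decomposed Unicode of the same string compare equal
  composed <- "\u00e9d"       # e-acute, precomposed
  decomposed <- "e\u0301d"    # e + combining acute
  expect_equal(normalize_transcription(composed),
               normalize_transcription(decomposed))
  expect_error(normalize_transcription("ˈ "), "empty")
})

test_that("distinct counts span 1 to n_sessions", {
  expect_equal(count_distinct(rep("A", 5)), 1L)
  expect_equal(count_distinct(c("A", "B", "C", "D", "E")), 5L)
  expect_equal(count_distinct(c("A", "B", "A", "B")), 2L)
})

test_that("response diversity matches the entropy worked examples", {
  expect_equal(response_diversity(rep("blɪsplə", 5)), 0)
  expect_equal(round(response_diversity(c("a", "b", "c", "d", "e")), 1), 1.6)
  expect_equal(response_diversity(c("A", "A", "A", "B", "B")),
               -(0.6 * log(0.6) + 0.4 * log(0.4)))
  expect_equal(response_diversity(c("A", "A", "A", "B", "B")), 0.673012,
               tolerance = 1e-6)
})

test_that("novelty coding matches the worked examples", {
  expect_equal(code_novelty(rep("A", 5)), c(0L, 0L, 0L, 0L))
  expect_equal(code_novelty(c("A", "B", "B", "B", "B")), c(1L, 0L, 0L, 0L))
  # late change with stable prior sessions: lone session-4 flag, and the
  # return to the old form in session 5 is old
  expect_equal(code_novelty(c("A", "A", "A", "B", "A")), c(0L, 0L, 1L, 0L))
  expect_equal(code_novelty("A"), integer(0))
})

test_that("novelty flags always sum to n_distinct - 1", {
  set.seed(3)
  for (i in 1:100) {
    prons <- sample(LETTERS[1:4], sample(1:6, 1), replace = TRUE)
    expect_equal(sum(code_novelty(prons)), count_distinct(prons) - 1L)
  }
})

test_that("diversity is bounded by log(n_distinct) and log(n_sessions)", {
  set.seed(4)
  for (i in 1:100) {
    prons <- sample(LETTERS[1:5], sample(1:6, 1), replace = TRUE)
    h <- response_diversity(prons)
    expect_lte(h, log(count_distinct(prons)) + 1e-12)
    expect_lte(h, log(length(prons)) + 1e-12)
    expect_gte(h, 0)
  }
})

test_that("merging two pronunciation categories never increases diversity", {
  set.seed(5)
  for (i in 1:50) {
    prons <- sample(LETTERS[1:4], 6, replace = TRUE)
    merged <- ifelse(prons == "B", "A", prons)
    expect_lte(response_diversity(merged), response_diversity(prons) + 1e-12)
  }
})

test_that("table validation enforces uniqueness and session contiguity", {
  good <- make_series(c("a", "b", "a"))
  expect_s3_class(validate_responses(good), "tbl_df")
  dup <- rbind(good, good[1, ])
  expect_error(validate_responses(dup), "duplicate")
  gap <- good
  gap$session <- c(1L, 2L, 4L)
  expect_error(validate_responses(gap), "contiguous")
})

test_that("gower distances hit the categorical endpoints", {
  recs <- dplyr::bind_rows(
    make_series(c("x"), "P1", "I1"), make_series(c("x"), "P2", "I1"),
    make_series(c("y"), "P1", "I2"), make_series(c("y"), "P2", "I2"),
    make_series(c("x"), "P3", "I1"), make_series(c("z"), "P3", "I2"),
    make_series(c("q"), "P4", "I1"), make_series(c("r"), "P4", "I2"))
  gd <- gower_distances(validate_responses(recs))
  pick <- function(a, b) gd$distance[gd$participant_a == a & gd$participant_b == b]
  expect_equal(pick("P1", "P2"), 0)         # identical rows
  expect_equal(pick("P1", "P3"), 0.5)       # differ on 1 of 2 items
  expect_equal(pick("P1", "P4"), 1)         # differ on every item
})

test_that("gower distances equal the naive mismatch-proportion oracle", {
  set.seed(6)
  for (rep in 1:25) {
    n_p <- sample(3:6, 1)
    n_i <- sample(3:10, 1)
    m <- matrix(sample(letters[1:3], n_p * n_i, replace = TRUE), n_p, n_i)
    # poke some missing responses (timeouts)
    m[sample(length(m), size = floor(length(m) * 0.1))] <- NA
    recs <- tidyr::expand_grid(p = seq_len(n_p), i = seq_len(n_i))
    recs$pron <- m[cbind(recs$p, recs$i)]
    recs <- recs[!is.na(recs$pron), ]
    tab <- tibble::tibble(participant = paste0("P", recs$p), session = 1L,
                          item = paste0("I", recs$i),
                          pronunciation = recs$pron)
    keep <- rowSums(!is.na(m)) > 0
    gd <- suppressWarnings(gower_distances(validate_responses(tab)))
    oracle <- naive_gower(m[keep, , drop = FALSE])
    for (k in seq_len(nrow(gd))) {
      i <- as.integer(sub("P", "", gd$participant_a[k]))
      j <- as.integer(sub("P", "", gd$participant_b[k]))
      io <- sum(keep[seq_len(i)]); jo <- sum(keep[seq_len(j)])
      expect_equal(gd$distance[k], oracle[io, jo], tolerance = 1e-12)
    }
  }
})

test_that("pair counts follow the per-session headcounts", {
  st <- simulate_responses(sim_config(seed = 9))
  gd <- gower_distances(st$responses)
  by_s <- table(gd$session)
  expect_equal(unname(as.integer(by_s)), c(231L, 231L, 231L, 231L, 190L))
  expect_equal(nrow(gd), 1114L)
  expect_true(all(gd$distance >= 0 & gd$distance <= 1))
  expect_true(all(gd$n_items_compared == 50L))
})

test_that("pronunciation frequencies count participants and zero-fill", {
  recs <- dplyr::bind_rows(
    make_series(c("x", "x", "y"), "P1", "I1"),
    make_series(c("x", "y", "y"), "P2", "I1"))
  pf <- pronunciation_frequencies(validate_responses(recs),
                                  drop_last_session = FALSE)
  get <- function(pron, s) pf$frequency[pf$pronunciation == pron & pf$session == s]
  expect_equal(get("x", 1), 2L)   # used by two participants in session 1
  expect_equal(get("x", 3), 0L)   # zero-filled where nobody used it
  expect_equal(get("y", 3), 2L)
  # per session, frequencies sum to the responding headcount
  sums <- tapply(pf$frequency, pf$session, sum)
  expect_true(all(sums == 2))
  # final-session exclusion drops session 3 rows
  pf2 <- pronunciation_frequencies(validate_responses(recs),
                                   drop_last_session = TRUE)
  expect_equal(sort(unique(pf2$session)), c(1L, 2L))
})

test_that("responses round-trip through CSV with normalisation applied", {
  st <- simulate_responses(sim_config(n_participants = 4, n_items = 5, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(st$responses, path)
  back <- read_responses(path)
  expect_equal(back, st$responses)
})
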