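#' Default synthetic grapheme inventory
#'
#' A small English-like inventory used by the simulator and by
#' [make_lexicon()]. Each grapheme occupies a syllable slot (onset, vowel,
#' coda) and carries a pronunciation probability vector; the vector defines
#' the grapheme's true pronunciation entropy. Ambiguity is graded: most
#' consonants are deterministic, while C, G, CH, TH and the vowel graphemes
#' map to several phonemes, mirroring the mix of consistent and inconsistent
#' spelling units in English.
#'
#' @return Tibble with columns `grapheme`, `slot`, `phonemes` (`|`-separated
#'   phoneme codes) and `probs` (`|`-separated probabilities summing to 1).
#' @export
default_sim_inventory <- function() {
  tibble::tribble(
    ~grapheme, ~slot,   ~phonemes,      ~probs,
    "B",  "onset", "b",            "1",
    "D",  "onset", "d",            "1",
    "F",  "onset", "f",            "1",
    "L",  "onset", "l",            "1",
    "M",  "onset", "m",            "1",
    "N",  "onset", "n",            "1",
    "P",  "onset", "p",            "1",
    "R",  "onset", "r",            "1",
    "S",  "onset", "s",            "1",
    "T",  "onset", "t",            "1",
    "C",  "onset", "k|s",          "0.7|0.3",
    "G",  "onset", "g|dZ",         "0.8|0.2",
    "CH", "onset", "tS|k",         "0.85|0.15",
    "SH", "onset", "S",            "1",
    "TH", "onset", "T|D",          "0.6|0.4",
    "A",  "vowel", "{|eI|@",       "0.5|0.3|0.2",
    "E",  "vowel", "E|i:",         "0.6|0.4",
    "I",  "vowel", "I|aI",         "0.7|0.3",
    "O",  "vowel", "Q|@U",         "0.6|0.4",
    "U",  "vowel", "V|u:",         "0.7|0.3",
    "EA", "vowel", "E|i:",         "0.5|0.5",
    "OO", "vowel", "U|u:",         "0.4|0.6",
    "AI", "vowel", "eI",           "1",
    "K",  "coda",  "k",            "1",
    "M",  "coda",  "m",            "1",
    "N",  "coda",  "n",            "1",
    "P",  "coda",  "p",            "1",
    "S",  "coda",  "s",            "1",
    "T",  "coda",  "t",            "1",
    "L",  "coda",  "l",            "1",
    "F",  "coda",  "f",            "1"
  )
}

inventory_entropies <- function(inventory) {
  vapply(strsplit(inventory$probs, "|", fixed = TRUE),
         function(p) shannon_entropy(as.numeric(p)), numeric(1))
}

#' Simulation configuration
#'
#' Bundles every parameter governing the synthetic reader population and the
#' session dynamic. Defaults mirror a 22-participant, 50-nonword,
#' five-session repeated reading-aloud design with two participants missing
#' the final session.
#'
#' @param n_participants Number of readers (default 22).
#' @param n_items Number of nonwords (default 50).
#' @param n_sessions Number of sessions (default 5).
#' @param dropout Participants missing the final session only (default 2).
#' @param kappa Concentration of the Dirichlet perturbation giving each
#'   participant a private knowledge distribution around each item's
#'   population pronunciation distribution; larger values keep participants
#'   closer to the population (default 8).
#' @param repeat_strength Per-session weight `alpha(t)` of re-sampling one's
#'   own past responses versus drawing fresh from knowledge; must be
#'   nondecreasing in `t` so that responses settle over sessions. Recycled or
#'   truncated to `n_sessions`. Default `c(0, 1, 1.5, 2, 2.5)`.
#' @param settle_sharpening Growth rate `g` of the sharpening exponent
#'   `gamma(t) = 1 + g * (t - 1)` applied to the knowledge distribution for
#'   fresh draws; positive values make later fresh draws commit to each
#'   reader's best-supported pronunciation (default 0.5).
#' @param literacy_effect Coupling of the participant literacy draw to the
#'   knowledge concentration: `kappa_p = kappa * exp(-literacy_effect * L)`,
#'   so positive values give more literate readers broader (more variable)
#'   pronunciation knowledge. Default 0 (no coupling).
#' @param inventory Grapheme inventory, see [default_sim_inventory()].
#' @param n_syllables Syllables per generated nonword (default 2).
#' @param seed Integer seed controlling every random draw.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 22, n_items = 50, n_sessions = 5,
                       dropout = 2, kappa = 8,
                       repeat_strength = c(0, 1, 1.5, 2, 2.5),
                       settle_sharpening = 0.5, literacy_effect = 0,
                       inventory = default_sim_inventory(),
                       n_syllables = 2, seed = 1) {
  alpha <- rep_len(repeat_strength, n_sessions)
  if (any(diff(alpha) < 0)) stop("repeat_strength must be nondecreasing")
  probs <- lapply(strsplit(inventory$probs, "|", fixed = TRUE), as.numeric)
  if (any(abs(vapply(probs, sum, numeric(1)) - 1) > 1e-8)) {
    stop("inventory probability vectors must sum to 1")
  }
  if (dropout >= n_participants) stop("dropout must leave participants in the final session")
  structure(list(n_participants = n_participants, n_items = n_items,
                 n_sessions = n_sessions, dropout = dropout, kappa = kappa,
                 repeat_strength = alpha,
                 settle_sharpening = settle_sharpening,
                 literacy_effect = literacy_effect, inventory = inventory,
                 n_syllables = n_syllables, seed = seed),
            class = "sim_config")
}

# Sample one syllable's grapheme indices (onset, vowel, coda) from inventory.
sample_syllable_idx <- function(inventory) {
  c(sample(which(inventory$slot == "onset"), 1),
    sample(which(inventory$slot == "vowel"), 1),
    sample(which(inventory$slot == "coda"), 1))
}

# All pronunciations of a grapheme-index sequence with their probabilities.
pronunciation_space <- function(idx, inventory) {
  phon <- strsplit(inventory$phonemes[idx], "|", fixed = TRUE)
  prob <- lapply(strsplit(inventory$probs[idx], "|", fixed = TRUE), as.numeric)
  grid <- expand.grid(lapply(phon, seq_along), KEEP.OUT.ATTRS = FALSE)
  pron <- apply(grid, 1, function(ch) {
    paste(mapply(function(p, k) p[k], phon, ch), collapse = "")
  })
  p <- apply(grid, 1, function(ch) {
    prod(mapply(function(q, k) q[k], prob, ch))
  })
  tibble::tibble(pronunciation = pron, prob = p)
}

#' Generate a synthetic syllabified lexicon and matching rule inventory
#'
#' Samples words as random grapheme sequences from a synthetic inventory and
#' draws each grapheme's phoneme from its pronunciation probability vector,
#' so that the empirical grapheme-to-phoneme relative frequencies of the
#' resulting lexicon converge to the inventory specification as `n_words`
#' grows. Standing in for a licensed lexical database, the output is written
#' in exactly the formats [read_lexicon()] and [read_grapheme_rules()]
#' consume.
#'
#' @param inventory See [default_sim_inventory()].
#' @param n_words Number of distinct words to generate.
#' @param n_syllables Syllables per word (default 2).
#' @param seed Integer seed.
#' @param dir Optional directory; when given, `lexicon.tsv` and `rules.csv`
#'   are written there.
#' @return List with `lexicon` (tibble: word, syl_orth, syl_phon, freq),
#'   `rules` (grapheme rule tibble) and, if `dir` was given, the file paths.
#' @export
make_lexicon <- function(inventory = default_sim_inventory(), n_words = 500,
                         n_syllables = 2, seed = 1, dir = NULL) {
  set.seed(seed)
  phon <- strsplit(inventory$phonemes, "|", fixed = TRUE)
  prob <- lapply(strsplit(inventory$probs, "|", fixed = TRUE), as.numeric)

  seen <- new.env(parent = emptyenv())
  words <- vector("list", n_words)
  made <- 0L
  tries <- 0L
  while (made < n_words && tries < n_words * 50L) {
    tries <- tries + 1L
    idx <- unlist(lapply(seq_len(n_syllables), function(i) sample_syllable_idx(inventory)))
    orth_syl <- vapply(seq_len(n_syllables), function(i) {
      paste(inventory$grapheme[idx[(3 * i - 2):(3 * i)]], collapse = "")
    }, character(1))
    word <- paste(orth_syl, collapse = "")
    if (!is.null(seen[[word]])) next
    seen[[word]] <- TRUE
    drawn <- vapply(idx, function(j) {
      phon[[j]][sample.int(length(phon[[j]]), 1, prob = prob[[j]])]
    }, character(1))
    phon_syl <- vapply(seq_len(n_syllables), function(i) {
      paste(drawn[(3 * i - 2):(3 * i)], collapse = ".")
    }, character(1))
    made <- made + 1L
    words[[made]] <- tibble::tibble(word = word,
                                    syl_orth = paste(orth_syl, collapse = "-"),
                                    syl_phon = paste(phon_syl, collapse = "-"),
                                    freq = 1)
  }
  if (made < n_words) {
    warning("grapheme space exhausted: generated ", made, " of ", n_words,
            " distinct words")
  }
  lexicon <- dplyr::bind_rows(words[seq_len(made)])
  rules <- as_grapheme_rules(tibble::tibble(
    grapheme = unique(c(inventory$grapheme, LETTERS)),
    position_class = "any", context_set = ""))
  out <- list(lexicon = lexicon, rules = rules)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    lex_path <- file.path(dir, "lexicon.tsv")
    rules_path <- file.path(dir, "rules.csv")
    readr::write_tsv(lexicon, lex_path)
    readr::write_csv(rules[c("grapheme", "position_class", "context_set")],
                     rules_path)
    out$lexicon_path <- lex_path
    out$rules_path <- rules_path
  }
  out
}

#' Simulate a multi-session nonword reading study
#'
#' Generates a response table with the structure the analyses assume. Each
#' item is a random grapheme sequence whose population pronunciation
#' distribution is the product of its graphemes' pronunciation probabilities.
#' Each participant receives a private knowledge distribution per item by
#' Dirichlet perturbation (concentration `kappa`) of the population
#' distribution. At session 1 the reader samples from knowledge. At session
#' `t > 1`, with probability `alpha(t) * (t - 1) / (1 + alpha(t) * (t - 1))`
#' a past response is re-used — drawn with weight (times used so far) x
#' (knowledge probability), a reinforcement urn biased towards the reader's
#' better-supported pronunciations — and otherwise a fresh draw is made from
#' the knowledge distribution sharpened by `gamma(t)`. Settling over
#' sessions, declining novelty, converging readers and the spread of popular
#' pronunciations are emergent consequences.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_study`: `responses` (tibble: participant,
#'   session, item, pronunciation), `truth` (list with per-item true
#'   consistency, per-participant literacy and knowledge concentration, and
#'   the config), `literacy` (tibble: participant, spelling, vocabulary —
#'   synthetic test scores driven by the latent literacy draw).
#' @export
simulate_responses <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  inv <- config$inventory
  ent <- inventory_entropies(inv)
  n_p <- config$n_participants
  n_i <- config$n_items
  n_s <- config$n_sessions
  alpha <- config$repeat_strength

  # --- items -------------------------------------------------------------
  items <- vector("list", n_i)
  seen <- new.env(parent = emptyenv())
  made <- 0L
  while (made < n_i) {
    idx <- unlist(lapply(seq_len(config$n_syllables),
                         function(i) sample_syllable_idx(inv)))
    orth <- paste(inv$grapheme[idx], collapse = "")
    if (!is.null(seen[[orth]])) next
    seen[[orth]] <- TRUE
    made <- made + 1L
    syl_ent <- vapply(seq_len(config$n_syllables), function(i) {
      mean(ent[idx[(3 * i - 2):(3 * i)]])
    }, numeric(1))
    items[[made]] <- list(
      item = orth, idx = idx,
      space = pronunciation_space(idx, inv),
      true_entropy = max(syl_ent),
      true_consistency = -max(syl_ent))
  }

  # --- participants -------------------------------------------------------
  pid <- sprintf("P%02d", seq_len(n_p))
  literacy_latent <- stats::rnorm(n_p)
  kappa_p <- config$kappa * exp(-config$literacy_effect * literacy_latent)
  spelling <- pmin(40, pmax(0, round(28 + 4 * literacy_latent + stats::rnorm(n_p, 0, 3))))
  vocabulary <- pmin(40, pmax(0, round(30 + 3 * literacy_latent + stats::rnorm(n_p, 0, 3))))
  dropouts <- if (config$dropout > 0) sample(pid, config$dropout) else character(0)
  sessions_of <- function(p) if (p %in% dropouts) seq_len(n_s - 1L) else seq_len(n_s)

  # --- response dynamic ---------------------------------------------------
  gam <- 1 + config$settle_sharpening * (seq_len(n_s) - 1)
  rows <- vector("list", n_p * n_i)
  cell <- 0L
  for (ii in seq_len(n_i)) {
    it <- items[[ii]]
    base <- it$space$prob
    n_pron <- length(base)
    for (pp in seq_len(n_p)) {
      g <- stats::rgamma(n_pron, shape = kappa_p[pp] * base)
      know <- if (sum(g) > 0) g / sum(g) else base
      sess <- sessions_of(pid[pp])
      resp <- integer(length(sess))
      for (t in sess) {
        n_past <- t - 1L
        p_repeat <- if (n_past == 0L) 0 else {
          alpha[t] * n_past / (1 + alpha[t] * n_past)
        }
        if (n_past > 0L && stats::runif(1) < p_repeat) {
          past <- resp[seq_len(n_past)]
          w <- tabulate(past, nbins = n_pron) * know
          if (sum(w) == 0) w <- tabulate(past, nbins = n_pron)
          resp[t] <- sample.int(n_pron, 1, prob = w)
        } else {
          ks <- know^gam[t]
          resp[t] <- sample.int(n_pron, 1, prob = ks / sum(ks))
        }
      }
      cell <- cell + 1L
      rows[[cell]] <- tibble::tibble(participant = pid[pp], session = sess,
                                     item = it$item,
                                     pronunciation = it$space$pronunciation[resp])
    }
  }
  responses <- validate_responses(dplyr::bind_rows(rows))

  truth <- list(
    items = tibble::tibble(
      item = vapply(items, `[[`, character(1), "item"),
      true_entropy = vapply(items, `[[`, numeric(1), "true_entropy"),
      true_consistency = vapply(items, `[[`, numeric(1), "true_consistency")),
    participants = tibble::tibble(participant = pid,
                                  literacy = literacy_latent,
                                  kappa = kappa_p,
                                  dropped_final = pid %in% dropouts),
    config = config)
  structure(list(responses = responses, truth = truth,
                 literacy = tibble::tibble(participant = pid,
                                           spelling = spelling,
                                           vocabulary = vocabulary)),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cfg <- x$truth$config
  cat("<sim_study> ", cfg$n_participants, " participants x ", cfg$n_items,
      " items x ", cfg$n_sessions, " sessions (",
      nrow(x$responses), " responses)\n", sep = "")
  invisible(x)
}
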