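---
title: "Measuring and modelling session-to-session variability in nonword reading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling session-to-session variability in nonword reading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nonwordvar)
```

## The problem

When a skilled adult reads a pronounceable nonword (BUDGORD, BLISPLE) aloud
on several occasions, the responses need not repeat. The degree and the
structure of that intra-individual variation bear on how nonword reading
tests should be interpreted: a single snapshot of performance mixes stable
spelling-sound knowledge with within-reader stochasticity. This package
provides the measurement pipeline for repeated-session designs — an
item-level predictability score, within- and between-reader variability
statistics, and the mixed-effects models that relate them — plus a
generative simulator that makes every stage testable end to end.

## Item consistency from grapheme-phoneme entropies

The item-level covariate asks: how predictable are this nonword's
spelling-sound mappings in the writing system? Given a syllabified phonemic
lexicon, each syllable whose grapheme parse has exactly as many graphemes as
phonemes is aligned one-to-one and tallied into context-dependent
grapheme-phoneme correspondences. For a grapheme rule with pronunciation
relative frequencies $p_1 \dots p_k$ the pronunciation entropy is
$H = \sum_i -p_i \ln p_i$ (nats): $0$ for a deterministic mapping, $\ln k$
for a uniform $k$-way one.

Three design choices deserve mention, all made for auditability:

* **Parsing** is greedy leftmost-longest match over a *declarative* rule
  inventory (a CSV the user can replace; a default covering the single
  letters and common English multi-letter graphemes ships with the
  package). Specialised reading-model parsers are not re-implemented; the
  consistency measure depends only on the parse output, and a declarative
  inventory makes the parse inspectable.
* **Context** is limited to two feature kinds: position class
  (word-initial/final, syllable-initial/final) and membership of the next
  letter in a declared set (the classic C-before-E/I/Y softening). When
  several rules match, a context rule beats a position rule beats an
  unconditioned rule, with inventory file order breaking ties — matching
  behaviour is therefore deterministic.
* **Weighting** defaults to types (each distinct word-pronunciation entry
  counts once, duplicates collapsed); token weighting through a frequency
  column is available. Word syllabification is always taken from the input
  lexicon, never recomputed.

A nonword is syllabified (a manual override file is authoritative,
mirroring hand-parsed item lists; otherwise vowel-letter groups are found
and intervening consonants split by onset maximisation over a fixed legal
onset list), parsed with the same inventory, and each grapheme receives its
rule's entropy — falling back to the grapheme's unconditioned rule when the
matched context rule was never observed, and failing loudly when no record
exists at all (an unmatched grapheme is never silently scored 0). Grapheme
entropies are averaged within syllables; the item score is the **negated
entropy of the most inconsistent syllable**. Alternative aggregations
(mean/sum/max over graphemes or syllables) are exported so the
metric-selection step — pick the candidate most correlated with the
dependent variable, `select_metric()` — can be reproduced.

**The covariate transform.** The negated metric is $\le 0$, so it has no
real logarithm; a log transform of the reported kind must act on the
magnitude. The default covariate is $-\ln(H_{\text{maxsyll}} + \epsilon)$,
centred over the scored item set, with $\epsilon = 0.01$ keeping perfectly
consistent items finite. This preserves the sign convention (higher = more
consistent) and is configurable (`transform = "identity"` centres the raw
negated metric instead). $\epsilon$ trades compression of the consistent
end against sensitivity near $H = 0$; 0.01 is about an order of magnitude
below typical single-grapheme entropies.

## Behavioural statistics

All statistics treat two responses as "the same pronunciation" iff their
normalised transcriptions are equal: Unicode NFC, stress marks stripped
(lexical stress is ignored), whitespace trimmed. No phonetic similarity
metric is used — the entropy and novelty definitions are set-based.

* **Distinct counts and response diversity.** Per participant and item,
  the number of different pronunciations across sessions, and the Shannon
  entropy of the pronunciation proportions over sessions (0 when stable;
  $\ln 5 \approx 1.6$ when all five sessions differ).
* **Novelty.** For sessions $\ge 2$, a response is novel iff unused by
  that participant for that item in any earlier session. The flags sum to
  (number of distinct pronunciations − 1), which ties the two analyses
  together and is asserted as a property test.
* **Gower distances.** Per session, the participants-by-items categorical
  matrix is passed to `cluster::daisy`; for categorical data the Gower
  dissimilarity is the proportion of mismatching items among mutually
  answered ones. Missing trials are handled by the standard Gower
  convention (pairwise deletion) with the number of compared items
  recorded. With 22 readers in sessions 1–4 and 20 in session 5 this
  yields $4 \times 231 + 190 = 1114$ pairs.
* **Pronunciation frequencies.** Per item, pronunciation and session, the
  number of participants using it, zero-filled across that item's sessions
  so trajectories are complete. The final session is excluded by default
  because a smaller headcount would bias raw frequencies downwards; the
  flag is configurable.

## The model stages

* Distinct counts: one-sample t tests of per-participant and per-item
  means against $\mu = 1$ (the no-variability value).
* Diversity: `diversity ~ consistency * literacy + (1|item) +
  (1 + consistency|participant)`, REML with Satterthwaite degrees of
  freedom (fractional df). Literacy is a composite: the average of
  within-sample z-scored spelling and vocabulary scores, used to avoid
  entering two correlated tests separately.
* Novelty: binomial logit GLMM (Laplace) with session (numeric, centred),
  consistency, literacy and all two-way interactions, random intercepts
  for participant and item; Wald z tests; a coarse complete-separation
  check fails with the offending predictor named.
* Distance: `distance ~ session_z + (1 + session_z|participant_a) +
  (1 + session_z|participant_b)` — two crossed random factors, one per
  pair member; session standardised.
* Trajectories: `frequency_c ~ 1 + (1 + session|pronunciation)` with the
  conditional modes of intercepts and slopes extracted and their Pearson
  correlation reported. Frequencies are zero-filled **then** centred;
  pronunciations observed in few sessions are shrunk, never dropped.

**Convergence fallback ladder.** The maximal stated random-effects
structure is tried first; on an optimiser error or convergence warning the
intercept-slope correlation is dropped, then the random slope. A singular
fit (a variance component estimated at zero) is accepted but flagged — it
is a boundary estimate, not a convergence failure. Every fallback is
recorded in the returned `nwv_model`.

**Variance explained.** `r2_mixed()` implements variance-decomposition
marginal and conditional R²: the fixed-effect prediction variance over the
total of fixed, random and residual variances, with random-slope terms
contributing the mean observation-level variance
$\overline{\mathrm{diag}(Z \Sigma Z^\top)}$ rather than a raw variance sum.
For binomial models the observation-level residual variance is reported
both as the theoretical logistic value $\pi^2/3$ and as the delta-method
value $1/(\bar p (1-\bar p))$ at the mean fitted probability.
`semipartial_r2()` refits without a term (and every interaction containing
it) and reports the marginal-R² drop; reduced-model refits are done by ML
so full and reduced fits are comparable.

## The generative simulator

`simulate_responses()` operationalises a specific, testable hypothesis
about where session-to-session variation comes from: probabilistic
spelling-sound knowledge plus reinforcement of one's own past responses.

* **Items** are random grapheme sequences from a synthetic inventory in
  which ambiguity is graded (deterministic consonants; C, G, CH, TH and
  the vowel graphemes with two- or three-way pronunciation
  distributions). An item's population pronunciation distribution is the
  product of its graphemes' distributions; its true consistency is the
  entropy of its most inconsistent syllable — the same functional the
  scoring pipeline estimates.
* **Readers** get a private knowledge distribution per item by Dirichlet
  perturbation with concentration $\kappa$ (default 8: clearly
  individual, yet usually preserving the population mode). Optionally a
  latent literacy draw scales $\kappa$ downwards for more literate readers
  (default coupling 0, reflecting the absence of evidence for
  participant-level literacy effects at this design size).
* **Sessions.** At session 1 a reader samples from knowledge. At session
  $t > 1$, with probability $\alpha(t)(t-1) / (1 + \alpha(t)(t-1))$ a past
  response is re-used, drawn with weight (times used) × (knowledge
  probability); otherwise a fresh draw is made from knowledge sharpened by
  the exponent $\gamma(t) = 1 + g(t-1)$. Defaults:
  $\alpha = (0, 1, 1.5, 2, 2.5)$ (nondecreasing, so repetition strengthens
  over sessions) and $g = 0.5$.

A *plain* reinforcement urn — re-sampling past responses uniformly — was
deliberately not used: such an urn is exchangeable, so each reader's
marginal response distribution, and hence the expected inter-reader
mismatch, would be constant across sessions, and the empirically observed
convergence between readers could not emerge. Weighting repetition by
knowledge support and sharpening fresh draws biases settling toward each
reader's best-supported pronunciation, which is usually shared across
readers; declining novelty, declining inter-reader Gower distance and the
spread of popular pronunciations then all emerge from one mechanism. These
emergent properties are verified over 100 seeds in the test suite.

Defaults mirror the repeated reading-aloud design the package targets: 22
participants, 50 two-syllable nonwords, 5 sessions, 2 participants missing
the final session only. Under the default parameters the simulator produces
a mean of roughly 1.5 distinct pronunciations per reader-item over five
sessions, inside the 1.3–2.0 band that brackets values reported for real
adult readers. What the simulator does **not** emulate: phonetically graded
similarity between responses (all non-identical pronunciations are equally
different), mispronunciations and timeouts, item-order or fatigue effects,
and transcriber disagreement. Passing tests therefore certify the
pipeline's arithmetic and the models' behaviour under the stated generative
assumptions, not the psychological truth of those assumptions.

## Parameter recovery and calibration

Model-level generators (`simulate_diversity_data()` and friends) draw data
from each stage's own model family with known coefficients at the design
size, so sign recovery, bias, RMSE, CI coverage and type-I error are
well-defined. `recovery_suite()` runs them replicate-wise; the test suite
uses 25 replicates per stage (strong effects: focal signs recovered in at
least 95% of replicates; null effects: the pooled false-positive rate of
the regression stages stays within 5% ± 3%). Pooling is used for the
type-I check because 25 binary outcomes per stage cannot resolve a ±3%
band. Strong focal effects are sized for near-certain power at the design
size (diversity consistency −0.15; novelty session −0.8 and consistency
−0.4 on the logit scale; distance session −0.03 per SD of session).

**A known limitation.** The trajectory stage's intercept-slope correlation
of conditional modes is biased toward the fitted random-effect correlation
parameter and is anti-conservative when the true correlation is zero (in
null simulations the estimate ranged up to ~0.98). It is therefore scored
on sign recovery under strong effects only, and its printed correlation
should be read as descriptive, not inferential.

## Numerical choices and degenerate inputs

* Entropies and diversities are in nats throughout (natural log), matching
  the defining formula; probabilities are renormalised defensively and
  zero entries contribute nothing.
* Ties in rule matching are broken by inventory file order; ties in
  metric selection by declared candidate order — both deterministic.
* `sim_config()` validates that probability vectors sum to 1 and that the
  repetition weight is nondecreasing; degenerate settings (deterministic
  inventories, effectively infinite repetition) are supported and give the
  exact limiting behaviour (all diversities 0, all distances 0).
* Zero-variance inputs fail loudly where a statistic is undefined (t test,
  entropy of an empty distribution) and are flagged where a sensible
  sentinel exists (undefined trajectory correlation).
* All file formats are plain UTF-8 text (TSV/CSV/JSON); the GPC table
  round-trips through its CSV export including rule inventory and
  syllable counters.

## Problem sizes used in the test suite

Unit tests run on handcrafted fixtures and lexicons of 10–10,000 synthetic
words. The recovery suite uses 25 replicates per stage at the full
22 × 50 × 5 design; the emergent-phenomena checks use 100 simulated studies
at the default configuration. These sizes give stable pass/fail behaviour
for the stated thresholds while keeping a full run of the suite to a few
minutes on a single core.
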