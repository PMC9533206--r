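---
title: "Methods: keyword theme scoring and topic modeling of survivor forums"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: keyword theme scoring and topic modeling of survivor forums}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(themescan)
```

## Overview

`themescan` implements a mixed-methods pipeline for large discussion-board
corpora from cancer survivors: a predetermined keyword lexicon turns every
post into a vector of *theme scores*; a threshold turns scores into
classifications; descriptive summaries and a qualitative sample follow from
the scores; and a from-scratch LDA with coherence-based model selection
provides the unsupervised counterpoint. This vignette records the model,
the tunable parameters, the numerical choices, and what the synthetic-data
tests do and do not establish.

## Tokenization

One tokenizer (`tokenize()`) is shared by the keyword matcher, the lexicon
loader, the word-frequency tables and the bag-of-words builder. It
lowercases and treats every maximal run of Unicode letters/digits as a
token; hyphens, apostrophes and all other punctuation are boundaries.
Sharing a single normalization is load-bearing: the lexicon entry
"full-time" becomes the phrase pattern `(full, time)` under exactly the
same rules that split a post's "full-time" into `full`, `time`, so matcher
and lexicon can never disagree about token boundaries.

## The lexicon and the matching semantics

The built-in lexicon (`builtin_lexicon()`) ships the 29
psychosocial-effects themes with their published keywords verbatim, each
lowercased and normalized by the tokenizer. Single words become *root*
patterns matched as token prefixes — `unemploy` captures "unemployment",
"unemployed", "unemployable" — and multi-word entries become *phrase*
patterns matched prefix-wise against consecutive token runs. Prefix-on-token
matching (rather than substring-anywhere) is deliberate: `rest` must match
"resting" but not "arrest".

Counting semantics, where the published description leaves room:

- **Within a theme, a token counts once.** If two roots of one theme match
  the same token, the theme score rises by 1, because the score is defined
  as keyword instances appearing in the post, not pattern hits. Distinct
  phrase spans count separately from token matches.
- **Across themes, double counting is allowed.** The lexicon itself repeats
  keywords across themes ("spouse" under both Interpersonal and Family and
  caregiver relationships), so one token may feed several themes.
- **Short ambiguous roots are kept verbatim** ("rest", "egg", "fire") for
  fidelity to the published list; `validate_lexicon()` flags roots shorter
  than 5 characters so users can audit the over-matching risk.
- The themes *Posttraumatic stress* and *Posttraumatic growth* carry
  identical usable keywords ("trauma", "traumatized") and are therefore
  indistinguishable to any scorer built from this lexicon. The package
  implements the list verbatim and does not attempt to disambiguate.

## Classification, descriptives and the qualitative sample

A post is related to a theme when its score reaches `min_score` (τ,
default 3, the published threshold; exposed everywhere as a parameter).
This one number is the pipeline's main precision/recall dial: τ = 1 lets a
single stray "tired" classify a post; τ = 3 demands sustained use of a
theme's vocabulary.

`summarize_corpus()` reports board counts with percent shares rounded to 2
decimals and per-poster activity with mean/SD to 1 decimal, matching the
publication's presentation; `prevalence_by_year()` divides related posts by
total posts within each (board, year) cell; `word_frequencies()` drops
stopwords (a shipped, overridable English function-word list — the original
work names none) and pure-digit tokens, with ties broken alphabetically.

`select_qualitative_sample()` sorts posts by total theme score (descending;
ties by post id ascending for reproducibility) and walks the list skipping
any post whose author already holds `max_per_user` (default 5) selections —
if a prolific poster's sixth post qualifies, it is excluded and the next
post from another user enters instead.

## LDA by collapsed Gibbs sampling

`fit_lda_gibbs()` implements the standard collapsed Gibbs sampler. Token
*i* in document *d* with word *w* is reassigned with probability
proportional to `(n_dk + α)(n_kw + β)/(n_k + Vβ)`, and point estimates come
from the final sample: `φ̂ = (n_kw + β)/(n_k + Vβ)`,
`θ̂ = (n_dk + α)/(n_d + Kα)`. Defaults where the original work is silent:
`α = 1/K`, `β = 0.01`, `n_iter = 1000`, single chain, no hyperparameter
optimization — common LDA practice, all exposed as arguments. With `K = 1`
the estimates reduce exactly to θ = 1 and the smoothed empirical word
distribution, which the tests assert.

The sampler's randomness comes from its own xorshift64* generator seeded by
the `seed` argument, so a fit is a bit-identical function of its inputs on
every platform and R's global RNG state is untouched.

## C_V coherence

`cv_coherence()` implements the standard C_V construction: the topic's
top-n words (default `topn = 20`) are segmented one-against-the-set; word
and pair probabilities are estimated from boolean sliding windows (default
`window = 110` tokens) over reference texts; each word's vector of
ε-smoothed NPMI values (ε = 1e-12) against the top-n set is compared by
cosine with the topic's summed context vector; the score is the mean over
topics of the mean per-word cosine.

Numerical choices:

- Windows are *exact*: presence means the word occurs in the window. A
  document shorter than the window contributes one window; a document of
  *n* tokens otherwise contributes *n − window + 1*. The widely used
  reference implementation computes window presence incrementally and can
  deviate from exact presence for documents longer than the window; the
  frozen-reference agreement test therefore uses documents that fit within
  one window (where both constructions coincide), and sliding behavior is
  checked against a brute-force oracle instead.
- A top word absent from the reference texts has probability 0; it is
  ε-floored with a warning rather than producing NaN.
- Empty reference documents are skipped.

`select_num_topics()` sweeps a grid (default 2–40 by 2), scores each fitted
model and returns the coherence argmax with ties going to the smaller K
(prefer the simpler model).

## Relevance and lexicon overlap

`relevance_rank()` scores `r(w, t) = λ log φ + (1 − λ) log(φ/p_w)` with
`p_w` the marginal corpus word frequency; `λ = 0.6` follows the published
choice, and `n_terms = 7` per topic matches the published 56 terms over 8
topics. `keyword_overlap()` declares a topic term overlapping when a root
pattern prefixes it or it equals a word of a phrase pattern — the rule under
which the published shared terms "sleep" (root `sleep`) and "work" (a word
of `return to work` and other phrases) both register.

## The synthetic-data world

`synthetic_config()` states one world and the tests live in it:

- three boards at the observed shares (49.16 / 45.43 / 5.41%), years
  2000–2020;
- heavy-tailed poster activity: users weighted ∝ rank^−2, user count chosen
  so posts/user averages about the observed 19.5 (the realized mean runs
  higher, as the power law leaves many candidate users unsampled — the
  point is the heavy tail, not the exact mean);
- lognormal post lengths (median 50 tokens, sdlog 0.7 — typical short
  forum posts);
- five frequently discussed themes (Fatigue, Distress, Family and caregiver
  relationships, Interpersonal, Insurance status) each planted
  independently at 4%, giving ≈18.5% of posts at least one theme, near the
  observed 18.69% related share;
- four keyword instances injected per planted theme (≥ τ = 3).

Detectability is guaranteed *by construction*: background words are
screened so no lexicon root or phrase word prefixes them, injected surface
forms come only from theme-exclusive patterns (a root plus a random suffix
is re-checked against the whole lexicon; the suffix is resampled if it
drifts into another theme's vocabulary, e.g. `rest` + `less`), and
insertions happen between whole units so a later injection can never split
an earlier phrase. Themes without any exclusive pattern (the Posttraumatic
pair) trigger a warning when planted. A `noise_keyword_rate` option injects
unrecorded stray keywords for false-positive experiments.

What a green recovery test establishes: the scorer implements the matching
and thresholding semantics exactly (sensitivity 1, FPR 0 on clean planted
corpora is a theorem of the construction, so any failure is an
implementation bug). What it does not establish: performance on real
language — real posts have morphology, negation, sarcasm and topic drift
that the generator deliberately omits, and short roots like "rest" will
over-match in real text. The generator also makes no attempt at linguistic
realism or at the real boards' temporal posting spikes.

For LDA tests the generator can draw most tokens (default 80%) from one of
several disjoint latent-topic vocabularies, yielding corpora where the
planted topic count is recoverable by the coherence sweep.

## Degenerate inputs and edge policies

- Empty post text is allowed (scores all zero); absent (`NA`) text is an
  error.
- Empty corpora: scoreable (empty matrix), writable (header-only CSV), but
  not summarizable.
- `post_corpus()` validates ISO-8601 dates within a configurable range and
  warns on non-canonical board labels rather than failing.
- Duplicate post ids, missing columns and malformed fixture HTML produce
  structured errors naming the offending id/field/element.
- `agreement()` requires identical key sets; `NA` designations agree only
  with `NA`.

## Known limitations

- The keyword method has no negation handling, word-sense disambiguation
  or sentiment; that is faithful to the method being implemented.
- The published corpus-scale findings (the 125k-post corpus, C_V = 0.52 at
  K = 8, the specific 8 topic labels) depend on an undeposited scraped
  corpus and are not reproducible here; the acceptance suite instead
  reproduces every printed ratio from its printed inputs and validates the
  machinery property-wise at desk scale.
- C_V values depend on the reference corpus, window, and top-n; comparing
  coherence across different corpora is not meaningful.
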