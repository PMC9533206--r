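# themescan

Dictionary-based theme scoring and topic modeling for cancer-survivor
discussion-board corpora.

Survivors of gynecological cancer discuss the psychosocial side of
survivorship — fatigue, distress, family and caregiver relationships,
insurance and money, fertility — on public discussion boards in volumes far
beyond what manual qualitative coding can absorb. `themescan` implements a
mixed-methods pipeline for such corpora: an a-priori keyword lexicon over
the 29 psychosocial-effects themes of the Quality of Cancer Survivorship
Care Framework drives automatic per-post *theme scores*, threshold
classification selects the psychosocial-related subset and the
highest-scoring posts for close qualitative reading, and an unsupervised
topic model (LDA) provides the contrasting data-driven view. A synthetic
corpus generator with planted ground truth makes the entire pipeline
testable without scraping anything.

## The method

**Theme scoring.** Each lexicon theme *t* owns a set of keyword patterns:
*root* patterns match any token they prefix (`unemploy` →
"unemployment", "unemployed", "unemployable"), *phrase* patterns match
consecutive token runs prefix-wise. The theme score of post *d* is

```
score(d, t) = # keyword instances of theme t appearing in d
```

where a token (or phrase span) counts at most once per theme even when
several of the theme's patterns match it. A post is *related* to theme *t*
when `score(d, t) ≥ τ` (default τ = 3, so a single stray mention never
classifies a post), and *psychosocial-related* when it is related to at
least one theme. The qualitative sample is the top *k* posts by total theme
score Σ_t score(d, t), capped at 5 posts per user.

**Topic modeling.** LDA is fit from scratch by collapsed Gibbs sampling
(C++ core, bit-reproducible under a fixed seed), with point estimates

```
φ̂[t, w] = (n_tw + β) / (n_t + Vβ)      θ̂[d, t] = (n_dt + α) / (n_d + Kα)
```

The number of topics is chosen by sweeping a grid (default 2–40 in steps
of 2) and scoring each model with C_V coherence (boolean sliding windows,
ε-smoothed NPMI, indirect cosine over each topic's top-n words). Topic
terms are ranked by LDAvis-style relevance

```
r(w, t) = λ log φ[t, w] + (1 − λ) log(φ[t, w] / p_w),   λ = 0.6
```

and compared against the a-priori lexicon with `keyword_overlap()`.

## Worked example

```r
library(themescan)

gen <- generate_corpus(synthetic_config(n_posts = 1000, seed = 42))
m   <- score_corpus(gen$corpus, builtin_lexicon(), min_score = 3)
m
#> <score_matrix: 1000 posts x 29 themes, tau = 3, lexicon 'builtin'>
#>   related posts: 192 (19.20%)

summarize_corpus(gen$corpus)
#> 1000 posts by 33 unique posters (mean 30.3, SD 113.4, range 1-644 posts/poster)
#>   uterine        494 (49.40%)
#>   ovarian        460 (46.00%)
#>   other_gyn       46 (4.60%)

recovery_report(gen$truth, m)$per_theme
#>                               theme n_planted sensitivity fpr planted_prevalence measured_prevalence
#>                             Fatigue        39           1   0              0.039               0.039
#>                            Distress        44           1   0              0.044               0.044
#>  Family and caregiver relationships        39           1   0              0.039               0.039
#>                       Interpersonal        35           1   0              0.035               0.035
#>                    Insurance status        47           1   0              0.047               0.047
```

The 1000-post synthetic corpus mimics the published corpus shape (three
boards at 49/45/5% shares, years 2000–2020, heavy-tailed poster activity)
with five themes planted at 4% each; because planted posts carry four
keyword instances (≥ τ) and the background vocabulary is screened against
the lexicon, the scorer recovers every planted label exactly — sensitivity
1, false-positive rate 0, and a 19.2% related share close to the configured
~18.5% expectation.

`select_qualitative_sample(m, gen$corpus, k = 20, max_per_user = 5)`
returns the post ids for qualitative reading, and
`prevalence_by_year()` / `word_frequencies()` produce the board-by-year
prevalence series and top-word tables.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "themescan-cli.R", package = "themescan"))')
Rscript $CLI synth    --n-posts 1000 --seed 1 --out-dir data --html
Rscript $CLI score    --corpus data/posts.csv --min-score 3 --out scores.csv
Rscript $CLI describe --corpus data/posts.csv --scores scores.csv --out-dir desc
Rscript $CLI topics   --corpus data/posts.csv --k-min 2 --k-max 40 --k-step 2 \
                      --lambda 0.6 --n-terms 7 --seed 1 --out-dir topics
```

## Fixture HTML dialect

Forum pages are parsed from a documented fixture dialect (live scraping is
out of scope): each post is `<div class="post" id="POST_ID">` containing
`<span class="username">`, `<span class="date">` (ISO 8601 date) and
`<div class="post-text">`. `generate_fixture_html()` emits this dialect and
`parse_forum_html()` inverts it exactly.

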