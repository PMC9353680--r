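---
title: "Methods: topic modeling, valence scoring, and percentile condensation of forum posts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topic modeling, valence scoring, and percentile condensation of forum posts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forumcondense)
```

## The problem this package addresses

Peer-support forums inside mobile-health (mHealth) interventions accumulate
thousands of short, unstructured posts. Interpretive thematic analysis
preserves the narratives in that user-generated content but scales poorly;
plain NLP summaries scale but flatten nuance. `forumcondense` implements the
computational half of a sequential NLP-to-qualitative workflow: it
characterizes a forum corpus with topic modeling and rule-based sentiment
scoring, then *condenses* each topic and valence stratum to the posts a
human coding team can realistically read — the top decile by
topic-representativeness or emotional polarity.

The pipeline has five computational stages, each exposed as ordinary R
functions and driven end-to-end by `run_forum_pipeline()`:

1. **Ingest** — read the forum export, drop staff/test content, and build
   two parallel corpora over the same posts: a *sentiment-analysis (SA)
   corpus* kept byte-for-byte verbatim, and a *topic-modeling (TM) corpus*
   that will be normalized.
2. **Topic modeling** — normalize and tokenize the TM corpus, prune the
   vocabulary, fit latent Dirichlet allocation (LDA), optionally excise a
   curated removal list and refit (the refined "second pass" model), and
   emit numeric coherence diagnostics.
3. **Sentiment** — score every verbatim post with a lexicon-and-rules
   valence model of the VADER family.
4. **Condensation** — within each dominant-topic stratum, rank posts by
   *affinity* (count of the topic's signature tokens in the post) and keep
   posts strictly above the 90th-percentile affinity; independently, rank
   all posts by positive and by negative polarity and keep the top decile
   of each.
5. **Reporting** — export one coder-ready CSV per meta-theme, summarize the
   condensation, and compute pooled two-coder Cohen's kappa for the
   downstream human coding.

## Models and procedures

### Dual corpora

The two analysis tracks need opposite preprocessing. Topic models rely on
term co-occurrence, so capitalization and punctuation are noise there; the
valence scorer, by contrast, *uses* capitalization, punctuation runs and
emoticons as intensity signals ("so happy" vs "SOO happy!!! <3"). The
`dual_corpus` object therefore carries the same posts twice, with the
invariant that the SA text is byte-identical to the input and both corpora
list the same post ids in the same order. Condensation never rewrites text:
retained ids always map back to verbatim SA text.

### Normalization and vocabulary

TM-corpus texts are lowercased, every punctuation character is replaced by
a space, and the result is split on whitespace. Replacing punctuation with
a space (rather than deleting it) fragments URLs into separate unigrams
("https", "x", "org"), which is how web fragments actually surface as
high-frequency tokens in forum topic models; the alternative
(strip-to-nothing) would create unanalyzable fused tokens.

Vocabulary pruning applies two filters on the normalized forms: unigrams
occurring fewer than `min_count = 3` times are discarded, and the bundled
571-term SMART stop list is removed. Counting on normalized forms first is
the only self-consistent ordering — a frequency filter on raw forms would
count "HIV", "hiv" and "HIV." separately. Because both filters are
per-term set removals on normalized counts, the frequency filter, the stop
list and any later removal list commute: refining with a removal list is
equivalent to building with the stop list extended by it (this is tested).

### LDA and its estimation

LDA models each document as a mixture $\theta_d \sim
\mathrm{Dir}(\alpha)$ over $K$ topics and each topic as a distribution
$\phi_k \sim \mathrm{Dir}(\eta)$ over the vocabulary; each token draws a
topic $z \sim \theta_d$ and then a word $w \sim \phi_z$. The package fits
this by collapsed Gibbs sampling in compiled code, with point estimates of
$\phi$ and $\theta$ averaged over post-burn-in sweeps.

Numerical and design choices:

* **Hyperparameters** default to symmetric $\alpha = \eta = 1/K$ with 500
  sweeps (half burn-in). These are conventional library defaults; all are
  arguments, so sensitivity runs are one call away.
* **Determinism.** The sampler uses its own counter-based generator seeded
  by an explicit integer, so a fixed seed reproduces $\phi$ and $\theta$
  bit for bit regardless of R's RNG state or platform.
* **Restarts.** `fit_lda()` runs three chains from seeds derived
  deterministically from the user seed and keeps the one with the highest
  in-sample log-likelihood. On corpora of near-single-topic documents a
  single chain can lock into a mode where two topics merge; best-of-$n$
  restart selection is the standard remedy and keeps results stable across
  seeds.
* **Empty documents** (common: short greetings often normalize to nothing
  after stoplisting) are excluded from the fit but stay in the corpus with
  a null topic, and are excluded from affinity scoring with a log message.
* **K is an input, not an inference.** The pipeline emits diagnostics for
  whatever K the operator requests; choosing K is a human judgment in this
  workflow.

### Topic diagnostics

Instead of an interactive intertopic-distance map, the package reports
numbers with the same content: the $K \times K$ matrix of base-2
Jensen–Shannon divergences between topic-term rows (0 for identical
topics, 1 for disjoint support), a 2-D classical MDS embedding of that
matrix, per-topic *prevalence* (each topic's expected share of corpus
token mass, document-topic weights weighted by document length), the mean
pairwise divergence, and the coefficient of variation of prevalence. A
coherent model has large pairwise divergences and no vanishing topic.
Degenerate MDS eigenvalues (coincident topics) simply leave trailing
coordinates at zero.

### Valence scoring

The scorer is a faithful R port of the published VADER rule set (Hutto &
Gilbert 2014), using the published lexicon bundled as plain text: term
valences in $[-4, 4]$, ALL-CAPS emphasis, exclamation/question-mark
amplification, degree-modifier boosting and damping with distance decay,
negation flipping (including "no", "least", and n't-contractions),
special-case idioms, and contrastive-conjunction ("but") reweighting.
`pos`, `neu` and `neg` are proportions of the post's tokens (they sum to 1
up to 3-decimal rounding); `compound` is the normalized valence sum
$s/\sqrt{s^2 + 15} \in [-1, 1]$. Empty input scores all zeros. The port is
validated against frozen reference outputs across a battery of texts
exercising every heuristic, including the reference implementation's
first-match update quirk in the "but" rule, which is reproduced
deliberately: printed worked examples must match at 3-decimal precision.
Emoji-codepoint translation is not implemented; classic character
emoticons (":)", "(:") are scored via the lexicon. Compound scores are
computed and persisted but condensation uses only the pos/neg proportions.

### Condensation

The threshold convention is the spreadsheet-style *inclusive* percentile:
with sorted values $v_1 \le \dots \le v_n$ and $h = 1 + p(n-1)$, the
threshold is $v_{\lfloor h \rfloor} + (h - \lfloor h \rfloor)(v_{\lfloor h
\rfloor + 1} - v_{\lfloor h \rfloor})$. Retention is *strict*: a post is
kept only if its score exceeds the raw (possibly fractional) threshold, so
integer affinities 1..10 give threshold 9.1 and exactly one retained post
— the ">n topic-specific tokens" reading. An inclusive ($\ge$) cut is
available behind `strict = FALSE` for sensitivity analysis, as is
substring affinity matching (`substring = TRUE`) instead of the default
whole-token matching. Topic strata are ranked within dominant-topic
groups independently; sentiment strata rank *all* posts on pos and,
separately, on neg — the two sentiment memberships are not exclusive, and
the overlap report surfaces ids retained in both a TM and an SA stratum.
Stratum summaries use the sample (n−1) standard deviation. A degenerate
stratum whose scores are all equal retains nothing and warns rather than
errors.

### Pooled intercoder reliability

For a multi-code schema, every (post, code) pair is one binary
applied/not-applied decision per coder; decisions are pooled into a single
2×2 table and Cohen's $\kappa = (p_o - p_e)/(1 - p_e)$ is computed on it.
The full set of posts shown to the coders can be supplied explicitly,
because posts coded by neither coder contribute neither-applied agreement
yet are invisible in a long-format label table. Degenerate marginals
($p_e = 1$) raise an error rather than returning a meaningless number.

## The synthetic corpus generator

Real trial forum data cannot be redistributed, so every stage is exercised
against `generate_forum_corpus()`, which plants known structure:

* **Topics.** `K_true` topic-term distributions over an abstract vocabulary
  of word-like strings. Each topic's exclusive block gets a geometric
  (Zipf-like) rank profile (ratio 0.85), giving unambiguous signature
  tokens, and a shared slice carries one profile common to all topics,
  scaled to a fraction `topic_vocab_overlap` of each topic's mass. Overlap
  is therefore a genuine hardness dial: the planted inter-topic divergence
  is $1 - \mathrm{overlap}$ by construction, and assignment accuracy
  degrades monotonically as it rises (both tested).
* **Posts.** Topic mixtures are symmetric Dirichlet with concentration
  0.05 — near-single-topic posts, the regime in which a dominant-topic
  partition is meaningful. (Simulation puts about 81% of posts above
  dominant weight 0.9 at this setting.) Lengths are discretized log-normal
  (median ≈ 18 tokens, default `meanlog = log(18)`, `sdlog = 0.6`).
* **Salutations.** Nearly half of real forum content is brief greetings
  and check-ins; the default `salutation_fraction = 0.45` plants 2–6-word
  greeting posts with no topic label. Many normalize to nothing and test
  the empty-document paths.
* **Valence injection.** 10% of posts each get a strongly positive or
  negative appended phrase built from genuine lexicon words with
  social-media emphasis (ALL-CAPS, "!!!", emoticons), so the scorer has
  real entries to react to. Injection labels are recorded as planted
  truth.
* **Staff content.** 2% of posts are flagged test posts, exercising the
  staff filter.

All randomness flows from one integer seed; the same spec and seed give a
byte-identical corpus.

What the generator does *not* emulate: real lexical semantics (topical
words are abstract strings, so stoplist interaction with topical content
is minimal), reply-thread discourse structure, user-level posting
dynamics, misspellings, or organically mixed sentiment inside long
narratives. Passing the bundled benchmarks therefore demonstrates that the
machinery is correct and well-calibrated on corpora with this structure —
not that any particular real forum will yield three clean topics.

One interaction worth knowing: planted greetings are *organically*
positive ("happy friday"), so under the full default conditions the
condensed (+)Pos stratum legitimately mixes organic greetings with
injected posts. The injection-recovery benchmark therefore isolates the
plant (no salutations) when asking whether retained high-polarity posts
are the injected ones (precision 1.0 in that setting); under full
conditions the scorer's preference for concise emotive posts is exactly
the behavior the workflow expects.

## Benchmark problem sizes

The bundled test-and-acceptance benchmarks were sized as desk-scale
recovery experiments: the main topic-recovery run uses 2,000 posts over a
500-term vocabulary with K = 3 (dominant-topic accuracy ≈ 0.98 and matched
top-10 token Jaccard ≥ 0.8 across seed sweeps); hardness and degeneracy
properties use 150–800-post corpora; the percentile oracle is checked on
1,000 random arrays; determinism is asserted by byte-comparing two full
pipeline manifests on a 500-post corpus.

## Known limitations

* Unigrams only; no phrase detection, stemming, or lemmatization (matching
  the workflow's preprocessing conventions).
* The scorer is English-only and lexicon-bound; sarcasm and in-group
  re-appropriation of slurs are known failure modes of any lexicon method.
* Collapsed Gibbs point estimates carry label-switching ambiguity across
  *different* seeds (topic indices are arbitrary); comparisons against a
  reference model should go through `match_topics()`.
* The human stages — topic labeling, the removal-list curation between the
  first and second pass, thematic code development — are deliberately out
  of scope: the package prepares their inputs and quantifies their
  reliability, nothing more.
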