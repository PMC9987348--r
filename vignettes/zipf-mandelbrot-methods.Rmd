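---
title: "Fitting Zipf-Mandelbrot distributions to child-directed speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting Zipf-Mandelbrot distributions to child-directed speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zipfcds)
```

## The model

Across languages, word frequency falls off with frequency rank approximately
as a power law. `zipfcds` works with the Zipf-Mandelbrot form

$$f(r) \propto \frac{1}{(r + \beta)^{\alpha}},$$

where $r = 1, 2, \dots, N$ is the rank of a word type when types are ordered
by descending frequency, $\alpha > 0$ is the exponent governing how fast
frequency decays, and $\beta \ge 0$ is Mandelbrot's shift, which flattens the
very top of the curve and markedly improves the fit of real text at low
ranks. Normalising over the $N$ observed types gives the probability mass
function

$$p(r) = \frac{(r+\beta)^{-\alpha}}{\sum_{r'=1}^{N} (r'+\beta)^{-\alpha}},$$

implemented by `zm_pmf()`. Natural language is only *near*-Zipfian: observed
distributions deviate systematically at both frequency extremes, so the
package treats the model as a description whose quality is measured, not as a
hypothesis to be accepted or rejected.

Three modelling commitments matter:

* **The likelihood is multinomial over observed ranks.** `fit_zm()`
  maximises $\sum_r f(r)\log p(r)$ with $N$ equal to the number of observed
  types. No unseen-type correction is applied: the object being described is
  the observed rank-frequency distribution itself.
* **Ranks are assigned with explicit random tie-breaking.** Words sharing a
  count occupy a block of consecutive ranks in a seeded random order
  (`assign_ranks()`). Because tied words have identical counts, the
  rank-to-frequency mapping — and therefore every fitted parameter — is
  invariant to the tie seed; the seed is recorded purely for audit.
* **Goodness of fit is the Pearson correlation of observed with expected
  frequencies** (`evaluate_fit()`), not of frequency with rank: the question
  is how much of the observed frequency vector the fitted law reproduces.
  The same correlation on a log-log scale is reported alongside, restricted
  to ranks where both vectors are positive.

## Estimation

`fit_zm()` uses bounded quasi-Newton optimisation (L-BFGS-B on the mean
negative log-likelihood) restarted from a fixed 6 × 4 grid of starting
values, $\alpha_0 \in \{0.8, 1.2, 1.6, 3, 10, 50\}$ and
$\beta_0 \in \{0.1, 1, 10, 100\}$, so results are deterministic. The default
box is $\alpha \in (0.05, 200]$, $\beta \in [0, 1000]$ — deliberately wide,
because closed-class categories such as prepositions can drive fitted
exponents beyond 100. Convergence is assessed on the objective at tolerance
comparable to 1e-8; the per-start objective values are kept in the returned
object. All likelihood computation is done in log space, so extreme
parameters do not overflow or underflow.

One numerical caveat is worth knowing. For nearly geometric frequency decays
(each count about a constant fraction of the previous), the ZM likelihood
increases along the ridge $\alpha, \beta \to \infty$ with $\alpha/\beta$
fixed, because $(r+\beta)^{-\alpha}$ approaches a geometric sequence in that
limit. On such data the estimate runs to the box boundary; the wide default
bounds make this visible rather than hiding it, and the test suite compares
the optimizer against an exhaustive grid oracle inside a common box.

### Degenerate fits

When the fitted exponent is extreme, the expected distribution cannot
support correlation-based evaluation. `zm_degenerate()` flags a fit when
either essentially all mass sits on rank 1 ($p(1) > 1 - 10^{-9}$) or the
rank-1 unnormalized weight $(1+\beta)^{-\alpha}$ underflows below the
smallest normal double (about $2.2\times10^{-308}$): beyond that point the
expected frequency vector is not representable in ordinary double-precision
arithmetic, and direct evaluation collapses it onto rank 1 — the most
frequent word receives probability one and every other word probability
zero. Parameters of order $\alpha \approx 115$, $\beta \approx 476$ trigger
the flag; every fit with $\alpha \le 2$ is far from it. Degenerate fits
report their parameters but no correlations; this is a reported state, not
an error.

## Corpus construction

CHAT transcripts are read by `parse_chat()`: `@ID` headers resolve speaker
roles and the target child's age (years;months.days, days dropped); `*`
main tiers become utterances; `%mor` tiers provide per-token category codes
when they align 1:1 with the cleaned tokens. Cleaning (`clean_tokens()`)
removes bracketed transcriber annotation, event and filler codes,
unintelligible-speech codes, omitted-word codes and punctuation, keeping
the orthographic word form. Choices the format leaves open:

* **Case folding is on by default** (configurable). CHAT capitalises
  sentence-initial words; without folding, "The" and "the" split one type.
* **Child exclusion** removes the target-child and generic child roles, and
  by default also sibling/playmate-style roles, retaining caregivers and
  investigators; `corpus_selection(exclude_young = FALSE)` restricts
  exclusion to the child roles alone. Utterances with unknown roles are
  conservatively kept as adult input.
* **Repetition markers** (`[x N]`) are stripped, not expanded; clitic and
  compound joiners inside a word are kept, the word being its surface
  string.
* Transcripts without a parseable age are kept for pooled analyses and
  excluded (with counts) from age-binned ones.

Frequency lists distributed as word/relative-frequency tables are read by
`read_frequency_list()`; fractional counts are permitted throughout, which
is why token totals are not forced to integers.

## Subsampling and stability

`continuous_samples()` builds *conversationally continuous* samples:
whole transcripts are concatenated in corpus order until the target token
count is reached, a transcript is never split mid-file, and a trailing
remainder below the target is discarded. `stability_curve()` repeats this
from random transcript orderings at a ladder of sample sizes (by default
5,000 to 100,000 by 5,000, ten replicates each) and summarises the spread of
$\hat\alpha$ per size; the replicate SD shrinking with size identifies the
smallest corpus for which estimates are stable, and the package's age-binned
analyses adopt 50,000 tokens as the fitting floor on that basis. Because
samples are whole-transcript unions, emitted sizes slightly exceed their
targets. Sampling of transcript orderings is without replacement within a
replicate and independent across replicates; overlap between replicates is
allowed. Cross-group comparison of per-sample estimates (`compare_groups()`)
is an ordinary one-way ANOVA with $(k-1, n-k)$ degrees of freedom.

## Developmental analyses

`bin_by_age()` pools adult tokens into six-month bins by the target child's
age at recording (a transcript on a bin boundary belongs to the bin
containing that exact month). Bins at or above the 50,000-token floor are
fitted; smaller bins are summarised with absent parameters. `age_trend()`
regresses a per-bin quantity ($\hat\alpha$ or Pearson's $r$) on the bin's
start age in months, centred, with a language-level random intercept and age
slope. When the maximal structure fails to converge or is singular it is
simplified stepwise — random intercept only, then fixed effects — and the
structure actually used is reported. Mixed-model p-values use the
Satterthwaite approximation (lmerTest); this choice is named in the output
rather than hidden.

## Part-of-speech analyses

`extract_pos_tokens()` classifies each token by its own morphology-tier tag
(so a form occurring as both noun and verb contributes to both categories);
tag/token alignment is positional, and misaligned or untagged utterances
are skipped and counted. Tag profiles map exact `%mor` category codes to the
four analysed categories (noun, verb, adjective, preposition) with no
subcategory absorption, and are plain editable lists per language. Manual
cleaning of extraction errors is represented reproducibly by plain-text
exclusion lists: `apply_exclusions()` removes listed types — never
reassigning them to another category — and reports the error rate as
excluded types over types before exclusion. `fit_pos()` declines to fit
fewer than 10 types and flags fits on fewer than 50 types as low-reliability,
since exponent estimates from tiny type inventories (the preposition case)
are unstable.

## The synthetic generator, and what passing tests mean

`synthetic_spec()` / `make_corpus()` generate corpora whose distributional
ground truth is known: tokens are drawn i.i.d. from the ZM pmf at chosen
$(\alpha, \beta)$ over a fixed vocabulary, packed into utterances
(shifted-geometric lengths, mean 6 — a plumbing choice nothing depends on)
and transcripts of about 2,000 adult tokens carrying an age schedule, with a
configurable fraction (default 0.1) of child-role utterances interleaved to
exercise speaker filtering, and optional per-category POS structure with
aligned `%mor` tags. The rank-to-word-form mapping is fixed and injective,
so generated ranks are recoverable. All randomness flows from the single
spec seed.

The generator reproduces the *distributional* structure the analyses assume
and nothing more: real child-directed speech is bursty, topically coherent
and full of repeated frames, none of which i.i.d. sampling models. Passing
recovery tests therefore demonstrates that the estimation machinery is
correct at the published corpus scales — not that real corpora satisfy the
model. The validation regimes mirror published whole-corpus scales
(6.31M tokens over 27,476 types at $\alpha = 1.57$, $\beta = 19.48$;
300K tokens over 13,801 types at $\alpha = 1.19$; 797K verb tokens over
3,978 types at $\alpha = 1.74$), with five seeded replicates each and the
median estimate compared against the generating value. At these scales the
estimator's replicate spread is of order $10^{-3}$, far inside the
tolerances used.

Routine tests run the same machinery at reduced scale (vocabularies of a few
hundred to a few thousand types, $10^4$–$10^5$ tokens), which keeps the
default suite under a minute apart from the full-scale recovery checks; the
problem sizes are stated in each test.

## The threshold-based alternative fit

`fit_clauset()` implements the common alternative to whole-distribution
fitting: treat the frequency values of all types as draws from a discrete
power law $p(x) \propto x^{-a}$ above a threshold $x_{\min}$, estimate $a$
by maximum likelihood for each candidate threshold (the normaliser is a
Hurwitz zeta, computed as a truncated sum with an Euler-Maclaurin tail
correction), and choose the threshold minimising the Kolmogorov-Smirnov
distance between empirical and model CDFs of the tail. Candidates are the
observed values leaving at least 10 tail observations, thinned to at most 60
quantile-spaced values for tractability. This value-domain formulation is
the standard one; a rank-domain variant (thresholding on minimal rank) can
be emulated by truncating the ranked frequency vector before calling the
fitter. The whole-distribution correlation method remains the package's
headline procedure, since near-Zipfian data violate the pure power-law
assumption that the threshold method relies on.

## Known limitations

* Words are orthographic forms; no lemmatisation or morphological merging,
  so morphologically rich languages show inflated type counts.
* The generator does not model burstiness, variation sets or discourse
  structure; recovery results speak to estimator correctness, not to the
  adequacy of the ZM law for real speech.
* CHAT conformance is partial by design: overlap markers, timing and media
  links, and phonological tiers are ignored.
* Whether sibling and peer utterances count as adult input is genuinely
  underdetermined in the field's corpus conventions; both behaviours are
  available and the default (exclude) is recorded in `corpus_selection()`.
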