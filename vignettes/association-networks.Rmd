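---
title: "Mapping mental representations from free word associations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping mental representations from free word associations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A free word association (FWA) survey asks each participant for the first five
words that come to mind for a cue — here, the most disturbing excessive
activity in their life — and then asks them to attach two emotion labels from
a fixed 20-item positive/negative affect list to each association, to name the
substance or behavior they were thinking of (4 substance and 10 behavior
categories, plus "other"), and to rate the intensity of the problem on a
4-point item ("I did it too much in the past 12 months").

The analytic question is whether the associations organize into a small number
of shared *mental representations* — clusters of words that co-occur within
participants more often than chance — and how membership in those clusters
relates to the substance/behavior distinction, to problem intensity, and to
the emotions attached to the words. coopnet implements that chain as a tested
pipeline: preprocessing, a signed co-occurrence network, signed-modularity
consensus clustering, participant profiling, and a contingency/rank-test
inference layer, plus a synthetic generator that supplies ground truth for
validation.

## Preprocessing

Tokens are lower-cased, accent-stripped and whitespace-normalized. Synonym and
translation merging is inherently a human judgment, so it enters as an
explicit user-supplied merge map (raw token to canonical token, validated to
be idempotent); the package never guesses synonyms. The pipeline order is
fixed and each step idempotent:

1. normalize, 2. merge, 3. drop participants whose category is "other" (their
substance/behavior status is unknowable), 4. drop tokens mentioned by fewer
than `min_token_count` participants (default 10 — idiosyncratic associations
are unstable parts of a representation, and frequency-rank curves of such
surveys show a breakpoint around 10; `frequency_rank_report()` exposes the
diagnostic without ever choosing the threshold automatically), 5. drop
participants left with no retained tokens, 6. keep only emotion labels
provided by at least `emotion_label_threshold` of the remaining participants
(default 0.50, inclusive; a participant "provides" a label if it appears
anywhere among their ten selections).

Counting is participant-based throughout: a participant mentioning a token
twice contributes once to its frequency and to any pair count, because the
participant is the co-occurrence unit.

## The signed co-occurrence network

For every pair of retained tokens the 2x2 table over participants (both / one
/ neither mentioned) is scored by the log-likelihood ratio against
independence,

$$G = 2 \sum_{\text{cells}} O \,\ln(O/E), \qquad 0\ln(0/E) \equiv 0,$$

the standard collocation (G) statistic: twice the gap between the saturated
and the independence multinomial log-likelihood. The edge weight is $+G$ when
the pair co-occurs more often than expected (attractive), $-G$ when less
often (repulsive), and the pair is omitted at exact equality. All pairs are
scored — no pair-level significance threshold is applied, because thresholding
is the clustering step's job; an undefined statistic (a token mentioned by
every participant) skips the pair with a warning. Degenerate inputs (fewer
than two tokens, empty corpora, self-pairs) raise classed errors.

## Signed modularity and its conventions

With repulsive edges, plain Newman–Girvan modularity is not applicable, so
partitions are scored by the signed extension

$$Q = \frac{1}{2\,(v^+ + v^-)} \sum_{ij}
\left[(w^+_{ij} - e^+_{ij}) - (w^-_{ij} - e^-_{ij})\right]\delta_{M_i M_j},$$

where $v^\pm$ is the total attractive/repulsive weight (each undirected edge
counted once), $e^\pm_{ij} = s^\pm_i s^\pm_j / (2 v^\pm)$ is the
strength-preserving configuration-model expectation within each sign layer
(zero for an empty layer), and the sum runs over ordered pairs. The
double-counting convention has to be pinned down once, and this one is chosen
because it makes the formula collapse exactly to Newman–Girvan modularity on
all-positive networks, gives $Q = 0$ for the all-in-one partition by
construction, and conserves $\sum_{ij} e^\pm_{ij} = 2v^\pm$ over ordered pairs
including self-pairs. Three consequences used as test oracles: the unit
triangle has $e^+_{ij} = 2/3$ and $Q = -1/3$ under singletons, and positive
random graphs agree with a brute-force double-loop Newman oracle to 1e-12.

Within-module repulsive weight is penalized, so a clique of repulsive edges is
split into singletons while its sign-flipped twin is kept whole — the
anti-symmetry that motivates the extension.

## Louvain optimization and consensus

`louvain_signed()` is the greedy two-phase heuristic adapted to the signed
gain: a node's move gain is the positive-layer gain minus the negative-layer
gain, each with its own null term, renormalized by $v^+ + v^-$. Local moves
accept only strict improvements (tolerance 1e-12), ties go to the lowest
module id, the node-visit order is shuffled from the seed (same seed, same
partition), and modules are then aggregated into super-nodes (sign layers
aggregated separately — collapsing them into one matrix would let attractive
and repulsive weight cancel) and the process repeats. The modularity of the
induced partition is recorded after every phase and is non-decreasing by
construction.

Louvain output varies with the seed, so modules are defined by consensus:
`runs` restarts (default 100) build the co-classification matrix (fraction of
runs placing a pair together); entries below `threshold` (default 0.40,
inclusive "at least") are zeroed and the resulting consensus graph is
re-clustered the same way until every restart agrees, capped at 20 iterations
(a hit cap flags the result rather than throwing, and reports the
best-modularity partition of the last iteration). The 0.40 threshold is used
both inside the consensus loop and as the natural cutoff when drawing the
consensus graph; runs and the cap are unstated in the source methodology and
therefore configurable.

## Profiling and inference

Participants are linked to the module holding the plurality of their retained
tokens. Plurality ties are broken by the larger summed corpus frequency of the
participant's tied tokens, then by the lowest module id — a deterministic,
data-driven rule (the source methodology does not state one). Participants
with no retained tokens stay unassigned.

Module emotion distributions count one unit per
(participant, association, label) triple among retained tokens and labels and
normalize to percentages within modules; positive/negative affect shares
aggregate them through a configurable label-to-valence map. Module summary
tables report per-module n, top member tokens (frequency order, alphabetical
ties), the distribution of substance-type and of behavior-type participants
across modules (each normalized within its own type), and the within-module
high-intensity share.

The inference layer is deliberately plain: Pearson chi-square tests of
independence without continuity correction (with $(O-E)/\sqrt{E}$ cell
residuals for deviation maps), the intensity item dichotomized at "Totally
agree" (4 = high, 1–3 = low), tie-corrected Kruskal–Wallis H tests on
per-participant label counts, and Dunn's pairwise z tests on pooled ranks with
tie correction. Dunn p-values are unadjusted by default (Holm and friends are
one argument away) because the source tradition reports unadjusted pairwise
values. The observation unit for the rank tests — each participant's count of
the focal label among their retained selections — is a package decision;
participants are the independent sampling units. Because "comparing emotions
between substances and behaviors across the four modules" is ambiguous
between a 2-group and a 4-module grouping, `emotion_rank_tests()` implements
both (`group = "type"` or `"module"`) and leaves the choice to the caller.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` plants everything the pipeline is supposed to find: each
participant has a home module (default shares 35/21/29/15% over four
modules); their five distinct tokens come from the home module with
probability `concentration` (default 0.9), otherwise from a uniformly chosen
other module, with Zipf(1) popularity within modules over a 26/19/17/15-token
vocabulary (77 tokens, 546 participants — dimensionally comparable to a
mid-sized survey of this kind); emotion labels follow module-specific
profiles; the category follows module-specific substance/behavior weights
(baseline popularity from realistic response counts, substance odds
multiplied by 3 for the substance-leaning half of the modules); and the
probability of answering "Totally agree" on the intensity item is
module-specific (0.66/0.74/0.60/0.60).

The default emotion profiles put 75% of every module's label mass on a
six-label dominant core (worries, shame, anxiety, contempt, joy, calmness),
tilted 2x towards two module-signature emotions, and spread the rest over the
remaining 14 labels. This reproduces the characteristic outcome of the 50%
participation filter — a handful of dominant labels retained, the rest
excluded — while keeping module emotion profiles distinguishable.

Two intentional artifacts of the design are worth knowing. First, drawing
five *distinct* tokens per participant makes any token pair slightly
negatively dependent even at the uniform-concentration baseline, so G-edge
calibration against a literal independence null is conservative-biased on
generator corpora (the statistic itself is exactly calibrated on corpora with
independent Bernoulli mentions, which the test suite checks separately).
Second, drawing two *distinct* labels per association biases the realized
label marginal away from the raw profile; recovery of emotion distributions
is therefore scored against the induced pair-inclusion marginal
$q_l \propto p_l\,(1 + \sum_{k \ne l} p_k/(1-p_k))$, against which the error
shrinks like $1/\sqrt{n}$.

What passing tests on synthetic data do *not* show: real surveys have
open-vocabulary tokens needing spellcheck/lemmatization/merging (emulated
only through the merge-map interface), module structure that is neither
disjoint in vocabulary nor uniform in concentration, and emotion labels
correlated with intensity and demographics in ways the generator does not
model. Recovery benchmarks certify the machinery, not the field validity of
any particular survey.

## Problem sizes and numerical choices

Validation runs at desk scale: exhaustive G-oracle enumeration over all 2x2
tables with margins up to 20 (~35k tables, tolerance 1e-9); modularity
equivalence on random graphs up to 30 nodes (1e-12); planted-partition
recovery at 600 participants, 80 tokens, concentration 0.9, 100 consensus
runs, 20 seeds (the idiosyncratic-token filter at its default 10 is part of
the validated chain — rare tokens carry genuinely unstable co-occurrence
evidence, and one 4-participant token in one seed is correctly ambiguous
without it); chi-square type-I calibration on 10,000 fixed-margin tables and
power on 100 replicates at 500 participants with the default coupling of 3
(consensus scaled to 25 runs there, to which recovery at concentration 0.9 is
insensitive). The full default pipeline (546 participants, 77 tokens, 100
consensus runs) completes in a few seconds.

## Limitations

The Louvain heuristic has no optimality guarantee (hence consensus); module
labels such as "Guilt/Shame/Relief" are human annotations outside the
package's scope; no resolution parameter, overlapping communities, or Leiden
refinement is provided; and the inference layer intentionally stops at the
tests described — no regression or ordinal modeling.
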