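---
title: "Binding-site models with dinucleotide dependencies: methods and design"
author: "motifHMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-site models with dinucleotide dependencies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifHMM)
```

## The model

A transcription factor flexible model (TFFM) is a hidden Markov model
over the DNA alphabet in which emissions are conditioned on the
previously *observed* nucleotide: state $s$ emits nucleotide $n$ with
probability $e_s(n \mid m)$ when the preceding sequence position showed
$m$. This first-order conditioning is what lets the model express
dinucleotide preferences inside binding sites — stacking and shape
effects that position weight matrices cannot represent. The state space
is a background state (or four, see below) plus a chain of match states,
one per motif position; entering the chain from the background starts a
site, and leaving the last match state ends it.

Three topologies trade off expressiveness against parameter count:

* **order0**: every state's four conditional rows are constrained to be
  identical (the `tied` flag), so the model is exactly a position
  frequency matrix wrapped in an HMM — the natural baseline within the
  same machinery.
* **order1**: match states have free conditional rows. At initialization
  all four rows equal the seed PFM row, so *no* dependency is present at
  the start; dependencies exist in the trained model only insofar as the
  data put them there. This avoids fabricating structure the seed motif
  does not contain.
* **detailed**: each motif position is represented by four states, one
  per nucleotide, with indicator emissions ($P = 1$ for the state's own
  letter). Dependencies move into the transitions, which also makes the
  *entry* into the motif conditional: each of the four background states
  owns its own background-to-motif transition row, so the probability of
  starting a site may depend on the last background nucleotide. We use
  four background states (mirroring the four-fold decomposition of the
  match positions); the indicator emissions are definitional, so
  training freezes them and re-estimates transitions only.

Likelihood, posteriors and training use the standard scaled
forward-backward recursions, batched across equal-length sequences so
each position costs one matrix product. The first position's emission is
conditioned on a fixed sentinel nucleotide, `A` by default; for tied
states the sentinel is irrelevant, and for conditional states it
contributes one of four nearly identical terms, so scores are
insensitive to the choice. There is no explicit end state: the
likelihood is over the full sequence with free termination.

**Initial state distribution.** Scan windows are treated as embedded in
background sequence, so the initial distribution equals the transition
row out of the background: mass $1-p$ on the background and $p$ on the
first motif position ($p$ = the background-to-motif probability). A
site that starts at the very first window position is therefore
scoreable; concentrating the initial mass entirely on the background
would make such sites structurally impossible.

## Training

Baum-Welch (EM) with three package-level conventions:

* **Stopping rule**: stop when the mean per-sequence log-likelihood
  improvement falls below $10^{-4}$, or after 100 iterations, whichever
  comes first. These are declared defaults of this implementation, not
  facts inherited from any dataset; at the problem sizes below, training
  typically converges in 30–80 iterations.
* **Pseudocount** $10^{-4}$ is added to the expected counts of
  *structurally allowed* parameters before renormalization. Structural
  zeros — parameters exactly zero at initialization — are masked out and
  can never be resurrected, so the topology (including flexible-length
  edits) is invariant under training. The pseudocount prevents
  numerically underflowed counts from creating new zeros.
* **Tied states** pool their expected emission counts over the
  previous-nucleotide index, keeping order-0 states order-0. Frozen
  parameter blocks (the detailed model's indicator emissions) are left
  untouched.

EM guarantees a non-decreasing likelihood; with the pseudocount the
M-step maximizes a lightly penalized surrogate, so the trace is
monotone within $10^{-9}$ in practice and the test suite asserts exactly
that.

Sequences containing `N` are excluded from training (their likelihood
contribution would depend on an arbitrary missing-data convention).
During scanning, an `N` emits with probability $0.25$ in every state and
conditions downstream emissions on the mean of the four conditional
rows — this keeps likelihoods defined while making `N` uninformative.

## Scanning and scores

Sequences are scored on both strands at every position; the score at
$t$ is the posterior probability of being in a final match state, i.e.
that a site *ends* at $t$. The reverse strand is scanned by scoring the
reverse complement with the same model and mapping coordinates back;
models are never reverse-complemented. A minus-strand score is indexed
by the forward-strand coordinate of the site's last base in reading
direction (the leftmost base of its forward interval). All reported
intervals are 0-based half-open (BED convention).

The best hit per sequence is the maximal score over positions and
strands, ties broken by smaller start then forward strand. For
flexible-length models the hit's width is decided by the site-path
variant (gap used or not, position skipped or not, ...) with the highest
posterior probability of ending at the chosen position; the package
enumerates the variant paths at the state-group level, so the detailed
topology stays tractable.

The probability of occupancy aggregates the per-position posteriors:
$$P_{occ} = 1 - \prod_t (1 - P_t),$$
the complement of "no site ends anywhere". The product runs over both
strands' positions by default (a single-strand flag exists); it is
monotone in every $P_t$, bounded by $\max_t P_t$ from below, and exactly
0 when all $P_t = 0$.

## Flexible-length edits

Four declarative edits rewire the match chain; each takes an initial
branch probability strictly inside $(0,1)$ that training re-estimates:

* `gap_insert(at, prob)`: a uniform-emission position between `at` and
  `at + 1`, used with probability `prob` (width range $+1$).
* `skip_position(at, prob)`: transition `at−1 → at` set to `prob`, new
  transition `at−1 → at+1` with $1 -$ `prob` (width range $-1$).
* `alternative_core(at, to, altPfm, prob)`: a parallel run of states
  over the span, possibly of different length.
* `flexible_edge(at, prob)`: the motif may end at `at`; that position
  joins the final states.

Edits apply at the state level for order-0/1 models and at the
nucleotide-group level for detailed models; the same edit list yields
the same width range on both, which the tests verify by enumerating all
realizable site paths. Newly created transitions (a gap's exit row, a
skip's bypass) are initialized from the average of the transition rows
they parallel, renormalized — the least-informative choice consistent
with the surrounding topology.

## Logos and information content

The summary logo uses the marginal probability of each nucleotide at
each position, computed by propagating an equiprobable distribution
through the conditional tables: $P_i(n) = \sum_m P_{i-1}(m)\,
e_i(n \mid m)$, with $P_0$ uniform. Conditionals come from the emission
tables (order-0/1) or the normalized transition rows (detailed). The
dense logo is the dinucleotide-aware view: a $4 \times L$ grid whose
row $m$, column $i$ cell draws $P_i(\cdot \mid m)$ probability-scaled,
with cell opacity proportional to $P_{i-1}(m)$, floored at 0.1 so rare
rows stay legible (a rendering choice with no model semantics). Letter
heights in the summary logo are scaled by the position's information
content; per-position IC uses the Schneider convention
$IC_i = 2 + \sum_n P_i(n) \log_2 P_i(n)$ with $0 \log 0 = 0$, giving a
model total in $[0, 2L]$ bits. Variable-length models have no
well-defined column layout and are rejected by the logo functions.
SVG output is assembled deterministically (fixed-precision formatting),
so the same logo data renders byte-identically.

## PWM baseline

The log-odds baseline is $w_{i,n} = \log_2\!\big((p_{i,n} + c)/(b_n +
c)\big)$ with uniform background and pseudocount $c = 0.01$ by default
(declared here; a zero pseudocount is allowed only when no PFM entry is
zero). Windows score as plain sums; `N` scores as the background
expectation of its column. Best hits follow the same tie rules as the
HMM scanner.

## Evaluation protocol

`crossValidate` implements the benchmarking loop: reserve the
`initSize` top-signal sequences for seeding (ties by input order),
shuffle and split the remainder into $k$ folds, and per fold initialize
from the seed PFM, train on the fold's training part, and score the
held-out part plus an equal-size background with the best hit (or
occupancy) per sequence. Backgrounds come either from a one-state
first-order Markov chain fitted to the fold's test sequences
(pseudocount 1 per dinucleotide) or from a user-supplied candidate pool
subsampled to match the foreground's %GC distribution
(1-percentage-point bins, without replacement). The headline number is
the pooled AUC over the concatenated fold scores; per-fold AUCs are
also returned since fold-to-fold model calibration differences make the
pooled value slightly conservative.

ROC curves sweep the union of observed scores, grouping ties at one
threshold; the AUC is the trapezoidal integral and equals the
tie-corrected Mann-Whitney statistic, which the tests check by direct
pairwise comparison and against an independent ROC package. Method
comparisons use the paired Wilcoxon signed-rank test on per-dataset AUC
differences with Benjamini-Hochberg correction, plus a ratio-to-best
table flagging methods within 95% of the best. Score-signal
correlation bins sequences into twenty 5-percentile groups by signal,
takes the median score per bin, and reports the Spearman correlation of
the bin medians with bin rank together with the ordinary
least-squares slope p-value on the same 20 points; constant medians are
reported as $\rho = 0$ with a degeneracy flag rather than `NA`.

## Synthetic data

The generator emulates summit-centered ChIP-seq peak windows: 101-nt
sequences from an order-1 background chain, each carrying (with
configurable probability) one site sampled from a known generative TFFM
— including flexible-width variants at their branch probabilities — at
a uniform or summit-concentrated position, on either strand
(forward-strand probability 0.5 by default, matching real peak sets;
parameter-recovery studies set it to 1 because the emission parameters
of a near-palindromic motif are not identifiable from a 50/50
reverse-complement mixture). The planted site's first emission is
conditioned on the background nucleotide actually preceding it, so
sites are seamless order-1 insertions. Signal values follow
$\exp(a z + \varepsilon)$ where $z$ is the standardized per-nucleotide
generative log-probability of the planted site — a monotone
strength-to-enrichment map with log-normal noise, giving the
score-signal trend the correlation analyses expect.

Defaults: the background chain has human-like composition (~41% GC)
with a depleted CpG dinucleotide, so %GC-matching operates on realistic
variation; the reference motif (`simulationMotif()`) is E-box-shaped —
consensus CACGTGA core at 95% per-position probability with three
degenerate flanks — calibrated so its information content is
approximately 12 bits (11.9), concentrated in a core as real TF motifs
are.

What the simulation does *not* emulate: read-level coverage and peak
calling, mappability structure, co-factor motifs, repeats, and
sequence-composition heterogeneity along the genome. Passing the test
suite therefore demonstrates the *machinery* — correct posteriors,
convergent training, faithful protocol — not that any particular AUC
will be attained on real ChIP-seq data. One consequence visible in the
acceptance numbers: because the generative sites are drawn from a PFM
(no true dinucleotide dependencies), the PWM baseline is the
correctly-specified model for these data and scores on par with — or
slightly above — the HMM variants; the HMM's advantage is expected only
when real dependencies exist.

## Numerical choices and problem sizes

Scaled (linear-space) recursions are stable beyond $10^5$ nt. Posterior
correctness is asserted against exhaustive path enumeration at
$10^{-10}$ on models up to 6 states. Model JSON serialization is
full-precision (round-trips within $10^{-12}$). The packaged studies
use 500 windows for discrimination (10-fold), 1000 for emission
recovery, 800 for width-mixture recovery and 600 for the order-0
consistency check — sizes at which the recovered quantities sit well
inside their tolerance bands while the whole suite runs in a few
minutes on one core.

## Known limitations

* Flexible-length models have no logo representation.
* Edit placement is manual; the package does not search for where a
  gap or skip should go.
* The detailed topology trains all transitions independently, so it
  needs more data than order1 for the same stability.
* Dinucleotide-weight-matrix (DWM) scoring is out of scope; the PWM is
  the only non-HMM baseline.
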