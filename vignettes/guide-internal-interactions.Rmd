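---
title: "Methods: screening guide RNAs for internal interactions and quantifying activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening guide RNAs for internal interactions and quantifying activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(guideqc)
```

# Scientific background

A single-guide RNA (sgRNA) consists of a 20-nt target-specific *spacer*
followed by an invariant *scaffold* (backbone) that binds Cas9. For the
guide to direct cleavage, the spacer must remain single-stranded until it
pairs with target DNA, and the scaffold must adopt its native stem-loop
architecture. Two classes of unintended base pairing defeat this:

1. **Internal hairpins** — the spacer pairs with itself, forming a
   stem-loop that sequesters the seed region.
2. **Backbone interactions** — the spacer pairs with scaffold bases,
   disrupting the repeat:anti-repeat duplex or the scaffold stem-loops.

Both are predictable from sequence alone with simple base-pairing rules,
and guides carrying strong predicted stems show sharply reduced cleavage
activity that can often be rescued by refolding or by redesigning the
spacer. `guideqc` implements the screen, a transparent folding score, the
activity quantification used to validate such predictions, and a genomic
similarity scan, each testable against exhaustive oracles.

# Base-pairing model

Pairing is defined by `base_pair_rule()`:

* allowed pairs: canonical G:C and A:U, plus the G:U wobble when
  `allow_wobble = TRUE` (the default — wobbles are real and commonly
  stabilise spurious stems);
* A:G and all other combinations are mismatches and terminate a stem.

Each pair class carries an integer weight (`pair_scores`, default
`G:C = 3, A:U = 2, G:U = 1`). The absolute scale is arbitrary; only the
ordering G:C ≥ A:U ≥ G:U > 0 matters, and the constructor enforces it.
The default 3/2/1 ladder keeps scores additive, integer, and easy to read
(a 4-pair all-G:C stem scores 12), while encoding that a G:C pair is
stronger than A:U, which is stronger than the wobble. `stem_stability()`
sums these weights over a stem and is the quantity all monotonicity
properties are stated in: extending a stem can never lower it, hardening
G:U to G:C strictly raises it, and breaking a pair removes its
contribution.

# Duplex screen

`find_intra_spacer_duplexes()` enumerates *maximal* intramolecular stems:
runs of consecutive pairs (i, j), (i+1, j−1), … that cannot be extended
outward or inward without violating pairing or the minimum loop. A stem
is reported with 1-based spacer coordinates, where position 1 is the 5'
(PAM-distal) end and position 20 abuts the PAM.
`find_spacer_backbone_duplexes()` does the same for antiparallel duplexes
between spacer and scaffold, annotating hits with the named scaffold
region(s) they overlap.

Screening parameters (`screen_config()`):

* `min_stem = 4` pairs — shorter runs are ubiquitous in random sequence
  and thermodynamically negligible at assay temperatures.
* `min_loop = 3` nt — the sterically minimal hairpin loop.
* `wobble_extra = 1` — a stem containing at least one G:U must be
  `min_stem + 1` pairs long to raise a flag. Wobble pairs are weaker, so
  a 4-pair stem with a wobble is borderline; requiring one extra pair
  keeps sensitivity for long wobble stems without flagging noise.
* `min_stability = 0` — an optional extra threshold on the summed pair
  score; 0 means stem length and the wobble rule alone decide.

`classify_guide()` reduces the passing hits to flags
(`internal_hairpin`, `backbone_interaction`) and a `clean` verdict;
`screen_guides()` vectorises this over a guide table and `screen_report()`
serialises the result. The optional `gg = TRUE` switch substitutes the
first two spacer bases with G (the T7/U6 transcription-start constraint)
before screening, since that substitution can create or destroy stems.

# Maximum-pairing fold

`max_pair_fold()` implements the Nussinov dynamic programme: `M[i, j]` is
the best total pair score of any non-crossing structure on the subsequence
`i..j`, with hairpin loops of at least `min_loop = 3` unpaired bases.
Complexity is O(n³) time and O(n²) space — instantaneous at sgRNA length.
The traceback is deterministic: at each interval it first prefers leaving
base `j` unpaired only when pairing cannot do better, and when several
partners for `j` tie, it takes the smallest index `k`. Ties are therefore
resolved identically on every run and on every platform, which the test
suite checks. The score is a *pair-count-style* upper bound on duplex
content, not a free energy; it deliberately trades thermodynamic realism
for a model simple enough to verify against exhaustive enumeration of all
non-crossing structures (done in the tests for every sequence length ≤ 10).

# Activity quantification

Single-turnover cleavage assays titrate Cas9:sgRNA (default two-fold
dilutions from 600 nM: 600, 300, 150, 75, 37.5) against trace substrate.
`fraction_cleaved()` converts gel densitometry to
product / (product + substrate), and `fit_ec50()` fits

fraction = f_max · c² / (c² + EC½max²)

by bounded Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with
the Hill exponent fixed at 2 (`fix_hill = FALSE` frees it; the acceptance
suite verifies that refitting noiseless curves with the exponent free
recovers 2). Constraints: `f_max` in (0, 1], `EC½max` > 0.

**Initialisation.** `f_max` starts at the observed maximum fraction
(clamped to [0.05, 1]). The EC50 start is the concentration whose observed
fraction lies closest to half the observed maximum — the empirical
half-max crossing. A fixed start at the geometric mean of the series can
place Levenberg–Marquardt on a path that collapses onto the EC50 lower
bound, where the Jacobian is singular and the fit aborts; the half-max
crossing avoids this, and the geometric mean, minimum and maximum
concentration are retained as ordered fallbacks (first convergent fit
wins, keeping the procedure deterministic).

Replicates (≥ 2 in practice) are fitted separately by default and
summarised as mean ± s.e.m. across replicate fits; `pooled = TRUE` fits
all points jointly instead. Estimates above `censor_threshold = 1000` nM
— or guides where no replicate converges — are censored and reported as
`"> 1000"`, because values beyond the titration range cannot be measured
accurately. `tidy()`, `glance()`, `augment()` and `autoplot()` methods
expose the results in tidyverse-native form.

`mutagenesis_rate()` covers the cellular readout: mutant reads divided by
mutant + wild-type reads at the cleavage site.

# Genome scan

`pssm_from_consensus()` builds a mismatch-count matrix from a query
sequence (score of a window = number of substitutions versus the query);
`read_pfm()` ingests JASPAR-style count matrices in either orientation,
adds a pseudocount of 0.25 (a standard small-sample correction that keeps
zero counts finite), and converts to −log frequency scores. In both modes
**lower scores are better** — the scan *minimises* substitutions.
`scan_pssm()` scores every window of every sequence on the + strand and,
by default, the − strand (by scoring forward windows with the
reverse-complemented matrix), skips windows containing N, and returns the
`top_k` hits in a deterministic order: score ascending, then sequence id,
start, and strand (+ before −). `hits_to_bed()` exports 0-based
half-open BED.

# Synthetic fixtures

No real sgRNA scaffold sequence ships with the package; the bundled
scaffolds (`builtin_scaffold("standard")`, 72 nt, and `"extended"`,
80 nt) are synthetic sequences engineered to have the canonical
architecture — repeat:anti-repeat duplex plus three stem-loops — with
labelled regions, so region annotation and the `--bb` choice behave like
they would on a real backbone without asserting any published sequence.

The generators are pure functions of their parameters and `seed`, restore
the caller's RNG state, and attach a ground-truth `"planted"` manifest:

* `make_hairpin_spacer()` plants one stem (arm length, loop length and
  number of wobbles chosen by the caller) and verifies, via the screen
  itself plus rejection sampling, that it is the *only* flagged structure.
* `make_backbone_spacer()` embeds the reverse complement of a scaffold
  window and verifies the verdict is exactly `backbone_interaction`.
* `make_clean_spacer()` draws a random spacer and repairs it (mutating a
  base inside the strongest offending stem) until it screens clean.
* `simulate_cleavage_curve()` evaluates the Hill model on the default
  series, adds i.i.d. Gaussian noise truncated to [0, 1], and tags
  replicates; `plant_genome()` writes motif occurrences (optionally
  mutated and/or on the − strand) into random DNA and records their exact
  coordinates.

A deliberately short 24-nt **toy scaffold**
(`extdata/scaffold_toy_synthetic.txt`) is used in simulations and smoke
tests: against a full-length scaffold, essentially every random 20-mer
shares at least one 4-pair wobble-permitting duplex (the expected count is
in the dozens), so "backbone-clean versus the full scaffold" is not a
satisfiable generator contract at default thresholds. The toy scaffold
keeps the clean/hairpin/backbone trichotomy realisable while exercising
identical code paths.

These fixtures emulate the *structure* of real experiments (planted
ground truth, replicate noise, censoring, strand placement), not their
biology: noise is Gaussian rather than densitometry-shaped, planted
genomes are uniform random DNA, and stability is a pair-count score, not
ΔG. They exist so that every claim the package makes is checkable against
a known answer.

# Problem sizes and verification

The test suite verifies, among others: the duplex finder against
exhaustive stem enumeration on 1,000+ random 20-mers; the fold DP against
brute-force enumeration of all non-crossing structures on 500 random
sequences of length ≤ 10; the PSSM scan against naive all-window scoring
on 50 kb planted genomes; EC50 recovery on 600 noisy simulated curves
(median relative error ≤ 20%, spurious censoring < 5%); and an end-to-end
run of the command-line tool against generator manifests. All oracles are
implemented independently of the production code.

# Limitations

* The pairing model ignores thermodynamics (no stacking energies, no
  temperature); scores rank stems but do not predict ΔG or folding
  kinetics, and pseudoknots are outside the non-crossing model.
* EC½max fits assume a fixed Hill exponent of 2; strongly cooperative or
  biphasic curves will be misfit.
* The PSSM scan assumes position independence and scores substitutions
  only — no indels, no PAM-awareness.
* The bundled scaffolds are synthetic; screen against your actual
  backbone sequence via `read_scaffold()` for production use.
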