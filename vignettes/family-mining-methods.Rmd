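---
title: "Mining protein families in assemblies with profile HMMs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining protein families in assemblies with profile HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famscan)
```

# Scope

famscan builds a profile hidden Markov model (HMM) of a protein family from
a multiple sequence alignment, screens six-frame-translated nucleotide
assemblies (metagenomes or reference genomes) for significant matches, and
summarises the results the way microbiome mining studies do: per-sample hit
counts, hits-per-megabase densities grouped by body site, cross-method
overlap counts, and rank-sum / Welch comparisons between groups.  The
motivating use case is mining human-microbiome assemblies for lanthionine
dehydratase (LanB) genes, the hallmark of subclass I lantibiotic
biosynthetic gene clusters, but nothing in the code is specific to that
family: any aligned protein family works.

Everything downstream of the alignment is implemented here; the alignment
itself is not.  `read_aligned_fasta()` consumes aligned FASTA from any
aligner (MUSCLE, MAFFT, ...).

# The model

## Architecture

A profile HMM with `M` match states is estimated from the alignment's
match columns.  Each position has the classic three states — match (emits
a residue from a position-specific distribution), insert (emits from the
background), delete (silent) — with the seven core transitions M→M, M→I,
M→D, I→M, I→I, D→M, D→D.  There are no I→D or D→I moves; when an alignment
path contains such an adjacency (a residue in an insert column followed by
a gap in the next match column) that transition is simply not counted, and
pseudocounts keep every row a proper distribution.

## Column assignment and weighting

A column becomes a match column when its weighted non-gap occupancy is at
least `occupancy_threshold` (default 0.5, boundary inclusive).  Raising
the threshold can only remove match columns, never add them.

Sequence weights are Henikoff position-based weights by default: in each
column, each of the `r` distinct residue types splits a unit of weight
equally among the `s` sequences carrying it, and per-sequence column sums
are normalised to total the number of sequences.  This corrects for
phylogenetically redundant training sets.  It is deliberately *not* a
neutral estimator: sequences carrying rare residues are up-weighted, which
on independently sampled (i.i.d.) training data biases peaked emission
estimates toward uniform.  For that reason `build_profile()` takes
`weighting = "none"`, which the parameter-recovery experiments use —
simulated families have no phylogenetic redundancy to correct — while real
alignments keep the default `"henikoff"`.

## Emissions, transitions, pseudocounts

Match emissions are weighted residue counts plus a background-proportional
pseudocount of total mass `pseudocount_alpha` (default 1):
`P(a) = (c_a + alpha * bg_a) / (C + alpha)`.  Insert emissions are fixed to
the background.  Transitions are weighted counts of observed state moves
along each sequence with a pseudocount of `alpha/7` per transition type.
The background is flat (0.05) by default or empirical from the training
alignment.  All probabilities are strictly positive except the two
structurally impossible moves at the last node (M→D and D→D), which are
exact zeros and serialise as `*` in the profile file.

One consequence of a *fixed* pseudocount mass is that duplicating every
training sequence shifts estimates slightly (counts double, alpha does
not); the effect is bounded by roughly `alpha / 2C` per probability and is
tested at that tolerance.

## Local alignment scoring

Search scores a peptide `x` of length `L` in fully local mode, in log
space with explicit minus-infinity for forbidden moves:

* entry into match state `k` at any residue position with weight
  `1/(L*M)` — uniform over start positions and entry states.  The `1/L`
  factor is the length treatment that makes an uninformative peptide (all
  X) score at most 0 bits against the i.i.d. background null;
* exit from match state `k` with probability `1/(M-k+1)` (uniform over
  remaining exit opportunities; exit from the last match state is
  certain), with core moves out of a match state rescaled by the
  complement;
* flanking residues are emitted by the background and cancel against the
  null, so the dynamic programming works directly in log-odds; X and other
  unknown residues are score-neutral everywhere.

The forward score is `log2` of the summed odds of *all* local alignments;
the Viterbi score is the best single alignment, with deterministic
tie-breaking (match preferred over delete over insert, earlier positions
first).  Forward ≥ Viterbi always.  Both recurrences are verified against
exhaustive enumeration of every admissible path on small models — the
enumeration is an independent implementation used only in tests and in the
acceptance script.  The kernels are C++ (Rcpp) because calibration and
screening score 10^5–10^6 segments.

## E-values and calibration

A bit score `S` converts to an E-value via a Gumbel law:
`E = Z * (1 - exp(-exp(-lambda * (S - mu))))`, with `Z` the number of
segments searched (per-sample by default, mimicking per-sample search
runs; a fixed global `Z` is available for cross-sample comparability).
`mu` and `lambda` come from scoring `n_random` i.i.d. background peptides
whose lengths follow a gamma distribution — match `length_mean` to the
segments you will search.

The fitting default is a peaks-over-threshold fit of the Gumbel's
exponential tail: `lambda = 1/mean(excess)` over the top 2% of calibration
scores, with the location anchored so the fitted law reproduces the
observed exceedance fraction.  A whole-sample Gumbel maximum-likelihood
fit is available (`tail_fraction = 1`, and `pin_lambda` fixes
`lambda = ln 2`), but we measured it to overstate the tail decay rate
(bulk fit lambda ≈ 1.7 versus tail behaviour ≈ 0.9 on forward scores),
which inflates deep-tail hit counts by one to two orders of magnitude.
Since significance calls live at E ≤ 1e-5, the tail fit is the default.
Two caveats follow: calibrated E-values are trustworthy in the tail
(roughly E ≤ 0.1·Z) and saturate toward `Z` in the bulk; and deep-tail
accuracy improves with `n_random` — use 10,000 when E-values near 1e-5
must be quantitatively reliable.  E-values that would underflow are
floored at 1e-320 to stay positive.

## Translation and screening

Assemblies are translated in all six frames with the standard genetic
code.  Stop codons split each frame into maximal stop-free segments —
translating through stops would create biologically meaningless chimeras —
and segments shorter than `min_peptide_len` (default 20 residues, the
scale below which random hits dominate) are dropped.  Codons containing N
translate to X; IUPAC ambiguity codes are normalised to N on input.
Coordinates are 1-based, inclusive, on the forward strand, so
`nt_end - nt_start + 1 = 3 * nchar(peptide)` in every frame, and
re-translating a segment's mapped interval regenerates the peptide
exactly.

`screen_sample()` searches every translated segment, keeps candidates with
E-value at or below the cutoff (inclusive, default 1e-5), and collapses
hits whose nucleotide intervals overlap on the same contig across frames
to the single lowest-E hit, so one locus is counted once.  The density
denominator is the total assembled nucleotides of the sample.  For
cross-method comparisons (`method_overlap()`), hits from different methods
are the same locus when their intervals overlap by at least 50% of the
shorter one; loci are single-linkage clusters of that relation, so each
method's region counts add up to its deduplicated hit total.

## Statistics

Group density comparisons are two-sided (the conservative default):
Wilcoxon rank-sum through `stats::wilcox.test()` (exact when the combined
size is ≤ 10 without ties, otherwise the normal approximation with
continuity correction) or Welch's t through `stats::t.test()`.  No
multiple-testing correction is applied across pairwise site comparisons,
matching how such screens usually report raw p-values; apply
`p.adjust(..., "holm")` if you need it.  The test suite checks the
Wilcoxon path against full enumeration of rank assignments for all
tie-free layouts with combined n ≤ 8.

# The synthetic-data generator

Because the original screening databases are multi-gigabase downloads, all
tests run on synthetic data with known ground truth:

* `make_family()` draws a random ancestor and substitutes each site
  independently at the chosen divergence (default 20% per site, a
  comfortably detectable but non-trivial family spread), giving gap-free,
  trivially aligned homologs;
* `random_profile()` + `sample_from_profile()` generate sequences from a
  known model, retaining the generating paths so `sampled_alignment()` can
  rebuild the ground-truth alignment for parameter-recovery experiments;
* `diverge()` at rate 0.9 manufactures "diverged beyond recognition"
  decoys for negative controls;
* `reverse_translate()` picks synonymous codons weighted toward a target
  GC content and appends a stop, so translating frame +1 regenerates the
  protein exactly;
* `make_metagenome()` builds i.i.d. background contigs (negative-binomial
  lengths, configurable GC, default 0.45 as typical for gut taxa) and
  splices implants at stated offsets and strands, recording every implant
  in a truth table.

What this emulates: homologous families at controlled amino-acid distance,
decoy sequence space, and coding loci embedded in noncoding-like
background on both strands.  What it does not emulate: real phylogenetic
correlation (rate variation across sites and lineages), codon usage of
real taxa, repeats, sequencing error, or assembly artifacts.  Passing the
synthetic benchmarks therefore demonstrates that the machinery — model
estimation, translation coordinates, scoring, calibration, thresholding,
bookkeeping — is correct, not that any particular published hit count will
be reproduced; published counts additionally depend on the exact training
set, aligner and search-tool versions.

# Study conditions used by the tests and the acceptance script

* scoring oracle: 100 random models (M ≤ 3) × peptides (length ≤ 4),
  agreement within 1e-9 bits;
* parameter recovery: 10 match states, 2,000 sampled sequences, every
  emission row within total variation 0.05;
* calibration accuracy: 10,000-peptide calibration, then 20 seeds ×
  10,000 background peptides; mean counts of hits with E ≤ t within a
  factor of 3 of t for t in {0.1, 1, 10};
* end-to-end screen: 20 contigs (~5 kb), 5 implants at 20% divergence,
  all detected at E ≤ 1e-5 with zero background hits;
* control panel: 9 positive strains (held-out family members implanted in
  DNA) and 7 far-diverged negatives; sensitivity and specificity 1.0;
* genomic screen: ~5 Mb of synthetic genomes with 2 implants, reported
  as aggregate hits/Mb.

These sizes keep the full suite and the acceptance script within a few
minutes while leaving the statistical margins comfortable.

# Numerical choices and degenerate inputs

* All dynamic programming is in natural-log space; forbidden transitions
  are explicit `-Inf`; conversions to bits happen once at the end.
* Viterbi ties break deterministically (M > D > I, then earlier position),
  so repeated runs are byte-identical.
* Emission/transition rows must sum to 1 within 1e-9 in memory; profile
  files store negative natural logs at 6 decimals, so round-trips are
  exact to 1e-6 per probability and validation of parsed files uses that
  looser tolerance.
* Degenerate inputs fail loudly: empty peptides, empty assemblies,
  alignments with unequal lengths, calibration on constant scores, implant
  collisions, and occupancy thresholds yielding fewer than
  `min_match_states` match columns are all errors, not warnings.
* Generators are pure functions of (configuration, seed): repeated calls
  are identical, and the caller's RNG state is restored.

# Known limitations

* One hit per translated segment (the best local alignment); multi-domain
  proteins are counted once per overlapping locus after deduplication.
* No acceleration pre-filters (MSV/SSV-style); screening cost is linear in
  segments × model length, so scanning many gigabases will be slower than
  heavily optimised engines.
* E-values from different calibrations are not comparable to other tools'
  E-values at face value; detection decisions at a fixed cutoff are the
  comparable quantity.
* Insert emissions equal the background, and priors are single-component
  background-proportional pseudocounts rather than Dirichlet mixtures —
  adequate for training sets of hundreds of sequences, less so for very
  small families.
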