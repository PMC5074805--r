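---
title: "From a single helical hairpin to a folded TPR: methods and design choices"
author: "tprhairpin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a single helical hairpin to a folded TPR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tprhairpin)
```

## The scientific question

The tetratricopeptide repeat (TPR) is a 34-residue helix-turn-helix unit
stacked into right-handed solenoids. Repeat folds are thought to arise by
amplification of subdomain-sized peptides, so a natural question is whether
TPR-like helical hairpins survive today inside *non-repetitive* proteins —
and whether such a hairpin can be turned back into a folded TPR by
amplification plus a handful of point mutations. This package implements
the computational side of that program: detecting TPR-like hairpins in
sequence databases, filtering them structurally, judging their
repeat-stacking compatibility, designing three-repeat constructs from the
helical hairpin of ribosomal protein S20 (RPS20-hh), and analysing the
phylogenetic and biophysical evidence.

## Profile scanning and p-values

A 34-column log-odds profile is built from an ungapped repeat-unit
alignment with background-weighted pseudocounts,

$$S(p,a) = \log_2 \frac{n_{p,a} + w\,b_a}{(N+w)\,b_a},$$

and every 34-residue window of a query is scored additively. Additive
log-odds is the simplest defensible score for an ungapped fixed-length
motif; any calibrated monotone score would serve.

**Calibration.** p-values come from a simulated null: sequences drawn
i.i.d. from a reference composition (Robinson–Robinson frequencies by
default) with lengths resampled from an empirical pool. The maximum window
score of a sequence with $m = L-33$ windows is modelled as Gumbel with
location $\mu_0 + \beta \ln m$ and scale $\beta$, fitted by maximum
likelihood. The logarithmic length offset is the exact behaviour of maxima
of i.i.d. exponential-tailed scores and keeps one calibration valid across
sequence lengths.

A pure Gumbel fit, however, badly overestimates extreme quantiles here:
window scores are sums of 34 bounded terms, so their (and their maximum's)
upper tail decays faster than exponentially. Measured on fresh simulated
sequences, the bulk-fitted Gumbel threshold at nominal $p = 10^{-4}$ was
exceeded more than thirty times less often than nominal. We therefore
splice a Weibull excess model onto the standardized maxima above their
empirical 99th percentile (MLE on the exceedances; continuous and monotone
across the splice). The residual tail miscalibration is about a factor of
two — adequate for rank statistics and for the FDR machinery below, and
stated honestly rather than hidden: absolute p-values from any profile
scanner are only as good as its null model.

**Hits, suppression, singletons.** Windows with $p \le 10^{-4}$ (the
pipeline default) are reported; overlapping windows whose starts lie within
17 residues (half a unit) of a better-scoring window are suppressed so one
hairpin is never reported twice. Hits with no neighbour within a 10-residue
inter-unit gap ($s_B - e_A - 1 \ge 10$) are *singletons* — TPR-like units
outside repeat arrays, the interesting case for ancestry. The gap-based
reading of "within a distance of 10 residues" was chosen over
start-to-start distance; identical windows across a database are reported
once.

**FDR.** The false discovery rate at a cutoff is the ratio of hits in a
composition- and length-matched simulated database to hits in the real
database, repeated (100 times by default) for a mean ± SD. Simulated
databases reuse the real database's exact length multiset — the strictest
reading of "same number of sequences of the same length distribution".

## Structure filtering

All 34-residue hairpins share a fixed position correspondence, so no
multiple structure alignment is needed: `average_unit()` superposes every
member onto the current mean (Kabsch least squares, proper rotations only),
recomputes the coordinate mean, and iterates to convergence — the
fixed-correspondence specialisation of iterative multiple superposition.
Candidates farther than 2.0 Å Cα RMSD from the average unit are discarded
as non-hairpin-like. Interface positions are transferred between hairpins
by superposition followed by nearest-Cα matching (ties to the lower index);
with the shared numbering of the TPR unit and RPS20-hh this is the identity
on positions 3, 7, 10, 21, 28.

One caveat discovered during testing: an index-shift oracle ("shift the
query by one residue and the mapping shifts by one") is ill-posed for
helical geometry, because least-squares superposition re-registers a
shifted helix by a screw motion and restores the identity mapping. The
mapping tests therefore check rigid-motion invariance and noise robustness
instead.

## Interface hydrophobicity

Positions 3, 7, 10, 21 and 28 of the unit are buried between stacked
repeats. A hairpin is stacking-compatible when at least three of the five
carry Ala, Ile, Leu, Met, Phe or Val; Trp is excluded as too large for the
inter-repeat interface. `screen_family()` maps the 34 columns of a family
alignment covering a reference fragment (by the reference row's gap
structure — no re-alignment), drops rows with indels in the window, and
filters by that count. The RPS20-hhta parent passes with exactly three
(L10, I21, V28).

## Coevolution

`mutual_information()` computes column-pair MI in nats with a small uniform
pseudocount (1 per pair table) and pairwise deletion of gapped rows; no
sequence weighting by default, because the simplest estimator is the most
reproducible one (weighting and average-product correction are exposed as
options). "Non-local" pairs are those at least 5 positions apart —
neighbouring columns covary trivially through local structure. In TPR
units the dominant non-local signal links positions 7 and 23, which face
each other across the hairpin; the design rules below preserve it.

## Consensus design

`assemble_construct()` implements the assembly grammar: an Asn–Ser
N-terminal cap, three copies of the (mutated) unit with the last four
residues of all but the final repeat replaced by the consensus inter-repeat
loop DPNN, the native IDKA tail on the final repeat, and the natural RPS20
C-terminal helix as stop helix (or the two-residue stub "AK" for
stop-helix-free constructs). Mutations use one-letter codes ("K7L"), carry
per-repeat applicability — V9N applies to repeats 1–2 only, since V9 packs
against the stop helix in the last repeat — and are limited to five per
repeat so the design keeps its RPS20 character. `design_report()` enforces
the coevolution coupling at 7/23 (admissible joint states: K7L+I23Y,
K7R+I23D, I23D alone, or both native — exactly the tested combinations,
deliberately not generalised) and scores candidates by interface
hydrophobicity, signature-residue agreement (W4, L7, G8, Y11, A20, Y24,
A27, P32, evaluated on the middle repeat where every non-exempt mutation
applies) and net charge, counted as (K+R)−(D+E) with His neutral.

The seven published constructs (M0, M2, M4E, M4N, M4RD, M5 and the
stop-helix-free M4NΔC) are reproduced byte-for-byte from the parent 34-mer
plus their mutation lists; this exact-string round trip is the module's
primary test surface.

## Repeat phylogenetics

Units are fixed-length (34) so unit alignments are indel-free and the
p-distance (Hamming/34) is well defined; no substitution-model correction
is applied because none is warranted for such short, closely related units
(a model hook would slot in at `p_distance_matrix`). Trees are built by
Saitou–Nei neighbor joining (exact on additive matrices), negative NJ
branches are clamped to zero with compensation on the longest sibling
branch, and bootstrap support comes from resampling the 34 columns with
replacement (1000 replicates by default), counting bipartitions on the
full-data tree. Supports on zero-length internal edges are reported as 0 —
an edge no site supports should not inherit spurious resampling counts.
Recently amplified arrays give star-like trees with short internal edges;
ancient divergence gives long, well-supported internal edges.

## Unfolding thermodynamics

Chemical denaturation follows the linear extrapolation model,
$\Delta G([D]) = \Delta G_{H_2O} - m[D]$, with the observed CD signal a
population-weighted average of folded and unfolded baselines:

$$y([D]) = \frac{(y_F + m_F[D]) + (y_U + m_U[D])\,e^{-(\Delta G_{H_2O} - m[D])/RT}}
                {1 + e^{-(\Delta G_{H_2O} - m[D])/RT}}.$$

$R = 1.987\times10^{-3}$ kcal/(mol·K) and $T = 296.15$ K (23 °C) unless
configured. Sloped baselines are the default — they are the standard
generalisation and reduce bias — with a flat-baseline mode available to
mirror the classical transform $f_U = (y_F - y)/(y_F - y_U)$ literally
(values are deliberately not clipped to [0,1]; noise legitimately crosses
the baselines and clipping would bias fits). Fits use Levenberg–Marquardt
least squares initialised from three-point baseline fits and the
steepest-slope midpoint. A valid cooperative fit requires $m > 0$ and a
midpoint $C_m = \Delta G_{H_2O}/m$ inside the data range; flat or linear
curves raise a distinct no-transition error, mirroring the behaviour of
unfolded constructs whose curves carry no transition to fit. Thermal melts
are summarised by the inflection $T_m$ of a Boltzmann sigmoid with linear
baselines — a shape summary, not a van 't Hoff analysis.

## Synthetic data: what it emulates, and what it does not

Every stage has a generator with known ground truth: null databases with
given composition and length pool; planting of 34-mers with a truth table;
idealised hairpin Cα traces from canonical helix geometry (1.5 Å rise,
100° twist, 2.3 Å radius — chosen because real structures, which the
original analysis used, need no synthetic geometry); alignments with one
covarying column pair whose MI is available in closed form; and forward
two-state curves. All generators are pure functions of their seed.

The generators deliberately do *not* emulate: homologous redundancy and
phylogenetic correlation in sequence databases (null sequences are i.i.d.),
insert-state idiosyncrasies of curated family alignments, side-chain-level
structural detail, or non-two-state (molten-globule-like) unfolding.
Passing tests therefore demonstrate correctness of the machinery under the
stated models, not performance on any particular curated database — which
is version-dependent in any case.

## Problem sizes and numerical choices

The test suite and the acceptance script use desk-scale problem sizes
chosen to make the statistics decisive: 10,000-sequence null databases
with 50 planted units and 100 FDR repetitions; 10,000 calibration
sequences; 50-structure averaging at σ = 0.5 Å; 100 replicates of the
coevolution and phylogeny checks; 100-seed noise sweeps for the fits.
Tolerances follow the statistic: exact string equality for constructs,
1e-9 for closed-form geometry/NJ checks, 1e-6 for noiseless fit round
trips, and 3-SD bands for Monte-Carlo quantities. Ties break to the lowest
index (nearest-atom mapping, top-MI pair) or smallest label pair (NJ);
all randomness flows from one integer seed via a fixed counter scheme
(`derive_seed`), so every result in the package is bit-reproducible.

## Known limitations

- Absolute p-values depend on the null model; only rank behaviour and the
  self-consistent FDR are calibrated quantities. Scores from other
  profile scanners (different profiles, different statistics) are not
  comparable number-for-number.
- The design rule set encodes exactly the published mutation sites and
  7/23 couplings; it is a faithful formalisation, not a general consensus
  designer.
- p-distance phylogenies underestimate multiple substitutions at larger
  divergences; acceptable for near-identical repeat units, not for deep
  phylogenies.
- The two-state machinery will (correctly) refuse non-cooperative curves
  rather than fit them; Ising-type repeat-protein models are out of scope.
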