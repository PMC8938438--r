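---
title: "Models and methods behind perturbMPRA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind perturbMPRA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

perturbMPRA implements a complete perturbation lentiMPRA workflow for a
differentiation time course: selecting which motif instances to perturb,
constructing the oligo library, assembling barcode counts, estimating
transcription rates, calling functional regulatory sites (FRSs), and testing
motif pairs for non-additive cooperation. This vignette explains the models,
the tunable parameters and the design choices; the README shows a worked
run.

## The design-selection ILP

The design universe is a tripartite graph: region nodes (candidate
171-bp regulatory sequences), motif nodes (TF binding motifs found in those
regions), and property nodes (temporal chromatin/expression patterns,
pathway membership, curated neural factors). Instance edges connect a motif
to every region it occurs in and carry a low-confidence flag; property edges
tie regions and motifs to the biology they represent.

Selection is a 0/1 program over region indicators $\theta_r$, motif
indicators $\theta_t$ and instance-edge indicators $e_{t,r}$, minimizing

$$\sum_r \theta_r + 3 \sum_{(t,r) \in E} e_{t,r}$$

(one wild-type oligo per region plus three perturbation designs per chosen
instance), subject to the constraint families enforced by `build_ilp()`:
property coverage by at least 12 motifs and $\min(17, \deg)$ regions; at
least $\min(3, \deg)$ chosen motifs per chosen region and $\min(20, \deg)$
chosen regions per chosen motif; edge-endpoint coupling; at most two motifs
per TF group with every hand-picked TF represented; at least 40% of regions
used; selected edges outnumbering selected low-confidence edges five-fold;
and a high-degree motif share of at least 60% (motifs with five or more
candidate regions, measured on the input graph, not the selection).

Two implementation notes. First, the printed program couples edges only from
below ($e \ge \theta_t + \theta_r - 1$), relying on the positive objective
cost to pin $e$ at its minimum; the model and the checker additionally
enforce $e \le \theta_t$ and $e \le \theta_r$ so that feasibility is
solver-independent. Second, the per-region bound is the equation's
$\min(3, \deg)$ even though the accompanying narrative mentions "at least
two different perturbations"; the bound is a `design_params()` field.

`solve_design()` hands the model to a branch-and-bound MILP solver (HiGHS,
via the bundled scipy front end) and reports proven optimality or the
remaining gap; an exhaustive pure-R backend covers small graphs and serves
as the oracle in the test suite. `check_constraints()` recomputes every
family from the raw edge lists and the selection alone — never from solver
state — and reports the worst-case margin per family. Whether the
low-confidence budget counts selected edges only (it does here) follows the
summation indices of the printed constraint, which run over chosen edges.

## Library construction

Per selected region the library holds the wild type (WT), a full-sequence
nucleotide shuffle (SCRAM, the negative control; mononucleotide shuffling,
matching "shuffle all nucleotides"), and three random-window controls
(RAND) in which a 12-bp window — the median motif width, a `sim_config()`
field — at a random position is perturbed by each method. Per selected
instance there are three perturbed sequences (PERT):

* methods 1 and 2 replace the hit window with the length-matched prefix of
  one of two fixed "non-motif" sequences;
* method 3 shuffles the window's own nucleotides (seeded; redrawn up to 100
  times if the shuffle reproduces the wild type, then the best Hamming
  distance is kept).

The non-motif sequences are derived by `derive_nonmotif_sequences()`:
1000 dinucleotide-frequency-matched candidates of maximal motif length are
screened through the motif scanner at $p < 10^{-4}$ under two embedding
strategies — between the hit's 3-bp wild-type flanks and substituted into
the full region — and the two candidates with the lowest median hit-count
rank across strategies win (ties break to the lower candidate index). The
screening retains both strategies for ranking, but the library embeds the
replacement directly in context, since the synthesized oligo is the full
region. For minus-strand hits the reverse complement of the prefix is
inserted so the disrupted unit is the motif-bearing strand. Hit
multiplicity follows the array rules: one hit (`hit1`) is perturbed as is;
an exactly-duplicated plus/minus pair (`hit2`) is perturbed once on the plus
strand; two distinct hits (`hit2diff`) are perturbed singly and jointly
(overlapping joint windows are applied left-to-right and such pairs are
excluded from interaction analysis later); three or more hits of a motif
are discarded and logged.

The bundled scanner is deliberately minimal: log-odds scores against a
uniform background with exact p-values from the standard dynamic-programming
convolution, both strands, 0-based half-open coordinates. It stands behind
a pluggable closure interface (`make_pwm_scanner()`) so a heavier scanner
can be substituted.

## Barcode association and counts

A barcode is confidently assigned when its top sequence holds at least 3
supporting UMIs and at least 80% of the barcode's UMIs (both inclusive;
exact ties never assign). Counting requires a perfect barcode match with no
error correction, and classifies counted barcodes as assigned, ambiguous,
or unobserved in the association run. Within each (timepoint, replicate)
pair, only barcodes with positive counts in both the DNA and RNA library of
that pair are retained — the pair-wise reading of "at least two
corresponding libraries"; the association threshold is a parameter, so the
99% robustness variant is a setting rather than a separate mode.

## Quantification

Transcription rates follow the nested-GLM scheme: a gamma GLM with log link
estimates the latent construct abundance from the DNA counts
(`~ timepoint + replicate + barcode`), and a negative-binomial GLM with log
link estimates the transcription rate alpha from the RNA counts
(`~ timepoint + replicate`), with the latent DNA estimates and the RNA
library size factors entering as fixed offsets. Size factors are
upper-quartile per library, rescaled to unit geometric mean, computed once
on the full dataset and reused by every analysis. NB dispersion is
estimated per fit by maximum likelihood (`MASS::glm.nb`), with reduced
models refit at the full model's dispersion so nested likelihood-ratio
tests are well defined; a fit whose dispersion estimation fails falls back
to a near-Poisson dispersion and a ratio-based alpha, and is flagged, never
silent. The chi-square reference is asymptotic; fits on fewer than 10
barcodes are worth treating with caution.

Three comparative designs are exposed through `lrt_compare()`: per-timepoint
perturbed-vs-wild-type (`~ sequence` against `~ 1`, corrected jointly across
all timepoints of an analysis), temporal perturbed-vs-wild-type
(`~ timepoint * sequence` against `~ timepoint`), and temporal-vs-control,
in which a joint model over all scrambled sequences supplies per-timepoint
coefficients that are applied as RNA-model offsets (the coefficients are
transcription-side quantities, so they belong in the RNA model) before
testing `~ timepoint` against `~ 1`. Activity classification uses the MAD
z-test: alphas are median/MAD-normalized against the scrambled null
(MAD scaled by 1.4826 for normal consistency) with a one-sided upper-tail
normal p-value — "more active than the null" — and a two-sided option; the
normal tail is used throughout, with an empirical tail left as an option.
The closed-form RNA/DNA ratio (per-barcode normalized ratios averaged per
sequence, pseudocount 1 on the numerator and denominator counts, per-sample
median normalization, cross-replicate averaging) is retained as a
model-free cross-check; alpha and ratio are rank-concordant on simulated
data.

## FRS calling and categorization

Four filters, evaluated per instance and perturbation method at FDR 0.05:
(1) perturbed differs from wild type in at least one timepoint; (2) the
perturbed time course differs from wild type; (3) the wild type beats the
scrambled null at **all** timepoints or the perturbed sequence at **at
least one**; (4) the perturbed or wild-type time course deviates from the
scrambled-control behaviour. The consensus FRS set keeps instances passing
all four filters in method 3 and in method 1 or 2 with a concordant
direction of effect; duplicates with identical perturbed coordinates under
different PWMs resolve to the lowest temporal FDR.

Direction is the sign of the temporal-model log fold change — a single
well-defined summary even when different timepoints reach significance —
with a per-timepoint mode available; instances with both significantly
increased and decreased timepoints are labeled mixed and kept out of
sub-categorization rather than forced into a main category. Activating
sites are *essential* when the perturbed sequence is indistinguishable from
the controls (temporal FDR above threshold **or** the MAD test
non-significant at every timepoint — the printed OR, with an AND switch
since the intended connective is unknowable), else *contributing*;
dampening sites are *silencing* when the wild type is indistinguishable
from controls under the same rule, else *inhibiting*.

Activation dynamics of activators fits ordinary least squares of the
absolute effect on the wild-type level, `delta ~ wt`, across timepoints.
The implied fold-change curve is $FC = (1-b) - a/\mathrm{WT}$ for fitted
intercept $a$ and slope $b$; published descriptions of this curve swap the
two constants relative to the fitted intercept/slope, and the fitted values
are authoritative here.

## Motif-pair interactions

The log-additive (billboard) null says the double perturbation equals the
product of the single fold changes. `test_interaction()` fits the RNA GLM
with binary covariates for the two perturbations, full model
`~ timepoint + pert1 * pert2` against reduced
`~ timepoint + pert1 + pert2`, 1-df LRT; the interaction coefficient
$\gamma$ is reported on the model's natural-log scale (the model's native
scale — worth noting because the magnitude threshold of 0.5 is applied to
$|\gamma|$). `classify_pairs()` applies, in order: overlap exclusion
(interval intersection of the perturbed windows), a functionality gate
(at least one single perturbation passes the four-filter scheme), and a
consistency gate (the same significant/non-significant label in method 3
and in method 1 or 2, on the label only; sign consistency is a strict
mode). Survivors are additive or interacting.

## The synthetic-data generator

The generator exists so that every stage is testable with planted ground
truth and no downloads. `generate_graph()` builds graphs that are feasible
by construction: TF groups capped at two motifs, properties wired to at
least 12 motifs and 17 regions, about 80% of motifs given region-degree 5
or more, and a low-confidence share of about 10%, so the all-nodes
selection satisfies every family. At the study's dimensions
(1547 x 4393 x 68) the default degree distributions yield a total edge
count near 10^5^, matching the scale the design was built for.

Counts follow the assay's generative hierarchy. Each barcode draws a latent
construct abundance once — a rounded gamma (`dna_shape`, `dna_scale`) times
a lognormal per-barcode factor, the integration copy number — and each
sample observes a Poisson draw around it (sequencing counting noise). RNA
counts are negative-binomial with mean alpha x latent abundance x library
size factor: transcription happens from the integrated construct, and the
DNA reads measure it. This matters: simulating RNA from the realized DNA
draw instead couples the measurement noise into the model's offset and
makes the nested-GLM tests conservative, while attributing all gamma
variability to per-sample measurement noise makes them anti-conservative;
the hierarchy above is the model-consistent reading, and the per-timepoint
and interaction tests hold close to their nominal 5% size under it.

Planted truth assigns each region an archetype: active regions draw a
temporal profile from the early-peak / late-peak / transient basis and an
amplitude of 1.5-2.5 natural-log units over the scrambled baseline
(`scram_alpha` 0.15); blocked regions sit flat at baseline. Flat profiles
are deliberately reserved for blocked regions: the assayed regions enter
the design because they are temporally active, and a flat active region
could never pass the temporal filter — its shape equals the control shape
by construction. Instance categories respect region archetypes (essential
and contributing activators and inhibiting dampeners in active regions;
silencing dampeners in blocked regions, where perturbation reveals an
active non-flat profile), with per-timepoint effects scaled by the region
profile; essential effects drop the perturbed sequence exactly to
baseline, contributing effects are capped below the region amplitude so
activity stays above baseline. Pairs carry an interaction coefficient, zero
for additive pairs and 0.8-1.5 in magnitude otherwise.

What the generator does not emulate: chromatin or integration-site context,
read-level errors and barcode collisions beyond the ambiguous/shallow
association classes, motif families with correlated PWMs, and effect-size
distributions estimated from real data. Passing tests therefore demonstrate
the pipeline's statistical machinery and bookkeeping on data that obey the
stated model, not performance on a real library.

## Problem sizes and numerical choices

The bundled analyses run at desk scale: the design run uses a
300 x 60 x 8 graph (about 1200 candidate instances, solved to proven
optimality in seconds); calibration uses 500 null per-timepoint tests and
300 null interaction tests at the default depth of 30 barcodes per
sequence; recovery uses 18 regions at 50 barcodes with planted effects of
at least 1 natural-log unit, and the pair bank 150 pairs at 12 barcodes.
The demo pipeline (16 regions, 14 motifs, 15 barcodes) completes in a few
minutes on one CPU. Zero DNA counts are tolerated throughout (the gamma fit
floors counts at 0.5; the pair-presence filter removes zero rows before
analysis); MAD z-tests refuse degenerate nulls (zero MAD, or fewer than 10
controls) rather than returning fragile values; shuffles that reproduce the
wild type are redrawn; and every stage draws from its own RNG stream
derived from the master seed, so stages can be re-run independently with
identical results.

## Known limitations

The chi-square LRT is slightly liberal at very low barcode counts; the
plug-in of latent DNA estimates (rather than a joint DNA-RNA likelihood)
contributes a small additional inflation, shrinking with depth. The MAD
z-test assumes an approximately normal null on the alpha scale. The
per-timepoint comparative model inherits the barcode-sequence confounding
of the printed designs (each barcode belongs to one sequence), so the
barcode term there is absorbed rather than identified. Only pairwise
interactions are modeled; constructs perturbing three or more sites are
built by the library module but not tested.
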