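---
title: "Calibrated hit calling for TMT proximity-labelling secretomes"
author: "secretoscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated hit calling for TMT proximity-labelling secretomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretoscore)
```

## The problem

Proximity labelling with an ER-targeted promiscuous biotin ligase
biotinylates proteins trafficking through the secretory pathway; after
streptavidin capture and multiplexed TMT quantification, each protein
carries reporter intensities across case (ligase-expressing) and control
channels. Calling secretome "hits" from such data is harder than a plain
two-group comparison because streptavidin enrichment has a strong
non-specific bead background, endogenously biotinylated carboxylases are
abundant in *both* genotypes, and channel loading differs. secretoscore
implements two complementary hit-calling paths for a case/control channel
design, plus supporting modules for annotation summaries, peptide-topology
mapping, and synthetic-data generation.

## The enrichment-score path

For $n_c$ case and $n_k$ control channels, every pairwise ratio
$r_{ij} = I_{\text{case}_i} / I_{\text{control}_j}$ is formed on the linear
scale after median normalization — $3 \times 3$ channels give nine ratio
datasets per protein. Cutoffs for "enriched" ratios are calibrated from two
user-supplied control lists: positive controls (PC; proteins known to be
secreted or to traffic through the ER) and negative controls (NC; nuclear,
transcription-factor and cytoskeletal proteins, purged of anything also
annotated secreted/receptor/ER). For a candidate cutoff $r$ the
false-positive rate is the likelihood ratio of upper tails

$$\mathrm{FPR}(r) =
  \frac{\#\{\mathrm{NC} \ge r\}/N_{\mathrm{NC}}}
       {\#\{\mathrm{PC} \ge r\}/N_{\mathrm{PC}}},$$

and the selected cutoff $r^*$ is the smallest observed ratio whose whole
suffix of candidates sits at or below the target (default 0.1, i.e. a
passing protein is ten times more likely to behave like a positive than a
negative control). The enrichment score (ES) of a protein is the number of
its ratios at or above their column cutoffs, an integer $0..9$ in a
3-vs-3 design; hits are called at ES $\ge 5$.

Design choices worth stating explicitly:

* **Tail reading of "ratio range".** The FPR is computed over upper tails
  ($\ge r$), the direction of enrichment. A binned (local density) reading
  was considered and rejected: with control lists of tens to hundreds of
  proteins, per-bin counts are unstable and the resulting curve is not
  monotone enough to support a cutoff.
* **Per-column calibration.** Each ratio column is calibrated
  independently (nine calibrations), treating the columns as distinct
  datasets; `calibrate_cutoffs(global = TRUE)` pools them when a single
  cutoff is preferred.
* **Inclusive boundary.** Ties at the cutoff pass (`ratio >= cutoff`), and
  ES $\ge$ `min_es` is a hit — boundaries are inclusive on both levels.
* **Suffix rule for non-monotone curves.** Empirical FPR curves can dip
  below the target and rise again; selecting inside such a dip would admit
  a ratio range where negatives outnumber positives further up. The
  selected cutoff must dominate every larger candidate.
* **Missing ratios** (missing parent intensity, or a zero denominator)
  never count towards ES and are never imputed; they reduce the evaluable
  ratio count, and a protein with fewer than `min_es` evaluable ratios can
  never be a hit (`es_attainable` flags these).
* **Controls are not held out.** PC/NC proteins are scored like any other
  protein: the lists are annotation-derived, not a training split.

## The moderated-test path

The second path is a per-protein empirical-Bayes moderated two-sample
t-test on log2 intensities. Pooled within-group variances $s_g^2$ with
residual df $d_g$ are shrunk towards a scaled inverse-chi-square prior
$(d_0, s_0^2)$ fitted across proteins by moment matching on
$\log s_g^2$ (digamma/trigamma), giving

$$\tilde{s}_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
  \tilde{t}_g = \frac{\widehat{\mathrm{lfc}}_g}
  {\sqrt{\tilde{s}_g^2 (1/n_{c,g} + 1/n_{k,g})}}
  \sim t_{d_g + d_0},$$

with Benjamini–Hochberg adjustment across proteins and an enrichment call
at adjusted $p < 0.05$ **and** $\log_2 \mathrm{FC} > 1$, both strict.
Numerical conventions: when the moment fit finds no excess dispersion the
prior df is infinite and the total df is capped at $10^6$ for the p-value;
exactly-equal variances short-circuit to that common value; zero variances
are floored at $10^{-3} \times$ the smallest positive variance during
prior fitting only; proteins quantified in only one group are excluded,
never imputed. The test runs on log2 intensities with the full
case/control design (not on the pairwise ratios): intensities keep the
per-channel replicate structure the variance model assumes, whereas the
nine ratios are mutually dependent. `limma::squeezeVar` is used in the
test suite as an independent cross-check of the prior fit.

## Annotation summaries and topology mapping

`fraction_flagged()` reports secreted and SignalP-or-TMH fractions
(the inclusive OR of the signal-peptide and transmembrane-helix flags;
unannotated IDs stay in the denominator), `es_annotation_profile()`
stratifies the SignalP/TMH rate by ES level (empty strata are undefined,
not zero), `set_overlaps()` gives exact Venn/upset region counts, and
`tissue_enrichment()` tests hit lists against user-supplied tissue-specific
panels with the upper-tail hypergeometric test and BH adjustment. The
universe is a required input: results depend on it strongly, and no
default (all detected vs all annotated) is imposed. ID matching is exact
and case-sensitive; translation between ID namespaces is out of scope, as
is running the annotation predictors themselves — their outputs are
consumed as flag tables.

For ectodomain shedding, `map_peptides()` performs exact substring search
of identified peptides against the full-length sequence (all occurrences,
overlapping included; I/L collapsing available but off by default),
`classify_topology()` labels each unambiguous peptide with every topology
segment it intersects, and `call_shedding()` reports whether all peptides
are confined to extracellular topology and bounds the cleavage site
between the most terminal extracellular peptide and the transmembrane
segment (mirrored for proteins whose ectodomain is C-terminal). All
coordinates are 1-based inclusive. Ambiguous peptides never contribute to
bounds; signal-peptide segments are ignored when orienting. If the most
terminal peptide abuts the TM the bound is empty and reported absent
rather than inverted. `tryptic_digest()` cleaves after K/R, by default not
before proline, with an allow-P toggle and missed-cleavage enumeration.

## What the synthetic generator does and does not emulate

`simulate_experiment()` draws log2 base abundances $\sim N(20, 2)$
(typical reporter-intensity scale), adds a per-protein enrichment effect
$\sim N(2, 0.5)$ to case channels for the true-enriched class (10% of
proteins by default, floor rounding; defaults chosen once as the study
conditions of the validation suite), per-channel loading shifts
$\sim N(0, 0.2)$, per-cell noise $\sim N(0, 0.3)$, and 5% missingness
completely at random. Five endogenous-biotin proteins sit 4 log2 units
above the base scale, equal in both groups. The negative class (10%) is
unenriched background that doubles as the NC calibration list; the
true-enriched class doubles as the PC list, flagged SignalP-positive at
rate 0.9 against a background flag rate of 0.05. Draw blocks use fixed
seed offsets, so enlarging the experiment leaves earlier proteins' values
unchanged.

Deliberately not emulated: reporter-ion interference and compression,
peptide-to-protein rollup, informative (intensity-dependent) missingness,
correlated protein abundances, and multi-plex batch structure. Passing
recovery tests on this generator therefore demonstrates that the
statistics behave as designed under their own assumptions — not that real
spectra meeting those assumptions is guaranteed.

`simulate_shedding_case()` draws a random sequence (amino-acid
frequencies near natural composition, so K/R density gives realistic
tryptic fragment lengths), requires the topology layout to tile the
sequence, digests in silico, and emits only fragments of length $\ge 5$
(shorter fragments are rarely unique or confidently identified) lying
wholly within extracellular segments and occurring exactly once in the
sequence, re-drawing the sequence when needed.

## Validation problem sizes

The shipped test-suite checks run at sizes chosen to make their
conclusions meaningful while staying quick: oracle-equivalence loops use
dozens of randomized instances of up to 50 control proteins, 100
p-values, or 200-residue sequences; ES-path recovery uses 20 replicate
experiments of 1000 proteins (recall of true-enriched $\ge 0.9$ at
negative-control false-hit rate $\le 0.1$); the null calibration of the
moderated test uses 50 replicates of 2000 proteins (type-I error within
[0.03, 0.07]); prior recovery uses 5000 simulated variances; the shedding
round trip uses 100 random topologies. `scripts/acceptance.R` recomputes
the headline quantities (boundary ES values; achieved FPR and PC/NC
discrimination of a 500+500 calibration) from scratch at any seed.

## Known limitations

* Calibration quality is bounded by the control lists; small or
  contaminated NC lists make the empirical FPR curve coarse, and the
  suffix rule then tends to select conservative (high) cutoffs.
* The moderated test assumes a common variance model per protein across
  channels; array/channel weights, abundance-dependent variance trends
  and multi-factor designs are not implemented.
* The pipeline operates at protein level throughout; upstream search,
  PSM validation and rollup are out of scope.
* `run_pipeline()` analyses the synthetic generator's output; applying
  the stages to real tables is done with the per-stage functions
  (`read_protein_table()` onwards), which share all code with the
  pipeline.
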