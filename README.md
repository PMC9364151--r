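# secretoscore

Hit calling for quantitative secretome proteomics from proximity
labelling. An ER-targeted promiscuous biotin ligase biotinylates proteins
trafficking through the secretory pathway; after streptavidin capture,
TMT multiplexing quantifies each protein across case (ligase-expressing)
and control channels. The statistical difficulty is the background:
non-specific bead binders dominate the input, and endogenously
biotinylated carboxylases are abundant in both genotypes, so a plain
fold-change ranking mis-calls both.

`secretoscore` is an R package for this design. For proteomicists and
computational biologists analysing case/control TMT tables, it provides:

* **FPR-calibrated enrichment scoring (ES).** All pairwise case/control
  ratios are formed (nine per protein in a 3-vs-3 design). A cutoff per
  ratio column is calibrated from positive-control (secreted) and
  negative-control (nuclear/cytoskeletal) protein lists via the
  tail-probability ratio
  `FPR(r) = [#NC >= r / N_NC] / [#PC >= r / N_PC]`, selecting the smallest
  cutoff whose whole upper range stays at or below the target FPR
  (default 0.1 — a passing protein is ten times more likely to behave
  like a positive than a negative control). A protein's ES is the number
  of its ratios passing their cutoffs (0–9); hits are called at ES ≥ 5.
* **A moderated-test path.** Empirical-Bayes moderated t-test on log2
  intensities (inverse-chi-square variance prior fitted by
  digamma/trigamma moment matching), Benjamini–Hochberg adjustment, and
  an enrichment call at adjusted p < 0.05 and log2FC > 1.
* **Annotation summaries** (secreted / SignalP-or-TMH fractions,
  ES-stratified annotation rates, exact Venn/upset region counts,
  hypergeometric tissue-panel enrichment).
* **Ectodomain-shedding inference**: exact peptide-to-sequence mapping,
  topology classification (extracellular / TM / cytoplasmic, 1-based
  inclusive coordinates), cleavage-site bounding from the most terminal
  peptides, and in-silico tryptic digestion.
* **A seeded synthetic-data generator** reproducing the statistical
  structure above with known ground truth, used throughout the test
  suite.

## Worked example

```r
library(secretoscore)

sim  <- simulate_experiment(sim_config(n_proteins = 500, seed = 42))
norm <- median_normalize(sim$table)
rm   <- compute_ratio_matrix(norm)          # 9 ratio columns
ctl  <- label_controls(rownames(rm$ratios),
                       sim$control_lists$pc, sim$control_lists$nc)
calib <- calibrate_cutoffs(rm, ctl, target_fpr = 0.1)
head(calib, 3)
#>                   column   cutoff achieved_fpr
#> 1 ratio_case_1_control_1 1.317906   0.09302326
#> 2 ratio_case_1_control_2 1.135868   0.09302326
#> 3 ratio_case_1_control_3 1.358199   0.08888889
```

Each ratio column gets its own TMT-ratio cutoff; the achieved FPR is the
tail-probability ratio actually reached at that cutoff, always at or
below the 0.1 target.

```r
es <- call_hits(enrichment_score(rm, calib), min_es = 5)
head(es, 4)
#>   protein_id es n_evaluable  hit es_attainable
#> 1     P00001  9           9 TRUE          TRUE
#> 2     P00002  9           9 TRUE          TRUE
#> 4     P00004  9           9 TRUE          TRUE
#> 6     P00006  9           9 TRUE          TRUE
sum(es$hit)
#> [1] 52

mt <- moderated_test(norm)                  # the second hit path
sum(mt$enriched)
#> [1] 48
compare_hit_paths(es$protein_id[es$hit],
                  mt$protein_id[mt$enriched])$jaccard
#> [1] 0.8181818
```

The top proteins pass all nine ratio cutoffs (ES 9, highest confidence);
52 of the 500 proteins reach ES ≥ 5 — this run planted 50 truly enriched
proteins — and the two hit paths agree closely (Jaccard 0.82). The whole
chain, simulation through both hit paths plus a machine-readable report,
is also available as one call:

```r
report <- run_pipeline(run_config(seed = 42,
                                  sim = list(n_proteins = 500)),
                       out_dir = "run1/")
```

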