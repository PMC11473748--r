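# guardABA

Analysis toolkit for time-course transcriptomes of the abscisic acid (ABA)
response in *Brassica napus* guard cells — the paired stomatal cells that
close the leaf pore under drought. A typical study treats purified
guard-cell protoplasts with ABA for 0, 15 and 60 minutes in three replicate
batches, sequences each sample, and asks which genes respond, how fast, how
paralog families of this polyploid diverge in their response, and whether
known regulatory interactions and promoter binding sites explain the
observed regulation. guardABA implements that entire analysis as tested,
reusable R functions, together with a ground-truthed synthetic-study
generator so every stage has a parameter-recovery benchmark.

## The models at the core

**Differential expression.** Counts are negative binomial,
K<sub>ij</sub> ~ NB(q<sub>ij</sub>, α<sub>i</sub>) with
Var = q + αq², and a log-linear mean

&nbsp;&nbsp;log q<sub>ij</sub> = log s<sub>j</sub> + x<sub>j</sub>ᵀβ<sub>i</sub>,

where s<sub>j</sub> are median-of-ratios size factors and x<sub>j</sub>
encodes treatment time (15, 60 min vs mock) and replicate batch. Dispersions
are estimated per gene by Cox-Reid adjusted profile likelihood, regularized
toward a parametric trend α(μ) = a₁/μ + a₀ by a posterior-mode
empirical-Bayes shrinkage; coefficients are tested with Wald z = β̂/SE,
and multiplicity is handled by Benjamini-Hochberg with independent filtering
on mean expression (FDR 0.05 by default).

**Downstream stages.**

* temporal classification of each gene from its 15/60-minute calls
  (transient / delayed / sustained / opposite / unchanged);
* ortholog-family divergence: the sample SD of member log2 fold changes,
  families flagged divergent above a threshold (default 1.6);
* enrichment statistics: one-sided hypergeometric tests, chi-square and
  G tests, Cramér's V = √(χ²/N), odds ratios with Haldane-Anscombe
  correction, and pathway projection through the ortholog map;
* signed-network consistency: predicted target direction =
  sign(TF direction) × sign(edge), summarized as the odds ratio of a
  predicted-vs-observed 2×2 table, stratified by source-study size
  (low-throughput = studies reporting < 50 interactions);
* promoter analysis: IUPAC consensus scanning on both strands, presence
  enrichment among regulated genes, and a family-fixed-effects regression
  log2FC = β<sub>BSS</sub>·n<sub>BSS</sub> + β<sub>Orth</sub>·O with an
  F test for β<sub>BSS</sub> = 0.

See `vignettes/guard-cell-aba-methods.Rmd` for assumptions, parameter
choices and limitations.

## Worked example

```r
library(guardABA)

cfg   <- sim_config(n_genes = 500, frac_de60 = 0.2, n_tfs = 10, n_edges = 100)
study <- simulate_study(cfg, seed = 42)     # counts + truth + annotations

de    <- run_de(study$counts)               # size factors, dispersions, Wald
calls <- classify_temporal(de$de15, de$de60)
fs    <- family_lfc_stats(build_families(study$orthologs, de$de60$gene_id),
                          de$de60, sd_threshold = 1.6)
ev    <- evaluate_edges(filter_by_study_size(study$interactions, 50),
                        de$de60, study$orthologs)
consistency_table(ev)
```

This prints (among other things):

```
significant at 15 min: 3
significant at 60 min: 81

  delayed_down     delayed_up sustained_down   transient_up      unchanged
            31             48              2              1            418
divergent families: 6 of 159
low-throughput consistency OR: 75.36   Fisher p: 5.8e-74
power among truly DE at 60 min: 0.929
```

Reading: at this depth and effect size the 60-minute contrast recovers 93%
of the truly responsive genes while the 15-minute contrast, with half the
effect size, finds only a handful — so most calls are "delayed", as in real
guard-cell data. Six families exceed the 1.6 divergence threshold, and the
low-throughput network stratum (simulated at fidelity 0.9) yields a large
direction-consistency odds ratio.

A whole run can also be driven by a config object (`pipeline_config()` +
`run_all()`, writing stage TSVs and a `report.json`) or from the shell via
`inst/scripts/guardaba.R simulate|run`.

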