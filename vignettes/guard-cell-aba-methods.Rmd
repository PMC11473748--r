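---
title: "Models and methods behind guardABA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind guardABA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guardABA)
```

guardABA analyses time-course RNA-seq of the abscisic acid (ABA) response in
*Brassica napus* guard cells: a 3 x 3 design (mock, 15 and 60 minutes of ABA,
each in three replicate batches), with downstream stages that interpret the
differential-expression calls through ortholog families, gene sets, a signed
regulatory network, and promoter binding sites. This vignette explains the
models, the tunable parameters, the numerical choices, and what the synthetic
benchmark does and does not establish.

## The count model

Read counts $K_{ij}$ for gene $i$ in sample $j$ are modelled as negative
binomial with mean $q_{ij}$ and gene dispersion $\alpha_i$, so that
$\mathrm{Var}(K_{ij}) = q_{ij} + \alpha_i q_{ij}^2$. The mean combines a
per-sample normalization $s_j$ with condition and replicate effects through a
log link:

$$\log q_{ij} = \log s_j + x_j^\top \beta_i ,$$

where $x_j$ encodes the sample's treatment time and replicate batch. A
six-indicator encoding of this design (three time indicators plus three
replicate indicators) is rank-deficient, since each block sums to one; we fit
the equivalent full-rank parameterization — intercept, `time15`, `time60`,
`rep2`, `rep3` — and document the affine map back to the redundant effects on
the design matrix object. The identity-link reading of the mean model is
rejected because it admits negative means; the log link also makes the
replicate batch effects multiplicative on the mean, which is how
`batch_correct_counts()` removes them for visualization.

Mock samples from all isolation batches form a single reference level: the
contrasts `time15` and `time60` are each "ABA versus mock". `nb_pmf()`
exposes the exact pmf (evaluated in log space) used throughout.

### Normalization

`estimate_size_factors()` uses median-of-ratios against a geometric-mean
reference gene profile, restricted to genes observed in every sample, and
rescales the factors to geometric mean one so the intercept keeps the scale
of the data. No external spike-in or length correction is attempted; within
the model, multiplying one sample's counts by a constant moves only its size
factor (a tested invariant).

### Dispersion estimation

With three replicates per condition, gene-wise dispersion likelihoods are
wide, so `fit_dispersions()` proceeds in three stages:

1. **Gene-wise estimates.** For each gene the Cox-Reid adjusted profile
   likelihood of $\alpha$ (means refitted and the profile re-maximized until
   stable; a coarse grid brackets the maximum before local refinement over
   $\log\alpha \in [\log 10^{-8}, \log 30]$).
2. **Trend.** A parametric trend $\alpha(\mu) = a_1/\mu + a_0$ fitted by
   iterated gamma-family regression of the gene-wise estimates on $1/\mu$,
   excluding genes whose ratio to the current fit leaves $[10^{-4}, 15]$.
3. **Shrinkage.** The final dispersion is the posterior mode under a
   log-normal prior centred on the trend. The likelihood sampling variance
   on the log scale is approximated by $\psi_1((m - p)/2)$ (trigamma; $m$
   samples, $p$ coefficients), and the prior variance is the robust (MAD)
   spread of log residuals about the trend in excess of that, floored at
   0.25. Genes more than two residual standard deviations *above* the trend
   keep their gene-wise estimate (overdispersion outliers are not shrunk
   toward optimism); the gene-wise spread below the trend is dominated by
   estimates collapsing toward zero, which the posterior mode pulls back to
   the trend using each gene's actual likelihood curvature.

The robust prior width matters: a naive variance over log residuals is
exploded by collapsed estimates, weakening shrinkage exactly where it is
needed and inflating the false-positive rate several-fold.

### Testing and multiplicity

`wald_test()` fits the per-gene GLM by iteratively reweighted least squares
(weights $\mu/(1+\alpha\mu)$) and reports $z = \hat\beta/\mathrm{SE}$ against
the standard normal, with fold changes in log2 units. `adjust_pvalues()`
applies Benjamini-Hochberg after independent filtering on the mean of
normalized counts: candidate quantile thresholds 0-95% in 1% steps, choosing
the threshold that maximizes rejections at the target FDR (default 0.05),
ties broken toward the smaller threshold so fewer genes are discarded.
Filtered genes carry `NA` adjusted p-values and are treated as
non-significant downstream, mirroring the `NA` entries the study's printed
family table shows for filtered members.

### Calibration in small samples

A 3 vs 3 NB Wald test is known to be slightly anti-conservative. On a fully
null simulated study (5,000 genes, log-normal depth, batch effects,
dispersion scatter) about 6.3% of raw p-values fall below 0.05; running
DESeq2 on the identical counts gives the same 6.3% with per-gene z-statistics
correlating at 0.9999 with ours, so this is the intrinsic finite-sample
behaviour of the method rather than an implementation artifact. BH with
independent filtering remains strongly conservative under the null (well
under 1% of genes rejected at FDR 0.05). A strict Kolmogorov-Smirnov
uniformity test at n = 5,000 sits exactly at this noise floor and can reject
either implementation depending on the seed; the package's acceptance suite
runs it anyway and we report the outcome honestly rather than weakening the
check.

## Temporal classification

`classify_temporal()` calls a direction at each time point (sign of the LFC
when the adjusted p is below the threshold, otherwise `ns`) and maps the pair
onto eight categories (`transient_*`, `delayed_*`, `sustained_*`,
`opposite`, `unchanged`). "Transient" is defined by significance — significant
at 15 minutes and not at 60 — rather than by comparing magnitudes, because
that is the operational rule the printed transient-gene table follows and the
only one testable from printed FDR pairs. `opposite` is retained although
real data showed none. `lfc_correlation()` reports the unadjusted $R^2$ of
the ordinary regression of 60-minute on 15-minute LFCs.

## Ortholog families and divergence

*B. napus* genes sharing a closest *A. thaliana* ortholog are treated as a
paralog family descended from one ancestral gene. `family_lfc_stats()`
summarizes each family by the sample standard deviation (denominator
$n - 1$) of member LFCs at 60 minutes, over members with a finite LFC;
members filtered out of testing still contribute their estimated fold
change. The sample SD is deliberate: for the published four-member NAC
transcription-factor family with member LFCs (3.603, 3.304, 0.130, 3.179)
the sample SD is 1.626 — just above the 1.6 divergence threshold that family
was selected by — while the population SD (1.408) would miss it. The
threshold (default 1.6, strict inequality) is configurable.

## Enrichment statistics

`hypergeom_test()` is the one-sided upper-tail hypergeometric probability,
computed via the log-space tail so that p-values far below machine epsilon
of 1 remain accurate; a brute-force summation oracle checks it exactly on
small universes. `contingency_stats()` reports the chi-square statistic
(no continuity correction), the G statistic $2\sum O\log(O/E)$ with
$0\log 0 = 0$, Cramér's V $= \sqrt{\chi^2/N}$ for 2 x 2 tables, Fisher's
exact p, and the odds ratio $ad/bc$ with a Haldane-Anscombe +0.5 on all
cells only when some cell is zero (flagged). The default universe is all
annotated genes (the published arithmetic uses the 101,040-gene annotation),
switchable to an expressed-only universe. The printed hypergeometric
p-values of the modelled study do not reproduce from its printed margins
under the standard upper-tail test (the variant or universe used is
unstated); the printed Cramér's V values do reproduce, and those are what
the package asserts.

## Regulatory-network consistency

`evaluate_edges()` expands each signed *A. thaliana* TF-to-target edge to
every B. napus TF-ortholog x target-ortholog pair, so one conserved edge
with $k$ ortholog pairs contributes $k$ rows — the mapped network is the
unit of analysis, matching how the interactions were projected onto the
polyploid. The predicted target direction is sign(TF direction) x sign(edge)
when the TF is significantly regulated and the edge sign is known; edges
with unknown sign are excluded from the 2 x 2 consistency table but kept in
the SIF/GraphML exports. Conflicting records of the same pair from different
studies are evaluated independently. `filter_by_study_size()` keeps edges
whose source study reports strictly fewer than 50 interactions
("low-throughput"), the stratum in which direction consistency is expected
to be high.

## Promoter binding sites

`scan_motif()` counts positions whose bases all fall in the IUPAC classes of
the consensus; overlaps count, `N` in the sequence matches nothing, and by
default both strands are scanned (the count is the forward scan plus the
scan of the reverse complement). Promoters default to the 3'-most 1,000
bases of the supplied sequence — the region definition of the original scan
is unstated, so this is a documented package choice, configurable via
`extract_promoters()`. Enrichment among regulated genes uses presence
(at least one hit), tested hypergeometrically against non-changing genes and
BH-adjusted across motifs, separately for up- and down-regulated sets; the
regression below uses the raw count, matching the two distinct questions
(is the site there? how many copies?).

`fit_bss_glm()` fits

$$\log_2(\text{fold change}_i) = \beta_{\mathrm{BSS}}\, n_{i,\mathrm{BSS}}
  + \beta_{\mathrm{Orth}}\, O_i ,$$

with per-family fixed intercepts $\beta_{\mathrm{Orth}}$ absorbing shared
ancestry, by within-family demeaning of response and covariate
(Frisch-Waugh) followed by least squares — genes without a family form
singleton families whose demeaned contribution is zero. The F test for
$\beta_{\mathrm{BSS}} = 0$ uses $N - M - 1$ denominator degrees of freedom
($M$ families including singletons) and is identical to the explicit
dummy-variable regression, a tested exact equivalence. The fit refuses
(with an explanatory error) data whose site counts are constant within every
family, where the effect is collinear with the family intercepts.

## The synthetic benchmark

`simulate_study()` generates a complete study with recorded ground truth.
Its defaults are the study conditions the pipeline is meant for, chosen once:

* 3 time points x 3 replicates; 12% of genes DE at 60 minutes, 4% of those
  already significant at 15 minutes, and a 0.1% transient class — the
  proportions of the modelled experiment;
* baseline expression log-normal with median ~400 and log-sd 1.5, giving a
  mean of roughly 1,200 counts per gene, the depth of a study mapping about
  100 million reads per sample over ~78,000 expressed genes;
* |log2 FC| drawn from N(2, 0.8) (folded), 15-minute responses at half the
  60-minute amplitude;
* dispersion trend $\alpha(\mu) = 5/\mu + 0.05$ with log-normal scatter
  (log-sd 0.3) — trend coefficients are plausible placeholders chosen to give
  MA plots resembling bulk data of this depth, as no empirical trend was
  published;
* gene-wise replicate batch effects, log-sd 0.1, multiplicative on the mean,
  matching how the design matrix encodes replicates;
* families of size 1-6 (mean ~3.2, as expected for a polyploid with a
  fractionating history), within-family LFC correlation 0.9, a 5% chance of
  one divergent member per family (|LFC| ~ N(4, 0.5)), and 5% orphan genes;
* a signed network among DE genes with direction fidelity 0.9, half the
  edges from low-throughput (< 50-interaction) studies;
* 1,000-base uniform-composition promoters with an ABRE-like focal consensus
  planted at twice the background rate upstream of up-regulated genes
  (rate-ratio mode), plus never-planted decoy motifs.

Stages run in dependency order — families, promoters, counts, network — each
on a deterministic substream of the master seed, so any stage can be
regenerated in isolation. Families must precede counts because the
within-family correlation is a property of the true LFCs the counts are
drawn from. The promoter stage has a second, binding-site-driven mode
(`beta_bss > 0`) in which each planted copy adds `beta_bss` to the gene's
true LFC; it runs before the counts for the same reason and makes the truth
satisfy the binding-site regression exactly, which is how the motif stage's
end-to-end recovery is tested. The rate-ratio mode is the default because it
leaves the DE fractions untouched.

What the generator does *not* emulate: multi-mapping ambiguity between
paralogs (counts are unambiguous by construction), subgenome structure,
isoforms, GC or length biases, correlated genes outside families, and
realistic promoter composition. Passing parameter-recovery tests on this
benchmark therefore shows the estimators are correct under the stated model,
not that the model captures every feature of real guard-cell data.

## Numerical choices and degenerate inputs

* Dispersion optimization over $\log\alpha \in [\log 10^{-8}, \log 30]$;
  genes with mean normalized count below 0.5 are skipped (NA) and filtered
  genes never reach the Wald stage with a usable dispersion.
* IRLS: at most 50 iterations, relative deviance tolerance $10^{-8}$, means
  clamped to $[10^{-10}, 10^{12}]$; non-converged genes are reported with NA
  statistics rather than dropped silently.
* Designs with a single replicate level drop the replicate columns with a
  warning; designs without residual degrees of freedom are refused.
* Independent-filtering ties go to the smaller threshold; BH is monotone and
  order-invariant (tested).
* `compare_nb_poisson()` treats Poisson as the $\alpha \to 0$ boundary of
  the NB family, so a constant gene favours Poisson by exactly the
  2-unit parameter penalty in AIC.
* Odds ratios from tables with a zero cell are Haldane-Anscombe corrected
  and flagged, never reported as infinite without the flag.
* Test problem sizes (2,000-5,000 genes, hundreds of simulated networks)
  were chosen so each property runs in seconds to a few minutes on one CPU
  while keeping Monte-Carlo error well inside the asserted bands.

## Known limitations

* No LFC shrinkage estimator: reported fold changes for near-zero baselines
  are noisy (visible as flared MA-plot edges), as in any unshrunk NB GLM.
* The Wald test's small-sample anti-conservativeness discussed above; with
  three replicates, quasi-likelihood F tests would be more conservative but
  are out of scope.
* The family fixed-effects regression treats site counts as error-free and
  linear in effect; it is a detection tool for association, not a calibrated
  effect-size model for large counts.
* One-sided enrichment only; depletion is visible in the odds ratio but not
  tested directly.
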