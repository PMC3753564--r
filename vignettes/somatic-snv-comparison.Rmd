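---
title: "Comparing somatic SNV callers on matched cancer-normal pileups"
author: "snvcompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing somatic SNV callers on matched cancer-normal pileups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvcompare)
```

## The problem

Somatic single-nucleotide variants — substitutions present in a tumour
but not in the patient's germline — are detected by jointly analysing a
matched cancer/normal pair of sequencing samples. Detection is
confounded from three directions: germline polymorphism (a heterozygote
looks like a 50% variant signal in *both* samples), tumour biology
(subclonal mutations and impure samples push true somatic signals down
to a few percent variant allele fraction, VAF), and sequencing noise
(random base-call error plus *systematic* miscalls that recur at
susceptible positions, characteristically confined to one DNA strand).

`snvcompare` re-implements, at desk scale, four published calling
strategies for this problem, the post-calling filter suite used to
clean their output, and the concordance statistics used to compare
them — together with a synthetic paired-pileup generator so that every
stage is testable against planted ground truth without any external
data. The four callers deliberately share one per-read likelihood
kernel so that their differences are differences of *model*, not of
plumbing.

## The shared likelihood kernel

All Bayesian components reduce a site to a reference allele A and a
single variant allele B (the most frequent non-reference base; ties
broken A < C < G < T). A genotype g in {AA, AB, BB} emits the reference
with fraction $f_g$ (defaults $1-\varepsilon$, $1/2$, $\varepsilon$,
with $\varepsilon = 0.001$). For a read $r$ with base-call error
probability $e_r = 10^{-\mathrm{baseQ}/10}$ and mapping confidence
$m_r = 1 - 10^{-\mathrm{mapQ}/10}$,

$$P(b_r \mid g) = m_r\left[f_g\,P(b_r \mid A) + (1-f_g)\,P(b_r \mid B)\right] + \frac{1-m_r}{4},$$

where $P(b \mid a) = 1-e_r$ if $b = a$ and $e_r/3$ otherwise. A base
that is neither A nor B is generic error evidence; `N` calls and reads
whose alignment deletes the site carry no base call and contribute
likelihood 1. An unmapped read ($m_r = 0$) is uniform over the four
bases, hence uninformative.

## The four calling models

**Heuristic genotypes + Fisher's exact test** (`call_varscan`). Each
sample is genotyped from its empirical variant frequency: below 0.20
homozygous reference, from 0.20 to 0.75 heterozygous, above 0.75
homozygous variant, requiring at least 2 variant reads at base quality
15+. Where the genotypes differ, a one-tailed Fisher exact test on the
2x2 (ref, var) x (normal, tumour) table gives $p$; the class is somatic
if the normal is homozygous reference, LOH if heterozygous, unknown
otherwise, and the score is $1-p$. The 0.20 gate is the caller's
defining blind spot: true VAFs below it are invisible except when
binomial sampling pushes the *empirical* frequency across the gate.

**Joint-genotype posterior with a somatic transition**
(`call_somaticsniper`). The nine joint genotypes $(g_N, g_T)$ get prior
$P(g_N)\,P(g_T \mid g_N)$ with $P(g_N) = (1-\tfrac{3\theta}{2},\,
\theta,\,\tfrac{\theta}{2})$ and a transition that keeps $g_T = g_N$
with probability $1-\mu_s$, splitting $\mu_s$ evenly between the two
other genotypes (the source describes no transition structure; the even
split is our choice). The somatic score is the phred-scaled posterior
probability that the genotypes are *equal*,
$S = -10\log_{10} P(g_N = g_T \mid D)$, capped at 255.

**Joint binomial mixture trained by MAP-EM** (`train_jsm_em`,
`call_jointsnvmix`). The reference-supporting read counts in the two
samples are binomial given the joint genotype; the joint genotype
probabilities $\pi$ carry a Dirichlet prior $\delta$ and the
per-genotype reference-success rates $\mu_g$ carry Beta priors
$(\alpha_g, \beta_g)$. EM alternates site responsibilities over the
nine states with regularized updates

$$\pi_{jk} = \frac{\sum_i \gamma_i(j,k) + \delta_{jk} - 1}{n + \sum \delta - 9},
\qquad
\mu_j^{N} = \frac{\sum_i w_i(j)\,a_i^N + \alpha_j - 1}{\sum_i w_i(j)\,d_i^N + \alpha_j + \beta_j - 2},$$

and the penalized log-likelihood trace is non-decreasing (asserted per
iteration in the tests). The `jsm1` classifier uses the binomial counts
directly; `jsm2` replaces the counts with the quality-weighted per-read
kernel, $f_g \to \mu_g$. The somatic score is
$\gamma(AA,AB)+\gamma(AA,BB)$. Default pseudocounts put mass $10^6$ on
$(AA,AA)$ and 2 elsewhere, with $(\alpha,\beta)$ of (1000,10),
(500,500), (10,1000) for AA/AB/BB: almost every genomic site is
double-reference, and raising the off-diagonal Dirichlet mass is
exactly the lever that makes this mixture over-call somatic
probability — deliberately exposed rather than hidden.

**Marginalized allele frequency** (`call_strelka_like`). The normal is
a diploid genotype under the kernel; the tumour is either generated at
the normal genotype's allele fraction (non-somatic) or, with prior
$\mu_s$, at a variant fraction $s$ marginalized uniformly over the grid
$\{h, 2h, \dots, 1\}$ ($h$ = `grid_step`, default 0.01). The score is
the posterior probability of (most likely normal genotype, somatic);
the phred score is $-10\log_{10}(1-\mathrm{score})$, capped at 255.
This is an explicit simplification of the original tool, whose full
model (realignment, strand terms, noise tiers) is not published in
reproducible detail; its realignment-adjacent protections are delegated
to the filter suite. Marginalizing over *any* $s$ is what makes this
caller sensitive near 5% VAF where the others fail.

Default priors $\theta = 10^{-3}$, $\mu_s = 10^{-4}$ are conventional
values, configurable via `prior_config()`; the source material names
the concepts but not the numbers.

## The filter suite

Raw candidate sets are generated at deliberately permissive thresholds
(Fisher $p \le 0.05$, $S \ge 15$, mixture score $\ge 0.001$, phred
$\ge 1$) and then cleaned by eight removal rules, evaluated on the
tumour's variant reads for somatic candidates and the normal's for LOH
candidates:

1. all variant reads on one strand;
2. mean variant base quality < 15;
3. no variant base quality strictly over 30;
4. mean variant mapping quality < 15;
5. no variant mapping quality strictly over 40;
6. more than 2 other candidate positions (from *any* caller) within
   50 bp either side (distance <= 50, excluding the site itself);
7. spanning-deletion reads > 20% of overall depth in either sample
   (overall depth includes the deletion reads themselves);
8. reads with an immediately adjacent indel > 20% of reads in either
   sample.

"Over" and "less than" are read as strict inequalities — the plain
reading of the rule list. The eight rules group into six feature
families (strand bias; base quality; mapping quality; nearby SNVs;
spanning deletions; adjacent indels), which is how the pass-rate table
reports them: strand bias first, the other seven combined on the
strand-bias survivors, so the second column's denominator is the
survivor count.

Complete strand bias also arises from fair random strand sampling: with
$v$ variant reads the chance all land on one strand is
$2\cdot(1/2)^v = (1/2)^{v-1}$ (both one-sided outcomes count).
`expected_strand_bias_count()` sums these per-site probabilities into
the count expected under the null; an observed count far above it is
the signature of systematic error, which is the empirical argument the
filter rests on.

## The synthetic world

`sim_config()` states the generative world once; its defaults are the
conditions the analysis assumes, not tuning knobs:

* exome-like depth: Poisson mean 50 per sample (negative binomial
  optional for overdispersion);
* germline heterozygotes at $10^{-3}$ per site (VAF 0.5 in both
  samples) and homozygous variants at $5\times10^{-4}$;
* clonal somatic SNVs at tumour VAF purity/2 — a heterozygous mutation
  in a diploid tumour; aneuploidy and copy number are not modelled
  because none of the four callers model them;
* subclonal somatic SNVs at tumour VAF uniform on [0.02, 0.20], the
  range where the callers' sensitivities genuinely diverge; the normal
  sample sees `normal_contamination` times the tumour VAF (default 0);
* base qualities drawn from a discrete HiSeq-like distribution over
  Q20-Q40 (mass 0.05/0.10/0.20/0.30/0.35), mapping qualities over
  0/20/40/60 (0.02/0.03/0.15/0.80); each read miscalls with probability
  $10^{-\mathrm{baseQ}/10}$, uniformly over the other three bases;
* systematic-error sites at $10^{-3}$ per site: one strand is chosen
  once per site, and reads on that strand in *both* samples (site
  susceptibility is a property of the locus, not the sample) miscall to
  one fixed wrong base with probability 0.15;
* per-read spanning-deletion and adjacent-indel flags at 0.005.

`split_null()` simulates one non-cancer sample at double depth and
assigns each read to a pseudo-normal or pseudo-tumour half by a fair
coin — read-level because the original description does not state
whether mate pairs were kept together. Every somatic call on the
pseudo-pair is a false positive by construction.

What the generator does **not** emulate: capture geometry and
off-target strand asymmetry, GC and mappability bias, read-position
error profiles, sequence-motif (homopolymer/GG) error hotspots, indel
events beyond per-read flags, and copy-number variation. A green test
therefore establishes internal correctness of the models and filters
against this stated world, not performance on a real exome; the
original study's exact counts depend on its real dataset and the
original tool binaries and are out of reach by design.

## Numerical choices

* All posteriors are computed in log space with log-sum-exp; every
  9-state posterior sums to 1 within $10^{-9}$ (tested).
* Phred scores are rounded to integers and capped at 255 to keep
  $1 - 10^{-S/10}$ representable.
* EM stops when the penalized log-likelihood improves by less than
  `tol` ($10^{-6}$ by default) or at `max_iter`; degenerate
  pseudocounts that would push a parameter across 0 or 1 clamp it to
  $[10^{-6}, 1-10^{-6}]$ with a warning.
* The marginalization grid step 0.01 changes scores by less than 0.02
  versus step 0.005 (tested); the score is reported from the grid, not
  interpolated.
* Zero-depth samples: the Fisher caller declines to call; the Bayesian
  callers use a uniform likelihood for the empty sample. A site with no
  variant base call in either sample short-circuits to the no-signal
  result, which is below every default inclusion threshold.
* Ties in variant-base selection break alphabetically, and simulation
  under a fixed seed is byte-identical (RNG state is restored on exit).

## Design decisions that were genuinely open

* The joint-genotype caller operates in the reduced A/B space (the
  original works in full base space): the comparison's quantities —
  somatic and LOH probabilities — only need the reduced space.
* The somatic transition splits $\mu_s$ evenly between non-matching
  genotypes; no transition structure is published.
* The EM training subset is configurable (`train_fraction`, fixed-seed
  subsample) because "a subset of the data" is otherwise unspecified;
  default is all sites.
* Multi-allelic evidence beyond the top variant base is ignored; the
  comparison framework never discusses it.
* The pass-rate significance test is a two-proportion chi-square with
  continuity correction (Fisher's exact offered as an alternative); the
  original table reports significance without naming a test.
* The threshold sweep uses 101 evenly spaced thresholds; the original
  figures do not state their grid.
* "Found by multiple callers" uses raw pre-filter membership at any
  score, following the stated "(at any probability threshold)".
* The scaled index of the unique-call VAF profile is $i/(n-1)$; the
  exact formula behind "scaled index" is unstated.

## Known limitations

* The callers are desk-scale re-implementations sharing one kernel;
  they are not bit-compatible with the original four tools and do not
  implement purity-adjusted thresholds, indel realignment, or the
  original depth-tier noise models.
* The Fisher caller's "sensitivity is exactly zero below the 0.20
  gate" idealization is violated by sampling noise: a true VAF of 0.15
  at depth 60 crosses the empirical gate with probability ~0.03 per
  site, so a handful of sub-gate sites in a large simulation will be
  called — as the real tool would call them.
* dbSNP membership is abstracted to a user-supplied or truth-derived
  position set; no database access is attempted.
* LOH candidates are labelled but not biologically interpreted.

## A short run

```{r example, eval = FALSE}
cfg <- sim_config(n_sites = 5000, seed = 42, tumour_purity = 0.8,
                  n_clonal_somatic = 10, n_subclonal_somatic = 10,
                  subclonal_vaf_range = c(0.03, 0.15))
sim <- simulate_pair(cfg)
calls <- run_all_callers(sim$pileup)
verdicts <- apply_filters_all(calls, sim$pileup)
mat <- comparison_matrix(calls)
evaluate_against_truth(mat, sim$truth, vaf_bins = c(0, 0.1, 0.2, 0.5))
```

`run_pipeline(pipeline_config(...), out_dir)` chains all stages —
including the split null — into plain re-loadable files with an MD5
manifest; identical config and seed reproduce identical hashes.
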