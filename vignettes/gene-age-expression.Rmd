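---
title: "Dating genes and tracing them into the developing brain: methods"
author: "genebirth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating genes and tracing them into the developing brain: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genebirth)
```

This vignette is the package's account of its methods: the models and rules
each stage implements, the tunable parameters and their defaults, what the
synthetic-data generators emulate (and what they deliberately do not), the
numerical choices, and the known limitations.

## The question

Comparative annotation gives every gene an *origination branch* on the
species tree — branch 0 for genes shared by the whole clade, up to the focal
terminal branch for species-specific genes. Crossing those ages with
expression data asks a developmental-evolution question: do recently
originated ("young") genes contribute disproportionately to particular
tissues and stages — in the motivating application, the fetal brain and the
neocortex — and do those young, early-biased genes show evidence of adaptive
protein evolution?

## Gene dating by Dollo parsimony

A rooted species tree with focal tip $f$ defines the root-to-focal path of
internal nodes $v_0 \dots v_{B-1}$; the tips splitting off at $v_i$ form the
outgroup clade $O_i$, and branch indices run $0 \dots B$ (0 oldest, $B$ the
terminal branch). Under Dollo parsimony a gene arises once and can only be
lost, so a gene present in the focal species and in any tip of $O_i$ must be
at least as old as branch $i$. The assignment

$$b = \min\{\, i : \text{present in at least one tip of } O_i \,\}$$

(or $B$ if no outgroup shows presence) is exactly the minimum-loss
hypothesis, and it is *conservative*: a single presence in an old outgroup
forces an old age, and ortholog losses can only push the assignment toward
younger branches, never older. The test suite proves both properties —
equivalence with a brute-force loss-counting oracle over all presence
patterns on small trees, and `assigned >= true` on lossy simulations.

Assumptions worth stating: presence/absence is taken as input truth. Real
pipelines infer it from syntenic alignments, and cannot distinguish "absent"
from "undetected"; fast-evolving genes may be mis-dated upstream of this
package. Multifurcations on the focal path are rejected rather than silently
resolved, because the branch indexing would be ambiguous.

The default tree (`default_species_tree()`) is a 13-tip caterpillar from
zebrafish to human, giving branches 0–12 with 8–12 as the default young
(primate-specific) set and 12 the human terminal branch.

## EST presence and enrichment

A gene is *present* in a (species, tissue[, stage]) cell when supported by at
least `min_ests = 2` ESTs from normal-sample libraries (the headline analyses
are robust to `min_ests = 1`, which the threshold-monotonicity tests cover).
Per-cell young proportions are compared between species with a gene-level
2×2 Fisher exact test — rows species, columns (young expressed, old
expressed) — with Bonferroni correction over the number of cells tested in
the run.

Two resampling controls accompany the point estimates:

* **Bootstrap error bars** (default 100 replicates): within each cell, ESTs
  are resampled with replacement to the original depth (equivalently, a
  multinomial draw over genes weighted by observed counts), presence is
  re-called, and the young proportion recomputed; the mean ± 2 sd across
  replicates is reported. The resampling unit is the individual EST: the
  alternative units (libraries, genes) would answer slightly different
  questions, and the EST is the unit whose sampling depth differs between
  species, which is the artefact the control addresses.
* **Subsampling control** (default 1000 replicates): to compare species with
  unequal EST depth, an equal number of ESTs is drawn without replacement
  from each, presence re-called, and the young proportions compared; the
  empirical $p$ is the fraction of replicates in which the putatively
  enriched species fails to exceed the other, ties counting as failures (the
  conservative direction), reported as "< 1/n_reps" when no replicate fails.

## RPMK and the binomial likelihood-ratio test

Reads are fixed-length (32 nt). A read counts for a gene only if its sequence
(or reverse complement) occurs in that gene's transcripts and in no other
gene's; multi-gene and unmatched reads are discarded. The same rule applied
to all transcriptome 32-mers yields the *effective length*: the number of
32-mers unique to the gene. Expression is

$$\mathrm{RPMK} = \frac{\text{count}}{\text{total mapped}/10^6 \cdot
\text{effective length}/10^3}.$$

Duplicated genes (DNA-level duplicates, retrogenes) with fewer than
`min_mappable = 30` unique bases are excluded; de novo genes are exempt from
this filter so that their typically longer unique regions cannot manufacture
a spurious age contrast.

Differential expression between two pooled groups uses a binomial
generalized likelihood-ratio test: with counts $x_1, x_2$ out of totals
$N_1, N_2$, the null is a shared per-read rate $\hat p_0 = (x_1+x_2)/(N_1+N_2)$
and

$$\Lambda = 2\left[\ell(x_1; N_1, x_1/N_1) + \ell(x_2; N_2, x_2/N_2)
- \ell(x_1; N_1, \hat p_0) - \ell(x_2; N_2, \hat p_0)\right] \sim \chi^2_1,$$

with $0\log 0 \equiv 0$. The binomial (rather than Poisson) likelihood is
exact for fixed totals and numerically indistinguishable at these depths;
$\Lambda$ equals the G-test of the 2×2 table, which the tests assert to
1e-8. BH correction at FDR 0.05 gives q-values; direction is the group with
the larger per-read rate among genes with $q < 0.05$, ties unbiased. Sample
partitioning, when not given, is hierarchical clustering (average linkage,
distance $1 - r$ Pearson) cut into two groups.

Calibration: the type-I error of the LRT at nominal 0.05 sits inside the
exact binomial 99% interval over 10,000 null simulations at mean counts of
~100 per group (the asymptotic regime the pipeline operates in after
pooling; at mean counts of ~20 the χ² reference is visibly anticonservative,
which is one reason samples are pooled before testing).

## Age × bias inference

Unbiased genes are excluded, then: (i) the 2×2 age-class × direction Fisher
test; (ii) per-branch profiles with an exact two-sided binomial test of up-
vs down-bias against 0.5 (a one-sided upper-tail $p$ is reported alongside,
since directional phrasings are common), Bonferroni-corrected over branches —
the branches-only family is the default, configurable, as the comparison
family is a judgement call; (iii) *cluster pooling*: coordinate-sorted genes
on a chromosome chain into one cluster when successive genes share branch
and bias and the gap (end of previous to start of next, 0-based half-open;
overlaps merge) is at most the cutoff — defaults 100 kb and 1 Mb — after
which clusters replace genes as test units, so tandem duplicate blocks are
not counted as independent evidence. Gap definition (nearest-end distance,
strand ignored) is this package's choice; "neighbouring" admits several
formalisations and the chaining rule is the simplest order-independent one
(the tests verify order invariance and cutoff monotonicity against a
union-find oracle). (iv) Feature proximity: a gene is associated with a
feature set (enhancers, insulator sites) when some interval lies within the
cutoff (distance 0 on overlap, else nearest-end gap, inclusive boundary).
(v) Term enrichment: fold = (list hits/list size)/(background hits/background
size), one-sided Fisher, BH across terms; no EASE-style count shrinkage is
attempted.

## Selection layer

**Ka/Ks.** Nei–Gojobori (1986) counting with Jukes–Cantor correction
$d = -\tfrac34\ln(1 - 4p/3)$: per-codon synonymous site fractions averaged
between the two sequences, pathway-averaged difference counts (all
substitution orderings weighted equally; steps through stop codons count as
nonsynonymous, keeping $S + N = 3 \times$ codons exactly). Filters follow
the source analyses: alignments of ≤ 100 codons fail, as do alignments with
fewer than one estimated synonymous substitution ($K_s \cdot S < 1$); ratios
above 1 are trimmed to 1 in the plotting field. NG86 is a deliberate,
self-contained counting estimator that the test suite can verify by hand
enumeration; ML codon models (CODEML-style) are richer but not
desk-checkable, and externally computed values can be imported as TSV for
comparison.

**McDonald–Kreitman + PRF.** The 2×2 of fixed/polymorphic ×
synonymous/nonsynonymous counts gives the Fisher p, the neutrality index
$NI = (p_n/p_s)/(d_n/d_s)$ and $\alpha = 1 - (d_s p_n)/(d_n p_s)$, flagged
undefined (not pseudocounted) on zero denominators. The Poisson random field
adds a generative model:

$$E[p_s] = \theta_s L(0,n),\quad E[d_s] = \theta_s \tau,\quad
E[p_n] = \theta_r L(\gamma,n),\quad E[d_n] = \theta_r \tau G(\gamma),$$

with fixation factor $G(\gamma) = 2\gamma/(1-e^{-2\gamma})$ and sample-size-
aware polymorphism factor

$$L(\gamma, n) = \int_0^1 \frac{1 - e^{-2\gamma(1-q)}}{(1-e^{-2\gamma})\,
q(1-q)}\,\bigl(1 - q^n - (1-q)^n\bigr)\, dq,$$

which reduces to the harmonic sum $\sum_{i=1}^{n-1} 1/i$ at $\gamma = 0$
(asserted to 1e-10). Because $R(\gamma) = [L(\gamma,n)/L(0,n)]/G(\gamma)$ is
strictly decreasing, the MLE $\hat\gamma$ solves $R(\gamma) = NI$ by
monotone root finding (bracket $[-30, 30]$, doubled to $[-200, 200]$ before
flagging a boundary; quadrature at relative tolerance 1e-10 with the
integrable endpoints handled by the integrator). With $\gamma$ free the full
model saturates the four counts, so the $\gamma = 0$ likelihood-ratio test
coincides with the G-test of the 2×2 — a strong internal consistency check
the tests assert to 1e-6. `n_sample` defaults to 40 chromosomes and should
be set to the polymorphism panel's actual size when known.

This per-gene MLE is an analog of, not a substitute for, hierarchical
Bayesian PRF fits that share information across genes: published per-gene
posterior summaries (the shipped 16-gene table's p/u/sd columns) are parsed
and classified at the p < 0.1 rule but not numerically reproduced.
Classification is strict (`p < threshold`), and within the pipeline a
positive point estimate is additionally required, since the two-sided LRT
alone would also flag purifying selection.

## The synthetic-data module

The generators emulate the structure of the real inputs with controllable
truth, under a single integer seed from which each stage derives its own
substream (`stage_seed`), so stages rerun independently yet the whole bundle
is byte-identical under a fixed seed.

Default study conditions, chosen once to mirror the motivating data:

* 13-branch tree; branch origination probabilities (0.56 for branch 0, 0.05
  for branches 1–7, 0.018 for 8–12) putting ~9% of genes in the young set —
  the same order as ~1,800 primate-specific genes among ~20,000.
* `young_fetal_enrichment = 3`: the odds multiplier on young genes' sampling
  weight in (brain, fetal) EST libraries and on the fetal direction of young
  DE genes. The motivating study does not state an effect size; 3 is chosen
  for adequate test power and is of the order of the observed 2–4× young
  proportion contrasts.
* Young genes' baseline EST weight is scaled by 0.1, reflecting the narrow,
  weak expression typical of recently originated genes; without it, deep
  libraries saturate the ≥ 2-EST presence call and the proportion contrast
  vanishes. This is a property of real young genes, not a test convenience,
  and it applies identically to null (enrichment 1) configurations.
* EST libraries: 6 tissues × {fetal, adult} × 3 libraries of exactly 10,000
  ESTs (multinomial draws, so totals are conserved exactly).
* RNA-seq: error-free 32-nt reads, uniform positions, `prop_de = 0.1`,
  `de_effect_logfc = 2`, three samples per group. Reads are error-free
  because the mapper is exact-match; sequencing error and isoform structure
  are out of scope. Duplicate gene pairs share a `paralog_shared_bp = 40`
  block with their parent so that multi-gene read exclusion is exercised.
* MK tables: independent Poisson draws from the PRF means above, with
  γ ∈ {−2, 0, 2, 5} by default.

What passing tests on these data do **not** show about real data: no
sequencing error or mapping ambiguity beyond exact k-mer sharing, no library
composition effects beyond multinomial sampling, no isoforms, no
phylogenetic non-independence among genes beyond the planted paralog pairs,
and Poisson (not coalescent) MK counts. The generators validate the
machinery, not the biology.

One consequence of relative-abundance sequencing is worth noting: when a
fraction of genes is truly DE, the sampling probability of every *other*
gene shifts slightly between groups (the compositional effect familiar from
RNA-seq), so at `prop_de = 0.1` a fraction of truly-null genes is called at
q < 0.05 with small effect sizes. Null calibration is therefore asserted at
`prop_de = 0`, matching how the test statistic is defined.

## Problem sizes used by the tests and acceptance script

Dating round-trips use 1,000–2,000 genes; EST power runs use 5,000 genes at
30,000 ESTs per tissue×stage cell (100 replicate pairs for the power check,
10 for the null check); the end-to-end bundle uses 5,000 genes with 333,000
reads per sample (≈1M per pooled group, the depth at which the DE recall
condition of 0.8 is stated); LRT calibration uses 10,000 null draws; γ
recovery uses 51 tables per γ at θ = 1,000. These sizes are the package's
validation choices: large enough that every planted signal is comfortably
detectable, small enough to run on a laptop in minutes.

## Known limitations

* Presence/absence dating inherits upstream errors of homology detection and
  synteny; it cannot rescue fast-evolving genes the way syntenic aligners
  can, and it treats "undetected" as "absent".
* The exact-match mapper is a stand-in for probabilistic aligners (the
  motivating study's mapper keeps reads whose best alignment is ~3-fold more
  likely than the second best); with error-free synthetic reads the two
  agree, with real reads they will not.
* The per-gene PRF MLE is undefined when any MK cell is zero (declined with
  a reason, never pseudocounted) and saturates at the bracket boundary for
  extreme NI.
* Bonferroni families (tissues; branches) are reported explicitly because
  the right family is context-dependent; users combining runs should correct
  accordingly.
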