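---
title: "Deciding whether two tumors from one patient are clonally related"
author: "clonalPair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding whether two tumors from one patient are clonally related}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalPair)
```

## The problem

When a patient presents with two tumors — for instance a carcinoma in each
breast, or a breast tumor and a later liver lesion — the clinically decisive
question is whether the second tumor descends from the first (clonal:
metastasis or recurrence) or arose independently (a second primary). The two
situations call for very different management, yet histology alone often
cannot distinguish them.

`clonalPair` implements three independent genomic lines of evidence and a
joint verdict:

1. **Somatic-mutation concordance.** Two tumors of common clonal origin carry
   the founding clone's somatic mutations in both samples; independent tumors
   share mutations only by chance.
2. **Mutational-spectrum similarity.** Each tumor's SNVs are summarized as a
   strand-collapsed 96-trinucleotide-context spectrum; samples are clustered
   hierarchically and a patient's pair is scored by whether its two samples
   are mutual nearest neighbors in the tree.
3. **Copy-number clonality (LR2).** Arm-level gain/loss profiles are compared
   through a likelihood ratio contrasting a shared-aberration (clonal) model
   against independent draws from cohort reference frequencies.

A synthetic paired-tumor cohort generator with fully known ground truth makes
every stage testable at desk scale.

## Mutation concordance: the 2x2 Fisher test

Each catalog is a set of somatic variants keyed by (chrom, pos, ref, alt);
matching is exact on that key. For a pair with $n_1$ and $n_2$ mutations of
which $a$ are shared, the counts are embedded in a 2x2 table over a finite
universe of $N$ candidate sites:

|            | in tumor 2 | not in tumor 2 |
|------------|-----------:|---------------:|
| in tumor 1 | $a$        | $n_1 - a$      |
| not        | $n_2 - a$  | $N - n_1 - n_2 + a$ |

Under the null of independent mutation acquisition, $a$ follows the
hypergeometric law with population $N$, $n_1$ successes and $n_2$ draws, and
the one-sided (right-tail) Fisher p value is

$$p = P(X \ge a) = \sum_{k=a}^{\min(n_1,n_2)}
  \frac{\binom{n_1}{k}\binom{N-n_1}{n_2-k}}{\binom{N}{n_2}}.$$

The test is one-sided because only an *excess* of sharing is evidence of
clonality. The tail is accumulated in log space (`lchoose` plus
log-sum-exp), because clonal metastasis pairs produce p values around
$10^{-30}$–$10^{-44}$ and smaller: the linear-space sum is only exponentiated
at the end, so such values remain finite and exact. p values are adjusted
across the patients of a cohort by Benjamini–Hochberg (`bhAdjust`, a
validated front-end to the standard step-up adjustment).

**The universe $N$.** The fourth cell is not observable; some finite universe
of "sites that could have been called" must be declared. The package's
default (`concordanceReport(universeSize = NULL)`) is the *superset*
reconstruction: the size of the union of all somatic variants detected across
the analyzed cohort. It is the only finite universe the calling process
itself constructs, and with per-tumor loads near 73 across 12 samples it is
on the order of $900$. `universeSize` is always configurable; for the
simulator's cohorts the generating universe size (default 900) is the exact
null and is what `runReport` uses. The concordance p value depends on this
choice; conclusions should be checked for stability under a plausible range
of $N$.

Descriptive summaries reported alongside: the concordance fractions
$f_{\min} = a/\min(n_1, n_2)$ and $f_{\cup} = a/(n_1+n_2-a)$, the
transition:transversion ratio, and the exact binomial right-tail test of the
nonsynonymous:synonymous ratio (`nsSynTest`). For the latter the expected
nonsynonymous proportion under no selection defaults to $p_0 = 0.715$, an
approximation to the genome-wide nonsynonymous fraction under uniform
substitution; it is a configurable argument, not an estimate made by the
package.

## Mutational spectra

Every SNV with a usable 3-mer context is collapsed to the pyrimidine-reference
representation (purine-reference mutations are reverse-complemented), giving
96 categories: 6 substitution classes times 16 flanking combinations
(`collapseContext`, exhaustively tested over all 192 raw representations).

Scaling (`scaleSpectra`) proceeds in two steps: per-sample counts are first
converted to frequencies, so tumors with 28 and 185 mutations become
comparable, then each category is z-scored across samples, so the clustering
is driven by relative enrichment rather than by the dominant C>T class alone.
Zero-variance categories are left at zero; with a single sample only the
frequency step applies.

Clustering (`hierarchicalCluster`) defaults to **average linkage on
correlation distance** ($1 - r$ between scaled rows). Correlation/cosine-type
similarity is the standard way spectra are compared in signature analysis,
and in the package's own simulations it recovers clonal pairs as mutual
nearest neighbors markedly more reliably than Euclidean distance (about 99%
versus about 89% at a shared fraction of 0.8); Euclidean distance and other
linkages remain available as arguments. Pair adjacency is defined through
the cophenetic distance of the tree: a patient's two samples are "adjacent"
when each is the other's nearest leaf. Adjacency is reported as supporting
evidence only — it does not enter the verdict rule, since spectrum similarity
reflects shared mutational processes as much as shared origin.

## Superset rescue

A variant confidently called in one tumor may be missed in the other purely
by sampling. For each patient, the union of all called variants (the
superset) is re-examined in every tumor: at a site with $d$ reads and $x$
alt-supporting reads, the probability that background sequencing error alone
explains the support is the exact binomial tail
$P(X \ge x)$, $X \sim \mathrm{Binomial}(d, e)$ with $e = 0.01$ by default.
Benjamini–Hochberg adjustment is applied jointly across all (site, tumor)
tests not already called, and tests with $q < 0.10$ are called. The package
computes per-test binomial p values and applies the FDR rule as the operative
threshold; a nominal per-test level of 0.05 is carried in `RecoveryParams`
for provenance only. By convention $e$ is the total error probability toward
the specific alternate allele; `perAllele = TRUE` divides it by 3.

## Copy-number clonality

* **QC.** The derivative log ratio spread (`dlrs`) — the standard deviation
  of successive probe differences over $\sqrt 2$ — estimates probe noise
  independently of true copy-number structure; profiles scoring above 0.20
  are excluded (a boundary score passes).
* **Detection.** `detectAberrations` is an ADM-style scan: the score of a
  probe interval is $|\sum \text{log ratios}| / (\hat\sigma \sqrt{n})$ with
  $\hat\sigma$ the DLRS estimate; maximal non-overlapping intervals with
  score $\ge 6$ and at least 3 probes are reported. The minimum-probe rule
  acts as a *filter*: a top-scoring interval narrower than 3 probes is
  discarded rather than padded into a wider call, so an isolated 2-probe
  spike is never reported.
* **Arm states.** Segments are reduced to per-arm states in $\{-1, 0, +1\}$:
  an arm is called when same-sign segments with mean beyond $\pm 0.25$ cover
  at least half of it (boundary counts); conflicting signs resolve to the
  larger covered fraction, ties to normal.
* **Reference frequencies.** Per-arm state frequencies are estimated from
  the cohort and floored at $\varepsilon = 0.01$ (floored states get exactly
  $\varepsilon$; the remaining mass is rescaled), so every observable state
  has positive probability.

The likelihood model (`lr2Statistic`), independent across arms $k$: with
probability $c$ a shared clonal aberration occurs in both tumors, its sign
drawn from $\alpha_k(s) = \pi_k(s) / (\pi_k(-1) + \pi_k(+1))$,
$s \in \{-1,+1\}$; with probability $1-c$ the two states are independent
draws from the marginal $\pi_k$:

$$P(s_1, s_2 \mid c) = (1-c)\,\pi_k(s_1)\,\pi_k(s_2)
  + c\,\mathbf{1}[s_1 = s_2 \ne 0]\,\alpha_k(s_1).$$

$\mathrm{LR2} = \max_{c \in [0,1]} L(c)/L(0)$, maximized in log space by a
101-point grid followed by golden-section refinement; $\hat c$ is the
maximizer, and LR2 is 1 exactly when $c = 0$ already maximizes the
likelihood (e.g. two all-normal profiles, or disjoint aberrations). The p
value is the plug-in rank of the observed LR2 in a declared reference null —
all between-patient tumor pairings of the cohort, augmented with simulated
independent pairs when fewer than 20 such pairings exist.

This is an *arm-level* likelihood, deliberately coarser than probe-level
clonality statistics; its LR2 magnitudes are correspondingly modest and not
comparable to probe-level values. A property worth knowing: a concordant
aberration on an arm that is *common* in the reference population (frequency
around 0.25) barely moves the likelihood — the derivative of $\log L$ at
$c = 0$ is $\alpha_k/\pi_k^2 - 1$ minus one unit per non-concordant arm, so
only concordance on *rare* arms is strongly informative. Discrimination
therefore depends on how many rare-arm events pairs share; clonal pairs
sharing only hallmark-arm events can be indistinguishable from chance at arm
resolution. This is a known limitation of the arm-level reduction, stated
here rather than hidden.

## The synthetic cohort generator

`simulationParams()` encodes the study conditions the package is calibrated
against; `simulateCohort` reproduces a design of independent bilateral pairs
plus clonal primary/metastasis control pairs (default 4 + 2).

| Parameter | Default | What it encodes |
|---|---|---|
| `mutationsMean`, `mutationsDispersion` | 72.8, 8 | negative-binomial exonic mutation load per tumor; over-dispersed so realized counts span roughly 28–185 |
| `universeSize` | 900 | cohort-wide pool of candidate sites (≈ 72.8 × 12, rounded up); makes the 2x2 fourth cell well defined |
| `rho` | 0.8 | clonal shared fraction: the planted shared set has size `round(rho * min(n1, n2))`; independent pairs use 0, so their overlap is pure chance, expectation ≈ n1 n2 / N |
| `spectrumWeights` | C>T-dominated | class weights .10/.08/.45/.07/.15/.15 give Ti:Tv exactly 1.5; CpG contexts triple-weighted within C>T |
| `depthMean`, `errorRate` | 428, 0.01 | depth ~ 1 + Poisson(427); alt reads ~ Binomial(depth, v(1−e) + (1−v)e/3) |
| `vafShape1/2`, `vafMin` | 2, 5, 0.05 | true VAF ~ Beta(2, 5) truncated at 5% — a field-typical choice, not estimated from data |
| `armEventFreqs` | 0.25 / 0.02 | gain probability 0.25 on 1q, 3q, 8q, 20q, 21q and loss 0.25 on 8p, 11q, 16q, Xq (the breast-cancer hallmark arms); 0.02 background per direction; about 3 events per tumor |
| `armTable`, `noiseSd` | 46 arms × 22 probes, 0.1 | scaled-down genome at 2.1 kb probe spacing (≈1012 probes); probe noise sd 0.1 (DLRS ≈ 0.1, inside QC) |
| `gainLog2`, `lossLog2` | +0.5, −0.6 | planted segment means |
| `dropoutRate` | 0 | probability that a planted shared variant's *call* is suppressed in tumor 2 while its reads are kept — the ground truth for rescue experiments |

Background read counts at sites not mutated in a tumor are drawn as
Binomial(depth, e) toward the alternate allele — exactly the null the rescue
test assumes — while reads at true variants use the cross-contamination rate
e/3 toward each other allele.

**What the generator does not emulate:** subclonal structure and phylogenies,
copy-number-driven VAF distortion, germline contamination, focal (sub-arm)
events, mapping artifacts, and real genome geometry. Passing tests on this
generator therefore demonstrate the statistical machinery under its stated
model, not performance on real sequencing data.

## Numerical and degenerate-input conventions

* Fisher tails, LR2 likelihoods: all accumulation in log space; the Fisher
  tail agrees with direct pmf summation to at least 10 significant digits
  over every table with N ≤ 60.
* `bhAdjust` validates inputs; `binomialRescueP` returns 1 at zero depth
  (with a warning) and at zero alt reads.
* `titvRatio` returns `Inf` with no transversions and `NaN` with no SNVs;
  `concordanceFraction` returns `NA` for an empty tumor.
* `dlrs` requires ≥ 3 probes and differences are taken within chromosomes;
  a zero noise estimate in `detectAberrations` falls back to a configured
  floor (1e-3).
* Coordinates are 1-based inclusive in every file format; chromosome names
  are normalized by stripping a leading `chr`; indels are accepted in
  catalogs and participate in exact-key matching but are excluded from
  spectra and Ti/Tv.
* Ambiguous-context SNVs are excluded from spectra and counted in a
  `skipped` tally so totals are conserved.
* All simulation is deterministic given a seed; `simulateCohort` shares one
  universe across its patients.

## Verdict rule

A patient is called **clonal** when the concordance q value or the LR2 p
value falls below `alpha` (default 0.05), **independent** when both are
available (or at least one, with the other missing) and neither is below
`alpha`, and **indeterminate** when neither component could be computed.
Spectrum adjacency is reported but never decisive: a pair can share
mutational processes without sharing origin, and one bilateral pair
clustering together should not overturn two null tests.

## Problem sizes used by the test suite and acceptance script

Calibration uses 500 independent pairs (type-I error) and 200 clonal pairs
(power); LR2 separation uses 100 clonal + 100 independent pairs with a
300-pairing reference null; spectrum recovery uses 100 six-pair cohorts per
condition; rescue uses 100 pairs at 30% planted dropout. These sizes give
standard errors comfortably below the margins being tested while keeping a
full run around a minute of compute; they are the package's chosen
trade-off, and all of them rerun from scratch at every invocation.

## Known limitations

* The concordance test conditions on a declared universe N; there is no
  universally correct N for real cohorts, only reasoned reconstructions.
* Arm-level LR2 sacrifices the power of probe-level statistics (see above);
  it is a decision statistic, not an estimate of clonal fraction.
* The verdict rule is a transparent threshold rule, not a calibrated joint
  model of the three evidence lines.
* Matching is exact-key; representation differences between callers (indel
  normalization, multi-allelic splitting) must be resolved upstream.
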