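---
title: "Drift or selection? Haplotype scans and coalescent simulation for continental allele-frequency contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift or selection? Haplotype scans and coalescent simulation for continental allele-frequency contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodrift)
```

## The scientific question

The stop-gain allele 577X of the *ACTN3* "athlete gene" (rs1815739, a C>T
transition on chromosome 11) climbs in frequency with distance from Africa
and peaks in Native American populations: pooled continental frequencies run
from about 0.09 in Africa to 0.48 in East Asia and 0.76 in the Americas.
Does the 0.29 East Asia → Americas jump require positive selection, or is it
compatible with the drift expected from the founder-effect demography of the
peopling of the New World?

`haplodrift` implements the full analytical toolkit this question needs:

1. **popdata** — pooling per-population biallelic frequency tables into
   regional groups and summarizing allele-frequency differentials;
2. **allele age** — the closed-form expected age of a neutral derived
   allele from its current frequency;
3. **haplostats** — extended haplotype homozygosity (EHH), relative EHH
   (REHH) and the integrated haplotype score (iHS) computed from first
   principles on phased panels;
4. **coalsim** — a structured-coalescent simulator of five demographic
   models of the Asia → America split, scored by the proportion of neutral
   SNPs whose inter-continental frequency differential reaches 0.29;
5. **synthdata** — forward Wright–Fisher generators of haplotype panels
   (neutral, or carrying a recent partial sweep) and of regional frequency
   tables, so the whole pipeline is testable without access to the original
   genotype panels.

## Population tables and differentials

A population sample is a row `(population, region, chromosomes = 2n,
derived_count)`. Frequencies are always derived from counts; a
frequency-dialect input is converted by rounding `frequency * 2n` to the
nearest integer so the count-based model stays universal.

Three conventions are fixed here and recorded in output metadata:

* **Pooling is chromosome-count-weighted**: a region's frequency is
  `sum(derived_count) / sum(chromosomes)`. This is the only convention that
  reproduces the frequency of the concatenated raw sample exactly, and it
  makes pooling invariant to splitting or merging sub-samples
  (`mergeSameName()` then `poolByRegion()` is a no-op against pre-merged
  data).
* **A "genotype" is diploid**: the default inclusion rule of at least 4
  genotypes means at least 8 chromosomes.
* **Quantiles are linear-interpolation (type 7)** and exceedance uses the
  closed comparison `differential >= threshold` ("at least 0.29").

```{r}
tab <- data.frame(population = c("pooled_americas", "pooled_east_asia"),
                  region = c("Americas", "East Asia"),
                  chromosomes = c(394L, 581L),
                  derived_count = c(301L, 277L))
poolByRegion(tab)
frequencyDifferential(0.764, 0.477)
```

## Allele age from frequency

For a segregating neutral allele at frequency $p$ the expected age in units
of $2N$ generations is

$$E(t_1) = \frac{-2p}{1-p}\,\ln p,$$

increasing from 0 (as $p \to 0$) to 2 (as $p \to 1$). `alleleAge()`
evaluates it and converts with a configurable $N$ (default 6000, a
conservative long-term human effective size) and generation time (default
25 years). The estimator is deliberately parametric in $p$: users supply
whichever frequency summary they consider appropriate (pooled versus
unweighted mean across populations), because the two can differ materially.

One documented inconsistency is worth flagging: at the pooled African
frequency $p = 0.093$ with $N = 6000$ the formula gives approximately 5,845
generations, i.e. ~146,000 years — roughly 2.4 times the 61,373-year figure
quoted in earlier work from the same inputs. The quoted figure is only
consistent with a different (unstated) frequency summary, and no formula for
its ±27,783-year bound is recoverable. The package therefore reports the
formula's value, carries a "point estimate only" flag, and makes no attempt
to reproduce the quoted number; the discrepancy itself is asserted in the
test suite so it cannot silently disappear.

## EHH, REHH and iHS

All three statistics run on a `HaplotypeMatrix`: phased chromosomes × sites,
entries polarized to 0 = ancestral / 1 = derived, strictly increasing
physical positions (1-based bp, 5' distances negative, 3' positive).

**EHH** at target site $x$ for a core allele is the probability that two
randomly chosen carrier chromosomes are identical at every site between the
core and $x$ inclusive. We use exact unbiased pair counting over
extended-haplotype groups,
$\sum_h \binom{n_h}{2} / \binom{n}{2}$,
rather than squared frequencies — this matches the "two randomly chosen
chromosomes" definition verbatim and is what the brute-force
pair-enumeration oracle in the test suite checks, exactly, on random panels.
Extending the span can only refine the grouping, so curves are
non-increasing away from the core by construction.

**REHH** divides the tested core allele's EHH by the pooled EHH of all
other chromosomes at the same span. The core here is a single SNP's allele,
so "all others" means all non-carriers of that allele. A comparison class
with zero homozygosity yields an infinite ratio with a warning, not an
error.

**iHS** integrates each allele's EHH decay over physical distance
(trapezoid rule) into iHH, truncating each side at the first site where EHH
drops below 0.05 (the canonical level, exposed as a parameter). If the
panel edge arrives first the result is flagged `edgeTruncated` rather than
silently extrapolated. The unstandardized score is
$\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$; negative values mean longer
homozygosity around the *derived* allele. Because raw scores depend
strongly on derived-allele frequency, scores are standardized within
equal-width derived-frequency bins (default 20, configurable; the package
errors on bins too sparse to estimate a spread instead of guessing) of a
reference score set, and significance is the two-sided Gaussian tail
$p = 2\Phi(-|z|)$ — standard practice when no permutation null is
available. No genetic map support is attempted: integration is in bp, since
the target use case has no recombination map; missing genotypes are not
supported (panels are phased and complete upstream).

```{r}
scen <- sweepScenario(populationSize = 150, nSites = 21,
                      selectionCoefficient = 0.1, targetFrequency = 0.6,
                      sampleChromosomes = 100)
hap <- simulatePanel(scen, seed = 9)
focal <- which(siteIds(hap) == "focal")
ihs(hap, focal)
```

## The coalescent simulator

`coalsim` asks how often *neutral* SNPs reach an inter-continental
differential of at least 0.29 under five demographies of the Asia/America
split (times in generations before present; sizes are effective population
sizes):

| Model | America at split | America now | Substructure |
|-------|------------------|-------------|--------------|
| A | 9000 (= Asia) | 9000 | none |
| B | 1350 (0.15 × Asia) | 1350 | none |
| C | 540 (0.06 × Asia) | 1350 (exponential growth) | none |
| D | as B | as B | 25 + 18 demes from T1 |
| E | as C | as C | 25 + 18 demes from T1 |

Asia is constant at 9000 in all models and the ancestral population takes
the Asian size; only America grows in C/E (rate
$\alpha = \ln(N_{present}/N_{split})/T_2$). This is the one reading under
which the stated 0.06-at-split and 0.15-at-present ratios are jointly
consistent with a fixed Asian size; whether the ancestral size should vary
by model is left as configuration. The study grid is $T_2 \in \{1001, 740,
500\}$ and, for D/E, substructure onset $T_1 \in \{295, 195, 75\}$, both an
island and a ring stepping-stone topology at 5% migration per generation,
and optional circumarctic flow: one Asian and one American deme exchanging
migrants at rate 0.0022 while isolated from their own continents (active
while demes exist, i.e. from the present back to $T_1$). Continental sizes
are split equally across demes; per-deme samples default to 8 chromosomes
(the 4-genotype inclusion rule), giving 200 Asian and 144 American
chromosomes.

Simulation runs backward in continuous time with exact exponential waiting
times; the time-inhomogeneous American coalescence rate under growth is
sampled by closed-form inversion of its integrated rate, not by
discretization. At $T_1$ demes merge into panmictic continents, at $T_2$
the continents merge into the ancestral population, which guarantees
coalescence. Each replicate places **exactly one mutation** uniformly on
the realized genealogy's total branch length (the fixed-S convention of
classic simulators), so every replicate SNP segregates in the combined
sample by construction and no mutation rate needs to be invented.

Two subtleties of this convention are deliberate and tested:

* Placing the mutation on the *realized* tree makes the site-frequency
  spectrum slightly singleton-rich relative to the textbook
  $P(i) \propto 1/i$, which is a ratio of expectations. Weighting
  replicates by total branch length recovers the analytic spectrum exactly;
  the simulator returns that length per replicate and the test suite checks
  both facts. An independent plain-R coalescent and (during development)
  msprime agree with both behaviours.
* The signed differential (America − Asia) is only sign-symmetric when the
  two continental sample sizes are equal — with unequal samples, singletons
  alone skew the sign — so the symmetry test uses equal samples, where
  exchangeability makes it exact. The headline statistic is the unsigned
  differential (a signed mode is available).

A third convention needs care: substructure *emerges* at $T_1$ and persists
to the present, so setting $T_1 = T_2$ maximizes the structured epoch
rather than removing it. The limit in which D/E provably collapse to B/C is
$T_1 = 0$ (a zero-duration structured epoch); the suite verifies that
distributional degeneracy with Kolmogorov–Smirnov tests at zero migration.

Per-model headline numbers average the exceedance over the model's
configured variants with equal weight (3 variants for A–C; 36 for D/E).
`scripts/acceptance.R` recomputes all five from scratch at 1000 SNPs per
variant — about a minute on one CPU.

### What the simulator reproduces, and what it does not

With the parameterization above, the no-bottleneck model A yields well
under 1% exceedance and the bottleneck-with-growth model C yields the
maximum (≈ 10–11%), matching the published 0.8% and 10.5% and the published
qualitative conclusion: a founder bottleneck, not selection, is the main
generator of large neutral continental differentials, and even then such
alleles remain rare. Model D lands near the published 6.9%.

Two published figures are *not* reproduced, and we report rather than hide
this. The constant-bottleneck model B yields ≈ 7–8.5% here (published:
1.8%), and model E ≈ 10.5% (published: 6.4%). The implementation was
cross-validated against an independent coalescent simulator on exactly the
model-B demography, so the gap is parametric, not a code defect. Two
observations locate it: the published per-model values do not average to
the published overall mean under any simple weighting, and a B → D jump of
1.8% → 6.9% from adding 5%-migration substructure is hard to reconcile with
coalescent theory (at $Nm \approx 3.75$ the pooled continental frequency is
barely affected — our D − B difference is a fraction of a point). The
unpublished per-deme sizes and sample layout, and the unstated averaging
scheme across variants, are the most plausible sources. All five numbers as
this package computes them are emitted by `scripts/acceptance.R`, and the
corresponding test states the published bands so the mismatch stays
visible.

## Synthetic data

`simulatePanel()` produces phased panels by discrete-generation forward
simulation: the focal allele follows a Wright–Fisher trajectory under
additive selection (fitnesses $1, 1+s/2, 1+s$), conditioned on first
reaching the target frequency (re-drawn on loss, with a retry cap that
errors loudly). Flanking sites start as standing neutral variation (counts
from the neutral spectrum $\propto 1/i$, assigned to random chromosomes)
and are transmitted with per-interval crossover probabilities proportional
to physical distance; a crossover switches the donor parent, so linkage to
the focal allele decays with distance and time. Default geometry mirrors
the empirical window the selection scan targets: ~30 SNPs over ~510 kb,
focal site centered.

This generator is intentionally lighter than an ancestral-recombination-
graph simulation: initial flank alleles carry no LD among themselves, new
mutations during the sweep are not modelled, and drift during a long
conditioned neutral trajectory erodes flank polymorphism — panels emulate
the *contrast* between sweep and neutral haplotype structure, not human LD
in detail. Passing tests therefore demonstrate correctness of the
statistics and the expected qualitative sweep signatures (derived-core EHH
decaying slower than ancestral-core; negative mean standardized iHS;
derived REHH > 1 at long range; ≈ 5% false-positive rate on neutral
panels), not calibrated power on real data. Exactness of genealogical
simulation is covered separately by the coalescent module's analytic
cross-checks.

`simulateFrequencyTable()` draws per-population frequencies from a beta
distribution around each regional mean (dispersion is the intraclass
correlation $\rho$; $\rho = 0$ pins populations to the mean) and binomial
derived counts at each population's chromosome count, optionally including
populations below the 4-genotype inclusion threshold so the filtering path
is exercised end to end.

## Numerical and testing choices

* All randomness flows through R's RNG — including inside the C++ kernels —
  so a single `set.seed()` (or the `seed` arguments / `--seed` flag)
  reproduces any run byte-for-byte; derived seeds stay below $2^{31}$.
* Outputs are annotated TSVs: a `# metadata` block (resolved parameters,
  seed, package version) precedes every table, and numeric columns are
  formatted at full precision (`%.15g`) for byte-stable re-runs.
* Test problem sizes are chosen to make Monte-Carlo bands decisive but keep
  the suite at desk scale: 1000 SNPs per variant for the headline
  ensembles, 2000–3000 replicates for distributional checks (KS, sign
  test, TMRCA), 8000–20000 cheap single-population replicates for spectrum
  checks, and ~50 forward panels for the iHS null. Statistical assertions
  use explicit error bands (3.3–4 standard errors, sized for any maximum
  taken over multiple comparisons) at fixed seeds.
* Degenerate inputs fail loudly with the offending row, site, sample or
  bin named: count > chromosomes, unphased genotypes, unresolvable
  ancestral alleles, spread-less standardization bins, fewer than two
  carriers at a core, trajectory retry exhaustion.

## Known limitations

* EHH variants requiring unphased data, genetic-map distances, XP-EHH and
  nSL are out of scope, as is haplotype phasing itself.
* The coalescent models exclude recombination (each replicate is one SNP)
  and selection; the forward generator covers linked neutral variation
  around a selected site instead.
* The published REHH values for the empirical Asian/European/American
  panels (5.5/4.4/5.3/5.6; 1.7/0.7) and the genome-wide HGDP differential
  summaries depend on genotype data that are not redistributable; they are
  covered qualitatively by the sweep-panel properties above, not
  numerically.
* Models B and E: see the reproduction discussion above.
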