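---
title: "Methods: clone discrimination and population genetics in clonepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clone discrimination and population genetics in clonepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonepop)
```

## The problem

Microsatellite surveys of clonal organisms sample *ramets* — physically
distinct individuals such as coral colonies — of which many may belong
to one *genet*, the product of a single zygote propagated asexually.
Treating ramets as independent samples biases allele frequencies toward
the most successful clones and corrupts heterozygosity, inbreeding and
differentiation estimates. clonepop implements the standard workflow for
such data: discriminate clones, describe the clonal architecture, then
compute population genetics on exactly one representative per lineage.

## Clone discrimination

**MLG assignment.** Two individuals share a multilocus genotype (MLG)
when their unordered allele pairs agree at every locus. A missing call
is treated as an allele different from everything, including another
missing call: missingness can split true clones (an effect the package
reports) but can never merge distinct genotypes. This is the
conservative convention for clone detection, and it is why the
individual-level filter (drop specimens missing more than one locus,
`max_missing_loci = 1`) is applied before clone discrimination.

**Allele distance and MLL collapsing.** Scoring errors and somatic
mutations typically create spurious MLGs one allele away from a real
clone. The pairwise distance is the number of allele differences summed
over loci (per locus: `2 - |multiset intersection|`). MLGs at distance
at most 1 are merged into multilocus lineages (MLLs) as connected
components of the distance-threshold graph — single linkage, so chains
A–B–C merge even when d(A, C) = 2; chained merges are recorded on the
result. For *distance* purposes two missing calls at the same locus
contribute 0 (an otherwise-identical pair sharing a failed locus still
merges into one MLL), while missing against scored contributes 2. The
asymmetry with MLG identity is deliberate: identity asks "are these
provably the same?", distance asks "could these plausibly be the same
lineage?".

**P_sex.** For an MLG observed $n$ times among $N$ samples, the
probability that the repeats are independent sexual products is, under
the Parks–Werth convention (the default),

$$P_{sex} = \sum_{i \ge n-1} \binom{N-1}{i} p_{gen}^i (1-p_{gen})^{N-1-i},$$

taking the focal individual as given; the alternative convention
counting successes among all $N$ draws is available
(`convention = "binomial_n"`). The genotype probability $p_{gen}$ is a
product over loci of $f_a^2 + f_a(1-f_a)F_{IS}$ for homozygotes and
$2 f_a f_b (1 - F_{IS})$ for heterozygotes. Defaults that matter:

* **Allele-frequency scheme** (`freq_scheme = "per_genet"`): one copy
  per MLG, so dominant clones do not inflate their own genotype
  frequency. A leave-one-locus-out round-robin scheme and a raw
  per-ramet scheme are available.
* **Inbreeding correction**: the pipeline feeds $p_{gen}$ the
  multilocus per-population $F_{IS}$ estimated on unique MLLs, floored
  at 0 — clonal datasets routinely show heterozygote excess
  ($F_{IS} < 0$), which would drive corrected homozygote probabilities
  negative; per-locus terms that still go negative are clamped to 0 with
  a warning.
* **Threshold** `psex_alpha = 0.001` below which repeats are called
  ramets of one genet.

## Clonal architecture indices

Richness $R = (G-1)/(N-1)$; the unbiased Simpson complement
$D = 1 - \sum n_i(n_i-1)/(N(N-1))$ with its attainable bounds
$D_{max} = N(G-1)/(G(N-1))$ (equal clone sizes) and
$D_{min} = 1 - (N-G+1)(N-G)/(N(N-1))$ (one dominant clone); evenness
$V = (D - D_{min})/(D_{max} - D_{min})$. At the dominant configuration
the numerator is analytically zero but naive evaluation leaves float
noise of order $10^{-16}$, so numerators below $10^{-12}$ are reported
as exactly 0; when every genet is a singleton ($D_{max} = D_{min}$) V is
reported as 1, and for a single genet it is undefined (`NA`). The
clone-size power law is fitted by least squares on
$\log(\text{number of MLLs of size} \ge x)$ versus $\log x$, weighted by
the cumulative counts: the unweighted fit lets the one-or-two largest
clones (cumulative counts of 1–2, the noisiest points on the curve)
dominate the slope, and in repeated simulation at 500 lineages it missed
a true $\beta = 1.5$ by more than 0.2 in roughly 40% of replicates,
versus 1% for the weighted fit. Two distinct sizes suffice to define
the (then exact) two-point fit.

## Diversity and locus QC

Per locus and population on unique MLLs: allele count, observed
heterozygosity, and expected heterozygosity reported as the plug-in
$H_e = 1 - \sum f_i^2$ with Nei's (1978) small-sample correction
alongside (`He_unbiased`). The plug-in form is the headline column
because it is the one under which the diagnostic all-heterozygote
two-allele pattern common in clonal populations yields exactly
$H_o = 1.00$, $H_e = 0.50$, $F_{IS} = 1 - H_o/H_e = -1.00$ at any sample
size. The Weir–Cockerham within-population $f$ is reported as a second
inbreeding estimator (the two differ at small $n$; neither is privileged
downstream). Allelic richness is rarefied to $m$ gene copies,
$AR = \sum_a [1 - \binom{2n-c_a}{m}/\binom{2n}{m}]$, with $m$ defaulting
to the smallest scored cell so every locus–population value is
comparable; private alleles are counted by direct cross-population scan.

QC screens follow field practice: a null-allele screen per locus
(Brookfield-1 $r = (H_e-H_o)/(1+H_e)$ driving the flag at $r > 0.1$
together with a one-sided homozygote-excess binomial test at
$\alpha = 0.05$; Chakraborty's $(H_e-H_o)/(H_e+H_o)$ — the consistent
estimator when null homozygotes are scored as blanks and excluded, which
is how this package renders them — is reported alongside), and
permutation tests for Hardy–Weinberg (allele shuffling within
population; statistic $|F_{IS}|$; frequencies and hence $H_e$ are
invariant, isolating genotypic pairing) and linkage disequilibrium
(log-likelihood-ratio G of the two-locus genotype table; one locus's
genotypes permuted). Both use the $(\text{hits}+1)/(n_{perm}+1)$
smoothed p-value and honor a mandatory seed. Linkage p-values are
Bonferroni-corrected within the pair family and a significant pair flags
both members — matching the practice of removing every locus showing
disequilibrium with others. Null-allele drops are applied first;
linkage is evaluated among survivors. The screens run on one
representative per provisional MLG (clone-corrected, since ramet
duplication would fabricate both homozygote excess and inter-locus
association), and dropped loci never reach downstream statistics.

## Differentiation

Weir & Cockerham's (1984) $\theta$ is computed from the per-allele
variance components $a$ (among populations), $b$ (among individuals) and
$c$ (within individuals), summed over alleles and loci; slightly
negative estimates near zero are expected sampling behaviour, not
errors. The $G$-family uses Nei & Chesser's sample-size-corrected
$H_S$ and $H_T$ (harmonic-mean $\tilde n$), averaged over loci before
forming $G_{ST}$, Hedrick's $G'_{ST}$ and Meirmans & Hedrick's

$$G''_{ST} = \frac{k(H_T - H_S)}{(kH_T - H_S)(1 - H_S)},$$

which equals 1 exactly — the identity survives the sample-size
corrections — whenever the populations share no alleles. The
standardizations multiply whatever sign $G_{ST}$ has, so the hierarchy
$G''_{ST} \ge G'_{ST} \ge G_{ST}$ is only claimed for nonnegative
differentiation. Permutation p-values reassign *genets* (never ramets)
between the two populations with sizes preserved.

## The synthetic generator

`simulate_dataset()` emulates the structure of a two-locality clonal
coral survey: per population, allele frequencies are drawn from the
Balding–Nichols model (Dirichlet with concentration
$p_{anc}(1-F)/F$, so the divergence parameter $F$ is what $\theta$
should recover); genets are drawn with an autozygosity probability
`f_is_sim`; clone sizes follow a configurable law (`dominant`,
`uniform`, `pareto`, or explicit counts); and observation noise is
layered on top — per-ramet one-repeat-unit scoring errors (the exact
process MLL collapsing exists to absorb), per-call missingness, and
null alleles rendered the way fragment analysis sees them (carriers as
apparent homozygotes, null homozygotes as blanks). Allele values are
plausible fragment sizes (base + repeat-unit multiples) so exported
GenAlEx files look like real scoring output. Everything is
deterministic under the seed and the full truth record is returned.

`make_paper_like_fixture()` instantiates the survey shape used
throughout the tests: species 1 with 23 ramets in 13 genets (largest
clone 4) and 24 ramets in 6 genets (dominant clone 19); species 2 with
24 ramets in 5 genets (dominant 14) plus 2 injected scoring errors, and
24 ramets in 3 genets (dominant 22) plus 3 errors — so its MLG counts
(7, 6) exceed its MLL counts (5, 3) and lineage collapsing must do real
work. Two construction choices make recovery exact rather than merely
likely: genets within a locality are rejection-sampled to pairwise
allele distance ≥ 3 (a single one-allele error moves any distance by at
most 1, so errors can never chain a ramet into a foreign lineage), and
the fixture carries no missing calls (a missing call would place a ramet
at distance 2 from its own genet and inflate the lineage count — the
overestimation real surveys acknowledge). The fixture represents an
already quality-controlled 8-locus panel, so pipeline runs on it disable
the QC stage (`run_locus_qc = FALSE`).

What the generator does *not* emulate: coalescent ancestry and mutation
dynamics (allele frequencies are drawn, not evolved), spatial clonal
architecture, allele-size homoplasy, and locus-specific error profiles.
Passing recovery tests therefore demonstrates correctness of the
estimators under the stated sampling model, not robustness to every
artefact of real fragment data.

## Pipeline order and determinism

`run_pipeline()` fixes the stage order: import → locus QC (on
provisional unique MLGs) → individual missing-data filter → clone
discrimination per population (two passes, the second feeding the
clone-corrected $F_{IS}$ into $P_{sex}$) → diversity → differentiation,
the last two on exactly one representative per MLL (the member with
fewest missing loci, ties by input order). The missing filter runs
after locus QC so that a specimen is not discarded for failing at a
locus that was about to be dropped anyway. All randomness derives from
the mandatory config seed; reruns are byte-identical, and the run log
records seeds, dropped loci and removed individuals.

## Problem sizes used by the test suite

Chosen as the package's own validation design: exhaustive Simpson
checks over all clone-size partitions up to $N = 12$; a $10^6$-draw
Monte-Carlo oracle for $P_{sex}$; type-I error of the permutation tests
over 400 panmictic replicates at 199 permutations each, with $n = 500$
(HWE), $n = 200$ (linkage) and $2 \times 20$ genets (differentiation) —
sizes at which the permutation distributions are effectively continuous;
at much smaller $n$ the tests are valid but conservative because of
ties. $\theta$ recovery uses 200 replicates of 10 loci × 100 genets per
population at $F = 0.10$.

## Known limitations

* $P_{sex}$ inherits the accuracy of the allele-frequency scheme; with
  very few genets the per-genet frequencies are coarse.
* MLL collapsing at threshold 1 can over-merge genuinely close sexual
  relatives in low-diversity panels; the chained-merge log should be
  inspected when lineage counts look surprisingly low.
* The linkage screen's both-members drop rule is conservative; with
  many loci it can discard more markers than necessary.
* Missing data inflate MLG/MLL counts by construction (missing matches
  nothing); the package reports, but cannot correct, this bias.
* Reproducing a specific published survey requires its raw allele-size
  files; the package ships only synthetic stand-ins shaped like such
  data.
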