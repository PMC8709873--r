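---
title: "Familial aggregation and rare-variant segregation: models and methods"
author: "famseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familial aggregation and rare-variant segregation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famseg)
```

# The scientific problem

Extended multi-generation families with a striking excess of a rare
phenotype — here, suicide death, but the machinery is phenotype-agnostic —
are a classical resource for genetic risk discovery: the same risk factors
recur in many distantly related cases, so a rare variant shared by affected
relatives separated by many meioses is far more informative than the same
variant seen in unrelated cases. Turning that intuition into numbers takes
three pieces of statistical machinery, and this package implements all
three against a single, fully specified null model:

1. **Which families are high-risk?** Compare each family's observed number
   of affected members with the number expected under stratified
   population rates (aggregation module).
2. **Which variants are worth pursuing?** Apply explicit, auditable filter
   rules to annotated variant tables (variant-filter module).
3. **Could the observed sharing be chance?** Compute the nominal
   probability that all observed carrier cases in a family carry a variant
   of population frequency $q$ under null transmission (segregation,
   peeling and gene-drop modules).

# Familial aggregation

For family $i$, each member with known affection status contributes their
stratum's cumulative lifetime risk to the expected count $E_i$ (strata are
sex by birth-cohort band; a person-year mode, rate $\times$ years at risk,
is available when birth and death years exist). With observed count $O_i$,
the standardized incidence ratio is $O_i/E_i$ and familial significance is
the exact one-sided Poisson upper tail

$$p_i = P(X \ge O_i), \qquad X \sim \mathrm{Poisson}(E_i),$$

with the conventional ascertainment threshold $p < 0.01$. Two design
points deserve justification:

* **Why an exact Poisson tail?** Per-family expected counts are far below
  one (a 200-member family at ~1–2% lifetime risk expects 2–3 affected;
  small branches expect far less), so normal approximations to the SIR are
  invalid. The exact tail is also conservative under discreteness: in the
  calibration experiments below the realized type-I rate at
  $\alpha = 0.01$ is about 0.4%, never above nominal.
* **Members with unknown affection status are excluded from both the
  observed and the expected count**, so unobservable members cannot bias
  the ratio in either direction.
* No multiple-testing correction is applied to the headline flag (the
  threshold is a fixed nominal ascertainment rule); a Bonferroni-adjusted
  flag is reported as supplementary output.

Whether historic ascertainment used lifetime cumulative risk or
person-year standardization is not knowable from published counts; both
modes are implemented and neither is claimed to reproduce any particular
historical family count, which would also require the underlying
population database.

# The segregation null model

All sharing probabilities refer to one fully specified null model:

* every pedigree founder's genotype is Hardy–Weinberg at allele frequency
  $q$ (two i.i.d. Bernoulli($q$) alleles);
* every non-founder receives one uniformly chosen allele from each parent
  (fair Mendelian transmission, one biallelic locus, no linkage, no
  mutation, no genotyping error);
* a *carrier* is an individual with at least one copy (all carriers of
  interest in the motivating data are heterozygous, so no homozygote
  refinement is attempted);
* $q$ defaults to the control-population frequency of the variant, since
  the null hypothesis is population transmission, not case enrichment.

Three independent routes evaluate this model, and the package requires
them to agree:

**Closed form on the connecting subgraph.** `connectingSubgraph()` finds
the transmission tree of minimum meioses $M$ linking the carriers — a
directed Steiner tree in the parent-to-child graph, solved exactly by the
Dreyfus–Wagner subset dynamic programme (carrier sets are small, so the
$2^{|carriers|}$ table is cheap, and the search is exhaustive over apex
ancestors, so inbreeding loops are handled). The headline
single-introduction term is

$$p_{\text{single}} = \left(1 - (1-q)^{2c}\right) \cdot (1/2)^{M},$$

where $c$ is the number of individuals in the apex introduction point: a
founder couple counts as **one** introduction point with $c = 2$ (either
spouse may have introduced the allele), while an apex that is itself a
carrier has $c = 1$. Every co-parent along the tree is a marry-in founder,
an independent potential source with carrier probability $1-(1-q)^2$.
`closedFormSharing()` enumerates all $2^{1+m}$ carrier/non-carrier
configurations of the apex and the $m$ marry-ins, evaluates each
configuration's sharing probability exactly on the tree, and sums them —
by the law of total probability this equals the exact sharing probability
whenever the pedigree is loop-free and spouses are unrelated to the
lineage. The per-configuration table is returned so the decomposition can
be inspected. Beyond 12 sources the multi-introduction configurations are
folded into a single remainder term (the sum stays exact; only the table
is condensed).

**Exact peeling.** `exactPeeling()` prunes the pedigree to the ancestral
closure of the carriers and runs variable elimination over per-individual
genotype variables (founder Hardy–Weinberg priors, Mendelian transmission
factors, carrier evidence) — the general-pedigree form of Elston–Stewart
peeling, exact through loops. The exactness bound of 25 pruned
individuals keeps the dense elimination tables small; larger problems are
referred to gene dropping.

**Gene dropping.** `geneDrop()` simulates the null model directly,
vectorized over replicates, with a Wilson 95% interval (chosen over Wald
because the probabilities of interest are near zero). The RNG stream is
keyed by (family, variant, seed), so cohort simulations are
order-independent and bit-exact reproducible.

## Which probability is "the" segregation probability?

Three quantities are computed and reported side by side:

* `pAnySharing` — the unconditional probability that **all** carriers
  carry; this is the headline nominal probability of the observed
  configuration arising under null transmission.
* `pConditional` — `pAnySharing` divided by the probability that the
  **index case** carries. Conditioning on a designated index (the
  lexicographically smallest carrier id by default) reflects that the
  variant was discovered in one case before its relatives were examined,
  and yields the textbook rare-allele limits: a sibling pair tends to
  $1/2$ as $q \to 0$, first cousins to $1/8$, and a single carrier is
  exactly 1. (Conditioning instead on *at least one* carrier carrying
  gives a sibling limit of $1/3$; that probability is reported as
  `pAtLeastOne` so either convention can be formed.)
* `pSingleIntroduction` — the closed-form leading term above. It is a
  strict lower bound on `pAnySharing` and is exactly halved by each
  additional meiosis, which makes it the convenient reporting scale for
  "how surprising is sharing across $M$ meioses".

One ordering subtlety is worth recording because it contradicts the naive
expectation: at fixed $q$, a sibling pair's unconditional sharing
probability slightly *exceeds* a parent–child pair's
($q + 1.25q^2$ vs $q + q^2$, to second order) even though the
relationships have equal kinship — the two parental genomes above siblings
provide one more independent introduction route. First cousins sit well
below both. All three computation routes agree on this, including the
brute-force enumeration oracle in the test suite.

## Numerical choices

Probability sums stay in double precision throughout. The smallest
quantities the package is asked for (e.g. $q = 10^{-6}$ through 12
meioses) are of order $10^{-10}$, nearly 300 orders of magnitude above
double underflow, and the elimination and tree recursions multiply only a
handful of factors, so log-space accounting would add complexity without
measurable benefit. Ties in the Steiner search (several apex candidates at
the same meioses count) are broken by preferring an apex couple and then
the lexicographically smallest id; all tied candidates are reported in the
result's `ties` slot. Degenerate inputs (empty carrier sets, $q$ outside
$(0,1)$, expected counts $\le 0$, half-specified parentage, ancestry
cycles) raise structured conditions rather than producing numbers.

# Variant filtering

Two stages mirror the two discovery designs, as conjunctions of explicit
predicates with first-failing-rule attribution (so a report's elimination
tally always sums to the input count):

* **family-shared**: carrier count among the family's sequenced cases
  equals the required number (default 6) → rare (MAF < 0.01) in *every*
  control panel → impact severity HIGH or MODERATE ("MEDIUM" is accepted
  as a spelling of the same tier).
* **cohort functional**: missense consequence → SIFT deleterious *and*
  PolyPhen probably/possibly damaging → at least 5 carrier cases (a
  homozygote counts once) → case allele frequency ≥ 0.001 → frequency
  < 0.01 in every control panel. The carrier-count and case-frequency
  rules coincide for a cohort of ~4400 cases but are enforced
  independently.

Frequencies are always compared at full precision; the 4-decimal rounding
(`displayFrequency()`) is a display convention only. Case-control
comparison uses Fisher's exact test on the 2×2 allele-count table, with
the Haldane–Anscombe 0.5 correction applied to the odds ratio when a cell
is zero. A record missing a required annotation is tallied under an
`unannotated` rule rather than raising an error, so one bad row never
aborts a screen.

# What the synthetic generator emulates — and what it does not

`generatePedigree()` grows a monogamous branching process: one apex
founder couple, Poisson(`meanOffspring`) children per couple (the apex
draw is zero-truncated — an ascertained family always has descendants —
giving the size expectation
$E[L_2] = m/(1-e^{-m})$, $E[L_g] = E[L_2]\,m^{g-2}$, implemented in
`expectedPedigreeSize()`), and a brand-new founder spouse for every member
with children. Defaults are 7 generations and mean offspring 2, echoing
the 7–9 generation depth of extended genealogies, which yields families of
roughly 200 members. Affection is assigned independently at the member's
stratum rate times a lineage risk multiplier; the default rates (2% male,
0.5% female lifetime risk, one birth-cohort band) approximate US/Utah
sex-stratified suicide mortality. `plantVariant()` introduces one allele
copy at a founder and, optionally, forces it down a shortest descent path
to every affected lineage descendant (the upper-bound alternative; flagged
non-Mendelian-null in the truth sidecar, though the realized genotypes
remain Mendelian-consistent since forcing only conditions transmission
outcomes).

The generator deliberately omits: within-pedigree remarriage and
consanguinity (so marry-ins really are independent population draws —
which is exactly the assumption of the closed form; the peeling and
gene-drop engines do not need it), realistic demography (mortality,
cohort effects, assortative mating), liability-threshold correlation of
affection beyond the shared multiplier, and genotyping error. Passing
tests therefore demonstrate internal correctness of the statistics under
the stated model, not robustness to the messiness of real genealogies —
in real data, pedigree errors and cryptic relatedness would push sharing
probabilities upward.

# Problem sizes used by the checks

The test suite and the acceptance script fix their own scales: gene-drop
oracle comparisons run $10^6$ replicates per fixture-frequency pair
(agreement required within 3 binomial standard errors, on 5–6 fixtures
across $q \in \{10^{-4}, 10^{-3}, 10^{-2}, 0.1\}$); closed form and
peeling must agree to $10^{-9}$; rare-allele limits are checked at
$q = 10^{-6}$ with tolerance $10^{-4}$; aggregation calibration uses
10,000 null families at the generator defaults plus a planted-recovery
cohort of 400 families with a 10× multiplier in 5%. These sizes give
Monte Carlo resolution comfortably below every tolerance asserted.

# Known limitations

* The closed form treats every co-parent as an unrelated population draw;
  on pedigrees with loops or related spouses it is an approximation, and
  `exactPeeling()`/`geneDrop()` are the authoritative routes.
* The exact peeling bound (25 pruned individuals) is conservative for
  chain-like closures; it exists to cap the dense elimination tables, not
  because the algorithm breaks — beyond it, gene dropping at $10^6$–$10^7$
  replicates resolves the probabilities of interest.
* Historical cohort quantities that depend on proprietary population
  databases (total high-risk family counts, exact expected counts) are
  out of reach by construction; the package reproduces the arithmetic and
  the statistical behaviour, not the private data.
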