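---
title: "Estimating X-chromosome recombination and mutation rates from pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating X-chromosome recombination and mutation rates from pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrecomb)
```

## The problem

Forensic kinship analysis with X-chromosomal markers combines tightly linked
STRs (and, increasingly, SNPs and indels) into haplotypes, which requires
precise per-interval recombination rates between adjacent markers.
Recombination on the X happens only in female meiosis, and mutations —
common for STRs — confound naive counting of recombinants. The accepted
approach estimates both rate vectors jointly by maximum likelihood from
pedigree data, summing the exact probability of every inheritance
configuration. `xrecomb` implements that estimator end to end: PED parsing,
family extraction, phasing, exact likelihoods, bounded optimization, and a
ground-truth simulator.

## The model

A haplotype over the panel's $n$ markers is a vector $x = (x_1, \dots,
x_n)$; STR alleles are repeat counts (possibly fractional, e.g. 9.3),
non-STR alleles are coded as distinct negative integers. Let $m = (m^1,
m^2)$ be a mother's two haplotypes and $c$ a child's maternal haplotype —
read directly from a son's genotype (males are hemizygous), or obtained for
a daughter by subtracting her father's haplotype. An inheritance vector
$v \in \{1,2\}^n$ records which maternal haplotype each marker descends
from; switches between adjacent markers are recombinations. Given
recombination rates $\theta = (\theta_1, \dots, \theta_{n-1})$ and mutation
rates $\mu = (\mu_1, \dots, \mu_n)$,

$$
L(c \mid m, \theta, \mu, v) \;=\;
\prod_{i=1}^{n-1}\bigl(\theta_i + (1 - 2\theta_i)\,\delta(v_i, v_{i+1})\bigr)
\;\cdot\;
\prod_{i=1}^{n} p_i^{*}\!\left(m_i^{v_i},\, c_i\right),
$$

and the child likelihood sums this over all $2^n$ inheritance vectors. The
mutation kernel $p_i^{*}$ depends on the marker type:

* **STR (stepwise):** $1-\mu_i$ on a match, $\mu_i$ for a change of exactly
  one repeat unit, $0$ otherwise — multi-repeat and partial-repeat changes
  are excluded. Fractional repeats are compared exactly (internally in
  tenths of a repeat), so $|9.3 - 10.3|$ is one step.
* **non-STR (transition/transversion):** $1-\mu_i$ on a match,
  $\tfrac{9}{10}\mu_i$ for a transition (single-base A$\leftrightarrow$G or
  C$\leftrightarrow$T), $\tfrac{1}{10}\mu_i$ otherwise (transversions,
  indels, any multi-base change).

Neither kernel is a normalized distribution over target alleles (an
interior STR allele has total outgoing mass $1 + \mu_i$); they are applied
exactly as defined, without renormalization, since the estimator only
compares likelihoods across rate values.

Families enter the likelihood in two forms:

* **Type I** — the mother's own father (the maternal grandfather) is
  genotyped, so her phase is known; children are independent meioses and
  the family likelihood is the product of child likelihoods. One child
  suffices.
* **Type II** — no grandfather; the likelihood additionally sums over all
  $2^{h-1}$ maternal phasings compatible with her genotype ($h$ =
  heterozygous markers). At least two children are required for the family
  to carry linkage information.

### Two engines, one value

The *direct* engine enumerates all $2^n$ inheritance vectors — exponential,
readable, and kept as the reference implementation (refused above 20
markers). The *dynamic* engine computes the same sum by a forward recursion
over a two-state chain, $f_1(s) = p^*_1(m_1^s, c_1)$ and

$$
f_{i+1}(s') = p^*_{i+1}(m_{i+1}^{s'}, c_{i+1})
\sum_{s} f_i(s)\,\bigl[\theta_i \text{ if } s \neq s' \text{ else } 1-\theta_i\bigr],
$$

which is linear in $n$. It is written in C++ and rescales the state vector
at every marker, accumulating log scale factors, so likelihoods remain
finite in log space at 10,000 markers. For type II families the dynamic
engine branches depth-first through the heterozygous markers, sharing the
partial forward states of all children along each branch and pruning a
branch as soon as any child's partial likelihood hits zero; the result is
identical to exhaustive enumeration (this is asserted to 1e-12 relative in
the test suite against an independent oracle that enumerates ordered
phasings naively and halves). Phasings are counted *unordered*: the phase
is anchored at the first heterozygous marker, because relabeling the two
haplotypes leaves every child likelihood unchanged.

Two printed-formula choices deserve a note. First, the inheritance vector
is given length $n$ (not $n-1$): the sum over $\{1,2\}^n$ and a mutation
product indexing $v_i$ up to $n$ are only mutually consistent with the
length-$n$ reading. Second, no $\tfrac12$ prior is placed on the initial
inheritance state; it would be a constant factor with no effect on the
maximizer, and omitting it keeps absolute values comparable to the formula
as written.

## Estimation

`estimate_rates()` minimizes the dataset negative log-likelihood with
L-BFGS-B under box bounds $[\varepsilon, 0.5]$, $\varepsilon = 10^{-8}$
(the rates live in the half-open interval $(0, \tfrac12]$; a strictly
positive lower bound keeps the objective finite). Defaults: $\theta_0 =
0.1$, $\mu_0 = 0.001$ (mid-range values away from the bounds; the
literature does not prescribe a starting point), iteration cap 15,000.
Finite-difference steps are set to $10^{-6}$ — the `optim` default of
$10^{-3}$ exceeds the mutation-rate scale and derails the line search when
an estimate sits near a bound. Mutation rates can be estimated per marker
(default), shared across markers (one pooled rate — preferable when the
expected number of mutation events per marker is small, since a per-marker
estimate with zero observed events collapses to the lower bound), or fixed.

Non-convergence is reported, never hidden: the fit carries `converged` and
the optimizer message, and the CLI exits with a dedicated status. After
fitting, each free parameter is probed for flatness (likelihood unchanged
to $10^{-11}$ under $\pm 10^{-5}$ perturbation); a flat direction — e.g. an
interval whose flanking marker is missing in every child — is warned about,
since its "estimate" is just the initial value.

Zero-likelihood families (data more than one mutation step from every
explanation) are a hard error naming the family, not a silent `-Inf`: they
signal data incompatible with the single-step model.

## Preprocessing

`parse_ped()` reads the standard 6-column PLINK PED dialect. Males must
carry a duplicated allele (there is no hemizygous convention in PED); two
*different* alleles for a male is an error rather than a silent pick.
Marker types are inferred (all-numeric alleles, at most one decimal digit →
STR; anything else → non-STR), overridable by a two-column marker-info
file. Marker order is the PED column order. The missing sentinel `0`
becomes `NA` internally and never collides with a real allele.

`extract_families()` walks each connected component of the parent–child
graph and examines every genotyped mother independently, so one deep
pedigree can yield several families, and a female phased through her own
father can serve as a phased mother for her children. Conflict policy: a
grandfather–mother conflict at any marker voids the phase (the mother may
still found a type II family); a father–daughter conflict excludes that
daughter. Both are warnings with individual IDs — such conflicts imply a
paternal-line mutation, which the model does not cover, so the data are set
aside rather than force-fitted. Mothers with missing genotype markers are
skipped (summing phasings over unknown alleles would square the phasing
set); a child's missing marker is fine and contributes mutation factor 1
while recombination factors chain through it. Daughters whose father is
not genotyped are excluded rather than summed over their own phase — an
unphased daughter's contribution is not described in the estimation
framework this package follows.

## The simulator

`simulate_pedigrees()` generates the world the estimator assumes: mothers
with independently drawn haplotypes; children produced by an explicit
inheritance vector (uniform initial state, switch probability $\theta_i$)
and per-marker mutation; fathers for daughters; a grandfather carrying one
maternal haplotype for type I families; female genotypes stored sorted,
erasing phase. Choices where the stated procedure is silent:

* **Allele pools:** STR repeat counts uniform on 8–20 (a realistic forensic
  STR allele range); non-STR alleles uniform over the configured set
  (default `{A, G}`, i.e. a SNP). No Hardy–Weinberg or LD structure is
  modeled — founder haplotypes are exchangeable, which is exactly the
  regime the likelihood assumes.
* **STR mutation:** one step up or down, each with probability $\mu_i$; a
  step out of the pool is redirected inward so alleles stay representable.
  Total mutation mass is $2\mu_i$ per meiosis per marker, matching the
  kernel's mass at interior alleles.
* **Non-STR mutation:** each alternative allele gets mass
  $0.9\mu_i$ (transition partner) or $0.1\mu_i$ (otherwise); with a
  two-allele pool the single alternative receives the full $\mu_i$ mass —
  a documented deviation from the 9:1 split, which needs at least two
  alternatives.
* **Family size:** two children per family by default (typical of published
  pedigree panels, and the minimum informative size for type II).
* Mutations are single-step only, consistent with the likelihood's support.

Identical seeds give byte-identical PED files. Non-STR codes are
canonicalized to first-appearance order in the emitted file (and non-STR
female pairs are written in that order), so `parse_ped(write_ped(x))` is
the identity — the round trip is asserted in the tests.

A green simulation-based test therefore establishes internal consistency —
the estimator recovers the parameters of the process it models — not
robustness to real-data features the generator omits: genotyping error,
population allele-frequency structure, multi-step STR mutations, or
paternal-line mutations (which surface as phasing conflicts and are
excluded with warnings).

## Numerical and scale limits

* Type I likelihoods are linear-time; panels of 10,000 markers evaluate in
  well under a second per family (log scale).
* Type II cost doubles per heterozygous marker. A guard refuses type II
  likelihoods beyond 25 markers by default (`marker_cap` /
  `--max-markers-typeII`), overridable; practical panels reach roughly 21
  markers.
* The direct engine is a validation tool and refuses more than 20 markers.
* Estimation-time validation in this package's acceptance suite runs the
  216 + 185-family scenario at 10 markers (rather than the original 12) to
  keep the run inside a desk-scale time budget; the reduction is in marker
  count only, never in tolerance.

## Known limitations

No confidence intervals or standard errors (not part of the framework
reproduced here); no kinship likelihood-ratio computation; no
population-based (LD) recombination inference; single-step STR mutation
model only; bounded local optimization from one starting point (no
multi-start), with convergence failures reported honestly — the reference
framework itself reports failures near 130 markers.
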