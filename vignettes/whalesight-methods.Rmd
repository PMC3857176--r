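---
title: "Methods and design notes for whalesight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for whalesight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`whalesight` analyses long-term records of individually identified whales on
a coastal feeding ground. This vignette documents the statistical models it
implements, the parameters that matter and their defaults, the numerical
conventions, what the synthetic-data generator does and does not emulate,
and the design choices that were genuinely open.

## The encounter store

All analyses run over a validated store of three tables: individuals
(identity, sex, age class, identification features, mother link), encounters
(dated group observations with an estimated total group size), and the
membership relation. Validation enforces the structural facts every
downstream statistic relies on: unique ids, non-empty groups, no duplicated
member within a group, and an estimated group size at least the number of
identified members — field groups routinely contain animals that were never
photographed or biopsied, so the estimate may exceed the membership count
but never undercut it. Dates are calendar days (ISO 8601); an integer
sighting number orders encounters within a day. Sub-day clock times carry no
analytical weight in this kind of study, so they are deliberately out of the
data model.

Two derived labels drive most analyses. An individual is **resighted** when
it appears in at least two encounters; two encounters on one day already
qualify, because the encounter — a discrete data-collection event with one
group — is the sampling unit throughout. A group is **familiar** when it
contains at least one resighted whale.

## Attendance

Seasonal statistics use a 12-month **seasonal cycle** from 1 April to
31 March. Whales over-summer on this kind of mid-latitude ground; a cycle
boundary in austral autumn keeps a single visit from being split across two
analysis units. **Occurrence** counts distinct sighting days per cycle.
**Occupancy** is the whole-day difference between last and first sighting
dates in the cycle — counted from the day after the first sighting, so
consecutive-day sightings give 1 — and is reported only for animals seen on
two or more days. Both are invariant to shifting all dates by a constant
(within a cycle) and are checked against a naive day-recount oracle on
randomized stores.

The **operational sex ratio** is computed from (individual, day)
identification events of known-sex individuals, pooled by seasonal grouping
(May–Jul, Aug, Sep, Oct, Nov, Dec, Jan–Feb) across years. Pooling counts —
rather than averaging daily ratios — was an open choice; pooled counts are
stabler at the low daily sample sizes typical of boat surveys, and the
per-grouping chi-square against parity then has a clean sampling
interpretation. March and April belong to no grouping and are excluded with
a reported count. Calves of the year are excluded by default since their
presence tracks their mother's, not the breeding pool; unknown-sex whales
are excluded rather than raising errors, because unsexed individuals are a
routine feature of photo-identification data.

The parity test is the closed-form 1-df goodness of fit
`(f − m)²/(f + m)`, with Yates' continuity correction available but off by
default; the correction is applied only where a 2×2 comparison of two
classes' sex ratios is requested (`sex_ratio_comparison()`), which is the
conventional place for it.

Group-size summaries compare familiar and unfamiliar groups in four
variants: all groups, groups larger than one, and both again with the single
largest group per class removed — large feeding aggregations are rare and
a single outlier can carry a t-test. The t-test uses the pooled-variance
form. Degenerate inputs are defined rather than fatal: classes with fewer
than two groups omit the test with a warning, and two zero-variance classes
with equal means report t = 0, p = 1.

## Associations

The dyadic index is the half-weight association index at encounter level,

\[ \mathrm{HWI}_{ab} = \frac{X}{X + \tfrac{1}{2}(Y_a + Y_b)}, \]

with `X` the number of encounters containing both members and `Y_a`, `Y_b`
the counts of one without the other. This is the only half-weight form that
is symmetric in the pair, bounded by 1, and equal to 1 exactly when the dyad
co-occurs in every encounter of either member; with the encounter as
sampling unit there is no "same sampling period but different groups" term.
Same-day repeat encounters count separately — at small group sizes and
sparse coverage, within-day associations are real signal, not
pseudo-replication to be collapsed.

Only resighted individuals seen at least once with another resighted
individual enter the matrix: a resighted whale only ever seen alone or with
once-seen animals contributes no dyadic information to the resighted pool.
Per-individual **mean HWI** averages over *all* other eligible individuals,
zeros included. This was open (one could average over observed associates
only); the all-partners denominator makes the mean interpretable as an
individual's average connectedness to the study pool and scales correctly as
the pool grows. Computation is at full precision; rounding to the nearest
0.1 (half up — conventional display precision for association networks)
happens only at export, where edges also carry the exact value and a flag
for the display threshold (default 0.3). The matrix is checked exactly
against a brute-force triple-loop oracle on randomized stores.

## Relatedness

Pairwise relatedness uses the standard non-inbred genotype-pair likelihood.
At one locus, conditional on the pair sharing 0, 1 or 2 alleles identical by
descent, the probability of an unordered genotype pair is `P0` (the product
of the two Hardy–Weinberg genotype probabilities), `P1` (HW probability of
the first genotype times the transition probability that the second arises
given one IBD-copied allele), and `P2` (the HW probability when the
genotypes are identical in state, else 0). The implementation computes all
three from a single vectorised kernel; unit tests pin the resulting
seven-case table (e.g. identical homozygotes: `P2 = p²`, `P1 = p³`,
`P0 = p⁴`) and verify that for any IBD coefficients the probabilities over
all genotype pairs sum to one, to 1e−9, across random frequency vectors.

The multilocus log-likelihood sums loci typed in both members (pairwise
deletion), guarded by `min_loci` (default 6 of 10: complete genotypes are
the norm in curated panels, and below six loci the four hypotheses are
rarely separable). Maximisation over the `(k0, k1, k2)` simplex is
deterministic: a coarse grid (step 0.05, always including the four fixed
hypothesis points, so the unconstrained maximum can never fall below a fixed
hypothesis) followed by Nelder–Mead refinement at relative tolerance 1e−8.
Stochastic restarts were rejected: reproducibility of every reported
estimate matters more than marginal likelihood gains on a 2-simplex where
the grid already brackets the optimum. Classification evaluates
U > HS > FS > PO in that preference order, switching only on a strict
improvement — exact ties resolve to the less related hypothesis, which is
conservative against false kinship claims.

Allele frequencies come from direct counting over the full panel, focal
pair included (the convention of likelihood relatedness estimators; an
`exclude` argument is available). **Null alleles** are off by default. When
enabled, each locus receives a null frequency from the homozygote-excess
estimator `(He − Ho)/(He + Ho)` truncated at zero, visible frequencies are
rescaled to `1 − null`, and an observed homozygote is treated as an
ambiguity class — the likelihood sums over the true homozygote and the
null-heterozygote interpretation, with the null as an extra allele in the
same kernel. This is a documented approximation, adequate for flagging
PO-incompatibilities that nulls would otherwise cause.

**PO compatibility** requires one shared allele at every locus typed in
both, plus matching mtDNA haplotypes when both are known and the putative
link is maternal (fathers transmit no mtDNA, so `maternal = FALSE` drops the
haplotype requirement). **PO vs FS**: both hypotheses fix r = 0.5, so the
package simulates genotype pairs under the FS alternative and reports the
upper-tail fraction of `Λ = lnL(PO) − lnL(FS)`. Simulating the alternative
(rather than the PO null) was an open reading of the procedure; it was
chosen because the resulting p-value directly measures how often true full
siblings would look as PO-like as the observed pair, which is the error the
census must control, and the choice is calibrated by test: under
FS-simulated "observed" pairs the rejection rate at α = 0.05 is required to
sit in 0.05 ± 0.02 over 1000 replicates at 10⁴ simulations each. The
default `n_sim` for production use is 10⁶; tests and examples use 10³–10⁴.

A known limitation, exercised deliberately by the test suite: the
unconstrained MLE of r is truncated at the simplex boundary, so for truly
unrelated pairs its mean is positive — about 0.058 at 10 loci × 8
equifrequent alleles in the packaged simulation check, with the optimiser
verified exact against an exhaustive fine grid. This boundary bias is a
property of the estimator itself, not of the implementation, and should be
kept in mind when averaging r over many unrelated dyads.

## The synthetic-data generator

`scenario_wsa_default()` fixes the study conditions the package is
validated under: a pool of 300 identifiable whales over the 14 seasonal
cycles 1993/94–2006/07; boat effort drawn per month with a spring-heavy
calendar (October ≈ 7 and November ≈ 6 effort days per cycle, mid-winter
≈ 1); sex-specific annual return probabilities (females 0.40, males 0.30)
and arrival-month distributions (females peaking in October, males spread
over late winter–spring, cow–calf pairs arriving December–February);
exponential residencies of mean 30 days truncated at the cycle end; a
per-present-individual daily detection probability of 0.04; groups of
1 + Poisson(1.2) detected units with a 3% chance per day of one large
aggregation (up to 20) and a 4% per-individual chance of a second same-day
encounter; and an estimated group size adding Poisson(1.0) unidentified
animals. Genotypes use 10 loci with 8 alleles (Dirichlet frequencies,
concentration 1.5) and 12 mtDNA haplotypes; 12 mothers carry 1–3 calves at
1–3-year intervals, fathers are sampled into the panel with probability
0.3, and three families contribute full-sibling pairs. Founders are drawn
from Hardy–Weinberg; offspring inherit one uniformly chosen allele per
parent per locus and the mother's haplotype; biopsies — hence genotypes and
known sex — exist only for encountered whales.

Under the default seed this yields 185 identified individuals in 240
encounters, 69 of them resighted, a mid-spring operational sex ratio of
about 1 F : 0.6 M, and mean estimated group sizes near 2.2 — the scale of
the motivating study system. The detection probability was set by pilot
runs against those observable targets and is not revisited.

What the generator does **not** emulate: spatially explicit movement (all
locations are labels with jittered coordinates), effort gaps correlated
with weather, identification error (ids are exact; the retrospective
linking of photographic and genetic identities is assumed done upstream),
genotyping error, age-dependent detectability, and strandings. Passing
tests therefore demonstrate correctness of the computations and calibration
of the statistical procedures under a realistic sighting process — not
robustness to misidentification or genotyping artefacts in field data.

## Problem sizes used in the packaged checks

Oracle-equivalence suites run 200 randomized stores of up to 10 individuals
and 20 encounters (exact agreement required). Likelihood conservation sweeps
50 random frequency vectors of up to 6 alleles at all four fixed hypotheses
(tolerance 1e−9). Parameter recovery simulates 500 pairs per relationship at
10 loci × 8 equifrequent alleles; PO-vs-FS calibration uses 1000 replicates
of 10⁴ simulations. The end-to-end scenario runs the full default
configuration through every reporting step.
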