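---
title: "Scanning classification trees for healthcare-utilisation clusters in matched child cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning classification trees for healthcare-utilisation clusters in matched child cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

utilscan implements a register-style analysis of early-childhood healthcare
utilisation in a matched cohort: children with an exposed parent (here, a
parent with a lymphoma history predating the child's birth) compared with
1:5 matched children of unexposed parents, followed from birth to age five.
The package covers the whole chain — synthetic registry generation, cohort
construction with sampling weights, person-time rates with exact intervals,
mean cumulative counts under competing risks, and tree-based scan
statistics over ICD-10 and ATC coding hierarchies — so that each stage is
testable without access to confidential register data. This vignette is
the methods account: the models, their assumptions, the tunable parameters,
and the design decisions taken where the methodology left room.

## Cohort construction

**Sampling weights.** Comparator families in register platforms are often
drawn matched to patients, which distorts their demographic margins.
`compute_sampling_weights()` undoes this with Kaplan–Meier-type inverse
probability of sampling weights: within strata of parental birth year and
sex, the per-calendar-year sampling probability is
$q_{st} = m_{st}/N_s$ (sampled over stratum population), and an individual
eligible from year $t_0$ and sampled in year $T$ receives
$$w = \Big(q_{sT} \prod_{t_0 \le t < T} (1 - q_{st})\Big)^{-1},$$
the product-limit inverse probability of being sampled exactly when they
were. The literature does not pin down one formula for these weights; this
product-limit construction is one defensible reading, and the per-year
probabilities are exposed in the output so the weighting is auditable. A
one-year design reduces to simple inverse probability ($N_s/m_s$), under
which weighted comparator margins recover stratum population counts
exactly — the property the test suite asserts.

**Matching.** `match_children()` matches each exposed child to `ratio`
comparators on maternal age at childbirth, drawing without replacement with
probability proportional to sampling weight. The matching caliper is not
something the design fixes externally; the default is exact matching on
integer maternal age, widening to ±1 year only when the exact pool is
exhausted (counted and reported). The exposed children are processed in a
seed-controlled random order, so matching is greedy but reproducible.
Downstream analyses pool the groups rather than conditioning on matched
sets, consistent with the unconditional Bernoulli scan model below.

**Follow-up.** Follow-up runs from birth to the earliest of death,
emigration, and the fifth birthday. Dates are day-resolved; the five-year
cap is 5 × 365.25 days, so uncensored children contribute exactly 5.0
person-years while events (integer-day ages) can never fall in the
fractional final day. Drug-dispensation analyses restrict to matched sets
whose exposed child was born on or after 1 July 2005, when a national
prescribed-drug register would begin coverage; comparators follow their
set.

## Classification trees, masking, and exclusions

ICD-10 and ATC dictionaries are ingested as TSV (code, parent, label,
level) and validated into rooted trees: unique codes, exactly one root, no
orphans or cycles, sibling leaf sets disjoint. Codes are normalised by
stripping dots (Swedish ICD-10 writes `R620`) and converting en-dashes in
range codes to hyphens. Every non-root node — chapter, block, category,
subcategory; ATC levels 1–5 — is a candidate *cut*, enumerated depth-first
with code-lexicographic sibling order so all outputs are byte-stable.

Register extracts are typically coarsened by the data holder.
`apply_mask()` applies per-chapter/per-class granularity rules; the shipped
defaults emulate a typical extract: eye (H00–H59) and perinatal (P00–P96)
chapters at chapter level, congenital malformations (Q00–Q99) at block
level, and the ear chapter (H60–H95) at 3-character categories. The ear
chapter deserves a note: a block-level-only extract could not report a
3-character category such as H66, yet category-level ear findings are
exactly what such analyses surface, so the shipped default keeps
3-character categories there and the rule is configurable for extracts that
genuinely stop at blocks. For ATC, class J (anti-infectives) keeps full
7-character detail, classes A, B, C, G, H, L, M, N are truncated to
5 characters, and D, P, R, S, V — classes whose detail data holders often
withhold, without a stated level — default to 4 characters. Masking is
idempotent by construction. Visit analyses exclude the injury (S00–T98),
external-cause (V01–Y98), and health-services-contact (Z00–Z99) chapters,
with removal counts reported.

## Rates, exact intervals, risks

Incident rates count each child's first qualifying event with person-time
censored at it; all-event rates count every event over full follow-up.
When an analysis row filters on a care setting (e.g. outpatient only),
incident censoring applies at the first event *of that setting* — whether
the original analyses censored per setting or at the first event of any
setting is not determinable, and per-row censoring is the
internally consistent choice.

"Exact" rate-ratio intervals are the conditional-binomial construction:
given $c_1 + c_0$ events, $c_1$ is binomial with success probability
$\pi = \theta T_1/(\theta T_1 + T_0)$ for rate ratio $\theta$, the
Clopper–Pearson interval for $\pi$ maps monotonically to $\theta$, and the
null $\theta = 1$ gives an exact binomial test. This is the same
construction `stats::poisson.test` uses, which serves as an independent
cross-check in the tests (the implementation itself is a two-line
`qbeta` inversion, validated against a grid-search inversion oracle).
These intervals are conservative by construction; simulated coverage at
moderate counts sits near 96–97% for a nominal 95%.

Five-year risks are percentages of cohort children with at least one
qualifying event; risk ratios and differences are computed on unrounded
risks and rounded to two decimals only for display. Per-child utilisation
summaries use linear-interpolation quantiles (R type 7) for the median and
IQR — the convention behind any published IQR is unknowable, so ours is
simply documented.

## Mean cumulative count

The expected number of recurrent events per child by age $t$, with death a
competing risk, is estimated nonparametrically as
$$\widehat{MCC}(t) = \sum_{u \le t} \hat S_D(u^-)\, \frac{d(u)}{n(u)},$$
with $\hat S_D$ the Kaplan–Meier survivor function for death (censoring by
emigration or the age-5 cap only), $d(u)$ the recurrent events at age $u$,
and $n(u)$ the number still at risk. $\hat S_D$ enters left-continuously;
an event and a death at the same age are ordered event-first. With no
deaths the estimator collapses to the Nelson–Aalen-type mean event count,
and with additionally no censoring $\widehat{MCC}$ at the end of follow-up
equals total events over $n$ exactly — both limits are asserted in tests,
and the estimator is checked against a daily-grid brute-force oracle to
10⁻⁹ on random small cohorts. Group curves are computed separately for
exposed and comparator children; variance bands are out of scope.

## The Bernoulli tree scan

Each cut $G$ with $n_G$ affected children, $c_G$ of them exposed, is
scored under the unconditional Bernoulli model — each affected child is
exposed with the design probability $p$ (1/6 under 1:5 matching,
recomputed for sub-cohorts) — with the log-likelihood ratio
$$LLR_G = c_G \ln\frac{c_G}{p\,n_G} + (n_G - c_G)
  \ln\frac{n_G - c_G}{(1-p)\,n_G}$$
when $c_G/n_G > p$, else 0. Multiplicity over the thousands of cuts is
handled by Monte Carlo: each replicate relabels every affected child
exposed with probability $p$, recomputes all cuts, and records the maximum
LLR; a cut's adjusted p-value is $(1 + r)/(R + 1)$ with $r$ its LLR's
exceedance count in the $R$ replicates. The replicate kernel is a small
C++ routine driven by R's RNG, so scans are seed-reproducible.

**Counting unit.** Cut counts are *distinct children* with at least one
first event in the cut — a child with events in two sibling categories
counts once in each sibling and once in their parent. This matches
published five-year risks of the form events/cohort-size, and it makes the
Monte-Carlo relabelling operate at child level: all of a child's cut
memberships move together, preserving the within-child correlation across
codes that shared frailty induces. An event-level variant (each child-code
first event relabelled independently) is available behind
`unit = "membership"` for comparison, but the child-level scheme is the
default and the one under which the null is faithful.

**Calibration and conservatism.** Under the scan's own sampling model —
children exposed independently at $p$ — the adjusted p-values are exact by
construction, and simulation confirms family-wise error within Monte-Carlo
noise of 0.05. Under a fixed design (exactly $n_1$ exposed of $N$), the
affected-children labels are hypergeometric rather than binomial, their
variance is smaller by the finite-population correction, and the scan is
strictly conservative — markedly so when most of the cohort is affected,
as in utilisation data where ~85% of children have some healthcare
contact. Both behaviours are asserted in the test suite: two-sided
calibration under the Bernoulli design null, one-sided (never
anti-conservative) control under fixed margins. Cuts with $n_G = 0$ are
skipped; $c_G = n_G$ is a valid maximum; ranking ties break
code-lexicographically. ICD and ATC trees are scanned separately, each
against its own null distribution. Sampling weights enter cohort
construction only, never the scan, which takes the matched cohort as
given.

## The synthetic registry

`simulate_cohort()` and `simulate_events()` generate the structure the
analyses assume: per child and tree leaf, events follow a Poisson process
with rate (baseline × frailty × exposure multipliers × follow-up), where
the gamma frailty (mean 1, variance 0.5 by default) is *shared across all
leaves within a child* — one sickness-propensity factor, inducing
within-child correlation across codes. Without that sharing, child-level
and event-level relabelling nulls would coincide and the counting-unit
decision above would be untestable. Exposed children carry a uniform rate
multiplier (default 1.08, the overall utilisation excess the design
emulates — a health-seeking effect with no disease cluster), plus optional
injected cluster risk ratios on the leaves under chosen cuts. Death and
emigration are independent exponentials (defaults 5 × 10⁻⁴ and
5 × 10⁻³ per year, of the order of Swedish early-childhood rates), and
follow-up truncates at age five. Baseline per-leaf rates default to
0.04/year, giving a few events per child-year across the bundled ~20-leaf
dictionaries, in the range of early-childhood utilisation.

What the generator does *not* emulate: realistic per-code morbidity
spectra, calendar-period and seasonal effects, sibling clustering beyond a
shared parent, or dependence between death and morbidity. Passing tests
therefore demonstrate that the estimators and the scan behave correctly
under the stated stochastic structure, not that any particular
disease-specific finding in real registers would replicate.

## Power simulations

`power_at()` and `minimum_detectable_rr()` estimate detectability for a
cluster at a given comparator prevalence and risk ratio, at the study's
cohort size (1,424/7,120). The background is a synthetic balanced tree —
1,000 leaves in three levels of branching 10 by default — with a uniform
per-leaf first-event risk of 0.003 (about three affected codes per child,
~95% of children with at least one event, mirroring utilisation
saturation). The cluster sits on a ten-leaf second-level node whose leaves
carry no background risk, so its comparator prevalence is exact; exposed
children's cluster risk is prevalence × RR. A simulation counts as a
detection when the cluster cut or any ancestor/descendant reaches adjusted
p ≤ α. The generator works directly at the level of the scan's sufficient
statistic (which children have a first event under which leaf), which is
what makes 200-cohort × 999-replicate runs affordable on one core.

The minimum detectable RR walks an ascending grid (default 1.15–1.90 in
steps of 0.05 at 10% prevalence) and reports the smallest grid value whose
estimated power reaches the target (default 80% at α = 0.05 — the power
criterion behind any published detectability bound is unstated, and 80% is
the conventional choice). Grid points beyond the first success are not
simulated. Monte-Carlo standard errors are always reported. Because the
background tree, risks, and power level of the original detectability
analysis are not published, agreement with published bounds is expected to
be approximate; our design lands near RR ≈ 1.4 at 10% prevalence.

## Problem sizes and numerical choices

The shipped defaults are chosen for desk-scale reproducibility: scans use
R = 999 replicates in the analysis scripts (9,999 in the study design —
the adjusted p-value formula is identical and the resolution of the
smallest attainable p changes from 10⁻⁴ to 10⁻³); power runs use 200
simulations per grid point; calibration checks use 500 null cohorts of
300/1,500 children on the bundled dictionary. Degenerate inputs are
handled explicitly: zero comparator counts flag infinite upper CI bounds
or non-estimable risk ratios; empty strata are skipped with warnings;
events outside follow-up are treated as upstream bugs (hard errors, not
silent drops); unresolvable codes are dropped with counters. All
randomness flows through seeds — one master seed spawns fixed per-stage
offsets in the pipeline, so any stage can be reproduced in isolation.

## Known limitations

Sampling-weight estimation assumes the stratum population counts are
exact and the eligibility window is known; matching is greedy rather than
optimal (optimal matching would need a different algorithm and changes
little at pool sizes several times the demand); the scan reports no
unadjusted p-values (the adjusted ones are the inferential output); MCC
variance estimation and scan variants beyond unconditional Bernoulli
(conditional, tree-temporal) are out of scope.
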