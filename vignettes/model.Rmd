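---
title: "The spovsim model: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The spovsim model: assumptions, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spovsim)
```

## The model in one page

`spovsim` is a forward-in-time, individual-based model of a closed
population of burrowing wolf spiders at carrying capacity: every
generation exactly 500 females and 500 males reach maturity, live
through one 79-day mating season at daily resolution, and the mated
survivors found the next generation. A single X-linked locus controls
the female behavioral type. Females carry two copies, males one
(XX/X0); males are carriers with no behavior of their own. The
spillover allele `S` encodes genetically fixed aggression — a
behavioral syndrome in which voracity toward prey spills over into
attacks on courting males regardless of the female's mating or hunger
state. The `M` allele encodes the plastic "mate first, cannibalize
later" type, which attacks males only when the female is already mated
or not yet satiated. Heterozygous females express whichever allele the
scenario declares dominant.

Each simulated day runs, in a fixed order: (1) maturation entry,
(2) background mortality, (3) foraging, (4) male mate search over
female burrows, (5) cohabitation, attack and mating. At season end the
mated survivors reproduce through strategy-specific fecundity
allometries, a juvenile survival differential is applied to
spillover-type offspring, and exactly 500 + 500 new adults are sampled.
A run ends at fixation of either allele or after `max_generations`
(default 20,000).

## Parameters that matter

All defaults are the field-calibrated values for *Lycosa hispanica*-like
life history; units are days, millimeters and probabilities per day.

| parameter | default | meaning |
|---|---|---|
| `season_length` | 79 d | days in the mating season |
| `fem_mat` | N(56, 0.5) d; N(39, 0.5) for early variants | female maturation day |
| `mal_mat` | N(36, 0.5) d | male maturation day |
| `CW` | N(3.21 + b·fem_mat + 0.39·CL, σ) mm | adult carapace width; b = 0.047/σ = 0.5066 early, b = 0.024/σ = 0.4679 otherwise |
| `COND_o` | N(3.54 + 0.49·CW, 0.2671) mm | condition (abdomen width) at maturity |
| `maxCOND_f` | −38.98 + 11.73·CW − 0.63·CW² mm | satiation threshold; feeding stops above it |
| intake | U(0,1)·0.1482 mm/d (rich), halved in poor; ×1.5 for spillover | daily condition gain |
| `maxenc` | 3 (rich), 1 (poor) | burrow visits per searching male per day |
| `pspov` | 0.5 (rich), 0.9 (poor) | spillover female attack probability |
| `pescape` | exp(−0.1·CW) | male escape probability per attack |
| male meal | 2.39 mm | condition gained by eating a male, capped at `maxCOND_f` |
| mortality | 0.0030/d MFCL female; 0.0030 × 1.2 (rich) or × 1.5 (poor) spillover female; 0.0045/d male | daily background death |
| `vol` | strategy regressions, mm³ | egg-sac volume (see below) |
| offspring | 57.54 + 0.16·vol | brood size |
| `different` | 0.1–0.9 | spillover juvenile survival relative to MFCL |
| `pmate` | 0.5/d | mating probability per cohabitation day |

Egg-sac volume: plain spillover variants use
`N(−1156.43 + 277.21·CW, 140.33)`; body-condition-dependent (BCD)
variants add `123.44 × condition` (σ = 132.97); MFCL uses
`N(−2297.64 + 217.88·CW + 123.44 × condition, 129.59)`. The condition
covariate is the female's realized end-of-season condition, never more
than her satiation threshold, so for the condition-dependent strategies
adult foraging (including cannibalism) feeds into fecundity. The
printed σ values are used as-is even though they were estimated at
maximum condition; nothing in the model lets us do better.

`pmate` is not an observed quantity. Cohabitation lasts "a few days" in
the field; 0.5 per day gives a mean of about two days and is exposed
for sensitivity analysis.

Carapace length `CL` enters the size regressions only as a covariate
with no stated distribution; it is held at a constant 3.5 mm, which
keeps CW in the biologically plausible 5.5–6.5 mm range. Season days
are indexed 1–79 from season onset; calendar dates are cosmetic.

## Design choices made where the design was open

**Burrow visits, not "mature females only".** A searching male draws
`maxenc` distinct burrows among all living females; a not-yet-mature
female simply is not there and the visit is wasted. This matters
enormously: if males could only ever land on mature females, every
visit before the MFCL maturation date would hit an early-maturing
spillover female, males would be extinct by day 56 in essentially every
scenario, MFCL females would never mate, and the spillover allele would
trivially fix everywhere. Diluting search across all burrows is what
lets males survive to the date the plastic strategy needs them —
and with it, the whole maintenance/coexistence structure.

**The juvenile differential applies to carriers of both sexes.**
`different` compresses the unsimulated juvenile stage: voracious
spillover juveniles suffer higher predation. Juveniles of both sexes
forage, so the default applies the differential to spillover-phenotype
daughters and to sons carrying the spillover allele (a hemizygous son
expresses his single allele). With sons exempted the allele shelters in
males, escapes the differential almost entirely and fixes in nearly
every scenario; with the default, the classic spillover strategy always
collapses, the recessive early-spillover variant fixes only in
productive/low-cost scenarios, and dominance produces stable
frequency-dependent coexistence. `different_males = FALSE` restores the
daughters-only reading.

**Within-day ordering** (mortality → feeding → search → cohabitation)
is fixed; pairs formed during the day's search already face that day's
cohabitation step, so the minimum cohabitation is one day and the mean
is `1/pmate`. An attacked male that escapes ends his searching day; an
escape during cohabitation dissolves the pair. Mated females remain
encounterable — they no longer host residents, and an MFCL female that
has mated attacks suitors again, which is the "cannibalize later"
pathway.

**MFCL attack rule.** The literal state-dependent rule — attack iff
mated *or* not satiated — is the default; the stricter `mated_only`
reading is a config switch. The MFCL attack probability when the rule
fires is 1 and overridable. A satiated spillover female still attacks
but gains nothing from the kill, since satiation stops feeding.

**Degenerate females.** The satiation quadratic can fall below a
female's drawn initial condition (about 10–15 % of females, given the
CW spread). Such females are marked satiated at entry rather than
redrawn, preserving both the fixed population size and — for MFCL — a
docile-virgin fraction that turns out to carry much of that strategy's
mating success in poor environments.

**Next-generation sampling.** `different` acts as a relative sampling
weight (exponential-key weighted sampling without replacement) rather
than a pre-sampling cull, because the adult count is fixed at 500 + 500
regardless; `juvenile_mode = "cull"` provides the thinning variant.
Pools smaller than the quota are resampled with replacement and
flagged. An empty pool ends the run as an extinction classified by the
parental gamete majority.

**Allele frequency** counts all 1500 X copies (two per female, one per
male); a females-only accessor exists for sensitivity. Fixation is
declared on each freshly sampled adult generation.

## Randomness and reproducibility

Every stochastic step draws from R's global RNG in a documented order,
and the compiled engine consumes draws in exactly the same order as the
plain-R reference implementation, so one seed determines one trajectory
bit-for-bit in either engine. The test suite holds the two engines to
identical event traces on micro scenarios and identical multi-
generation trajectories at population scale. Maturation draws are
rounded half-up to whole days and clamped to the season; carapace
widths truncate below at 0.01 mm, conditions at 0; negative egg-sac
volumes truncate to zero (the regressions extrapolate outside their
fitted range for small females); attack decisions consume one uniform
draw even when the probability is 0 or 1, which keeps the two engines
aligned.

## What the simulations do and do not show

The generator *is* the study system: there is no external data. Default
runs reproduce a coherent qualitative picture — classic spillover always
collapses; early maturation plus larger size lets the spillover
syndrome fix where juvenile costs are low, most readily in productive
environments; dominance yields cells where both alleles persist for
thousands of generations, with the spillover strategy's relative
fitness significantly lower near fixation (negative frequency
dependence) driven by male scarcity.

Two quantitative caveats, both traceable to male survival under the
printed encounter/attack parameters, deserve mention. First, the
coexistence cluster sits in the rich environment here, with the
oscillating `different = 0.7` cell spanning p ≈ 0.50–0.98; in the
original study system the analogous cluster is reported for poor
environments. Second, in that rich oscillating cell MFCL mating is
rare (well under 1 %), so the MFCL-mating TOP/BOTTOM contrast has
essentially no power, while the relative-fitness reversal is sharp and
significant. Conclusions about the *direction* of frequency-dependent
selection are robust; cell-level environmental attribution is not.
Nothing here validates the model against field data: the model's
parameters are field-derived, but its outputs are simulation outcomes.

## Problem sizes used in the tests

The test suite runs scaled versions of the experiments: maintenance and
invasion sweeps capped at 2,000–3,000 generations, micro scenarios of a
handful of individuals for oracle traces, and 120–200 replicate batches
for the statistical properties (drift unbiasedness, segregation ratios,
type-I error of the equilibrium GLMs). These sizes were chosen to give
each assertion clear statistical power while keeping a full run of the
suite in the minutes range; the full 20,000-generation experiments are
reachable through `max_generations` and behave identically, only
longer.
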