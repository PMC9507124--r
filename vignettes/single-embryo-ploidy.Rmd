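---
title: "Ploidy calling from single-embryo sequencing depth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ploidy calling from single-embryo sequencing depth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoploidy)
```

## The problem

In *Wolbachia*-induced cytoplasmic incompatibility (CI), embryos fathered by
infected males mated to uninfected females suffer paternal-chromosome
segregation failure at the first zygotic division. Three outcomes follow:
complete paternal loss (a maternal-only haploid that develops to the
blastoderm stage but never hatches), partial paternal loss (severe
aneuploidy and early arrest), or a normal first division (a diploid that may
hatch). Distinguishing these classes in single cellularized blastoderms from
low-input whole-genome sequencing is the core inference problem this package
implements, together with the cohort-level statistics used to quantify the
two CI lethal phases and mitotic-defect frequencies.

## The dosage statistic

For one embryo with per-position depth track $d(\cdot)$, the percent depth of
a gene $g$ is

$$\mathrm{pct}(g) = 100 \times
  \frac{\overline{d}_{g}}{\overline{d}_{\mathrm{genome}}},$$

the mean depth across the gene divided by the mean depth across the whole
(nuclear) genome. Because the statistic is self-relative it is invariant to
library size, and a fully haploid genome reads ~100% everywhere — which is
exactly why haploidy is diagnosed through *paternal-only markers* (the
transgene carried by the father and the Y chromosome), not through genome-wide
depth. Five marker genes per chromosome arm (Y, X, 2L, 2R, 3L, 3R, 4) are
averaged through a majority vote to suppress single-gene noise.

Expected values are pure copy-number ratios: a gene on a sequence at $c$
copies against a genome whose length-weighted mean copy number is $\bar c$
has expectation $100\,c/\bar c$ (`expected_percent_depth()` computes this
closed form, and the simulation tests check it exactly in the noise-free
case).

## Dosage bands and the caller's decision rules

The nominal anchors are 0 / 50 / 100 / 150% of mean genome depth. The
source analysis gives no numeric cut-offs, so the bands are midpoint cuts,
half-open on the right for determinism:

| state       | band           | nominal meaning          |
|-------------|----------------|--------------------------|
| ABSENT      | [0, 25)        | 0 copies                 |
| HEMIZYGOUS  | [25, 75)       | 1 copy vs 2-copy genome  |
| DISOMIC     | [75, 125)      | 2 copies (or haploid 1/1)|
| AMPLIFIED   | [125, $\infty$) | $\ge 3$ copies          |

Per arm, the five gene states vote; "multiple genes" agreeing is
operationalized as a strict majority (≥ 3 of 5, concordance ≥ 0.6), below
which the arm is `ambiguous`. Transgene presence requires *both* a
meaningful mean depth (percent depth ≥ 25, the ABSENT/HEMIZYGOUS cut) and
even coverage (≥ 9 of 10 equal-length bins non-zero), so a spurious pile-up
in a corner of the transgene does not mimic presence. Both thresholds are
arguments. Ploidy is then:

* **diploid** — transgene present and all non-sex arms DISOMIC;
* **haploid** — every declared paternal marker absent and all non-sex arms
  DISOMIC;
* **segmental_aneuploid** — a non-sex arm HEMIZYGOUS/ABSENT while a paternal
  marker is present (the class the depth analysis was designed to detect);
* **ambiguous** — anything else.

Sex arms are excluded from the deviation test because a hemizygous X is
dosage-normal in males. Sex itself is called from the Y/X band pair.

## Why the genome-mean denominator makes 50% actually ~55%

A point that any reimplementation must confront: in a male (X = 1, Y = 1,
autosomes = 2), the X genes do **not** sit at exactly 50% of the genome mean,
because the hemizygous X itself deflates the denominator. With realistic
*D. simulans* arm proportions the closed form gives ~54.6% for male X genes
and ~109% for male autosomes; in a maternal-only haploid, the missing Y
leaves retained arms at ~102%. The printed 0/50/100/150 anchors are nominal
band centers, not attainable point values. This is also why the default
miniature genome uses realistic relative arm lengths
(`default_arm_weights`: majors near 1, X at 0.63, Y and the dot chromosome
at 0.10): with seven *equal* arms the male X would read 58.3% and haploid
autosomes 116.7%, drifting toward band edges and away from the biology the
statistic is meant to capture. The banding structure absorbs these
deviations by design.

## The synthetic world

The generator states one world and the tests measure it; none of its
parameters were adjusted against test outcomes.

* **Genome** (`build_layout`): seven nuclear arms with five non-overlapping,
  evenly spaced marker genes each (default 1 kb genes, largest arm 100 kb); a
  19.5 kb mitochondrion; a 720 bp transgene contig; a 714 bp randomized
  negative control that never receives reads.
* **Depth** (`simulate_depth`): position-wise independent Poisson counts with
  mean `coverage × copies / 2` (noise-free mode sets the mean exactly).
  The mitochondrion uses a free multiplier `mito_scale` (default 100:
  mitochondrial depth far exceeds nuclear; the source data never state the
  level, so this is an assumption, and only the *ratio* machinery depends on
  it).
* **Fates** (`simulate_cohort`): per cross, a categorical first-division
  outcome, then Bernoulli blastulation/hatch/adult conditionals; negative
  binomial fallout counts moment-matched to the printed mean ± sd (Poisson
  when sd² ≤ mean, since a negative binomial requires overdispersion);
  beta-binomial division errors with mean rate per cross and concentration
  20 (a moderate-overdispersion choice; only the mean is printed).

Default fate parameters are back-computed from printed marginals: CI
first-division arrest 0.70; of the 0.30 that blastulate, 42% diploid, so
`p_complete_loss = 0.30 × 0.58 = 0.174` and `p_normal = 0.30 × 0.42 = 0.126`;
haploids always blastulate and never hatch. `p_hatch_given_diploid = 0.7` is
a reconciliation, not a printed value: the observed CI hatch (2–9%) is below
the diploid fraction (~12.6%), and the gap is attributed to late defects
without a printed probability. Non-CI crosses use the printed hatch rates as
`p_normal` (0.92 / 0.88 / 0.91) with the remainder assigned to early arrest,
and printed egg-to-adult survivals (0.95 / 0.69 / 0.87; reciprocal assumed
wild-type-like).

What the generator does **not** emulate: read-level artifacts (GC bias,
mappability, duplicates), sub-gene deletions, *Wolbachia* titer, batch
effects between sequencing runs, or any correlation between neighbouring
positions beyond the shared mean. A green recovery test therefore
establishes that the caller's decision rules are correct and
noise-calibrated under shot noise — not that they are robust to alignment
pathology.

## Randomness and determinism

One master seed fans out to named sub-streams (layout / fates / per-embryo
depth / per-embryo sex) via a deterministic string hash, all below $2^{31}$.
Each embryo draws from its own sub-stream keyed by `(seed, cross, index)`,
so a cohort of 50 embryos is a strict prefix of a cohort of 120 at the same
seed, and enlarging one stage's consumption of random numbers cannot shift
another stage's draws. The demo pipeline writes byte-identical JSON reports
for identical configurations.

## Statistical battery

The wrappers keep one `TestResult` surface over the standard
implementations (the original analyses were run in R, so `chisq.test`,
`fisher.test`, `wilcox.test`, `kruskal.test`, `t.test` and `shapiro.test`
*are* the reference implementations). Conventions fixed here:

* chi-squared defaults to the **uncorrected** Pearson statistic
  (`chisq_yates` is exposed separately) since the source never states a
  variant; results on tables with any expected count < 5 carry a note.
* two-sided Fisher uses the "sum of all tables at most as probable"
  convention (with the implementation's `1 + 1e-7` probability slack), not
  tail-doubling. The suite verifies it against an exhaustive hypergeometric
  enumeration oracle.
* Mann–Whitney is exact by enumeration when $n_1 + n_2 \le 12$ with no ties,
  otherwise the normal approximation with tie and continuity corrections;
  the reported statistic is $U_1$ (and $U_1 + U_2 = n_1 n_2$ always).
* p-values are carried at full floating precision; the "p = 2 × 10⁻¹⁶"
  style of reporting floor is treated as a display convention, never stored.
* no multiple-testing adjustment, matching the source analyses.

Two calibration facts worth knowing: Fisher's exact test is conservative by
construction on discrete tables (its null rejection rate at α = 0.05 sits
well below 5%, around 4% at the n = 200 null used in the acceptance suite),
so the 5% ± 1% calibration criterion is asserted only for the asymptotically
calibrated tests (uncorrected chi-squared, Mann–Whitney normal
approximation, paired t). And the printed Fisher p = 1.9 × 10⁻⁸ for the
pre-blastoderm vs late-cortical comparison cannot be reproduced exactly from
any obvious 2×2 reading of the printed counts — the adopted 2/63 vs 72/190
table gives 6.7 × 10⁻⁹ (verified against the enumeration oracle), which
agrees at order of magnitude and is what the package reports.

## Worked example

```{r demo, eval = FALSE}
layout <- build_layout(100000, 1000, seed = 0)
prof <- simulate_depth(layout, karyotype_preset("diploid_xy"),
                       target_coverage = 50, noise = "poisson", seed = 7)
call_embryo(prof, layout)

cfg <- run_config(seed = 1, n_embryos_per_cross = 250, out_dir = tempfile())
res <- run_demo(cfg)
```

## Degenerate inputs and tie-breaks

* A zero mean genome depth makes percent depth undefined: hard error
  ("undefined normalization"), never NaN propagation.
* Band edges (25 / 75 / 125) belong to the upper band.
* A 2–2–1 split of gene states has no majority: the arm is `ambiguous`, and
  an ambiguous arm can render the embryo `ambiguous` but never force a
  concrete class.
* Zero-variance paired differences are rejected rather than returning
  t = ±Inf; Mann–Whitney on fully tied samples falls back to the corrected
  normal approximation.
* bedGraph gaps are real zeros; overlapping intervals are an error naming
  the first offending pair, as silent last-writer-wins densification would
  corrupt depth means.

## Known limitations

* Arm-level resolution only: no breakpoint segmentation, and sub-gene
  deletions are invisible (a caveat the source analysis itself makes).
* Haploid calling is only as good as the declared paternal markers; in a
  cross without a transgene, a Y-less haploid female is indistinguishable
  from a diploid XX female by dosage alone.
* The fate model treats embryos as independent draws; real hatch assays have
  plate/cross-level clustering the simulator does not model, so simulated
  standard errors are lower bounds.
* The genome-wide depth deficit of CI embryos relative to controls is
  reported via the mitochondrially normalized ratio
  (`mito_normalized_depth`) but deliberately not interpreted — whether it is
  biology or library input is an open question.
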