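---
title: "Quantifying numerical chromosomal variation between groups of single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying numerical chromosomal variation between groups of single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyostat)
```

## The problem

Whole-chromosome missegregation produces cell populations in which the copy
number of individual chromosomes varies from cell to cell. Experiments that
probe this — interphase FISH panels, spectral karyotyping (SKY), or
low-coverage single-cell whole-genome sequencing (sc-WGS) — typically compare
predefined treatment groups: senescent versus young fibroblasts, exposed
versus control cells, and so on. karyostat reduces all three input types to
one canonical object, an `N x T` cell-by-chromosome matrix of integer copy
numbers `c[n, t]`, summarizes each group with a small set of
population-level statistics, tests group differences by permutation, and
draws the standard comparative figures.

## The statistics

All statistics are computed against a per-chromosome *euploid reference*
`e[t]` (default 2 everywhere; `euploid_reference(..., sex = "XY")` sets
X = 1, Y = 1 for male karyotypes, `sex = "XX"` sets X = 2, Y = 0).

* **Instability index** `I = 100 * mean_t(k_t)`, where `k_t` is the fraction
  of cells whose count differs from the *modal* (most frequent) state of
  chromosome `t`: `k_t = 1 - modal_count_t / N_t`. It is a percentage of
  aberrant cells per chromosome, averaged over chromosomes, and does not use
  the euploid reference at all — a clonally tetraploid population has
  `I = 0`. Its upper bound is `100 * (1 - 1/N)`.
* **ANCA** `A = mean_n(q_n)`, the average number of copy-number-altered
  chromosomes per cell, with `q_n = #\{t : c[n, t] != e[t]\}`. Because `A`
  grows with the number of chromosomes measured, the **normalized ANCA**
  `AN = A / T` (in `[0, 1]`) is what should be compared across platforms
  with different probe counts.
* **Aneuploidy score** `D = mean over observed entries of |c[n, t] - e[t]|`
  — the only statistic sensitive to the *magnitude* of the change; a few
  cells at very high copy number move `D` but barely move the others.
* **Heterogeneity score** `H`: per chromosome, sort the state counts
  descending (`m_0 >= m_1 >= ...`) and weight each by its rank,
  `H_t = sum_f f * m[f, t] / N_t`; `H` is the mean of `H_t` over
  chromosomes. `H = 0` when all cells agree per chromosome and reaches its
  maximum `(N - 1) / 2` when every cell carries a distinct state. `H`
  depends only on the frequency spectrum of states, not their identity.
* **Ploidy proportions** `(P_A, P_D, P_P)`: each cell is classified
  *diploid* (every observed count equals its reference), *polyploid* (all
  counts a uniform integer multiple >= 2 of the reference — whole-genome
  duplication), or *aneuploid* (anything else); the proportions sum to 1.

The instability index and the ploidy proportions are features of a
*population* of cells and exist only at group level; ANCA, normalized ANCA,
`D` and `H` are additionally computed per chromosome (`T = 1`) to flag the
most perturbed chromosomes. On a complete matrix the chromosome-level `D`
and `H` average back exactly to the group aggregate.

### Numerical conventions

* The instability index is defined through the *fraction* of non-modal
  cells, `k_t = 1 - modal_count_t / N_t`, which keeps `k_t` in `[0, 1)` for
  any modal cell count and matches its reading as a percentage of abnormal
  counts. Under this definition `I` is bounded by 100.
* The ANCA denominator is the number of cells `N` ("per cell").
* Modal ties are broken toward the state closest to the euploid reference,
  then toward the smaller state. Only the modal *count* enters `I`, so the
  rule affects reported modal-state labels, never a statistic.
* A cell whose counts are a uniform multiple *below* the reference (an
  all-1 "haploid" cell against reference 2) is classified aneuploid, not
  polyploid: polyploidy denotes an integer-valued increase.
* Missing entries (unscored probes, unmappable chromosomes) are excluded
  entry-wise; every denominator counts observed entries only (`N_t` per
  chromosome, total observed entries for `D`). A cell with no observed
  entries is dropped with a warning.
* The number of copy-number states per chromosome is whatever is observed —
  no cap — and the scores are applied at whole-chromosome resolution, which
  is the resolution shared by FISH, SKY and chromosome-collapsed sc-WGS.

## Input readers

**FISH** tables are read as-is: one row per cell, one integer column per
probed chromosome; empty fields and `NA`/`na`/`NaN` become missing entries,
any other non-numeric field is an error naming the row and column (silent
coercion hides scoring mistakes). Delimiters (comma, tab, semicolon) are
auto-detected from the header.

**SKY** karyotypes arrive as ISCN strings. `parse_iscn()` extracts the
numerical content only: the leading modal number fixes the baseline ploidy
as its nearest multiple of 23 (46 → 2 per autosome, 69 → 3, 92 → 4), the sex
complement gives the X/Y counts, and `+N`/`-N` tokens adjust individual
chromosomes. Structural tokens — translocations, deletions, inversions,
markers — change no whole-chromosome count; they are retained in
`unparsed_tokens` rather than dropped, so a parse is always auditable.
Conventions for messy strings are deliberate and documented rather than
reconstructions of any particular lab's practice: modal ranges (`44~47`)
use the first number, mosaic karyotypes (`/`-separated) use the first clone
with a warning, bracketed clone sizes are stripped, and a reported modal
total that disagrees with the reconstructed sum is flagged per cell, never
silently corrected.

**sc-WGS** input is the integer copy-number *state matrix* an upstream
caller produces from aligned reads (bins as rows: chromosome, start, end in
0-based half-open BED convention; cells as columns). karyostat does not
segment or call copy number. Each chromosome is collapsed to a single
integer by a length-weighted average of its bin states — each bin
contributes proportionally to its size in base pairs — rounded to the
nearest integer. Exact halves round away from zero (2.5 → 3), a fixed,
tested choice; bins missing a state for a cell are excluded with weights
renormalized, and a chromosome with no observed bins yields a missing
entry. The collapsed count always lies between the minimum and maximum bin
state, and splitting any bin into two of the same state changes nothing.

Chromosome labels are normalized across platforms (`chr1` = `1`, `x` = `X`)
so FISH, SKY and sc-WGS strata share one label space and can be plotted and
compared together.

## Permutation testing

Group differences are tested without distributional assumptions. For a
chosen statistic, the observed per-group values are computed; then, `B`
times (default 500), the cell labels are shuffled jointly across *all*
groups (group sizes preserved), the statistic is recomputed per group, and
each unordered pair's permuted absolute difference is compared with its
observed one. The p-value uses the add-one convention
`p = (1 + #{permuted >= observed}) / (1 + B)`, which avoids `p = 0` and
makes the smallest attainable p-value at `B = 500` equal to `1/501 ≈ 0.002`.
Differences are compared in absolute value (two-sided); the Benjamini-
Hochberg step-up correction is applied across the pairwise tests of a run
(one statistic), not pooled across statistics; the reporting threshold is
0.05. A single seeded generator drives the shuffles, so identical seeds and
inputs reproduce identical tables.

Internally the permutation loop uses a precomputed integer coding of
(chromosome, state) pairs so each permuted group needs one `tabulate()`
call; a unit test pins the kernel's per-group values to the reference
statistic functions, which are themselves validated exhaustively against a
brute-force evaluation of the defining formulas (all matrices with
`N <= 4`, `T <= 2`, counts in {1, 2, 3}).

## Visualization

Every figure is a pure function of data the package also serializes, and is
asserted at the data layer (coordinates, percentages, page counts), never at
pixel level.

* **Scatter (D vs H)**: one point per (group, source) stratum; colors encode
  groups, symbols encode sources, so FISH and sc-WGS measurements of the
  same treatment sit on one panel.
* **Ternary plot**: each stratum's `(P_D, P_P, P_A)` are its barycentric
  coordinates in the diploid/polyploid/aneuploid simplex.
* **Bivariate percentage grid**: for a chromosome pair, the percentage of
  jointly observed cells at each combination of counts; all `choose(T, 2)`
  pairs are produced. Cells missing either count are excluded
  (pairwise-complete, so each grid uses as many cells as possible; a
  listwise rule would discard cells informative for other pairs). At the
  data layer the axes are the observed states plus the euploid state (whose
  gridline is drawn bold); the rendered plot pads one state on each side as
  a visual margin only.
* **Copy-number heatmap**: the raw matrix with cells re-ordered into
  contiguous group blocks; missing entries render as blank.

`export_pdf()` writes one page per figure in a fixed order (scatter,
ternary, grids, heatmap).

## The synthetic generator

`population_spec()` + `generate_population()` define the study conditions
used throughout the tests: each cell starts at the euploid reference, is
whole-genome doubled with probability `polyploid_fraction`, then every
(cell, chromosome) entry independently gains or loses a single copy with
probability `missegregation_rate` (directions equiprobable), clipped to
`[0, max_state]`. Defaults — 50 cells, 4 chromosomes, euploid 2, rate 0.1,
polyploid fraction 0.05, `max_state` 8 — emulate a four-color interphase
FISH panel on a moderately unstable near-diploid population, a scale at
which such experiments are commonly scored. Single-step ±1 missegregation
keeps expectations analytically checkable (ANCA has a binomial expectation
`T * rate`, checked at `n = 2000` within 3 standard errors), and both
nonzero rates guarantee all three ploidy classes occur.

The generator deliberately omits biological structure real data have:
no lineage or clonal substructure, no selection, no chromosome-specific
missegregation bias, no FISH probe inefficiency or sc-WGS segmentation
noise. Passing tests therefore demonstrate the *statistical machinery* —
correctness of the formulas, calibration of the permutation test, power
ordering with effect size — not robustness to platform-specific artifacts.

## Validation scales

The test suite validates the statistics exhaustively on small matrices
(about 7,500 enumerated cases), calibrates the null rejection rate of the
permutation test on 500 replicate two-group datasets of 50 cells each at
200 permutations (rejections at `p <= 0.05` must sit within 3 binomial
standard errors of 5% for both `D` and `H`), and checks power monotonicity
across missegregation-rate gaps of 0, 0.1 and 0.3 at 60 replicates each.
These sizes make the suite informative while keeping a full run around two
minutes; the properties tested are size-stable.

## Known limitations

* Whole-chromosome integers only: no segment-level (structural) CNV scoring.
* The ISCN parser covers numerical aberrations; derivative-chromosome
  arithmetic, breakpoints and marker chromosomes are logged as unparsed
  tokens rather than interpreted.
* A single euploid reference applies to the whole matrix, so mixed-sex cell
  populations need to be stratified by sex before classification.
* Permutation p-values are granular (multiples of `1/(B + 1)`); with few
  cells per group the attainable significance is limited no matter how
  large `B` is.
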