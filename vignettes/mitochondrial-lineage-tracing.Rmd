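---
title: "Tracing cell lineage with mitochondrial heteroplasmies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing cell lineage with mitochondrial heteroplasmies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitolineage)
```

## The idea

Each human cell carries hundreds to thousands of copies of the ~16.6 kb
circular mitochondrial genome, which mutates roughly ten times faster than
the nuclear genome. A somatic mtDNA mutation present in a fraction of a
cell's mtDNA copies — a *heteroplasmy* — is inherited by the cell's
descendants and drifts in frequency but is effectively irreversible. The
probability that one given site mutates in one given cell is approximately

$$P = n \cdot r,$$

with per-base mutation rate $r \approx 10^{-7}$ and $n \in [10^2, 10^4]$
mtDNA copies per cell, i.e. $P \in [10^{-5}, 10^{-3}]$
(`independent_origin_probability()`). The probability that $N$ cells share
the same variant through *independent* mutation is $P^N$
(`coincidence_probability()`): already at $N = 3$ this is at most
$10^{-9}$, so three or more cells sharing a heteroplasmy are, for all
practical purposes, clonally related. Because ATAC-seq libraries are
heavily enriched for (unchromatinized, accessible) mtDNA, chromatin
profiling data double as deep mtDNA sequencing, and lineage can be read
out of data generated for other purposes.

This vignette records the models, parameter choices and engineering
decisions behind each stage. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Input model and coordinates

The unit of input is a stranded pileup: per 1-based position on the rCRS
mitochondrial reference (length 16569), the reference allele and eight
counts (A/C/G/T × forward/reverse). Coordinates are 1-based inclusive
because that is how mitochondrial variants are universally labelled
(A302C, C6776T, ...). The circular genome is represented linearly — the
package consumes counts, not reads, so no wrap-around logic is needed.
Base- and mapping-quality filtering belongs upstream: the TSV dialect
carries already-filtered counts, which keeps every downstream computation
deterministic and testable without alignment data. The optional
`pileup_from_bam()` adapter applies the conventional floors (mapping
quality ≥ 30; base quality 30 for bulk, 20 for shallow single-cell
libraries) when building the table from a BAM.

Coverage summaries exclude a window around position 3107 by default
(`default_coverage_mask()`, 3105–3110). The rCRS contains an 'N'
placeholder at 3107 that produces an artificial coverage crater nearby;
the exact affected width is not standardized, so the default covers the
ACNTT context and is configurable. Mask intervals lying entirely beyond a
(shorter, e.g. simulated) genome are ignored rather than rejected;
intervals straddling the boundary are errors.

## Bulk variant calling and the filter cascade

`call_variants()` emits a candidate for every (position, non-reference
allele) with VAF ≥ `min_vaf` (default 0.001) and at least `min_alt_reads`
supporting reads. The permissive 0.1% floor is deliberate: with the
10,000–20,000X mtDNA coverage typical of bulk ATAC-seq, real low-level
heteroplasmies sit well below ordinary germline-calling thresholds. The
floor is distinct from the *reporting* threshold (1%) applied later —
candidates in between remain visible to single-cell recounting workflows
while being excluded from bulk reports.

Three filters follow, each of which only *appends* failure reasons, so the
final pass/fail set is independent of filter order (a property the test
suite asserts by permutation):

* **Blacklist** — 13 substitutions recurrently miscalled in mtDNA data:
  six from the homopolymer at 302–315, four from the tract at 513–525,
  three flanking the 3107 'N'. Matching is on (position, alternate allele)
  pairs, exactly as the artifact list is printed; because the underlying
  mechanism (misalignment) is positional, `match = "position"` optionally
  widens removal to any alternate allele at those positions. The printed
  list includes G316C under the 302–315 tract even though 316 lies just
  outside it; the list is taken verbatim.
* **Strand filter** — sequencing errors (including the elevated A-base
  error of some Illumina instruments and G→T / C→A oxidative damage) are
  strand-asymmetric far more often than real variants. A call passes only
  with strictly more than 2 supporting reads on *each* strand and a
  forward fraction strictly inside (0.3, 0.7). The inequalities are
  strict; the brute-force enumeration test pins the boundary behaviour
  (3 forward / 7 reverse fails at exactly 0.30).
* **VAF classification** — calls above VAF 0.9 are homoplasmic:
  effectively fixed variants that distinguish individuals, not clones.
  VAF values in (0.9, 1) are additionally annotated `suspect_homoplasmic`
  — not-quite-fixed calls are enriched for reference-mapping bias — but
  retained as homoplasmic rather than discarded, since lineage work uses
  only the heteroplasmic stratum either way. Heteroplasmies at or below
  the 1% reporting cut are filtered as `below_report_threshold`. The
  reporting cut is applied uniformly to all samples; it is a single
  config key for cohorts that want it stratified.

`screen_contamination()` addresses a failure mode specific to mtDNA:
cross-individual contamination injects the contaminant's homoplasmic
variants as spurious low-VAF heteroplasmies. A sample is flagged when its
heteroplasmy count reaches 30 (chosen below an observed contaminated
case carrying 37, and far above the handful typical of clean samples) or
when at least half its heteroplasmies coincide with common population
variants. Both thresholds are configurable; an absent common-variant list
skips the overlap check with a warning rather than failing.

## Single-cell genotyping and detection modelling

`genotype_cells()` re-counts the *bulk-accepted* variants in each cell:
support counts only reads matching the bulk alternate allele, so a
different non-reference allele at the same position contributes depth but
no support. A position absent from a cell's pileup is depth 0, not an
error — sparsity is the norm.

Positivity is any-read by default (`min_support = 1`). A single supporting
read is meaningful here only because candidates were already vetted in
deep bulk data; the same rule applied de novo would drown in errors. The
`min_support` knob exists because one read *is* fragile against residual
sequencing error (see the doublet discussion below) and because legend
conventions in the field vary between "any read" and "more than one read";
the any-read methods convention is taken as the default.

For a variant at cellular VAF $f$ genotyped at site depth $d$, the
detection probability under binomial read sampling is

$$R(f, d) = \Pr[\mathrm{Bin}(d, f) \ge k] \;\stackrel{k=1}{=}\; 1 - (1-f)^d,$$

implemented in closed form (`detection_probability()`) and verified
against Monte-Carlo simulation in the tests (10,000 cells, agreement
within 3 standard errors). Empirical detection-rate curves
(`detection_rate_by_depth()`) bin cells by site depth into half-open
intervals $[0,10), [10,20), \dots$; width 10 is the field's convention
and edge handling (a depth-20 cell belongs to $[20,30)$) is pinned by a
brute-force test since prose descriptions of binning never specify it.
Empty bins are reported with `n_cells = 0` and an undefined rate rather
than silently dropped.

Linked variants rescue each other's dropouts: if a clone carries variants
with per-variant detection rates $R_1, \dots, R_k$, detecting *any* of
them identifies the lineage, at rate

$$R_{\mathrm{comb}} = 1 - \prod_i (1 - R_i)$$

(`combined_detection_rate()`), which dominates every individual rate. At
20X and VAF 0.20, $R = 1 - 0.8^{20} \approx 0.988$; the acceptance script
recomputes this and the four-variant combination by simulation.

Cells with no detected clone variant are only called wild-type when their
mean mtDNA coverage exceeds 40X (`classify_wt_cells()`): below that,
absence of evidence is uninformative (`insufficient`). A detected variant,
by contrast, is positive evidence at any coverage, so carrier status has
no coverage floor.

## Clone inference

Grouping variants into clone-defining sets was historically done by
inspecting intersection (UpSet-style) plots. The algorithmic surrogate —
this module's main engineering decision — is a co-detection graph. Under
the null that variants $v_1, v_2$ mark unrelated lineages, the expected
number of cells detecting both is

$$E = P_{v_1} \cdot P_{v_2} \cdot N,$$

with $P_v$ the observed per-variant detection frequency and $N$ the cell
count. ($P_v$ could also be read as clone prevalence; the observed
detection frequency is used because it is directly measurable and
conservative — it already folds in dropout.) "Normalization by sequencing
depth" is realized as optional per-cell weighting: each cell contributes
$R(\hat f_{v_1}, d_{c,v_1}) \cdot R(\hat f_{v_2}, d_{c,v_2})$, rescaled so
uniformly full detectability recovers the unweighted formula, with
$\hat f_v$ estimated as the mean support fraction among carriers. No
closed prescription for this normalization exists in the field; this
interpretation is documented as such.

An edge joins $v_1, v_2$ when the observed co-detection count exceeds the
Poisson 99% quantile of $E$ (`exceedance_quantile`, configurable).
Connected components supported by at least `min_cells = 3` carrier cells
become clone sets — 3 because that is where the coincidence probability
$P^N$ becomes negligible; the threshold is a config key since "more than
3" is ambiguous between $\ge 3$ and $> 3$ and we adopt the inclusive
reading. Weaker components stay ungrouped. The exceedance test needs
enough cells to have power: with $N \lesssim 20$ cells and high-prevalence
variants, a perfectly co-detected pair may not exceed the 99% Poisson
bound of its (already large) null expectation. The block-recovery tests
therefore run at $N = 40$ and $N = 150$; sparse datasets should be
interpreted with that in mind.

`assign_clones()` then labels each cell: detections confined to one set →
that clone; detections spanning two or more sets → `doublet` (two cells
captured in one library — such cells are excluded from downstream clone
counts); no set detections → `WT` if the coverage rule allows, otherwise
`unassigned`. Cells whose only detections are in *ungrouped* variants are
`unassigned`, not WT — they carry evidence, just not interpretable
evidence. Under any-read positivity a stray error landing exactly on
another clone's variant allele also produces a doublet flag; at error
rate $10^{-3}$ and 100X this happens to a few percent of cells, which is
visible in the README example and is the main argument for
`min_support = 2` in error-rich data.

`population_hierarchy()` lifts the same logic to sorted cell populations
(e.g. pre-leukemic HSCs, leukemic stem cells, blasts): a variant present
above the reporting threshold in two or more populations is
`shared_across_populations` (placing those populations on a common
lineage branch), otherwise specific to its population. Output rows are
ordered by breadth of sharing, then position.

## The simulator

`simulate_cells()` generates the data structure the pipeline consumes,
with known truth:

* each cell draws a clone from `clone_fractions`;
* for each variant in the clone's set, the cell draws a cellular VAF from
  a Beta distribution parameterized by mean and concentration
  (`shape1 = m\kappa`, `shape2 = (1-m)\kappa`). The Beta family is chosen
  for conjugacy with binomial read sampling and because random mtDNA
  segregation produces exactly this kind of unit-interval spread;
  `vaf_concentration = 80` (a moderate spread) is the fixture default and
  `Inf` fixes the VAF;
* per covered site, depth is drawn from a negative binomial (default;
  mean 50, size 10 — overdispersed like real per-site ATAC coverage),
  Poisson, or fixed model; variant-supporting reads are
  $\mathrm{Bin}(d, f)$; each remaining read flips to an error allele with
  probability `error_rate` (default $10^{-3}$, a typical post-quality-
  filter substitution rate), split evenly over the three non-reference
  alleles — so ref + alt + error reads sum exactly to the drawn depth;
* reads are assigned to the forward strand with probability
  `strand_prob = 0.5`;
* a `doublet_rate` fraction of libraries merge the counts of two
  independently drawn cells, matching the additive-mixture interpretation
  of microfluidic doublets. Note that only *mixed-clone* doublets are
  observable; tests compare flagged fractions against
  `doublet_rate × P(two different clones)`.

Simulation is deterministic given the config (including its seed):
identical configs give bit-identical output, asserted in the tests. By
default all positions 1..`genome_length` are simulated densely, so
genome-denominator coverage summaries (and the 40X WT rule) behave
honestly; `covered_positions` restricts simulation to chosen sites, used
for large detection-rate experiments where only the variant positions
matter. Desk-scale tests use reduced genome lengths (100–2000 bp) with
dense coverage rather than sparse sites on the full genome — the
statistical structure is identical and the suite stays fast; the
acceptance script simulates 10,000 cells at the variant sites only.

What the simulator does *not* emulate: alignment artifacts (homopolymer
misalignment enters only through the blacklist), sequence-context error
spectra, strand-correlated damage, library-size variation across cells
beyond the depth model, and selective or asymmetric mitochondrial
inheritance. Passing tests on simulated data therefore demonstrate the
statistical machinery — binomial dropout, clone grouping, doublet
arithmetic — not robustness to alignment pathology, which must come from
the upstream pileup producer.

## Numerical and degenerate-input choices

* VAF is computed as supporting reads over total site depth; the
  candidate floor uses `vaf >= min_vaf` (closed) while classification
  cuts are open (`> 0.9`, `> 0.01`) matching their prose definitions.
* Strand-balance uses strict inequalities; a call with zero alt reads on
  one strand fails both the support and the balance condition.
* `combined_detection_rate()` and `detection_probability()` are exact
  closed forms; no Monte-Carlo is used outside tests.
* Empty pileups yield empty (zero-row) call tables, not errors; a
  position absent from a cell yields support 0 / depth 0; an empty clone
  set list yields all-`unassigned`/`WT` assignments.
* Ties in clone-set ordering (equal carrier counts) resolve by the
  grouping order of the underlying components; variant ids within a set
  are sorted lexicographically for stable output.
* All randomness flows through explicit seeds (`withr::with_seed`);
  `simulate_bulk()` offsets the cell seed by one so bulk and cells from
  one config are independent draws.

## Limitations

* Substitutions only — no indels, no phasing along reads.
* The co-detection test assumes detections are independent across cells
  under the null; strong depth correlation between variants is only
  partially absorbed by the optional weighting.
* No imputation of missing genotypes: dropout is modelled, not repaired.
* Deep hierarchies (clones nested within clones) are reported only as the
  shared/specific partition of `population_hierarchy()`; full phylogeny
  reconstruction is out of scope.
* Mean coverage for the WT rule uses the whole-genome denominator; for
  targeted or sparse site sets, supply an appropriate `genome_length` or
  the rule will be conservative.
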