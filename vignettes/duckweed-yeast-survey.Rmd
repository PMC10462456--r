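---
title: "Analysing a culture-based duckweed yeast survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing a culture-based duckweed yeast survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duckweedyeast)
```

## The problem

Culture-dependent surveys of plant-associated microbes produce a simple but
information-dense artefact: an inventory of isolated strains, each tied to an
environmental sample, identified by a barcode sequence, and screened for
functional traits. `duckweedyeast` implements the complete quantitative
analysis of such an inventory for a survey of yeasts on duckweed
(*Lemnaceae*): 252 strains cultured from 53 of 72 collected samples across
four host genera (*Landotia*, *Lemna*, *Spirodela*, *Wolffia*), identified to
58 taxa by the D1/D2 domain of the LSU rRNA gene, and screened for three
plant-growth-promotion (PGP) traits — indole-3-acetic acid (IAA) production,
siderophore production, and phosphate solubilization.

The packaged inventory (`duckweed_survey_path()`) is the worked dataset;
every statistic below can equally be computed on a user-supplied table in the
same format or on synthetic surveys from `simulate_survey()`.

## The data model

The survey table is one row per strain. Two details matter more than they
look:

* **Assay cells are tri-state.** A measured `0` means *assayed, no
  activity*; `-` means the strain did not grow on the assay plate (CAS agar
  for the siderophore screen); `nd` means the assay result is unavailable.
  These are different denominators: producers and assayed non-producers
  partition the *assayed* strains, while `no_growth` and `not_determined`
  strains are excluded from both. Cells of the form `a ± b` keep the mean
  `a`; the replicate SD `b` is carried as metadata and never used by a
  statistic.
* **Samples that yielded nothing exist.** 19 of the 72 collected samples
  produced no isolates and therefore no rows. The number of *collected*
  samples is supplied by the caller (`n_samples_collected = 72`) rather than
  inferred, because it is the denominator of frequency of occurrence.

The `host_genus` column of the packaged inventory is a **reconstruction**:
per-strain host genera are not published, so the 53 yeast-bearing samples
were partitioned to match the published per-genus totals exactly (33/9/8/3
samples carrying 183/36/23/10 strains for
*Lemna*/*Spirodela*/*Landotia*/*Wolffia*), with the constraint that the two
species observed on all four genera (*Papiliotrema laurentii*,
*Crinitomyces flavificans*) indeed span all four. Statistics that do not
group by host genus are unaffected; genus-grouped outputs (the per-genus
abundance subsets and the genus-pooled ordination) depend on this synthetic
assignment and should be read as structurally plausible rather than
historically exact.

## Rank assignment from barcode identity

Identification uses inclusive identity thresholds against the closest type
strain: species level at ≥ 99.41% (Ascomycota) or ≥ 99.51%
(Basidiomycota), genus level at ≥ 97.11% for either phylum, otherwise
unplaced. Inclusivity is forced by the convention that the genus-level band
runs *from* 97.11%: a strain at exactly the cutoff is inside the band.
`assign_rank()` is monotone in identity by construction and reports the
threshold each identity was actually compared against.

## Alpha diversity and the deduplicated tally

For per-taxon counts $n_i$ with $N = \sum_i n_i$ and $S$ taxa,
$P_i = n_i / N$:

$$H' = -\sum_{i=1}^{S} P_i \ln P_i, \qquad
  E_H = \frac{H'}{\ln S}, \qquad
  1 - D = 1 - \frac{\sum_i n_i (n_i - 1)}{N (N - 1)}.$$

All logarithms are natural — $E_H = H'/\ln S$ fixes the base. The Simpson
index is the finite-sample (unbiased) form exactly; the plug-in
$1 - \sum P_i^2$ variant is deliberately not offered, and the unbiased form
is verified in the test suite against exhaustive pair enumeration on every
abundance vector with $N \le 8$.

**Which tally?** The survey's protocol excluded isolates with identical
barcode sequences before computing diversity, richness and ordination. The
inventory does not record sequences, so the exclusion cannot be replayed
exactly. The package therefore exposes both tallies:

* `to_abundance(survey)` — raw strain counts (58 taxa, $N = 252$), the
  contract used by frequency statistics (relative frequency is defined on
  strains);
* `to_abundance(survey, dedup = "sample")` — at most one strain per taxon
  per sample (58 taxa, $N = 148$), the closest inventory-level proxy for
  the identical-sequence exclusion, since conspecific isolates from one
  sample are the likeliest duplicates.

The headline diversity report and the acceptance script use the
deduplicated tally. On the raw tally the indices are systematically lower
(the dominant species' 55 strains weigh more), and the true
sequence-level tally lies between the two; this is an irreducible
uncertainty of reanalysing from the inventory alone.

```{r}
survey <- read_survey(duckweed_survey_path(), n_samples_collected = 72)
diversity_report(to_abundance(survey, dedup = "sample"))
```

Frequency statistics use their natural denominators: relative frequency
$RF_t = 100\,n_t/N$ over strains (raw tally), and frequency of occurrence
$FO_t = 100\,s_t/72$ over *collected* samples — a species found in 18
samples has $FO = 25\%$ even though only 53 samples yielded yeasts.

## Richness estimation and accumulation

Three nonparametric estimators, in their standard forms:

* **Chao1** (abundance-based): with $F_1$ singletons and $F_2$ doubletons,
  the default bias-corrected form is $S_{obs} + F_1(F_1-1)/(2(F_2+1))$;
  `variant = "classic"` gives $S_{obs} + F_1^2/(2F_2)$, falling back to the
  corrected form when $F_2 = 0$. Bias-corrected is the default because it
  is the default of the survey software family this analysis mirrors, and
  it is defined for every input.
* **First-order jackknife** (incidence-based):
  $S_{obs} + Q_1 (m-1)/m$, $Q_1$ = taxa in exactly one of $m$ samples.
* **Analytic bootstrap** (incidence-based):
  $S_{obs} + \sum_k (1 - p_k)^m$, $p_k$ = fraction of samples containing
  taxon $k$.

The accumulation curve randomises sample order (default 100 permutations,
seed mandatory) and reports, for every prefix length $t$, the mean and SD of
observed richness and of all three estimator trajectories computed on the
pooled prefix. Randomisation was chosen over the closed-form expectation
because one mechanism then serves the observed curve and the estimator
curves uniformly; at this scale the two agree within Monte-Carlo error. At
$t = m$ pooling is order-independent, so the curve ends exactly at the
full-survey values with zero spread — a property the tests assert. The
jackknife factor $(m-1)/m$ vanishes at $t = 1$, so curves are defined from
the first sample without a special case.

## Jaccard distances and PCoA

Community similarity uses presence/absence: for sample taxon sets $T_i$,
$d_{ij} = 1 - |T_i \cap T_j| / |T_i \cup T_j|$. Principal coordinate
analysis Gower-centres the squared distances,
$B = -\tfrac12 C (d \circ d) C$, and eigendecomposes $B$. Numerical
choices, all made for reproducibility:

* axes are retained while $\lambda_j > 10^{-10} \lambda_1$ (relative
  tolerance, adjustable);
* negative eigenvalues — Jaccard distances need not be Euclidean-embeddable
  — are reported unaltered; no Lingoes/Cailliez correction is applied,
  matching common practice for this analysis;
* eigenvector sign is fixed by making the largest-magnitude coordinate of
  each axis positive, so output does not depend on the eigen-solver's sign
  whims;
* coordinates are centred by construction (asserted to $10^{-10}$ in tests),
  and a planted Euclidean configuration is recovered to Procrustes residual
  below $10^{-8}$.

The default grouping ordinates the 53 per-sample communities labelled by
host genus; `grouping = "host_genus"` pools four genus-level communities
instead. Both are provided because the survey's figure does not state its
grouping; neither is asserted to be the original.

## PGP trait summaries

A *producer* is a strain whose measured mean is strictly positive. The
plate-assay ratios are dimensionless: siderophore activity units (AU) =
orange-halo diameter / colony diameter on CAS agar; solubilization
efficiency (SE) = clear-zone diameter / colony diameter on Pikovskaya's
agar (`activity_ratio()`, also applied across optional per-strain diameter
columns by `zone_ratios()`). Producers are binned into left-closed
intervals; the default edges — IAA 0/50/100/∞ mg/L, AU 0/2/∞, SE 0/1/∞ —
are the only edge sets consistent with the survey's reported screening
ranges, whose printed endpoints are data-driven minima and maxima within
each bin. The four assay states always partition the table, and bin counts
always sum to the producer count; both invariants are enforced by tests.

## The synthetic survey generator

`simulate_survey()` draws surveys with the structure the analysis assumes:
a pool of `S_true` taxa with geometric (default) or log-series ranked
abundances, `n_samples` collected samples of which a fraction
`p_empty_sample` yields nothing, Poisson isolate counts, host genera drawn
per sample by weight, barcode identities drawn inside the rank band of
their taxon, and zero-inflated lognormal trait assays (the CAS screen
additionally drawing `no_growth`). One root seed drives a named substream
per sample, so early samples are unchanged when `n_samples` grows — a
property the tests pin down — and output is byte-identical per seed.

Defaults are the surveyed conditions: 72 samples, `p_empty = 19/72`,
`252/53` isolates per yielding sample, genus weights `33/9/8/3`, geometric
`k = 0.22` matching the observed 22% dominance of the top species, and
trait rates estimated from the inventory (IAA producers 178/223 assayed,
AU 173/218 with 21/252 no-growth, SE 106/239). `S_true = 70` represents a
regional pool somewhat above the 58 observed taxa, in line with what the
richness estimators indicate.

What the generator does *not* emulate: a geometric series with the observed
dominance decays far faster than the real community's long singleton tail,
so default simulations observe fewer taxa than the real survey at equal
effort; there is no spatial or temporal structure, no per-genus community
differences, and identities are uniform within rank bands rather than
phylogenetically structured. Passing tests on synthetic surveys therefore
validate the estimators' mechanics and seeded reproducibility, not the
ecological realism of any particular parameter set. Estimator-recovery
tests use a deliberately saturating design (20 taxa, `k = 0.1`, 25 samples
of ~50 isolates, 20 replicate seeds) where the whole pool is observable;
the survey-like defaults are used where only bounds, not recovery, are
asserted.

## Numerical and reporting conventions

* Display rounding is half-up (`round_half_up()`), 2 dp for indices and
  1–2 dp for percentages, matching the survey's reporting; all internal
  computation is full precision. `run_all(..., rounding = "display")`
  applies this profile to the emitted report; the default emits full
  precision.
* Degenerate inputs fail loudly and early: single-taxon evenness, $N < 2$
  Simpson, single-sample jackknife, empty host-genus subsets, all-zero
  incidence rows, non-symmetric distance matrices and all-nonpositive
  eigenspectra are errors, not NAs.
* `run_all()` writes TSV/JSON only, with no timestamps, so re-runs with the
  same inputs and seed are byte-identical.

## Problem sizes

The test suite and the analysis scripts run the full 252-strain inventory
everywhere it appears; exhaustive oracles are bounded ($N \le 8$ for
Simpson pair enumeration, $N \le 10$ for the evenness maximality search),
accumulation curves use 30–100 permutations, and synthetic benchmarks use
20 replicate seeds of ~1,250-isolate surveys — sizes chosen so the whole
suite completes in well under a minute while keeping Monte-Carlo error far
below the asserted margins.

## Known limitations

* The identical-sequence exclusion behind the survey's headline indices is
  approximated by per-sample deduplication (see above); the raw and
  deduplicated tallies bracket the original.
* Host-genus labels in the packaged inventory are reconstructed, not
  transcribed.
* The threshold module ranks a single supplied identity; ties among
  multiple closest type strains, alignment and BLAST are out of scope.
* No significance testing is attached to the ordination (no
  PERMANOVA/ANOSIM), and richness estimators are reported without
  confidence intervals, mirroring the original analysis.
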