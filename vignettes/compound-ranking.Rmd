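---
title: "Ranking compounds for aging modulation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking compounds for aging modulation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agerank)
```

## The problem and the model

Many genes modulate aging in *C. elegans* and *D. melanogaster*, and many
drug-like compounds bind the mammalian orthologues of those genes in
solved complex structures. `agerank` scores each such compound for its
likelihood of modulating aging in one invertebrate species, so that
experimentalists can pick a short candidate list for lifespan assays.

The score is an empirical composite:

$$s = \mathrm{clip}_{[0,1]}\!\left(
  f_{\text{aging}} \cdot f_{\text{dom}} \cdot f_{\text{site}} \cdot
  f_{\text{aff}} \cdot f_{\text{bio}}
  + t_{\text{lip}} + t_{\text{prom}} + t_{\text{purch}} + t_{\text{appr}}
\right)$$

The five factors are multiplied because each is a *requirement*: a
compound that cannot reach its target, or whose binding site is not
conserved, should not be rescued by excellent values elsewhere. The four
terms are conveniences and red flags (drug-likeness, promiscuity,
purchasability, approval status) that only modulate the base score.

All factor transforms use the logistic
$\mathrm{logistic}(x; l, s) = 1/(1 + e^{-(x-l)/s})$, which spends its
dynamic range on *medium* values — differences between mediocre and good
similarity matter more than equally large differences between two
excellent or two hopeless values. This parameterisation is confirmed by
the affinity factor: the five reference compounds with reported
dissociation constants (100, 23, 35, 63, 120 nM) reproduce their
two-decimal reference factors (0.88, 0.93, 0.92, 0.90, 0.87) exactly under
$\mathrm{logistic}(-\log_{10} K_d;\, 5,\, 1)$.

## Conservation factors

Residue similarity is Grantham-based: $sim(a,b) = 1 - d(a,b)/215$, where
$d$ is the published physicochemical distance (maximum 215). The vendored
20×20 table was cross-checked cell-by-cell against a reconstruction from
the composition/polarity/volume formula; every cell agrees within the
integer rounding of the published table. Ambiguity codes are averages: B
over {D, N}, Z over {Q, E}, X over all twenty; the extended 23×23 matrix
ships as `inst/extdata/grantham_similarity.tsv` and a test rebuilds it
from the distances.

**Domain conservation** compares reference and orthologue over the
*scoring regions*: every annotated domain interval containing a ligand
contact, plus a ±50-residue window around each contact that falls outside
all domains (window size is a config parameter; 50 is the default).
Overlapping and adjacent intervals are merged, so double-covered residues
are counted once. The mean similarity over the region columns passes
through `logistic(x; 0.6, 0.1)` — midpoint at 60% similarity, where
orthologue pairs begin to be credible binders.

**Binding-site conservation** uses the ligand-contact positions
(PDBsum-style lists on the ungapped reference), mapped through the family
alignment to columns. Because most binding sites are mostly identical,
only the 50% most dissimilar positions are averaged: with $N$ site
columns, the $k = \max(1, \lfloor N/2 \rfloor)$ lowest per-column
similarities. Floor (rather than ceiling) reproduces the worked reference
value for an 11-residue site with a single Y→H substitution,
$(0.614 + 4)/5 \approx 0.92$; ceiling remains available via
`ranking_config(k_mode = "ceil")`.

## Numerical and policy choices

* **Gap policy** (not specified by the procedure's description; our
  choice, exposed in the functions' contracts): alignment columns where
  the *reference* is gapped leave the denominator — they have no
  structure-side residue to compare. A gap in the *homologue* at a
  considered column counts as a mismatch (identity contribution 0,
  similarity 0) and as a gap for homologue selection: a deletion at a
  contact position is evidence against conserved binding, so it is
  penalised, not skipped.
* **Homologue selection**: per family and species, fewest binding-site
  gaps, then highest site similarity, then highest site identity, then
  lexicographic member id. The final tie-break makes the pipeline
  deterministic under input reordering.
* **Aging-implication formula**: the published rendering of the mapping
  discount is typographically ambiguous. The default reading is
  $1 - (ev + 0.1\,m)/2$; the alternative $1 - ev - 0.1\,m/2$ is selectable
  via `ranking_config(aging_formula = "half_mappings")`. Both floor at 0.
  One reference compound's printed aging value (0.98) is not derivable
  under either reading from the listed evidence classes; it is treated as
  an input in validation rather than recomputed.
* **Evidence pairs**: the paired scores per GO category (0.01/0.02 etc.)
  are mapped to direct vs orthologue-transferred annotation; GenAge
  overrides to 0.01 regardless of category.
* **Multi-target aggregation**: domain conservation, site conservation
  and affinity are aggregated by maximum across targets — the compound
  only needs one good, conserved target. Aging implication is aggregated
  by maximum too, for consistency (the procedure's description lists only
  the first three).
* **Lipinski boundaries**: violations fire at mw ≥ 500 Da, logP > 5,
  donors > 5, acceptors > 10, following the rule's "less than 500 /
  no more than" phrasing.
* **Clipping and display**: the composite is clipped to [0, 1]; all
  internal math is unrounded. Report cards display two decimals (halves
  rounding up) and keep the unrounded score to six decimals in JSON.
* **Ranking ties** receive distinct consecutive ranks (ordered by HET
  code), so absolute rank statements are well defined; the top-10% cutoff
  indexes rank $\max(1, \lfloor N/10 \rfloor)$ (floor chosen; the
  alternative affects at most one rank).

## The synthetic-data generator

`simulate_ranking_data()` builds a full input set — aligned families,
contacts, domains, compounds, evidence, links — plus expected score
breakdowns from an independent oracle. Each family is a random root
sequence (the human reference, default 300 residues, the scale of a
kinase catalytic domain) with per-species substitution rates scaled by
divergence multipliers (rodents 0.15, fly 1.0, worm 1.25 of the base rate,
default 0.2). These defaults give invertebrate global identities around
60–80% and well-conserved binding sites, the regime of the kinase families
that dominate real rankings. Binding sites default to 10 residues, a
typical small-molecule pocket; log-affinities are drawn around 6.5 ± 1.2
(tens of nanomolar); Burns scores around 5 ± 2.

The generator deliberately omits features of real data: no indels (all
members share the alignment frame, so gap handling is exercised only by
the unit tests), no correlation between conservation and affinity, no
multi-domain architectures, and uniform residue usage. Passing tests
therefore demonstrate the *arithmetic* of the pipeline — factor
computation, mapping, selection, aggregation, ranking — on realistic
scales, not biological realism of any particular score.

The oracle (`oracle_score_breakdowns()`) is a straight-line, loop-based
reimplementation of every formula that shares no code with the pipeline
beyond the distance TSV: positions are mapped by character scanning,
scoring regions are a per-position mask rather than merged intervals, and
each transform is written inline. Pipeline and oracle agree exactly
(difference 0, not merely within tolerance) on the synthetic corpora used
in the tests.

## Problem sizes and runtime

The test suite runs with 6 families × 5 species × 300 residues and 12–100
compounds, and the property suites use 10^4 random factor draws; the full
suite completes in well under a minute. These sizes were chosen to
exercise every code path — multi-target compounds, out-of-domain contacts,
species-absent exclusions — while keeping iteration fast; the scoring
arithmetic is identical at any corpus size, and the pipeline scales
linearly in links.

## Known limitations

* Dataset-scale quantities of the original application — corpus counts,
  absolute ranks of named drugs, the 0.91/0.81 and 0.56/0.40 distribution
  cutoffs — depend on external databases and predictor runs
  (Ensembl/UniProt mappings, RF-Score, the Burns predictor) that are
  consumed here as inputs, and so cannot be recomputed from this package
  alone; validation instead recomposes the vendored reference components.
* The package consumes alignments; it does not build them. Alignment
  quality directly bounds the conservation factors.
* The *D. melanogaster* bioavailability constant (0.9) is an explicit
  placeholder for a predictor that does not yet exist; tailored rankings
  can down-weight or exclude the factor
  (`tailored_score(b, factor_weights = c(bioavailability = 0))`).
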