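# agerank

Prioritising drug-like compounds for lifespan experiments in
*Caenorhabditis elegans* and *Drosophila melanogaster*.

Pharmacological screens in invertebrate models are the practical entry
point for testing whether existing, well-characterised compounds modulate
aging — but screening thousands of compounds blind is infeasible. `agerank`
implements an empirical ranking procedure for compounds with known
mammalian protein targets and solved ligand–protein complex structures. It
asks, for each compound and each model organism: is the target implicated
in aging, is the binding interface conserved in the invertebrate
orthologue, does the compound bind tightly, will it reach its target, and
is it practical to test? Compounds are scored, ranked, and documented with
per-compound report cards. The package is aimed at researchers assembling
candidate lists for *in vivo* lifespan assays.

## The scoring model

The ranking score is bounded to [0, 1] and combines five multiplicative
factors with four additive terms:

```
score = clip01( Aging × DomainCons × SiteCons × Affinity × Bioavail
                + LipinskiLoss + PromiscuityLoss
                + PurchaseBonus + ApprovalBonus )
```

Multiplicative linkage means no factor can compensate for another: a
perfectly conserved target with negligible binding affinity scores poorly,
as does a strong binder whose target has no invertebrate orthologue.

- **Aging implication** — from Gene Ontology evidence codes for the
  target's aging annotation (experimental 0.01 … automatic 0.29; GenAge
  listing forces 0.01), discounted for identifier-mapping steps:
  `1 − (ev + 0.1·m)/2`.
- **Domain conservation** — Grantham-based similarity (`1 − d/215`)
  between the structure's sequence and the selected orthologue over the
  domains containing ligand contacts (±50-residue windows for contacts
  outside domains), through `logistic(x; 0.6, 0.1)`.
- **Binding-site conservation** — mean Grantham similarity of the 50% most
  dissimilar ligand-contact positions, mapped through the family
  alignment.
- **Binding affinity** — `logistic(x; 5, 1)` of the predicted log-affinity
  `x = −log10(Kd)` (e.g. an RF-Score prediction); 100 nM ⇒ 0.88.
- **Bioavailability** — *C. elegans*: `logistic(Burns; 4, 2.25)·0.8 + 0.2`
  from the Burns bioaccumulation predictor; *D. melanogaster*: fixed 0.9
  substitute.
- **Terms** — Lipinski rule-of-five loss `−n/20`; promiscuity loss
  `−logistic(#targets; 7, 1)/5`; +0.1 if purchasable (ZINC/eMolecules);
  +0.1 approved drug (ChEMBL) or +0.075 if only in DrugBank.

Per compound, factors are aggregated over multiple targets by maximum; the
orthologue scored per family and species is the one with fewest
binding-site gaps (ties: highest site similarity, then identity).

## Worked example

Scoring components behave as closed forms — a dasatinib-like breakdown
(all factors near 1, both bonuses) saturates the score:

```r
library(agerank)
composite_score(1, 0.96, 1, 0.95, 0.9,
                purchase_bonus = 0.1, approval_bonus = 0.1)
#>   aging domain_cons site_cons affinity bioavailability ... final
#> 1     1        0.96         1     0.95             0.9 ...     1

round(affinity_factor(log_affinity_from_kd(c(1e-7, 2.3e-8, 1e-3))), 4)
#> [1] 0.8808 0.9333 0.1192   # 100 nM, 23 nM, 1 mM
```

A full synthetic run (the generator emulates families, contacts, domains,
compounds, evidence and links; see the vignette):

```r
sim <- simulate_ranking_data(seed = 42, n_compounds = 8)
scored <- score_compounds(sim$links, sim$compounds, sim$evidence,
                          sim$families, sim$contacts, sim$domains, sim$config)
ranking <- rank_compounds(scored$breakdowns)
ranking |> dplyr::select(rank, het_code, final)
#>    rank het_code final
#> 1     1 C01      0.517
#> 2     2 C04      0.510
#> 3     3 C08      0.503
#> ...
glance(ranking)
#>   n_ranked min_score max_score top15_cutoff top10pct_cutoff
#> 1        8     0.280     0.517        0.280           0.517
```

The worm scores sit well below 1 mostly because of the bioavailability
factor, mirroring the behaviour of real rankings. `autoplot(ranking)`
draws the score density with the top-15 (dashed) and top-10% (dotted)
cutoffs; `render_report_card(ranking[1, ], "json")` emits the per-compound
report card.

A command-line wrapper ships in `inst/cli/agerank`:

```sh
inst/cli/agerank simulate --seed 4 --out-dir in/
inst/cli/agerank rank --in-dir in/ --species celegans --out-dir out/
inst/cli/agerank report --ranking out/ranking.tsv --het C01 --format html
```

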