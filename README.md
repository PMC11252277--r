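# saprolens

Bioassessment of running waters from planktonic protozoan communities.

Free-living heterotrophic protozoans respond within days to changes in
organic load, which makes them practical sentinels of river water quality.
`saprolens` implements the full desk pipeline a monitoring campaign needs,
from the microscope to a quality class:

* **Enumeration** — Sedgwick-Rafter chamber counts to concentrations,
  `N/mL = C·V_C·1000 / (V_T·N)`;
* **Biometry** — geometric biovolume (sphere, oval, ellipsoid, cone,
  cylinder), dry weight at 0.524 pg·µm⁻³, biomass in µg·L⁻¹;
* **Community indices** — richness, Shannon `H' = −Σ p_i ln p_i`,
  occurrence frequency, frequency-weighted dominance `Y_i = (n_i/N)·f_i`
  (dominant at ≥ 0.02), phylum shares, grouped mean ± SD summaries;
* **Saprobity** — the Pantle–Buck index `SI = Σ S·h / Σ h` over
  saprobity-coded taxa, classified into the seven half-open bands from
  oligosaprobic (class I) to polysaprobic (class IV);
* **Community–environment matching** — square-root transform, Bray–Curtis
  and (standardised) Euclidean dissimilarities, Ward clustering with
  similarity-level cuts and Newick export, Spearman screens, Mantel-type
  matrix correlation with permutation inference (RELATE) and exhaustive
  best-subset selection of environmental variables (BIOENV);
* **Simulation** — a seeded generator of balanced multi-site campaigns with
  a lognormal species-abundance distribution, occupancy, seasonality, and a
  planted pollution gradient coupled to saprobic valences and to chosen
  environmental drivers, plus a recovery scorer.

A published six-site, twelve-month Nile River survey ships as plain-text
fixtures (species table with abundance, biomass, saprobity codes and
feeding guilds; environmental site means; the saprobic classification), so
every step can be exercised against printed numbers.

## Worked example

```r
library(saprolens)

avg <- load_study_fixture("table4_averages")
sprintf("Taxa: %d | mean abundance %.1f ind/L | mean biomass %.2f ug/L | H' %.3f",
        nrow(avg), sum(avg$abund_avg), sum(avg$biom_avg), shannon(avg$abund_avg))
#> "Taxa: 54 | mean abundance 1088.9 ind/L | mean biomass 86.61 ug/L | H' 3.127"

sm  <- load_study_fixture("table4_site_means")$abundance
reg <- load_study_fixture("trait_registry")
campaign_saprobity(sm, reg, group_by = "site")[, c(1:4, 7)]
#>   group   SI n_classified_taxa classified_fraction  class
#> 1     I 2.42                14               0.695 II-III
#> 2    II 2.49                15               0.707 II-III
#> 3   III 2.50                18               0.760 II-III
#> 4    IV 2.31                17               0.704 II-III
#> 5     V 2.43                12               0.784 II-III
#> 6    VI 2.75                13               0.699    III
```

The six sites classify as moderately-to-critically loaded (II-III) except
the downstream agricultural site VI, which is α-mesosaprobic (class III)
and carries the highest index — the survey's central finding. Only about
70% of abundance carries a saprobity code; the `classified_fraction`
column makes that coverage explicit.

```r
head(dominance(sm)[, c("taxon_id", "relative_abundance",
                       "occurrence_frequency", "dominance")], 4)
#>                     taxon_id relative_abundance occurrence_frequency dominance
#> 43 paradileptus_elephantinus             0.1952                1.000    0.1952
#> 32          didinium_nasutum             0.0804                1.000    0.0804
#> 54    vorticella_convallaria             0.0893                0.833    0.0744
#> 16    acanthocystis_turfacea             0.0625                1.000    0.0625
```

The omnivorous ciliate *Paradileptus elephantinus* is present at every site
and alone carries a fifth of community abundance — dominance 0.195, far
above the 0.02 threshold.

Simulated campaigns validate that the pipeline recovers planted structure:

```r
camp <- generate_campaign(campaign_config(seed = 42))
rec  <- recovery_suite(camp, k_max = 2)
sprintf("SI-gradient Spearman: %.3f | BIOENV top subset: %s | dominant recall: %.2f",
        rec$si_gradient_rho, paste(rec$bioenv_top_variables, collapse = " + "),
        rec$dominance_recall)
#> "SI-gradient Spearman: 1.000 | BIOENV top subset: Turb + NH3 | dominant recall: 1.00"
```

The per-site saprobic index reproduces the planted pollution gradient
exactly, and the best environmental subset contains one of the planted
drivers (NH3).

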