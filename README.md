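# fdlandings

Trait-based functional diversity analysis of fisheries landings.

Fisheries landings are a record of which ecological roles fishing
removes from an ecosystem. `fdlandings` turns a species × trait table
and a per-(species, year, month, fleet) landings table into that
record: it codes 14 categorical fish traits (76 modalities across four
ecosystem functions — habitat use, locomotion, feeding, life history;
13 crisp traits plus a fuzzy-coded diet) into a merged binary/fuzzy
matrix, builds a Gower-type mixed trait distance

d(i,j) = sqrt( (1/K) Σ_k δ_k(i,j) ),   δ_k = matching (crisp) or
half-Manhattan (fuzzy) dissimilarity on trait block k,

ordinates species by principal coordinates analysis (retaining
m = ⌊log₂ s⌋ axes for s pool species), and computes the four
landings-weighted functional diversity metrics in that space:

* **FRic** — convex-hull volume of the assemblage, standardised by the
  full pool's hull (so the pool scores 1);
* **FEve** — minimum-spanning-tree evenness of species spacing and
  weighting (Villéger et al. formulation), in [0, 1];
* **FDiv** — weighted divergence from the mean distance to the
  hull-vertex centroid, in [0, 1];
* **FDis** — weighted mean distance to the weighted centroid
  (Laliberté & Legendre).

Differences between fleets and between decade pairs are tested with
trait-profile permutation null models (whole coded rows reassigned to
species; exceedance p-values over 999 permutations), and trait–species
associations are explored by fuzzy correspondence analysis (FCA) with
per-axis inertia decomposition, modality–axis Pearson correlations and
convex-hull vertex species. A synthetic generator emulates the
structure of multi-decadal, two-fleet, strongly dominance-skewed
landings records for method evaluation, calibration and power studies.

## Worked example

```r
library(fdlandings)
library(dplyr)

cfg <- scenario_config(n_species = 100, seed = 42)   # synthetic study
sc  <- simulate_scenario(cfg)                        # pool + landings
sc$coded
#> <coded_traits> 100 species x 76 modalities in 14 trait blocks (1 fuzzy)

agg <- standardize_weights(aggregate_landings(sc$landings, by = "fleet"))
fd  <- compute_fd(sc$coded,
                  filter(agg, fleet == "local")[, c("species", "weight")])
fd
#>            fun nbsp sing_sp quali_fric n_axes fric_raw fric_std  feve  fdiv  fdis
#> 1  habitat_use  100     100      0.506      6  0.00289        1 0.520 0.882 0.409
#> 2   locomotion  100      68      0.643      6  0.00426        1 0.482 0.937 0.516
#> 3      feeding  100      97      0.606      6  0.00373        1 0.448 0.900 0.461
#> 4 life_history  100      93      0.554      6  0.00400        1 0.515 0.882 0.444
#> 5          all  100     100      0.407      6  0.00154        1 0.450 0.867 0.373
```

Reading the table: all 100 pool species appear in the local fleet's
landings (`nbsp`), but only 68 distinct locomotion profiles exist among
them (`sing_sp`, the functional-entity count). The retained 6-axis
space carries 41–64% of the trait-distance structure (`quali_fric`).
The assemblage spans the full pool's trait space (`fric_std = 1`,
since every species is landed), with moderate evenness (~0.45–0.52)
and high divergence (~0.87–0.94): the heavily landed species sit far
from the trait-space centre.

Is the local/coastal difference in feeding-trait evenness more than a
random arrangement of trait profiles would produce?

```r
wa <- filter(agg, fleet == "local")[,   c("species", "weight")]
wb <- filter(agg, fleet == "coastal")[, c("species", "weight")]
nt <- null_test(sc$coded, wa, wb, metric = "FEve", fun = "feeding",
                n_iter = 199, seed = 1)
nt
#> <fd_null_test> FEve / feeding: |0.4483 - 0.4533| = 0.004906, p = 0.392
#>   (199 of 199 iterations)
```

Here p = 0.392: the observed difference (0.0049) is typical of the
permutation distribution, as expected under this null scenario (the
generator assigned landings independently of traits). `tidy(nt)` gives
the one-row results table; `run_comparisons()` runs the full battery
(fleet pair + six decade pairs per fleet × four metrics × five function
sets), and `run_pipeline()` writes every intermediate artifact (coded
matrix, distances, ordinations, FD tables, null tests, FCA tables) as
CSV with a manifest.

## Documentation

The methods vignette
(`vignettes/trait-diversity-of-landings.Rmd`) explains the models, the
design decisions (distance construction, axis retention, zero-weight
handling, null-model statistic), what the synthetic generator does and
does not emulate, and the package's known limitations — including a
Monte-Carlo characterisation of which metrics the permutation test can
and cannot detect composition shifts with.
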