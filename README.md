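# aiidval

Validation of **acoustic individual identification (AIID)** predictions
*without ground-truth labels*, for passive acoustic monitoring of
territorial species.

Recorder arrays can localize a vocalizing animal by multilateration, and a
classifier can predict which individual (or family group) called. But in
wild populations there is rarely an annotated test set to tell you whether
those ID predictions can be trusted. `aiidval` scores the predictions
against the *spatial* behaviour territoriality imposes, along two
independent routes:

1. **Locality assumptions.** Within one day, an individual sings only
   within a close radius of itself, and no two individuals sing within
   that radius of each other. Each localized call is scored for
   - *consistency* — its predicted ID is a modal ID among the other calls
     within the close radius, and
   - *specificity* — it has strictly more same-ID calls inside the radius
     than outside.

   The mean of the two proportions estimates classifier accuracy; a
   label-corruption simulation (systematic class confusions with
   probability *q*, isolated mistakes with probability *p*, over a
   3,000-run grid in *N*, *n*, *q*, *p*) calibrates how well it tracks the
   true accuracy it cannot see.

2. **Home-range agreement.** When approximate (possibly overlapping)
   home-range polygons are known: per-group kernel-density rasters
   (bandwidth 1,000 m in the `MASS::kde2d` convention, 50 × 50 grid) are
   summed within each polygon to give relative likelihoods; each range's
   profile is summarized by the rank power-law slope *k* (of log *P·i*
   against log *i*; strongly negative = one group dominates), and the
   range × group call counts by normalised mutual information,

   *NMI = Σ n_kc log(N·n_kc / (n_k·n_c)) / √((Σ n_k log(n_k/N))(Σ n_c log(n_c/N)))*.

   Both statistics get one-sided permutation ("exact") tests that shuffle
   IDs over points (10,000 iterations by default).

Supporting stages: TDOA multilateration with convex-hull flagging, song
sequence segmentation, build-up trimming and travel-speed plausibility
filters, and a synthetic territorial-population generator so the whole
pipeline runs without field data.

## Worked example

```r
library(aiidval)

# a synthetic territorial population: 6 groups, 20 days, with the
# classifier emulated at q = 0.1 (confusions), p = 0.1 (isolated errors)
ds <- attach_predictions(
  generate_population(population_config(n_groups = 6, n_days = 20, seed = 7)),
  q = 0.1, p = 0.1, seed = 8)
ds$true_accuracy
#> [1] 0.8776758

# locality-based estimate (radius = the generator's 200 m intra-individual
# distance bound), no labels used:
compute_locality_metrics(ds$calls, locality_config(radius = 200))
#> Locality-assumption validation
#>   consistency : 0.859 (N = 305)
#>   specificity : 0.740 (N = 327)
#>   accuracy (avg of metrics)  : 0.800
#>   accuracy (1 - error count) : 0.740
```

The estimate (0.800) tracks the hidden truth (0.878) with no labels; a
random-ID baseline (`random_baseline()`, 100 runs) scores 0.138 on the
same data, so the classifier is far from chance. The home-range route on
the same dataset:

```r
validate_homerange(ds$calls, ds$homeranges,
                   kde_config(bandwidth = 400), conf_threshold = 0)
#> Home-range agreement (327 calls)
#>   mean power-law coefficient k : -125.525
#>   NMI(home range, group)       : 0.755
#>   dominant groups:
#>     G1 -> G1
#>     ...
```

Each home range is dominated by its true group (the very negative mean
*k* reflects the tight 100 m kernel sd on well-separated territories),
and `permutation_test()` puts both statistics at the minimal attainable
p-value.

A thin command-line front end over these functions ships in
`inst/cli/aiidval.R` (subcommands `validate-locality`, `simulate-sweep`,
`validate-homerange`, `localize`, `synth`).

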