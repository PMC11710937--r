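# socioscope

Social-network and multimodal-communication analysis for stable,
group-living equid societies observed across contrasting periods — for
example a typical dry season versus a severe drought.  The package is
aimed at behavioural ecologists working with nearest-neighbour scan
samples, video-coded multimodal interactions and focal activity budgets,
and turns those three data streams into association networks, signal
co-occurrence networks and analysis-ready budget tables, each with the
resampling null models the field uses.

## What it computes

**Association.** For every within-harem dyad, the simple ratio index of
association over sampling periods,

    SRI = x / (y_a + y_b + y_ab + x)

with `x` = periods in association (nearest neighbour, symmetrised),
`y_a`, `y_b` = periods each member was observed alone, `y_ab` = periods
both were observed but apart.  Per-harem weighted networks over members
older than one year give degree, mean and CV of each individual's bond
strengths, network density, and the harem-level CV of dyadic SRI values.
`preferred_associate_test()` judges that CV against either the literal
edge-randomization null (fixed nodes and edges) or a scan-level
within-period identity permutation — the data-stream null with actual
power against dyadic preference.  `cross_period_dyad_regression()` asks
whether bond strength carries over between periods.

**Communication.** Postures (sets of concurrently produced signal
components) build a weighted co-occurrence network per period after a
cleaning filter drops components seen in fewer than two interactions.
The package reports component diversity (connected nodes) with a
posture-jackknife null, density adjusted for mutually exclusive
morphological states (`n(n-1)/2` impossible pairs per body-part group)
with a node-subsampling null, fast-greedy modules with their modularity
Q, and cross-period module-flow and per-modality signal-loss tables.

**Budgets.** Per-focal activity proportions over a self-maintenance /
passive-social / active-social taxonomy, steps per minute, active
interactions per 30-minute block, and the juvenile mother vs
non-maternal partner table.

**Synthetic data.** Generators with planted ground truth (preferred
dyads, context modules, repertoire masks, target budget proportions)
make every stage testable without field data.

## Worked example

```r
library(socioscope)

# a harem of six adults followed over 40 scan periods, with one planted
# preferred dyad
roster <- tibble::tibble(
  individual_id = sprintf("h01_i%02d", 1:6), harem_id = "h01",
  age_sex_class = c("stallion", rep("nonlactating_female", 5)),
  age_months = 60
)
cfg <- social_sim_config(
  n_harems = 1, n_periods = 40, size_range = c(6, 6),
  planted = tibble::tibble(harem_id = "h01", a_id = "h01_i01",
                           b_id = "h01_i02", multiplier = 4),
  seed = 99
)
sim <- simulate_scans(cfg, roster = roster)
tal <- tally_dyads(sim$scans, roster)
net <- build_harem_network(tal, roster, harem_id = "h01")
net
#> Harem network `h01`: 6 nodes, 15 edges, density 1, CV 0.441

preferred_associate_test(net, n_perm = 1000, seed = 7,
                         null = "scans", scans = sim$scans)
#> Permutation test (within-period identity permutation)
#>   observed: 0.440531
#>   null: n = 1000, mean = 0.282062, 2.5% = 0.182205, 97.5% = 0.392825
#>   p (upper, count convention) = 0.003 [yes]
```

The observed CV of bond strengths (0.44) sits above the null CVs obtained
by relabelling who-is-who within each scan (mean 0.28, 97.5th percentile
0.39), so the harem shows statistically preferred associates (p = 0.003)
— here, the planted dyad.

The full pipeline runs from one config:

```r
bundle <- run_pipeline(list(simulate = TRUE, seed = 42, n_perm = 1000,
                            out_dir = "results/run1"))
bundle$communication$summary
#> # A tibble: 2 × 6
#>   period       n_postures diversity adjusted_density modularity_q n_modules
#>   <chr>             <int>     <int>            <dbl>        <dbl>     <int>
#> 1 pre_drought        1168        36            0.634       0.0625         2
#> 2 late_drought        394        30            0.640       0.0517         2
```

Here the simulated drought period uses a smaller repertoire — 30 of 36
components still connected, the six planted losses flagged by
`modality_loss_summary()` — and low modularity (Q « 0.3) indicates a
graded, flexible repertoire in both periods: the same descriptors a
field dataset would yield.

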