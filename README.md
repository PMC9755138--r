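# dielmove

Daily and seasonal activity analysis for GPS-collared predators and
their prey.

Movement ecologists studying large carnivores in seasonal environments
face a recurring stack of problems: collar fixes arrive on coarse,
battery-saving schedules (every 5 h for the predator here, hourly for
wild prey, a corral schedule for livestock); raw fixes contain
positioning errors; clock time misaligns observations across the year;
and the quantities of interest — when in the diel cycle an animal is
active, how much two schedules overlap, and how schedules shift between
summer and winter — live on the circle, not the line. `dielmove`
implements that full pipeline for displacement (straight-line distance
between consecutive fixes) and accelerometer activity data, for anyone
analysing biologging records of this shape.

## What it computes

* **Track screening** — two-stage GPS error removal (gross outliers
  beyond `D` = 100,000 m from a running window median; speed/turning
  spikes at `a` = 5,000 m/h and cos(turn) < −0.97), fix-cadence
  filtering (5 h ± 15 min), post-capture trimming (24 h), and
  behavioural exclusion windows: kill sites (≥ 4 consecutive fixes all
  pairwise within 200 m) and females with cubs (birth to 5 months).
* **Ephemeris and suntime** — sunrise, solar noon, sunset and
  astronomical twilight from a standard solar-position algorithm; the
  *suntime* transformation mapping each day onto the circle with sunrise
  at π/2, noon at π, sunset at 3π/2; dawn/day/dusk/night labels; a
  low-precision lunar model for illuminated fraction and altitude.
* **Activity densities** — 5-h displacements disaggregated by the 1/5
  rule into hourly pseudo-observations; 24-bin suntime profiles sampled
  by a Metropolis–Hastings chain (10,000 samples per group); von Mises
  kernel densities f(θ) with unit circular integral; the coefficient of
  overlapping Δ(f, g) = ∫₀^{2π} min(f, g) dθ; and day/night activity
  proportions (share of samples in [π/2, 3π/2)).
* **Accelerometer metrics** — active/resting classification at the
  behavioural threshold 28 (0–255 scale), axis-correlation QC, and
  per animal × month × light-period components: proportion of time
  active and activity rate when active.
* **Seasonal inference** — hierarchical-bootstrap monthly displacement
  estimates per demographic group, penalized cyclic harmonic (Fourier)
  seasonal curves per light period, and the lunar-illumination effect on
  night activity.
* **Synthetic telemetry** — a labelled generator reproducing the study
  conditions (fix schedules, group displacement levels, night-share
  seasonality, bimodal step lengths, correlated accelerometer axes,
  injected GPS errors, kill-site episodes) so every stage is testable
  without field data.

## Worked example

```r
library(dielmove)

cfg <- synth_config("predator", n_animals = 4,
                    groups = c("adult_male", "adult_female"),
                    start_date = "2019-01-01", end_date = "2019-12-31",
                    seed = 7)
cohort <- generate_tracks(cfg)
res <- run_pipeline(cohort, rc = run_config(seed = 7), n_boot = 100)

cat(sprintf("male-female overlap: %.2f\n", res$overlaps$male_female))
cat(sprintf("summer-winter overlap: %.2f\n", res$overlaps$summer_winter))
cat(sprintf("night share, males:   %.2f\n", res$proportions$male["p_night"]))
cat(sprintf("night share, females: %.2f\n", res$proportions$female["p_night"]))
print(res$monthly$grand, digits = 4)
```

```
male-female overlap: 0.93
summer-winter overlap: 0.92
night share, males:   0.63
night share, females: 0.57
         group grand_mean grand_se n_months
1   adult_male     1455.3    42.62       12
2 adult_female      818.9    23.79       12
```

Reading the output: the two sexes apportion activity over the diel
cycle almost identically (Δ = 0.93), both are mostly night-active
(males more so), and adult males cover roughly 1.8× the 5-h displacement
of adult females (grand means ± SE over the twelve monthly estimates).
The night shares sit a couple of points below the generator's configured
0.66/0.60 — the expected blunting from reading hourly structure off a
5-h fix schedule, quantified by `validate_disaggregation()`.

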