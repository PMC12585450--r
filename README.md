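# coordgait

Quantifying how adjacent lower-limb joints coordinate during running — and
whether that coordination changes between groups and across an intervention —
from sagittal-plane joint-angle time series and a synchronized vertical
ground reaction force (GRF) channel.

The package targets the analysis used in running-biomechanics studies of
intersegmental coordination (for example, comparing athletes with and
without a recent ankle sprain before and after a training block): hip–ankle
and knee–ankle coupling by **modified vector coding**, coordination
variability by **circular statistics**, aggregation over the four subphases
of the running gait cycle, and a **2×2 (group × time) mixed ANOVA** with
partial eta-squared effect sizes and noncentral-F confidence intervals.
A synthetic running-gait generator with known ground-truth coupling makes
every stage testable without motion-capture recordings.

## The method

For a joint pair (proximal = hip or knee, distal = ankle), each stride is
time-normalized to 101 points (0–100% of the gait cycle, initial contact to
ipsilateral initial contact). The coupling angle at step *t* is the
orientation of the step vector on the angle–angle plot (distal on X,
proximal on Y), relative to the right horizontal:

```
theta_coord(t) = atan2( Δtheta_prox(t), Δtheta_dist(t) )  wrapped to [0, 360)
```

Angles of 0°/180° mean only the distal joint is moving; 90°/270° mean only
the proximal joint is moving; diagonals mean in-phase (same direction) or
anti-phase (opposite direction) motion. Each angle falls into one of four
coordination patterns (in-phase/anti-phase × proximal/distal dominancy) on
the standard 45°-bin polar classification.

Coordination angles per subphase come from the coupling series of the
**ensemble-mean** joint trajectories. Coordination **variability** comes
from per-stride coupling series: at each cycle step the circular standard
deviation across strides,

```
R = | mean_j exp(i * theta_j) |        (mean resultant length)
var_coord = sqrt(-2 ln R) * 180/pi     (circular SD, degrees)
```

averaged within each subphase window — first half stance (0–20%), second
half stance (21–40%), first half swing (41–70%), second half swing
(71–100%). Group-level inference is a mixed 2×2 ANOVA per outcome × pair ×
subphase (between: group; within: time), with partial eta-squared
`SS_effect / (SS_effect + SS_error)` labelled by the 0.01/0.06/0.14
thresholds and a 95% CI from inverting the noncentral F distribution.

Preprocessing follows the field's conventions: zero-phase third-order
low-pass Butterworth filtering (10 Hz kinematics, 50 Hz GRF), quintic
interpolation of short marker gaps (≤ 10 frames), gait events from the
vertical GRF crossing 20 N, and a minimum of 8 strides for variability
estimates.

## Worked example

Simulate one five-second-style treadmill trial (10 strides, 120 Hz
kinematics, 1000 Hz GRF), detect events, normalize strides, and summarise
coordination for both joint pairs:

```r
library(coordgait)

trial  <- generate_trial(gait_sim_config(n_strides = 10, seed = 42))
events <- detect_gait_events(trial$grf$grf_N, rate = 1000)
cycles <- segment_and_normalize(trial$angles, 120, events, 1000) |>
  require_min_strides()
coordination_summary(cycles)
#> # A tibble: 8 × 7
#>   pair       subphase    coord_angle_deg     R variability_deg pattern n_strides
#>   <chr>      <fct>                 <dbl> <dbl>           <dbl> <fct>       <int>
#> 1 hip-ankle  first_half…           249.  0.982            16.8 in_pha…        10
#> 2 hip-ankle  second_hal…           261.  0.504            19.8 in_pha…        10
#> 3 hip-ankle  first_half…           114.  0.966            17.9 anti_p…        10
#> 4 hip-ankle  second_hal…            19.2 0.878            17.0 in_pha…        10
#> 5 knee-ankle first_half…           147.  0.904            30.1 anti_p…        10
#> 6 knee-ankle second_hal…            98.2 0.971            13.5 anti_p…        10
#> 7 knee-ankle first_half…           182.  0.386            10.8 in_pha…        10
#> 8 knee-ankle second_hal…           332.  0.737            10.7 anti_p…        10
```

`coord_angle_deg` is the subphase circular-mean coupling angle from the
ensemble-mean trajectories; `R` its mean resultant length (1 = a single
consistent direction within the window); `variability_deg` the
stride-to-stride circular SD averaged over the window; `pattern` the polar
classification of the mean angle.

The inferential layer works on tidy tables. A published-style benchmark:
an interaction with `F(1, 21) = 1.693` has

```r
eta_p2_ci(1.693, 1, 21)
#> [1] 0.000 0.339
```

i.e. partial eta-squared 0.075 (medium) with 95% CI [0.000, 0.339].

End to end, `simulate_cohort()` builds a two-group pre/post cohort whose
hip–ankle coupling shifts — in the treatment group only — in a single
subphase, and `run_pipeline()` carries every recording through
preprocessing, coordination and the ANOVA layer:

```r
library(dplyr)
co  <- simulate_cohort(n_per_group = 4, n_strides = 8, seed = 2)
rep <- run_pipeline(co$trials)
rep$anova |>
  filter(outcome == "coord_angle", pair == "hip-ankle",
         effect == "interaction") |>
  select(subphase, statistic, p.value, eta_p2, size_label)
#> # A tibble: 4 × 5
#>   subphase           statistic  p.value eta_p2 size_label
#>   <fct>                  <dbl>    <dbl>  <dbl> <fct>
#> 1 first_half_stance      0.210 0.663    0.0339 small
#> 2 second_half_stance    45.4   0.000521 0.883  large
#> 3 first_half_swing       3.19  0.124    0.347  large
#> 4 second_half_swing      1.65  0.246    0.216  large
```

The prescribed shift sits in the second half of stance, where the
interaction dominates (with only 4 subjects per group the other subphases
are noisy; the shipped analyses use 12 per group). `tidy()` / `glance()`
methods, `autoplot()` for trials and fitted ANOVAs, `plot_angle_angle()`
and `plot_coupling_polar()` cover inspection and figures; `write_trial()` /
`read_trial()` / `write_results()` define the delimited-text interchange
format.

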