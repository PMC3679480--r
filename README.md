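# larvatrack

High-throughput tracking and behavioral classification of zebrafish
larvae from high-speed video, in R.

Zebrafish larvae (5–7 dpf) swim in discrete bouts. Given grayscale video
of dark larvae in bright circular wells (or the package's own synthetic
renderer), `larvatrack` produces, per larva and frame, the core position,
heading axis, 10-point tail midline and signed tail-bending angle α;
segments α(t) into bouts; summarizes each bout (oscillations, tail-beat
frequency, duration, heading range, distance, speed, and a curvature
kymograph c = |x′y″ − y′x″| / (x′² + y′²)^{3/2} along the rostro-caudal
axis); classifies bouts as slow forward swim (S), routine turn (T) or
escape (E) with a two-stage PCA + linear-SVM cascade on 53 dynamic
features; and quantifies maneuver recurrence with the Markov transition
index

    I(B1 → B2) = p(x_i = B2 | x_{i−1} = B1) / p(B2),

computed over time × distance windows within and between larvae, with a
label-permutation test for its maxima. It is intended for quantitative
behavior labs that need bout-level kinematics and interaction statistics
from multi-animal well recordings, and for method development against
ground truth: the synthetic-video generator renders multi-larva scenes
with exact per-frame cores, midlines, bend angles, event boundaries and
class labels.

## Worked example

Simulate a well, track it, detect and classify bouts:

```r
library(larvatrack)

cfg <- larva_config()          # 66 um/px, 337 Hz, all thresholds in mm/ms/deg
lay <- well_layout(1, radius_px = 120)
sc  <- larva_script(1, x = lay$wells$cx - 30, y = lay$wells$cy,
                    heading_deg = 0,
                    events = data.frame(start_ms = c(50, 300),
                                        class = c("S", "T"),
                                        turn_sign = c(1, -1)))
vid <- render_video(lay, list(sc), n_frames = 200, cfg = cfg, seed = 3)
trk <- track_well(vid, vid$wells[1, ], cfg,
                  background = render_video(lay, list(), 1, cfg, 1, 0)$frames[[1]])
trk
#> <larva_tracks> 200 frames, 1 larva(e); tail valid 100.0%; 0 collision record(s)

trace <- bend_traces(trk)[, 1]
ev <- detect_movements(trace, trk$core[, , 1], trk$eroded_change[, 1], cfg)
cbind(ev, do.call(rbind, lapply(seq_len(nrow(ev)), function(k)
  compute_global_params(ev[k, ], trace, trk$core[, , 1],
                        trk$heading[, 1], cfg))))
#>   start_frame end_frame ... n_oscillations    tbf_hz duration_ms heading_range_deg distance_mm speed_mm_s
#> 1          16        68 ...              1  6.358491    157.2700          6.971008   0.7474722   4.752795
#> 2          98       188 ...              4 14.813187    270.0297         47.024544   1.3179776   4.880862
```

Two bouts are recovered: the scheduled slow forward swim (small heading
change, short) and the routine turn (47° heading change, longer, slower
alternation). The measured bend-angle trace tracks the rendered ground
truth to 1.6° RMS on this clip
(`sqrt(mean((trk$bend_deg[,1] - vid$truth$bend_deg[,1])^2))`).

The staged pipeline (PNG frames + CSV/JSON between stages) runs the same
chain end to end and is also exposed as a command-line tool:

```sh
Rscript inst/scripts/larvatrack all --out-dir run1 --larvae 3 --frames 800 --seed 4
```

Interaction analysis on a classified movement table:

```r
mv <- simulate_maneuver_sequence(10000, seed = 1)   # i.i.d. null
round(transition_index(mv, "all")$I, 2)
#>      S    T    E
#> S 1.01 1.01 0.95
#> T 0.99 1.00 1.04
#> E 1.01 0.99 1.00      # all ~1: no order structure
```

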