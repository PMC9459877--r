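# gaitsva

Gait analysis with clothing-mounted and body-mounted inertial sensors.

Walking carries clinically useful information, and small six-axis IMUs on the
lower body (waist, thigh, lower shank) capture it well — but taping sensors to
the skin is impractical for daily wear. Sensors mounted inside everyday loose
clothing are far more comfortable, at the price of extra movement from the
fabric. `gaitsva` implements the full validation pipeline for comparing the
two, for researchers in wearable movement analysis:

* **Sensor-to-segment alignment**: a gravity rotation from a standing segment
  (Rodrigues' formula about the axis perpendicular to the mean acceleration
  and the vertical) followed by a rotation about the vertical that maps the
  dominant sagittal acceleration direction onto the x-axis.
* **Orientation and the sensor-to-vertical angle (SVA)**: per-sample
  quaternions from a Madgwick-type IMU filter (gyro integration with
  gradient-descent corrections toward the accelerometer's gravity direction,
  gated to quasi-static periods), and the SVA

  ```
  theta = acos(2 q0 q2 + 2 q1 q3) - 90   [degrees]
  ```

  the angle of the sensor x-axis relative to the horizontal plane — 0 when
  the segment is vertical, oscillating around 0 during walking, and (unlike
  the z-axis inclination `acos(q0^2 - q1^2 - q2^2 + q3^2)`) able to
  distinguish leaning forward from leaning backward.
* **Gait-cycle extraction**: mid-swing (MS) as acceleration-magnitude peaks
  above 1.8 g (body) / 2.0 g (clothing) with a 1 s minimum separation on the
  lower-shank sensor; fixed-length cycles equal to the rounded mean MS gap;
  initial contact (IC) and toe-off (TO) as the first/last prominent local
  minima of the low-pass-filtered medial-lateral shank gyro within each
  cycle.
* **Pair agreement**: per-cycle Pearson correlations between clothing and
  body SVAs, and clothing-minus-body angle differences during standing, at
  IC, and at the instant the body-mounted shank passes vertical in stance.
* **A synthetic session generator** (`generate_session()`): ground-truth
  sagittal kinematics for a full multi-activity protocol (standing, sitting,
  sit-to-stand, leg raises, walking), forward-modelled into six IMU streams
  with random mounting misorientations, sensor noise, gyro bias, and a
  spring-damper fabric-coupling model with motion-driven fabric noise — so
  every pipeline stage can be scored against known truth.

## Worked example

```r
library(gaitsva)

proto <- data.frame(activity = c("standing", "sit_to_stand", "leg_raise", "walking"),
                    duration = c(30, 20, 20, NA),
                    n_cycles = c(NA, NA, NA, 50))
sim <- generate_session(proto, seed = 1)
res <- run_pipeline(sim$session)
summary(res)
```

prints (numbers from this exact call):

```
Clothing vs body sensor agreement (per placement):
   placement n_cycles corr_coef standing_mean standing_sd ic_mean ic_sd
       waist       50     0.855       -0.0880       0.484  -0.569  1.78
       thigh       50     0.988       -0.0493       0.492  -2.676  1.91
 lower_shank       50     0.980        0.0209       0.538   5.736  1.49
 shank_vertical_mean shank_vertical_sd
               -1.07              2.18
               -3.66              2.41
                1.60              1.58

Body-shank cycles: 50 (0 flagged); mean stance fraction 60.5%
```

Reading: all 50 simulated gait cycles were found from the body-shank
acceleration peaks; the recovered stance phase occupies about 60 % of the
cycle; the clothing waist pair correlates around 0.85 per cycle while the
thigh and shank pairs exceed 0.97; the standing angle differences are near
0°, confirming that both sensors of each pair were aligned to the same
vertical, and the differences during walking are a few degrees with larger
spread — the fabric's own movement. `plot(res, "mean_cycle")`,
`plot(res, "phase_portrait")` and `plot(res, "correlation")` show the mean
SVA cycle with its SD band, the angular-velocity-vs-angle loop with MS/IC/TO
markers, and the per-cycle correlation box plots.

A thin command-line wrapper with `simulate`, `run` and `report` commands is
installed at `system.file("cli", "gaitsva.R", package = "gaitsva")`.

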