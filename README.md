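# fidreg

Landmark-based rigid registration for two clinical imaging workflows:

1. **Cardiac CT/US fusion** — registering an ECG-gated contrast CT of the
   mitral valve onto free-running 4D transesophageal ultrasound, so that the
   high-resolution pre-operative anatomy (CT) can be read together with the
   pre-/post-operative functional images (US). The method is point-based:
   an observer places paired anatomical fiducials (valve annulus, leaflets,
   atrium/ventricle, aortic root) on both volumes and a closed-form rigid
   fit aligns them.
2. **Jaw mirror reconstruction** — rebuilding a unilaterally damaged
   mandible for surgical planning by mirroring the healthy side across the
   mid-sagittal plane and locally registering the mirrored volume to the
   original with landmarks placed on structures adjacent to, but unaffected
   by, the defect.

The package is aimed at image-analysis researchers who want these pipelines
as scriptable, testable R code with a fully synthetic validation bed:
4D cardiac CT/US phantoms and an asymmetric jaw phantom with exact ground
truth replace patient data.

## The method

**Rigid fit.** Given paired fiducials `m_i` (moving) and `f_i` (fixed), the
registration is the rotation `R` (det = +1) and translation `t` minimizing

    sum_i || R m_i + t - f_i ||^2

solved in closed form by the SVD of the centred cross-covariance (the
classical absolute-orientation solution), with the standard sign correction
so a reflection is never returned. `fit_rigid()` is exact on noiseless data
and optimal in the least-squares sense on noisy data; both properties are
verified in the test suite against brute-force numeric minimization.

**Error metrics.** Three scores assess a trial registration `T` against a
gold standard `G` (an expert alignment on real data; the generator's true
transform on phantoms):

- `rmse1(T, G)` — RMS difference of the six rigid parameters (ZYX Euler
  angles in degrees; translations in mm), rotation and translation reported
  separately;
- `fre(T, pairing)` — fiducial registration error, the RMS residual
  `sqrt(mean ||T(m_i) - f_i||^2)` in mm;
- `rmse2(T, m, G)` — RMS distance between the landmarks mapped by `T` and
  by `G`, i.e. how differently the two transforms act on the anatomy.

**Temporal alignment.** The gated CT provides frames at phases
0.0, 0.1, ..., 0.9 of the cardiac cycle; the US runs free. One US cycle is
delimited between two consecutive "fully open" valve states and CT phase
`p` is matched to US frame `start + round(p * (end - start))`
(round-half-even). Registration is then performed at 90% phase
(end-diastole).

**Validation protocol.** The landmark count N is swept from 3 to 12 with 10
trials per count and two simulated observers; curves of the three metrics
versus N, boxplot summaries at the operating point N = 10, and the bounds
check (every RMSE2 <= 15 mm and FRE <= 8 mm) reproduce the study design the
package is built around.

## Worked example

```r
library(fidreg)

spec <- cardiac_phantom_spec(ct_shape = c(48L, 48L, 24L),
                             ct_spacing = c(1.2, 1.2, 2.2),
                             us_shape  = c(40L, 40L, 40L),
                             us_spacing = c(1.1, 1.1, 0.8), seed = 7L)
res <- run_cardiac_pipeline(cardiac_config(out_dir = "run1", seed = 7L),
                            phantom_spec = spec)
res$transform
#> rigid_transform (moving -> fixed, LPS)
#>   rotation ZYX (deg): 24.8396 -9.8405 44.8834
#>   translation (mm):   6.6103 -5.4187 7.6432
res$record
#>    patient     user trial n_landmarks rmse1_rot rmse1_trans      fre    rmse2
#>  synthetic pipeline     1          10  3.084171    1.186866 2.346444 1.773491
```

The pipeline delimited the US cycle at frames 10..26, matched the ten CT
phases into it, placed 10 noisy landmark pairs (1 mm observer SD) at the
90% phase, and fit the registration. The fitted pose (US into CT space) is
within observer noise of the phantom's true pose; `fre` = 2.35 mm is the
residual on the placed fiducials and `rmse2` = 1.77 mm the disagreement
with the ground-truth transform over the landmarks — both comfortably
inside the 8 mm / 15 mm acceptance bounds.

```r
jaw <- run_jaw_pipeline(jaw_config(out_dir = "run2"))
unlist(jaw$summary[c("dice_registered", "dice_mirror_only",
                     "p95_registered", "p95_mirror_only")])
#> dice_registered dice_mirror_only   p95_registered  p95_mirror_only
#>       0.9414261        0.5947445        1.2000000        3.7947332
```

Mirroring alone leaves the reconstructed ramus misaligned (Dice 0.59
against the pre-defect truth, 95th-percentile surface distance 3.8 mm);
the local landmark registration recovers the asymmetry (Dice 0.94,
1.2 mm = one voxel).

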