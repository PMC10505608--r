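# rsomskin

Quantification of diabetes-related skin changes from raster-scan
optoacoustic mesoscopy (RSOM). RSOM images the first ~1.5 mm of human
skin label-free at 532 nm over a 4 × 2 mm² field; reconstructing the
detected ultrasound separately in a low (10–40 MHz) and a high
(40–120 MHz) band yields co-registered volumes in which large
(~40–150 µm) and small (<40 µm) dermal vessels dominate respectively.
The package is aimed at researchers analysing such dual-band skin
volumes — and at anyone who wants a fully synthetic, ground-truthed
test bed for the analysis itself.

From a band pair it computes six per-subject biomarkers:

| biomarker | definition |
|---|---|
| SVN | junctions of the high-band dermal vessel network with connected-vessel mean diameter < 40 µm |
| LVN | low-band junctions ≥ 40 µm |
| TVN | SVN + LVN |
| TBV | `100·N/T`, `N` = dermal voxels above 20 % of the dermal maximum, `T` = all voxels of the 4 × 2 × 1.5 mm³ dermis slab |
| EP thickness | mean width between the epidermis boundaries found by an exact dynamic-programming graph search on per-stack sagittal MIPs |
| EP signal density | mean intensity per voxel of the segmented epidermis |

Vessels are segmented by a multi-scale matched filter (zero-mean
Gaussian-profile line kernels, 5 scales × 12 orientations), masked by
Otsu's threshold with half-maximum width refinement, thinned to
centerlines, and quantified through skeleton junctions (crossing
number ≥ 3) and distance-transform diameters. Cohort statistics cover
normality-gated two-sample tests (unpaired t / Mann–Whitney U) with
star annotation, Spearman correlations, covariate-adjusted logistic
regression, and a single-biomarker threshold classifier with
rank-identity AUC.

A synthetic module generates (a) two-band skin phantoms — an epidermis
slab with ridge texture over hard-cylinder vessels, PSF-blurred and
noise-corrupted, with exact pre-blur ground truth — and (b) cohort
biomarker tables drawn from the published per-group statistics
(healthy n = 48, diabetic n = 95; severity subgroups NC/LN/HN and the
neuropathy-with-atherosclerosis group), so the whole pipeline is
testable without any clinical data.

## Worked example

A phantom with a Y-shaped 60 µm vessel pair in the low band and an
unbranched 24 µm vessel in the high band, run through the full
per-subject pipeline:

```r
library(rsomskin)

big    <- vesselSpec(rbind(c(800, 200, 500), c(800, 1000, 500),
                           c(800, 1800, 200)), diameter = 60, band = "low")
branch <- vesselSpec(rbind(c(800, 1000, 500), c(800, 1800, 800)),
                     diameter = 60, band = "low")
small  <- vesselSpec(rbind(c(600, 200, 700), c(600, 1700, 200)),
                     diameter = 24, band = "high")
spec <- phantomSpec(gridShape = c(640, 160, 84), surfaceDepth = 300,
                    epThickness = 105, vessels = list(big, branch, small),
                    noiseSigma = 0.02, seed = 1)
ph  <- makeSkinPhantom(spec)
res <- runSubject(ph$pair, subjectId = "phantom-01")
round(res$biomarkers, 3)
#>             svn             lvn             tvn         tbv_pct ep_thickness_um
#>           0.000           1.000           1.000           0.330         105.071
#>      ep_density
#>           0.972
```

The Y junction is counted once as a large vessel (`lvn = 1`); the
straight 24 µm tube has no junction, so `svn = 0` under the literal
junction-count rule. The 105 µm epidermis is recovered to 0.07 µm, and
TBV (0.33 %) sits just above the analytic truth (0.27 %) by the
expected PSF-blur margin.

Cohort statistics on a generated table (`group` column as in the
study: healthy, NC = no complications, LN/HN = low/high-score
neuropathy, NA_ = neuropathy + atherosclerosis), SVN comparisons:

```r
tab <- makeCohort(cohortSpec(seed = 1))
out <- runCohort(tab)
out$comparisons[out$comparisons$biomarker == "svn",
                c("group_a", "group_b", "test", "p", "stars")]
#>  group_a  group_b           test        p stars
#>  healthy diabetic Mann-Whitney U 2.18e-17   ***
#>  healthy       NC     unpaired t 1.45e-11   ***
#>       NC       LN     unpaired t 4.37e-04   ***
#>       LN       HN     unpaired t 7.06e-06   ***
#>      NnA       NA     unpaired t 2.91e-05   ***
out$roc
#> auc 0.935, accuracy 0.867, sensitivity 0.905, specificity 0.792 (threshold 8.15)
```

The small-vessel count separates every severity step, and the
threshold classifier on SVN reaches an AUC of ~0.93 — the behaviour
reported for the clinical cohort.

A thin command-line front end is installed at
`inst/cli/rsom.R` (`phantom`, `subject`, `simulate-cohort`, `cohort`
subcommands).

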