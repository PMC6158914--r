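# cupseg

Automatic segmentation of the **optic cup** in digital fundus photographs,
with the blood vessels removed by PDE inpainting before the boundary is
sought.

The optic disc of a retinal photograph contains a bright central
depression, the optic cup; the ratio of the vertical diameters of cup and
disc (the vertical cup-to-disc ratio, CDR) rises as glaucoma destroys
nerve fibers, which makes automatic cup segmentation a core step of
computer-aided glaucoma screening.  The hard part is that retinal vessels
cross the cup boundary and locally erase its contrast.  `cupseg`
implements a pipeline built around vessel removal:

1. green channel `U_G` (best cup contrast of the three);
2. morphological enhancement with a flat 5×5 structuring element,
   `U = (U_G + T_hat(U_G)) − B_hat(U_G)`;
3. vessel extraction by median-filter differencing,
   `U_sub = median_9×9(U) − U`, thresholded and cleaned, then dilated into
   an inpainting band;
4. **BSCB-type inpainting** of the vessel pixels — alternating isophote
   transport `∂U/∂t = (∇L · T⃗) |∇U|` (with `L` the 3×3 neighborhood mean
   of the discrete Laplacian and `T⃗` the unit isophote direction) with
   curvature diffusion `∂U/∂t = g_ε κ |∇U|` on the band;
5. **local Chan–Vese level set** segmentation of the cup, seeded
   automatically at the centroid of the brightest region, with
   `α = 0.1` and `μ = 0.1·255²`, statistics restricted to the disc
   (supplied as a mask — disc delineation is an input of the method);
6. evaluation: pixel F-score, mean radial boundary distance, vertical CDR.

A deterministic **fundus phantom generator** (bright elliptical disc,
brighter cup with a smooth rim, dark Bézier vessels crossing the cup
boundary, Gaussian noise, exact ground-truth masks and CDR) makes the
whole pipeline testable without any clinical data.

## Worked example

```r
library(cupseg)

ph  <- make_phantom(phantom_spec(seed = 7))   # 480x480, true CDR = 0.5
rec <- run_pipeline(ph)   # phantom truth supplies the disc mask

rec
#> <run_record: cup 12446 px, vessels 2437 px, F=0.9953>
rec$metrics
#> <metrics_report: P=0.9955 R=0.9950 F=0.9953 D=0.29 px CDR=0.5083>
```

The pipeline found 2,437 vessel pixels, inpainted them, and recovered a
12,446-px cup mask that overlaps the true cup with F-score 0.995
(precision 0.9955, recall 0.9950); its boundary lies on average 0.29 px
from the true boundary, and the measured vertical CDR 0.508 is within
0.009 of the true 0.5.

On real images, supply the photograph and the expert disc mask:

```r
img  <- read_fundus("fundus.png")
disc <- read_mask("disc.png", dim(img$pixels)[1:2], role = "disc")
rec  <- run_pipeline(img, pipeline_config(), disc_mask = disc)
write_mask(rec$seg$cup_mask, "cup.png")
```

A thin command-line front end (`inst/cli/cupseg.R`) wraps the same
functions: `run`, `eval`, `phantom`, `sweep` (structuring-element and
median-window size studies) and `ablate` subcommands.

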