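# dirsynth

Synthesis of artificial double inversion recovery (DIR) brain MRI from
conventional sequences, with lesion-level evaluation statistics — in pure
R (plus Rcpp kernels), runnable end to end on physics-based phantoms
without any clinical data.

## The problem

Cortical multiple-sclerosis lesions are nearly invisible on routine T1-,
PD- and T2-weighted MRI. The DIR sequence — two inversion pulses timed so
the longitudinal magnetization

> Mz/M0 = 1 − 2·e^(−TI₂/T1) + 2·e^(−(TI₁+TI₂)/T1) − e^(−TR/T1)

vanishes simultaneously for white matter and CSF — leaves a grey-matter
image on which those lesions are hyperintense, but DIR is slow and
missing from most protocols and historical trial datasets. `dirsynth`
implements the workaround: a 3D conditional adversarial network (U-shaped
generator with instance normalization and leaky ReLU; PatchGAN
discriminator; binary cross entropy + λ·MAE generator loss, Adam, patch
sampling with stochastic augmentation) that learns to translate
(T1, PD, T2) stacks into artificial DIR volumes, and the statistics used
to judge the result at the lesion level: hyperintensity detection with a
3 mm² minimum axial cross-section, greedy one-to-one centroid matching,
precision/recall, the two-way-mixed absolute-agreement intraclass
correlation with its F-based confidence interval, and lobe/type
contingency tables.

A tissue phantom generator (deformed concentric WM/GM/CSF anatomy with
planted intracortical/juxtacortical/mixed lesions, converted to realistic
contrasts via relaxation-time signal equations) supplies fully ground-truthed
training and test data. For whom: image-analysis researchers who want a
self-contained, inspectable reference implementation of the synthesis +
evaluation pipeline, or the evaluation statistics alone for their own
lesion-reading studies.

## Worked example

```r
library(dirsynth)

# ground-truthed phantoms: one to train on, one held out
phTr <- makeTissuePhantom(c(32, 32, 32), nLesions = 4,
                          lesionRadiusRange = c(1.2, 2), seed = 301)
phTe <- makeTissuePhantom(c(32, 32, 32), nLesions = 4,
                          lesionRadiusRange = c(1.2, 2), seed = 1301)
stTr <- simulateChannelStack(phTr, seed = 301)   # T1/PD/T2 + DIR, in [-1,1]
stTe <- simulateChannelStack(phTe, seed = 1301)

cfg <- new("NetworkConfig", depth = 3L, baseFilters = 8L, patchEdge = 16L,
           discStages = 2L, discBaseFilters = 8L, epochs = 200L,
           lr = 1e-3, maeWeight = 100)
fit <- trainTranslator(list(stTr), cfg, seed = 2301,
                       valStacks = list(stTe))

aDIR <- predictVolume(fit$generator, stTe, patchEdge = 16L, stride = 8L)
bm <- brainMask(stTe)
cor(aDIR[bm], getChannel(stTe, "DIR")[bm])
#> [1] 0.9751
```

A few minutes of single-CPU training suffice for the scaled problem: the
correlation between the predicted and the analytic DIR inside the brain
(here 0.975) exceeds 0.9, the held-out MAE falls from 0.232 (epoch 1) to
0.034, and the planted lesions stay hyperintense relative to grey matter
(mean contrast +0.128 in normalized units), so they are recoverable by
the same detector that reads the reference image:

```r
gm <- tissueLabels(phTe) == 2L
rec <- detectCandidates(aDIR, gm, zThresh = 3, subject = "s1",
                        source = "aDIR")
ref <- detectCandidates(getChannel(stTe, "DIR"), gm, zThresh = 3,
                        subject = "s1", source = "cDIR")
m <- matchLesions(rec, ref, tolMm = 5)
precisionRecall(m)$pooled
#> precision    recall
#>      1.00      0.75
```

The reference reading finds all four planted lesions; the synthetic image
renders three of them above threshold (no spurious detections), giving
precision 1.00 and recall 0.75 for this single held-out subject.

The full pipeline (phantoms → training → prediction → evaluation report)
is one call — `runPipeline(defaultRunConfig("smoke"), "out")` — and a thin
command-line front end wraps it (`inst/cli/adir.R` with `phantom`,
`preprocess`, `train`, `predict`, `evaluate`, `run` subcommands).

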