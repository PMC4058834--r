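# fuzzymrf

Automatic lung tumor segmentation on co-registered PET/CT volumes with a
fuzzy Markov random field (MRF) model.

## The problem and the model

Lung tumors that extend into the chest wall or mediastinum are nearly
indistinguishable from the adjacent soft tissue on CT, while on PET they
stand out through elevated standardized uptake values (SUV) but with much
coarser spatial resolution. `fuzzymrf` fuses the two modalities: each
voxel `i` of a user-selected region of interest carries a continuous
tumor membership `x_i ∈ [0, 1]`, estimated by maximizing the concave MAP
objective

    C(x) = Σ_i { ln[ x_i·min(p11(y_SUV), p21(y_CT))
                   + (1 − x_i)·max(p10(y_SUV), p20(y_CT)) ]
                 − β Σ_{j ∈ R_i} (x_i − x_j)² }

where `p21`, `p20` are Gaussian models of tumor / normal CT intensity,
`p10` a Gaussian model of normal-tissue SUV, and `p11` a uniform density
that is 0 below an SUV threshold `a` and `1/(b − a)` at or above it
(`b` = the ROI's maximum SUV). The `min` demands that *both* modalities
look like tumor; the `max` lets *either* modality veto. `R_i` is a 5×5×3
voxel neighborhood carrying the Gibbs smoothness prior with weight `β`.
Model parameters are estimated from a rough fuzzy C-means segmentation of
each modality (membership > 0.1), the field is optimized by projected
gradient ascent, and the final gross tumor volume (GTV) is the set of
voxels with membership ≥ 0.5. Segmentations are scored with Dice's
similarity coefficient, DSC = 2|v1 ∩ v2| / (|v1| + |v2|).

A synthetic phantom generator reproduces the hard case — a tumor abutting
a slab with identical CT statistics but normal SUV, plus PET-like blur of
the SUV volume — with known ground truth, so the entire pipeline is
testable without clinical data. See the methods vignette
(`vignettes/fuzzy-mrf-petct.Rmd`) for the full model, parameter
rationale, and limitations.

## Worked example

```r
library(fuzzymrf)

ph  <- generate_phantom(default_spec(1))   # co-registered CT + SUV + truth
seg <- segment(ph$ct, ph$suv)              # fused PET/CT fuzzy-MRF pipeline
seg
#> <fmrf_segmentation> mode petct, 1 iterations (converged), GTV 805 voxels
#> <fmrf_model_params>
#>   p10 (normal SUV): N(1.015, 0.0919^2)
#>   p20 (normal CT):  N(-700.4, 40.1^2)
#>   p21 (tumor CT):   N(39.94, 15.18^2)
#>   p11 (tumor SUV):  uniform, a = 2.01, b = 6.774
dsc(seg$mask, ph$truth)
#> [1] 0.978
```

The fitted parameters recover the phantom's generating values: normal SUV
near 1 (its SD shrunk by the PET-like blur), lung CT near −700, soft
tissue near 40, and an SUV threshold `a ≈ 2` separating tumor uptake from
normal. The data-driven initialization is already near the concave
objective's maximizer here, so ascent converges almost immediately; from
a flat start it takes a few hundred monotone iterations to the same
field. The resulting 805-voxel GTV overlaps the 771-voxel true tumor with
DSC 0.978.

Batch comparison of the fused method against its ablations on 5 phantom
replicates:

```r
evaluate_batch(5, base_seed = 100)
#> <fmrf_eval_report> DSC reference: phantom ground-truth mask (stands in for manual contours)
#>      mode n n_failed  mean_dsc      sd_dsc mean_voxels
#>  fcm_only 5        0 0.9739509 0.002648601       794.6
#>  pet_only 5        0 0.7905492 0.004800885      1179.6
#>     petct 5        0 0.9796798 0.003530712       803.0
```

The fused `petct` mode is the most accurate; `pet_only` (CT terms dropped
from the min/max mixture) produces systematically larger GTVs because of
PET's blur — the clinically familiar behavior — and plain fuzzy C-means
on SUV trails the fused model.

The same pipeline runs from the shell:

```sh
fuzzymrf phantom --seed 1 --out ph
fuzzymrf segment --ct ph/ct.nii.gz --suv ph/suv.nii.gz --out seg
fuzzymrf evaluate --n 5 --seed 100 --out eval
```

Every run directory contains a `manifest.yaml` with all effective
parameters and the seed, so results can be regenerated exactly.

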