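# flowmesh

Template-based multi-organ 3D segmentation by diffeomorphic mesh deformation,
in R.

## What problem this solves, and for whom

Voxel segmentations of abdominal organs (liver, kidneys, spleen, pancreas)
are limited to the imaging grid: boundaries become staircases, and there is no
vertex correspondence between subjects, so statistical shape analysis and
longitudinal modelling are off the table. `flowmesh` is for image-analysis
researchers who want *mesh* segmentations with built-in anatomical priors:
every output is a deformed copy of a fixed multi-organ template, so each organ
is a closed genus-0 surface and every vertex is homologous across subjects.

## The method

A 3D residual UNet maps an intensity volume to a stack of five stationary
flow fields Φ₀…Φ₄, one per decoder stage, at coarse-to-fine grid resolutions.
The template mesh 𝒯 is deformed by integrating the ODE

    dx/dt = Φ(x(t), t),   x(0) = x_T,   Φ(x, t) = Φ_⌊t⌋(x)

with forward Euler (h = 0.2, five steps per field). Stages 0–3 carry one
field per organ; the final stage applies a single shared field so close-by
organ boundaries cannot cross. Mesh connectivity never changes, which
preserves template correspondence; in the continuous limit the flow is
diffeomorphic, so self-intersections are (nearly) absent in practice.

Training minimises

    L = L_CE + L_Ch + λ·L_E,   λ = 10

where L_CE is deeply supervised voxel cross-entropy (the *voxel branch*),
L_Ch the symmetric squared-distance Chamfer loss between sampled surfaces
(per organ, summed), and L_E the mean squared edge length. With *deep mesh
supervision* the mesh terms apply to the intermediate mesh after every flow
stage. Output heads are zero-initialised so an untrained model predicts the
identity deformation. At test time the meshes can be aligned to the predicted
voxel segmentation by rigid ICP (topology-preserving) or non-rigid ICP (more
accurate, may introduce self-intersections).

The package also contains a synthetic multi-organ phantom generator (so the
whole pipeline runs without any data), the template builder (30% occupancy,
marching cubes, 20 Laplacian smoothing steps), the evaluation metrics of the
field (Dice, ASSD, HD99, SIF), and PLY/NIfTI/YAML I/O.

## Worked example

```r
library(flowmesh)

# a synthetic population: 32^3 volumes, 1.5 mm voxels, K = 4 organs
spec <- phantom_spec()
train_set <- lapply(0:9, function(i) generate_phantom(spec, i))

# multi-organ template from the training label volumes
template <- build_template(lapply(train_set, `[[`, "labels"), spec$spacing)
print(template)
#> <mesh_template> 4 component(s) for classes {1,2,3,4}; 6290 vertices, 12564 faces
sapply(split_components(template$mesh), euler_characteristic)
#> [1] 2 2 2 2          # every organ is a closed genus-0 surface

# a freshly initialised model predicts the identity deformation
cfg <- net_config()
ck0 <- structure(list(params = init_params(cfg, seed = 1), net_cfg = cfg,
                      icfg = integration_config(), template = template,
                      train_cfg = train_config(), epoch = 0L,
                      val_assd = NA_real_, history = NULL),
                 class = "flow_checkpoint")
test_case <- generate_phantom(spec, 20000)
pred <- predict_volume(ck0, test_case$intensity)
identical(pred$mesh$vertices, template$mesh$vertices)
#> [1] TRUE

# the undeformed template scores like this against a held-out phantom:
set.seed(1)
report <- evaluate_cases(list(pred$meshes), list(test_case$labels), spec$spacing)
print(as.data.frame(report), digits = 3)
#>   case organ  dice assd_mm hd99_mm sif_pct
#> 1    1     1 0.784    1.18    3.23       0
#> 2    1     2 0.788    1.04    2.30       0
#> 3    1     3 0.719    1.11    2.66       0
#> 4    1     4 0.746    1.05    3.21       0
```

Those numbers are the *starting point*: Dice ≈ 0.75 and ASSD ≈ 1.1 mm is how
well the average-shape template fits before any learning. Training closes the
gap — `train()` on 16 phantoms for 16 epochs lifts held-out mean mesh Dice to
≈ 0.89 at ASSD ≈ 0.56 mm with zero self-intersecting faces (the acceptance
run below prints 0.886 / 0.564 / 0.000 at seed 1):

```r
ck <- train(train_set, val_set, template, net_config(),
            train_config(max_epochs = 16L, seed = 1L))
ev <- evaluate_checkpoint(ck, test_set)                      # unregistered
ev_icp <- evaluate_checkpoint(ck, test_set, registration = "icp")
plot_history(ck); plot_metric(ev, "dice")
```

A thin command-line front end (`inst/cli/flowmesh`) wraps the same functions:
`make-phantoms`, `make-template`, `predict`, `evaluate`.

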