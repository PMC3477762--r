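# kneedea

Semiautomated estimation of **tibiofemoral contact stress** for
population-scale knee studies, in R.

Contact stress — the pressure the femur exerts on the tibial cartilage
under weight bearing — is a direct mechanical exposure implicated in knee
osteoarthritis, but measuring it per subject across hundreds of knees
requires automation. `kneedea` implements the full chain:

1. **3D-to-2D silhouette registration.** MRI-derived bone surfaces
   (STL/PLY/OBJ triangle meshes) are posed against a standing
   posterior-anterior fixed-flexion radiograph. A virtual scene reproduces
   the acquisition (source at 72 in = 1828.8 mm from the detector, caudal
   beam tilt of 5/10/15 degrees); the model silhouette is ray-cast onto the
   film plane, rasterised, and compared with the traced bone edges by a
   symmetric mean distance-transform cost. The 6-DOF pose is found by
   CMA-ES (70 candidates/generation, up to 8000 cost evaluations, best of
   3 seeded runs), femur first, then tibia with a proximity penalty that
   keeps the pair in apposition.
2. **Discrete element analysis (DEA).** Rigid bones, cartilage as a bed of
   independent compressive-only springs of combined thickness *t* = 6 mm:
   each tibial facet paired with its nearest femoral facet, deformation
   *d* = max(0, *t* − *s*), stress by the confined-compression law
   σ = E(1−ν)/[(1+ν)(1−2ν)] · d/t with E = 12 MPa, ν = 0.42. The femur is
   translated vertically until the net spring force balances a 1000 N load
   within 0.5%. Peak and mean stress are reported per medial/lateral
   compartment.
3. **Reliability statistics.** Shrout-Fleiss ICC(2,1) (two-way
   random-effects, absolute agreement, single score) and Bland-Altman
   summaries (limits at ±2 SD, zero-stress pairs omitted) for day-to-day
   and interrater designs.

A synthetic knee phantom (spherical condyles in conforming tibial sockets,
with self-rendered ground-truth edge images, segmentation-like surface
perturbations, and two-way random-effects ratings tables) exercises every
stage with known ground truth — no restricted imaging data is needed.

## Worked example

```r
library(kneedea)

# a phantom knee with known ground truth, placed in the radiographic scene
scene  <- build_scene()                       # SDD 1828.8 mm, 10 deg caudal
ph     <- generate_knee_phantom(phantom_spec(refinement = 2))
placed <- place_in_scene(list(femur = ph$femur, tibia = ph$tibia), scene)
edges  <- synthesize_radiograph_edges(placed$surfaces, scene)

# register both bones back to the rendered edges (truth = zero pose)
reg <- register_knee(placed$surfaces$femur, placed$surfaces$tibia,
                     edges$femur, edges$tibia, scene,
                     seed = 1, n_runs = 2, popsize = 20, max_evals = 1000)
reg$femur
#> registration_result: best cost 0.004826 mm over 2 runs
#> rigid_pose: t = (-0.0002405, 0.003034, -0.03067) mm, r = (-0.01499, -0.1324, 0.005652) deg

# contact stress at the registered pose, 1000 N vertical load
fem <- apply_pose(placed$surfaces$femur, reg$femur$best_pose, center = reg$femur$center)
tib <- apply_pose(placed$surfaces$tibia, reg$tibia$best_pose, center = reg$tibia$center)
field <- solve_equilibrium(fem, tib, dea_params(), load_axis = scene$axis_v)
field
#> contact_stress_field: 495 active springs, peak 4.209 MPa, offset 5.100 mm, force 997.4 N (converged)
m <- compartment_metrics(field, ml_axis = scene$axis_u)
unlist(m[1:4])
#>  peak_medial  mean_medial peak_lateral mean_lateral
#>    4.2086108    0.9591922    3.8776255    1.1510688

# reliability of a simulated 10-knee, 3-rater, 2-day study
study <- simulate_ratings_study(10, variance_components = c(9, 0.5, 0.5), seed = 5)
reliability_report(study)$table
#>   reliability compartment      peak      mean
#> 1  day-to-day      medial 0.9563003 0.9222755
#> 3  day-to-day     lateral 0.9714314 0.9543399
#> 2  interrater      medial 0.8612408 0.7918464
#> 4  interrater     lateral 0.9481228 0.9392367
```

The registration recovers the known pose to thousandths of a millimetre in
plane; the depth component is always the least certain, since a single
projection only observes it through magnification. The DEA peaks sit at
the socket rims where the conforming gap closes last, and the two
compartments differ by ~10% because the phantom's condyles are deliberately
unequal (40 vs 36 mm). The ICCs
recover the population value implied by the simulated variance components
(9 / (9 + 0.5 + 0.5) = 0.9) up to sampling noise in a 10-knee study.

A command-line wrapper for batch work lives at `inst/cli/kneedea.R`
(subcommands `phantom`, `register`, `dea`, `reliability`, `run`; see the
file header for usage).

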