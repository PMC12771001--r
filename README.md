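# gitwin — patient-specific digital twins of gastrointestinal motion

Deformable image registration (DIR) in the abdomen is hard to validate:
stomach and bowel move by millimeters to centimeters, and their walls offer
no reliable landmarks. `gitwin` takes the opposite route — it *synthesizes*
the motion, so the deformation is known exactly. From a single static 3D
scan (CT or MR, NIfTI) and a binary organ mask it:

1. extracts an organ centerline by topology-preserving 3D thinning and an
   endpoint-to-endpoint path search,
2. rebuilds the organ as a tubular NURBS surface from radially cast
   sectional curves, with inner shells interpolated toward the centerline,
3. animates the surface with an analytical peristaltic traveling wave

   F(L, t) = (A / √3) · sin(2π (L − c·t) / λ),   D(u) = e^(−α·u)

   applied radially to every control point
   (P′ᵢⱼ = Pᵢⱼ + F·Dₛ·Dₜ·d̂; stomach default A = 16 mm, λ = 55 mm,
   c = 5 mm/s; large bowel λ = 40 mm, c = 8 mm/s; 21 phases over one wave
   period),
4. voxelizes the surface/shell correspondences into dense ground-truth
   displacement fields (collision averaging + iterative neighbor-average
   hole filling to 0.001 mm), and warps the scan into a 4D sequence,
5. scores any externally produced DVF against the ground truth: TRE at
   surface/shell points, DSC, 95th-percentile Hausdorff distance,
   log-Jacobian statistics, dose-warping error with direct dose mapping,
   and voxel-level RMSE binned by motion magnitude or dose.

Synthetic curved-tube phantoms (stomach-like C-arc, bowel-like torus arc)
make the whole pipeline testable without any patient data.

## Worked example

```r
library(gitwin)

spec  <- phantomPreset("stomach", noiseSd = 0)   # 96^3 grid, 2 mm voxels
mask  <- makeTubeMask(spec)
image <- makePhantomImage(mask, spec)
path  <- tubePath(spec)                          # ground-truth axis

model  <- buildOrganModel(mask, path@points[1, ],
                          path@points[nrow(path@points), ])
model$surface
#> NurbsSurface: 80 sections x 36 points, degrees (3, 3), length 156.543 mm

params <- stomachMotionParams()
params
#> MotionParams: A = 16 mm, lambda = 55 mm, c = 5 mm/s, alpha = 0 (none),
#> 21 phases over 11 s

f <- phaseField(list(model), list(params), t = 2.75, grid = mask,
                phaseIndex = 5L)
f
#> DisplacementField (phase 5): 96 x 96 x 96 voxels, spacing 2 x 2 x 2 mm
#>   |u|: mean 0.09275 mm, max 9.109 mm, nonzero 29816 voxels

warped <- warpVolume(image, f, kind = "image", inverse = f@info$inverse)

# evaluate a candidate field (here: ground truth + 2 mm x-offset)
cand <- f; cand@data[, , , 1] <- cand@data[, , , 1] + 2
pts  <- evalPoints(model$stack, mask)
tre(pts, f, cand)$mean
#> [1] 2
```

The maximum displacement approaches the wave's peak radial excursion
A/√3 ≈ 9.24 mm; the TRE of a uniformly offset candidate is exactly the
offset.

`runPipeline()` drives the same steps from a YAML config and writes per-phase
DVFs, warped images and masks, log-Jacobian maps and a checksummed
manifest; `inst/cli/gitwin.R` exposes `phantom`, `centerline`, `simulate`,
`evaluate` and `all` subcommands for shell use.

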