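# topolight

Topology-aware illumination design for direct volume rendering.

## The problem

When a volume-rendered data set contains nested or crowded structures — a
tumor inside an organ, a nucleus inside a cell — the transfer function alone
rarely makes the inner objects legible: a semi-transparent outer surface
catches the light and the interior sits in shadow. `topolight` addresses
this for researchers and tool builders working with 3D scalar fields
(CT/MR volumes, microscopy stacks, simulation output). It derives the
*lighting*, not the color, from the topology of the data: the contour tree
indexes every structure as a branch, and each branch receives its own
Blinn–Phong coefficients.

## The model

The volume is segmented by its contour tree (join/split-tree union-find
sweeps, merged and reduced; branch decomposition by greedy leaf pruning
under persistence, volume, hypervolume, or a combined importance-triangle
measure; simplification of noise branches). Each branch *i* is annotated
with persistence *p*, volume *v*, hypervolume *hv*, topological depth,
sibling/child counts, saddle value, and saliency

$$S_i = \frac{t_i}{\sum_j e^{-d(i,j)^2/r^2}\, t_j},$$

with *d* the depth difference and *r* the maximum depth. Illumination is
then generated by one of four mechanisms for the shading equation
*C* = (*k*<sub>a</sub> + *k*<sub>d</sub> *f*<sub>att</sub> (*N*·*L*)) *C*<sub>tf</sub> + *k*<sub>s</sub> *f*<sub>att</sub> (*N*·*H*)<sup>*n*</sup>:

* **attenuation** — Stokes' law α = 2ηξ²/(3ρV³) with water constants
  (η = 0.001002 Pa·s, ρ = 998.2071 kg/m³), ξ = sibling count, user speed
  *V*, and Beer–Lambert falloff *f*<sub>att</sub> = e<sup>−αz</sup>;
  low-persistence structures dim out first as *V* drops.
* **saliency** — *k*<sub>d</sub> = *w·S<sub>i</sub>*.
* **distance** — *k*<sub>d</sub> = *w*/(1 + e<sup>−depth</sup>), lighting
  inner structures more strongly.
* **perceptual** — a two-phase Just-Noticeable-Difference model:
  luminances initialized one JND apart along every parent–child edge, then
  optimized by a contrast-ratio residue flow
  (Δh = Qp/(K n<sup>c</sup>), K = 300; γ<sub>i</sub> = (1 − Δh)γ<sub>i−1</sub>)
  with sibling distribution by importance and saddle rank, and JND
  enforcement against each parent.

A small CPU ray-caster (orthographic, front-to-back compositing) renders
the segmentation under any lighting table, and synthetic volume generators
(ramps, Gaussian multi-blob fields, nested peak hierarchies) provide
ground-truth topology for testing. See the vignette
`vignettes/topology-aware-illumination.Rmd` for the full model account.

## Worked example

```r
library(topolight)
f <- nested_shell_volume(c(26, 9, 9), levels = 3)   # 3 nested structures
fit <- topo_illumination(f, mode = "perceptual", threshold = 1)
fit
#> Topology-aware illumination design
#>   mode: perceptual   (w = 0.71)
#>   field: 26 x 9 x 9, value range [0.000200183, 10.0004]
#>   contour tree: 36 critical nodes; 3 branches (max depth 2)
summary(fit)
#> Per-branch topological attributes and lighting (mode = perceptual):
#>  branch_id persistence volume hypervolume depth n_siblings n_children
#>         16       4.708     81       318.5     2          0          0
#>         17       6.938    205       628.2     1          0          1
#>         18      10.000   1820      1357.8     0          0          1
#>  saddle_value saliency triangle_area  ka     kd  ks shininess f_att luminance
#>         2.521   0.3414         1.299 0.1 0.7100 0.2        32     1     15.66
#>         1.566   0.3772         1.299 0.1 0.5667 0.2        32     1     12.50
#>            NA   0.5836         1.299 0.1 0.4533 0.2        32     1     10.00
#>   gamma
#>  0.7969
#>  0.7981
#>  0.8000
```

Reading the table: after pruning noise branches below persistence 1, three
branches remain — the root (depth 0, the outermost structure, persistence
10) and a chain of two nested structures. The root keeps the user luminance
L₀ = 10 cd/m²; its child is lifted to 12.50 = 10/0.8 (the contrast-ratio
amplification, accepted because the 2.5 cd/m² gap exceeds the ~1.37 cd/m²
JND at 10 cd/m²); the innermost branch reaches 15.66. The diffuse
coefficients `kd` scale those luminances by the weight w = 0.71, so the
innermost structure is lit brightest. `plot(fit)` renders the volume;
`predict(fit, "kd")` maps coefficients back onto the voxel grid;
`run_pipeline()` and the CLI at `inst/cli/topolight.R` write tree JSON,
attribute CSV, lighting JSON, segmentation and a PPM/PNG rendering.

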