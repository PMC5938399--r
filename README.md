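# projquant

Quantification of long-range axonal projections from single-neuron
reconstructions of mouse barrel-cortex layer 2/3 pyramidal neurons.

Excitatory L2/3 neurons of the primary whisker somatosensory cortex (wS1)
send axon collaterals to a characteristic set of ipsilateral targets:
secondary somatosensory cortex (wS2), whisker motor cortex (wM1/2), several
hotspots in the dysgranular zone surrounding the barrel field (AM, CM, PM),
posterolateral zones (PL1/2), a posterior zone (PP), perirhinal temporal
association cortex (TeA) and the dorsolateral striatum. `projquant` turns
serial-section tracings of such neurons into the standard quantitative
read-outs of this literature:

- **Reconstruction I/O and assembly** — standard 7-column SWC read/write
  (micrometre files, millimetre internals), and stitching of per-section
  tracing fragments into one 3D reconstruction using a manifest of rigid
  in-plane shifts, joining cut neurite endpoints across section faces
  within a configurable merge tolerance (default 5 µm).
- **Morphometry** — total dendritic length, number of dendritic stems,
  number of dendritic branch points (basal + apical pooled), total axonal
  length.
- **Region assignment** — named target regions as axis-aligned domains in a
  bregma-referenced frame (cortical columns plus a striatal box), with
  analytic clipping of every axonal segment against region boundaries, so
  per-region cable lengths conserve the total exactly. The two coordinate
  frames of the field — offsets relative to the injection site and absolute
  bregma coordinates — are related by `bregma = site + offset`.
- **Projection profiles and classification** — per neuron, branching-axon
  cable per region (cable belonging to intra-region subtrees that branch
  inside the region) separated from unbranched passing fibers; a
  cell-by-region matrix thresholded at > 1 mm (light) and > 10 mm (dark);
  S2p/M1p classification by the larger of the wS2 and wM1/2 branching
  lengths; the core fraction (wS1 + wS2 + wM1/2 share of branching axon);
  group summaries as mean ± sample SD.
- **Density hotspots** — voxelization of axonal cable into density volumes,
  coronal/horizontal 2D projections, and estimation of per-region hotspot
  centers across animals (mean ± SD in both frames), using smoothed local
  maxima, globally matched to nominal region seeds, and 50%-of-peak
  support centroids.
- **Synthetic data** — a generator producing reconstructions and
  multi-animal density volumes with exactly known ground truth (planted
  per-region cable, stems, branch points, hotspot centers), which is how
  every stage of the pipeline is validated end to end.

## Worked example

```r
library(projquant)

model <- prepare_model(default_region_model())

# a synthetic S2p-like neuron: 12 mm branching collateral in wS2,
# 5 mm in the striatum, 41.7 mm of local wS1 axon
spec <- synthetic_neuron_spec(
  "demo", collaterals = data.frame(
    region = c("wS2", "Striatum"), length_mm = c(12, 5),
    include_branch = TRUE),
  seed = 42)
g <- generate_neuron(spec, model)

summarize_morphometry(g$neuron)
#>   neuron_id dendritic_length n_stems n_branch_points axonal_length
#> 1      demo              8.1       8              64      64.83087

quantify_projection(g$neuron, model)
#> Projection profile 'demo': total axon 64.8 mm (6.1 mm unassigned)
#>    region branching_mm passing_mm
#>       wS2         12.0          0
#>  Striatum          5.0          0
#>       wS1         41.7          0

classify_projection_class(quantify_projection(g$neuron, model))
#> [1] "S2p"
```

The dendritic metrics hit the planted targets exactly (8.1 mm on 8 stems
with 64 branch nodes), the planted collateral lengths are recovered to
floating-point precision, and the 6.1 mm of unassigned cable is the
trunk plumbing that routes collaterals below the modelled regions.

A command-line wrapper over the same functions is installed with the
package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/projquant.R", package="projquant"))')" \
    simulate --seed 17 --out sim/
```

with subcommands `simulate`, `metrics`, `quantify`, `classify`, `stitch`
and `hotspots`.

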