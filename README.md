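# neuroarbor

Dendritic-complexity analysis for digitally traced neurons: per-neuron
morphometrics, exact three-dimensional Sholl profiles, stereological
neuron-density estimation, and two-group statistics, with a seeded
synthetic-cohort generator for end-to-end validation.

## The scientific problem

Neurodegeneration changes the fine structure of neurons long before cells
die. Studies of disease-model mice therefore trace individual
Golgi-stained pyramidal neurons from high-resolution brain volumes and
ask, per brain region, whether *dendritic complexity* differs between
cohorts (e.g. 6- versus 12-month-old animals). Complexity is summarised
per neuron as:

* **total dendritic length** — L = Σ over segments of |xᵢ − x_parent(i)| (µm);
* **terminal-dendrite count** — T, the number of last-stage (leaf) branches;
* **spatial volume** — V (µm³), the smallest cubic volume accommodating
  the neuron (axis-aligned box by default, literal cube as an option);
* the **3D Sholl profile** — N(r), the number of transversal crossings of
  the arbor with concentric spheres of radius r = Δr, 2Δr, … centred at
  the soma (Δr = 30 µm by default). Per segment, crossings are the roots
  of |a + t(b − a) − c|² = r² counted so that each crossing is attributed
  to exactly one segment.

Regional neuron density is estimated stereologically: soma centroids are
counted in systematically random cubic blocks (five 300 µm cubes at 3 mm
intervals by default) with half-open membership, and density is total
count over total block volume.

Cohorts are compared per metric as mean ± SEM with a two-sample t-test
(Student's pooled variant by default, Welch selectable) at α = 0.05;
Sholl profiles are compared per shell or as per-neuron sums over radius
ranges.

The package is aimed at users of tracing tools (Amira, or anything that
exports SWC) who want these analyses scripted, validated and
reproducible rather than embedded in one-off analysis code.

## A worked example

Read one traced neuron (a synthetic demo tracing shipped with the
package) and summarise it:

```r
library(neuroarbor)
f <- system.file("extdata/demo-cohort/AD06_PFC_L_L3_001.swc",
                 package = "neuroarbor")
nt <- readSWC(f, meta = parseSpecimenMetadata(f))
summarizeMorphometry(nt)
#>   cohort region hemisphere neuron_index length_um terminal_count
#> 1   AD06    PFC          L            1  793.9743              9
#>   spatial_volume_um3 node_count volume_mode
#> 1            4048085         49         box
```

The neuron has 794 µm of dendrite in 9 terminal branches inside a
4.0 × 10⁶ µm³ bounding box. Its Sholl profile peaks at mid radii and
ends where the arbor does:

```r
pr <- shollProfile(nt)   # 30 um shells
data.frame(radius_um = shellRadii(pr), intersections = intersectionCounts(pr))
#>   radius_um intersections
#> 1        30             3
#> 2        60             3
#> 3        90             4
#> 4       120             5
#> 5       150             5
#> 6       180             3
#> 7       210             0
```

Simulate a two-cohort study with a planted 15 % length deficit in the
older cohort and analyse it end to end:

```r
dirIn <- tempfile(); dirOut <- tempfile()
runSimulation(list(
  cohortSpec("AD06", 60, region = "PFC"),
  cohortSpec("AD12", 60, region = "PFC", lengthEffect = 0.85)),
  dirIn, seed = 1)
res <- runAnalysis(dirIn, dirOut)
subset(res$comparisons,
       metric %in% c("length", "terminal_count", "spatial_volume[box]"))
#>                metric    mean_a   sem_a    mean_b   sem_b     t  df        p significant
#> 1              length     747.6   28.62     625.2   22.56 3.360 118 0.001051        TRUE
#> 2      terminal_count       9.4   0.264       9.2   0.271 0.529 118 0.597799       FALSE
#> 3 spatial_volume[box] 4016033.6  427730 2455869.5  199679 3.305 118 0.001257        TRUE
```

The planted contrast is recovered: dendritic length (747.6 ± 28.6 µm vs
625.2 ± 22.6 µm, p ≈ 0.001) and the volume that shrinks with it are
flagged, terminal counts (untouched by a length effect) are not.
`dirOut` now holds `metrics.csv`, `sholl.csv`, `comparisons.csv/.json`
and a `manifest.json` echoing the configuration and seed.

Density estimation from a centroid list:

```r
ext <- regionExtent(c(12300, 350, 350))   # region span in um
cen <- readCentroids(system.file("extdata/demo_centroids.csv",
                                 package = "neuroarbor"))
d <- estimateDensity(ext, cen, seed = 2)
d$blocks$count
#> [1] 21 28 35 24 31
d$densityPerUm3
#> [1] 1.02963e-06
```

Five 300 µm blocks along the region's long axis count 21–35 somata each;
the pooled estimate (1.03 × 10⁻⁶ µm⁻³ ≈ 1030 mm⁻³) recovers the
intensity the demo field was simulated at (9.26 × 10⁻⁷ µm⁻³) within
sampling error.

A thin command-line wrapper with `analyze`, `simulate` and `density`
subcommands is installed at
`system.file("cli/neuroarbor.R", package = "neuroarbor")`.

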