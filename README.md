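# jsta — joint cell segmentation and cell type annotation for spatial transcriptomics

Hybridization-based spatial transcriptomics (MERFISH, osmFISH and similar
protocols) yields a 3D point cloud of decoded mRNA molecules and
DAPI-stained nuclei. The step that limits everything downstream is
segmentation: deciding which molecule belongs to which cell. `jsta`
implements joint segmentation and cell (sub)type annotation — an
expectation-maximization scheme in which an external scRNA-seq reference
taxonomy informs where cell borders go.

The method, in the field's standard notation: the spot cloud is converted
to a pixel-level expression matrix *E_p* by per-gene K-nearest-neighbor
density estimation, density = K / ((4/3)πr³) with r the radius to the
K-th spot (K = 5). A cell-level classifier *f_θ* (3 hidden layers of
width 3m, tanh, batch norm, L1 1e-4) is trained on the harmonized
reference and maps cell counts *E_c* to type probabilities *P_c*; cells
take the argmax type *T_c*. The segmentation is initialized by a
distance-capped watershed from the nuclei (2 µm). Then the EM loop
alternates: (M) train a pixel-level classifier *g_φ* (widths 2m/4m/8m,
tanh, batch norm, L2 1e-3) on a 10% sample of assigned pixels, labeled by
their cell's current type; (E) for every border pixel, rescale the
classifier's probability row by nucleus distance (score 10 within d = 2
µm, decay 5d/(2(r−d)) beyond, floor 0.05 empirical / 0.01 simulation,
restricted to neighboring types), boost the maximum by (1 + 0.05·t), and
sample the new assignment. Borders between same-type cells never move;
an all-zero row sends the pixel to background. The package also provides
the density-watershed baseline (compactness 10, watershed line), a
ground-truth tissue simulator, a dendrogram-aware mRNA assignment
accuracy, and permutation tests for subtype colocalization and
within-type spatially differential expression (spDEGs).

## Worked example

```r
library(jsta)

# 1. a synthetic reference taxonomy and a simulated ground-truth tissue
tax    <- synthetic_taxonomy(k = 6, m = 20, seed = 1)
tax    <- sample_reference_cells(tax, n_per_type = 50, seed = 2)
tissue <- simulate_tissue(tax, sim_params(extent = c(40, 40, 15), seed = 3))
#> <jsta_truth> 113 cells, 86714 spots, 40x40x15 um volume

# 2. joint segmentation + annotation (simulation schedule: 5 x 5)
fit <- run_jsta(tissue$spots, tissue$nuclei, tax, pixel_size = 1,
                params = reassignment_params("simulation", seed = 4))
#> <jsta_state> 113 cells, 29859/29988 pixels assigned, iteration 25

# 3. the watershed baseline on the same densities
base <- watershed_baseline(fit$grid, tissue$nuclei, fit$E_p)

# 4. taxonomy-aware accuracy at dendrogram heights 0, 0.4, 0.8
acc_jsta <- assignment_accuracy(fit, tissue)
acc_base <- assignment_accuracy(base, tissue)
round(rbind(jsta      = acc_jsta$mean_accuracy[c(1, 9, 17)],
            watershed = acc_base$mean_accuracy[c(1, 9, 17)]), 3)
#>               0   0.4   0.8
#> jsta      0.815 0.815 0.815
#> watershed 0.769 0.769 0.769

# 5. cell typing agreement with the simulated truth
mean(fit$cell_type[names(tissue$true_types)] == tissue$true_types)
#> [1] 1
```

The accuracy is a per-cell precision: for each predicted cell, the
fraction of its spots truly emitted by that cell or by a touching
neighbor of the same type group at the evaluated granularity. Here the
EM beats the geometric baseline by ~4.6 points at every granularity, and
every cell's annotated type matches the simulated truth. (With this
well-separated 6-type taxonomy the dendrogram only merges near the root,
so the sweep is flat; deep taxonomies rise with height.)

Segmentation outputs (`write_outputs()`) are plain text: a label-volume
table plus JSON manifest, the cell × gene matrix as a wide table and as
MatrixMarket with sidecars, the per-spot assignment, and a run manifest.

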