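# ringscape

Multi-range cellular context representation and multi-slice spatial domain
identification for spatially resolved single-cell and spot-based omics data.

## The problem

Spatially resolved omics assays (MERFISH, STARmap, osmFISH, Stereo-seq, 10X
Visium, ...) measure expression together with each cell's position in a
tissue section. A *spatial domain* is a recurrent tissue region — a cortical
layer, a tumor compartment, a germinal center — composed of multiple cell
states in a characteristic spatial arrangement. Studies now routinely
profile many sections (slices) from many donors, and domains must be
identified *jointly* across slices so that label `D2` means the same tissue
context in every section, at the same clustering granularity.

`ringscape` represents each cell by the composition of discrete **cell
states** counted in `S` concentric distance **rings** around it, restricted
to the cell's own slice. With `C` states and ring width `R` (micrometers),
cell `i` gets a row of the N × (S·C) count matrix **M**:

```
M[i, (s-1)*C + c] = #{ j : (s-1)*R <= Dist(i,j) < s*R,
                        slice_j = slice_i,  state_j = g_c }
```

Rings are half-open annuli, so a neighbor at exactly `s*R` belongs to the
outer ring; the index cell itself (distance 0) sits in ring 1. For
array-like spot platforms the annuli are replaced by exact hop-`s` shells of
the spot lattice graph (6 neighbors per Visium spot, 4 per ST spot). **M**
is normalized, log-transformed, PCA-reduced and clustered by Leiden
community detection over all slices at once — either at a fixed resolution
or by an automatic resolution search for a requested number of domains.

Around the core the package provides: evaluation metrics (NMI, ARI, and PAS
— the fraction of cells whose label differs from ≥ 6 of their 10 nearest
same-slice neighbors), a nearest-neighbor-distance diagnostic for choosing
`R` (`estimate_radius()`; 15 µm is the default for single-cell resolution
platforms), rank-sum **spatial signatures** that read each domain as
enriched (state, ring) features, patient-level representations with
cross-validated classification, and a synthetic layered-tissue generator
that makes every step verifiable without external data.

## Worked example

```r
library(ringscape)

# a 3-slice laminar tissue: 5 planted layers, 2000 cells/slice,
# ~15 um cell spacing, each layer dominated by its own cell states
sim <- generate_layered_tissue(tissue_spec(), seed = 1)
ds  <- sim$dataset
ds
#> <spatial_dataset> 6000 cells x 30 genes, 3 slice(s), 2D coordinates
#>   slices: slice1 (2000), slice2 (2000), slice3 (2000)
#>   cell metadata: truth_domain, truth_state

estimate_radius(ds)$recommended_radius
#> [1] 15.07529

res <- identify_domains(ds, mode = "radius", R = 15, S = 6,
                        target_k = 5, seed = 1, verbose = FALSE)
res
#> <domain_result> 6000 cells, 5 domain(s), resolution = 0.3162
#>
#>   D0   D1   D2   D3   D4
#> 1215 1201 1199 1196 1189

nmi(res$labels, ds$cells$truth_domain)
#> [1] 0.9089531
per_slice_metrics(res, ds$cells$truth_domain, ds)
#> # A tibble: 4 x 5
#>   slice      n   nmi   ari    pas
#>   <chr>  <int> <dbl> <dbl>  <dbl>
#> 1 slice1  2000 0.890 0.908 0.025
#> 2 slice2  2000 0.929 0.946 0.015
#> 3 slice3  2000 0.914 0.932 0.022
#> 4 joint   6000 0.909 0.929 0.0207
```

The joint NMI of 0.91 against the planted layers means the five domains
essentially coincide with the five layers (residual confusion sits in narrow
bands at the layer boundaries), and PAS ≈ 0.02 says the maps are spatially
smooth.
Because the three slices were clustered jointly, `D0` is the same layer in
every slice. Interpreting a domain:

```r
rank_signatures(res$representation, res, n_top = 2) |>
  dplyr::filter(domain == "D0") |>
  dplyr::select(domain, state, range, score, p_adjusted)
#> # A tibble: 2 x 5
#>   domain state range score p_adjusted
#>   <chr>  <chr> <int> <dbl>      <dbl>
#> 1 D0     g5        4  55.2          0
#> 2 D0     g5        5  55.0          0
```

i.e. domain `D0` is defined by having cell state `g5` throughout its
neighborhood at rings 4–5 (45–75 µm from the index cell). `autoplot(res, ds)` draws the
per-slice domain maps; `tidy(res)` returns one row per cell for downstream
dplyr work.

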