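# fixtures shared by property and acceptance tests

# tissue whose layers 2 and 4 share the same (pure) composition and differ
# only in their flanking layers: thin layers (60 um << S*R) so every cell's
# outer rings reach the flanks. Distinguishing the twins requires multi-range
# context; a single ring cannot do it.
adversarial_tissue <- function(seed, n_slices = 3, cells_per_layer = 200) {
  comp <- rbind(c(1, 0, 0, 0),
                c(0, 1, 0, 0),
                c(0, 0, 1, 0),
                c(0, 1, 0, 0),   # identical to layer 2
                c(0, 0, 0, 1))
  generate_layered_tissue(
    tissue_spec(n_slices = n_slices, n_layers = 5, layer_height = 60,
                width = 3400, cells_per_layer = cells_per_layer,
                composition = comp,
                state_means = ringscape:::default_state_means(4)),
    seed = seed)
}

# for every planted layer, the majority predicted label within each slice
majority_label_by_slice <- function(pred, truth, slice) {
  out <- list()
  for (layer in unique(truth)) {
    out[[layer]] <- vapply(levels(factor(slice)), function(sl) {
      sub <- pred[truth == layer & slice == sl]
      names(sort(table(sub), decreasing = TRUE))[1]
    }, character(1))
  }
  out
}
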