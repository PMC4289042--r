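# Programmatic fixtures: tiny labeled volumes and atlas mappings built at
# test time (no binary files in the repository).

# Complete 8-lobe label map: labels 1..8 as in the shipped example atlas.
full_label_map <- function() {
  tibble::tibble(
    label = 1:8,
    lobe = rep(c("frontal", "parietal", "temporal", "occipital"), 2),
    hemisphere = rep(c("left", "right"), each = 4)
  )
}

# 16^3 volume whose eight octants carry labels 1..8 (one per lobe), so every
# lobe has an 8x8x8 block; `extra_bg` randomly clears some voxels for
# variety.
octant_volume <- function(seed = 1, clear_frac = 0.1) {
  set.seed(seed)
  g <- array(0L, c(16, 16, 16))
  lab <- 0L
  for (h in 0:1) for (q in 0:3) {
    lab <- lab + 1L
    xs <- if (q %% 2 == 0) 1:8 else 9:16
    ys <- if (q < 2) 1:8 else 9:16
    zs <- if (h == 0) 1:8 else 9:16
    g[xs, ys, zs] <- lab
  }
  clear <- which(stats::runif(length(g)) < clear_frac)
  g[clear] <- 0L
  labeled_volume(g)
}

write_volume_nifti <- function(vol, path) {
  arr <- vol$grid
  attr(arr, "pixdim") <- vol$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int16"), path)
  path
}
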