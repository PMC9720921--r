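# Shared in-code fixtures and independent oracles.

# explicit unit cube mesh: 8 vertices, 12 triangles, outward orientation
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = 0
    c(5, 6, 7), c(6, 8, 7),  # z = 1
    c(1, 2, 5), c(2, 6, 5),  # y = 0
    c(3, 7, 4), c(4, 7, 8),  # y = 1
    c(1, 5, 3), c(3, 5, 7),  # x = 0
    c(2, 4, 6), c(4, 8, 6))  # x = 1
  triangle_mesh(v, f)
}

# brute-force AUC oracle: pair counting with ties at one half
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# binary mask of a sphere rasterized voxel-center-inside (independent of
# the phantom generator's internals)
raster_sphere_mask <- function(radius, spacing, margin = 4) {
  half <- radius + margin * spacing
  ax <- {
    n <- ceiling(2 * half / spacing)
    (seq_len(n) - (n + 1) / 2) * spacing
  }
  inside <- outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= radius^2
  binary_mask(inside, rep(spacing, 3))
}

# two-blob volume: a large and a small cube of foreground HU
two_blob_volume <- function() {
  vox <- array(10, dim = c(20, 20, 20))
  vox[2:9, 2:9, 2:9] <- 70       # 512 voxels
  vox[14:17, 14:17, 14:17] <- 70 # 64 voxels
  ct_volume(vox, c(1, 1, 1))
}
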