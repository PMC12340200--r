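# Independent brute-force oracles: plain nested loops, no vectorization,
# deliberately sharing no code with the implementation.

brute_burden <- function(mask) {
  d <- dim(mask); n <- 0L
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3]))
    if (mask[z, y, x]) n <- n + 1L
  100 * n / prod(d)
}

brute_pair <- function(a, b) {
  d <- dim(a); n <- 0L
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3]))
    if (a[z, y, x] && b[z, y, x]) n <- n + 1L
  100 * n / prod(d)
}

brute_triple <- function(a, b, cc) {
  d <- dim(a); n <- 0L
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3]))
    if (a[z, y, x] && b[z, y, x] && cc[z, y, x]) n <- n + 1L
  100 * n / prod(d)
}

# voxel count of the union of spheres, by exhaustive distance checks on
# voxel centres at (i - 0.5) * voxel_size
brute_union_sphere_count <- function(dims, vs, centers, radius) {
  n <- 0L
  for (z in seq_len(dims[1])) for (y in seq_len(dims[2])) for (x in seq_len(dims[3])) {
    cz <- (z - 0.5) * vs[1]; cy <- (y - 0.5) * vs[2]; cx <- (x - 0.5) * vs[3]
    for (k in seq_len(nrow(centers))) {
      if ((cz - centers[k, 1])^2 + (cy - centers[k, 2])^2 +
          (cx - centers[k, 3])^2 <= radius^2) {
        n <- n + 1L
        break
      }
    }
  }
  n
}

rand_mask <- function(dims, p, seed) {
  set.seed(seed)
  array(runif(prod(dims)) < p, dim = dims)
}

# small, fast scene presets for unit tests
tiny_params <- function(...) {
  scene_params(shape_vox = c(6L, 32L, 32L), ...)
}

noiseless_params <- function(...) {
  scene_params(psf_sigma_um = c(0, 0, 0), photon_scale = Inf,
               read_noise_sd = 0, ...)
}

f1_score <- function(pred, truth) {
  2 * sum(pred & truth) / (sum(pred) + sum(truth))
}
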