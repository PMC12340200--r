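# Synthetic 4-channel confocal scene generator.
#
# A scene is built in physical micrometre coordinates on a voxel grid:
# punctate synaptic spheres, an optional diffuse amyloid plaque with
# Gaussian intensity falloff, branched glial arbors (soma spheres plus
# capsule branches) for the microglial and astrocytic channels, and
# synaptic amyloid-beta cores. Ground truth is computed on the pre-blur
# binary geometry by exact voxel counting, then the intensity image is
# degraded by a Gaussian PSF, Poisson photon noise, Gaussian read noise
# and a constant background.

FOREGROUND_LEVEL <- 1.0  # clean foreground intensity; masks live at >= 0.5

#' Parameters of one glial channel's arbor
#'
#' @param soma_count number of glial somata in the field.
#' @param soma_radius_um soma radius (micrometres).
#' @param branch_count processes per soma.
#' @param branch_length_um process length.
#' @param branch_radius_um process radius.
#' @return a `glia_params` list.
#' @export
glia_params <- function(soma_count = 4L, soma_radius_um = 2.5,
                        branch_count = 5L, branch_length_um = 12,
                        branch_radius_um = 0.75) {
  if (soma_count < 0) abort_field("soma_count", "must be >= 0")
  if (soma_count > 0) {
    check_positive(soma_radius_um, "soma_radius_um")
    check_positive(branch_length_um, "branch_length_um")
    check_positive(branch_radius_um, "branch_radius_um")
    if (branch_count < 0) abort_field("branch_count", "must be >= 0")
  }
  structure(list(soma_count = as.integer(soma_count),
                 soma_radius_um = soma_radius_um,
                 branch_count = as.integer(branch_count),
                 branch_length_um = branch_length_um,
                 branch_radius_um = branch_radius_um),
            class = "glia_params")
}

#' Scene parameters for the synthetic generator
#'
#' Defaults describe a desk-scale field: 16 x 128 x 128 voxels at
#' 0.4 x 0.3 x 0.3 um (38.4 x 38.4 um field of view, 6.4 um deep). The
#' study's full field (184.7 x 184.7 um) is available by passing a larger
#' `shape_vox`; the voxel size and depth are conventions, since the source
#' protocol states the field size but not the voxel grid.
#'
#' @param shape_vox integer triple `(z, y, x)` voxel counts.
#' @param voxel_size_um positive triple `(z, y, x)` in micrometres.
#' @param synapse_density_per_um3 expected synaptic puncta per cubic
#'   micrometre (Poisson-distributed count).
#' @param synapse_radius_um radius of a synaptic punctum.
#' @param ab_in_synapse_fraction probability that a punctum carries an
#'   amyloid-beta-positive core.
#' @param plaque_present logical; render one diffuse plaque.
#' @param plaque_center_um plaque centre `(z, y, x)` in micrometres;
#'   `NULL` = stack centre. Must lie inside the stack when present.
#' @param plaque_radius_um half-intensity radius of the plaque.
#' @param plaque_halo_um halo width beyond the plaque radius within which
#'   `near_plaque_multipliers` apply.
#' @param glia list with elements `IBA1` and `GFAP`, each a [glia_params()].
#' @param engulfment_fraction fraction of puncta relocated into glia.
#' @param engulfment_ab_bias multiplier (>= 0) on the selection weight of
#'   amyloid-positive puncta during engulfment sampling; 1 = unbiased.
#' @param near_plaque_multipliers named triple
#'   `(glial_density, engulfment_fraction, ab_in_synapse_fraction)` of
#'   multipliers (>= 0) applied within `plaque_radius + halo`.
#' @param psf_sigma_um Gaussian PSF sigma `(z, y, x)`; zeros = no blur.
#' @param photon_scale photons per intensity unit for Poisson noise.
#' @param read_noise_sd Gaussian read-noise standard deviation.
#' @param background_level constant background intensity offset.
#' @return a validated `scene_params` list.
#' @export
scene_params <- function(shape_vox = c(16L, 128L, 128L),
                         voxel_size_um = c(0.4, 0.3, 0.3),
                         synapse_density_per_um3 = 0.10,
                         synapse_radius_um = 0.5,
                         ab_in_synapse_fraction = 0.15,
                         plaque_present = FALSE,
                         plaque_center_um = NULL,
                         plaque_radius_um = 8,
                         plaque_halo_um = 10,
                         glia = list(IBA1 = glia_params(),
                                     GFAP = glia_params(branch_radius_um = 0.9)),
                         engulfment_fraction = 0.05,
                         engulfment_ab_bias = 1,
                         near_plaque_multipliers = c(glial_density = 1.5,
                                                     engulfment_fraction = 2,
                                                     ab_in_synapse_fraction = 2),
                         psf_sigma_um = c(0.35, 0.15, 0.15),
                         photon_scale = 100,
                         read_noise_sd = 0.02,
                         background_level = 0.1) {
  check_positive(shape_vox, "shape_vox", len = 3L)
  check_positive(voxel_size_um, "voxel_size_um", len = 3L)
  check_positive(synapse_density_per_um3, "synapse_density_per_um3", strict = FALSE)
  check_positive(synapse_radius_um, "synapse_radius_um")
  check_fraction(ab_in_synapse_fraction, "ab_in_synapse_fraction")
  check_fraction(engulfment_fraction, "engulfment_fraction")
  check_positive(engulfment_ab_bias, "engulfment_ab_bias", strict = FALSE)
  check_positive(psf_sigma_um, "psf_sigma_um", len = 3L, strict = FALSE)
  check_positive(photon_scale, "photon_scale")
  check_positive(read_noise_sd, "read_noise_sd", strict = FALSE)
  check_positive(background_level, "background_level", strict = FALSE)
  nm <- c("glial_density", "engulfment_fraction", "ab_in_synapse_fraction")
  if (!all(nm %in% names(near_plaque_multipliers)) ||
      any(near_plaque_multipliers[nm] < 0))
    abort_field("near_plaque_multipliers",
                sprintf("must be named non-negative values for %s",
                        paste(nm, collapse = ", ")))
  if (!is.list(glia) || !all(c("IBA1", "GFAP") %in% names(glia)))
    abort_field("glia", "must be a list with elements 'IBA1' and 'GFAP'")
  extent <- shape_vox * voxel_size_um  # (z, y, x) in um
  if (isTRUE(plaque_present)) {
    check_positive(plaque_radius_um, "plaque_radius_um")
    check_positive(plaque_halo_um, "plaque_halo_um", strict = FALSE)
    if (is.null(plaque_center_um)) plaque_center_um <- extent / 2
    check_positive(plaque_center_um, "plaque_center_um", len = 3L, strict = FALSE)
    if (any(plaque_center_um < 0) || any(plaque_center_um > extent))
      abort_field("plaque_center_um", "must lie inside the stack bounds")
  }
  structure(list(
    shape_vox = as.integer(shape_vox), voxel_size_um = as.numeric(voxel_size_um),
    synapse_density_per_um3 = synapse_density_per_um3,
    synapse_radius_um = synapse_radius_um,
    ab_in_synapse_fraction = ab_in_synapse_fraction,
    plaque_present = isTRUE(plaque_present),
    plaque_center_um = if (isTRUE(plaque_present)) as.numeric(plaque_center_um) else NULL,
    plaque_radius_um = plaque_radius_um, plaque_halo_um = plaque_halo_um,
    glia = glia, engulfment_fraction = engulfment_fraction,
    engulfment_ab_bias = engulfment_ab_bias,
    near_plaque_multipliers = near_plaque_multipliers[nm],
    psf_sigma_um = as.numeric(psf_sigma_um), photon_scale = photon_scale,
    read_noise_sd = read_noise_sd, background_level = background_level),
    class = "scene_params")
}

# ---- geometry rasterization (voxel centres at (i - 0.5) * voxel_size) ----

# linear indices (into an array of dims d, (z,y,x)) of voxels whose centre
# lies within radius r of centre p (um)
sphere_voxels <- function(d, vs, p, r) {
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, floor((p[a] - r) / vs[a] - 0.5) + 1L)
    hi <- min(d[a], ceiling((p[a] + r) / vs[a] + 0.5))
    if (lo > hi) integer(0) else lo:hi
  })
  if (!all(lengths(rng))) return(integer(0))
  dz2 <- ((rng[[1]] - 0.5) * vs[1] - p[1])^2
  dy2 <- ((rng[[2]] - 0.5) * vs[2] - p[2])^2
  dx2 <- ((rng[[3]] - 0.5) * vs[3] - p[3])^2
  nz <- length(dz2); ny <- length(dy2); nx <- length(dx2)
  d2 <- rep(dz2, times = ny * nx) + rep(rep(dy2, each = nz), times = nx) +
    rep(dx2, each = nz * ny)
  keep <- d2 <= r * r
  if (!any(keep)) return(integer(0))
  iz <- rep(rng[[1]], times = ny * nx)[keep]
  iy <- rep(rep(rng[[2]], each = nz), times = nx)[keep]
  ix <- rep(rng[[3]], each = nz * ny)[keep]
  iz + (iy - 1L) * d[1] + (ix - 1L) * d[1] * d[2]
}

# linear indices of voxels within radius r of segment p0->p1 (a capsule)
capsule_voxels <- function(d, vs, p0, p1, r) {
  lo_um <- pmin(p0, p1) - r; hi_um <- pmax(p0, p1) + r
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, floor(lo_um[a] / vs[a] - 0.5) + 1L)
    hi <- min(d[a], ceiling(hi_um[a] / vs[a] + 0.5))
    if (lo > hi) integer(0) else lo:hi
  })
  if (!all(lengths(rng))) return(integer(0))
  cz <- (rng[[1]] - 0.5) * vs[1]; cy <- (rng[[2]] - 0.5) * vs[2]
  cx <- (rng[[3]] - 0.5) * vs[3]
  nz <- length(cz); ny <- length(cy); nx <- length(cx)
  Z <- rep(cz, times = ny * nx)
  Y <- rep(rep(cy, each = nz), times = nx)
  X <- rep(cx, each = nz * ny)
  dvec <- p1 - p0; len2 <- sum(dvec^2)
  if (len2 == 0) return(sphere_voxels(d, vs, p0, r))
  t <- ((Z - p0[1]) * dvec[1] + (Y - p0[2]) * dvec[2] + (X - p0[3]) * dvec[3]) / len2
  t <- pmin(pmax(t, 0), 1)
  d2 <- (Z - (p0[1] + t * dvec[1]))^2 + (Y - (p0[2] + t * dvec[2]))^2 +
    (X - (p0[3] + t * dvec[3]))^2
  keep <- d2 <= r * r
  if (!any(keep)) return(integer(0))
  iz <- rep(rng[[1]], times = ny * nx)[keep]
  iy <- rep(rep(rng[[2]], each = nz), times = nx)[keep]
  ix <- rep(rng[[3]], each = nz * ny)[keep]
  iz + (iy - 1L) * d[1] + (ix - 1L) * d[1] * d[2]
}

# separable Gaussian blur along all three axes; sigma in voxels, clamped
# (nearest) boundary handling
gaussian_blur3 <- function(arr, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    rad <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-rad:rad, sd = s); k <- k / sum(k)
    perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    a <- aperm(arr, perm)
    dd <- dim(a)
    m <- matrix(a, nrow = dd[1])
    out <- matrix(0, nrow = dd[1], ncol = ncol(m))
    for (j in seq_along(k)) {
      sh <- j - rad - 1L
      idx <- pmin(pmax(seq_len(dd[1]) + sh, 1L), dd[1])
      out <- out + k[j] * m[idx, , drop = FALSE]
    }
    a <- array(out, dim = dd)
    arr <- aperm(a, order(perm))
  }
  arr
}

pair_key <- function(a, b) {
  i <- match(c(a, b), STUDY_CHANNELS)
  paste(STUDY_CHANNELS[sort(i)], collapse = "&")
}

triple_key <- function(a, b, c) {
  i <- sort(match(c(a, b, c), STUDY_CHANNELS))
  paste(STUDY_CHANNELS[i], collapse = "&")
}

all_pair_keys <- function() {
  cmb <- utils::combn(STUDY_CHANNELS, 2)
  apply(cmb, 2, paste, collapse = "&")
}

all_triple_keys <- function() {
  cmb <- utils::combn(STUDY_CHANNELS, 3)
  apply(cmb, 2, paste, collapse = "&")
}

truth_from_masks <- function(masks, punctum_table, plaque_mask) {
  nvox <- length(masks[[1]])
  burden <- vapply(masks, function(m) 100 * sum(m) / nvox, numeric(1))
  pw <- vapply(as.data.frame(utils::combn(STUDY_CHANNELS, 2),
                             stringsAsFactors = FALSE), function(p)
    100 * sum(masks[[p[1]]] & masks[[p[2]]]) / nvox, numeric(1))
  names(pw) <- all_pair_keys()
  tr <- vapply(as.data.frame(utils::combn(STUDY_CHANNELS, 3),
                             stringsAsFactors = FALSE), function(p)
    100 * sum(masks[[p[1]]] & masks[[p[2]]] & masks[[p[3]]]) / nvox, numeric(1))
  names(tr) <- all_triple_keys()
  structure(list(true_burden_pct = burden, true_pairwise_pct = pw,
                 true_triple_pct = tr, punctum_table = punctum_table,
                 plaque_mask = plaque_mask, masks = masks),
            class = "ground_truth")
}

#' Generate one synthetic 4-channel scene with ground truth
#'
#' Rendering order: place geometry, relocate engulfed puncta into glial
#' volumes, compute exact voxel-count ground truth on the binary geometry,
#' then blur with the PSF and add Poisson photon noise, Gaussian read noise
#' and the constant background (clamped at zero). Identical
#' `(params, seed)` give bit-identical output.
#'
#' @param params a [scene_params()].
#' @param seed integer RNG seed for this scene.
#' @return list with elements `stack` (an [image_stack()]) and `truth`
#'   (class `ground_truth`: `true_burden_pct`, `true_pairwise_pct`,
#'   `true_triple_pct`, `punctum_table`, `plaque_mask`, and the binary
#'   geometry `masks` per channel).
#' @export
generate_scene <- function(params, seed) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(seed, {
    d <- params$shape_vox; vs <- params$voxel_size_um
    extent <- d * vs
    nvox <- prod(d)
    mk_mask <- function() array(FALSE, dim = d)
    masks <- stats::setNames(lapply(STUDY_CHANNELS, function(x) mk_mask()),
                             STUDY_CHANNELS)

    # --- plaque geometry ---
    plaque_mask <- mk_mask()
    plaque_density <- NULL
    halo_r <- if (params$plaque_present)
      params$plaque_radius_um + params$plaque_halo_um else 0
    if (params$plaque_present) {
      pc <- params$plaque_center_um
      # Gaussian falloff whose half-intensity surface sits at plaque_radius
      sig <- params$plaque_radius_um / sqrt(2 * log(2))
      cz <- (seq_len(d[1]) - 0.5) * vs[1]
      cy <- (seq_len(d[2]) - 0.5) * vs[2]
      cx <- (seq_len(d[3]) - 0.5) * vs[3]
      d2 <- rep((cz - pc[1])^2, times = d[2] * d[3]) +
        rep(rep((cy - pc[2])^2, each = d[1]), times = d[3]) +
        rep((cx - pc[3])^2, each = d[1] * d[2])
      plaque_density <- array(exp(-d2 / (2 * sig^2)), dim = d)
      plaque_mask <- plaque_density >= 0.5
    }
    in_halo <- function(p) {
      params$plaque_present &&
        sqrt(sum((p - params$plaque_center_um)^2)) <= halo_r
    }

    # --- glial arbors (extra somata concentrated in the plaque halo) ---
    mult <- params$near_plaque_multipliers
    halo_frac <- if (params$plaque_present)
      min(1, (4 / 3) * pi * halo_r^3 / prod(extent)) else 0
    p_halo <- if (halo_frac > 0) {
      m <- mult[["glial_density"]]
      m * halo_frac / (m * halo_frac + (1 - halo_frac))
    } else 0
    rand_point <- function() stats::runif(3) * extent
    rand_point_halo <- function() {
      # rejection-sample a point inside halo sphere (and stack bounds)
      repeat {
        u <- stats::runif(3, -1, 1)
        if (sum(u^2) <= 1) {
          p <- params$plaque_center_um + u * halo_r
          if (all(p >= 0) && all(p <= extent)) return(p)
        }
      }
    }
    for (gch in GLIAL_CHANNELS) {
      gp <- params$glia[[gch]]
      if (gp$soma_count == 0) next
      for (s in seq_len(gp$soma_count)) {
        ctr <- if (stats::runif(1) < p_halo) rand_point_halo() else rand_point()
        masks[[gch]][sphere_voxels(d, vs, ctr, gp$soma_radius_um)] <- TRUE
        for (b in seq_len(gp$branch_count)) {
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          masks[[gch]][capsule_voxels(d, vs, ctr,
                                      ctr + u * gp$branch_length_um,
                                      gp$branch_radius_um)] <- TRUE
        }
      }
    }

    # --- synaptic puncta ---
    n_syn <- stats::rpois(1, params$synapse_density_per_um3 * prod(extent))
    centers <- matrix(stats::runif(3 * n_syn), ncol = 3) %*% diag(extent, 3)
    near <- if (n_syn > 0) apply(centers, 1, in_halo) else logical(0)
    p_ab <- pmin(1, params$ab_in_synapse_fraction *
                   ifelse(near, mult[["ab_in_synapse_fraction"]], 1))
    ab_pos <- stats::runif(n_syn) < p_ab
    engulfed_by <- rep("none", n_syn)

    # --- engulfment: weighted selection, relocation into glial volume ---
    e_i <- pmin(1, params$engulfment_fraction *
                  ifelse(near, mult[["engulfment_fraction"]], 1))
    glia_vox <- lapply(masks[GLIAL_CHANNELS], which)
    n_glia <- vapply(glia_vox, length, integer(1))
    if (n_syn > 0 && sum(e_i) > 0 && any(n_glia > 0)) {
      k <- min(n_syn, round(sum(e_i)))
      w <- e_i * ifelse(ab_pos, params$engulfment_ab_bias, 1)
      if (k > 0 && sum(w > 0) >= k) {
        sel <- sample.int(n_syn, k, prob = w)
        host <- sample(GLIAL_CHANNELS[n_glia > 0], k, replace = TRUE)
        for (j in seq_len(k)) {
          i <- sel[j]; gch <- host[j]
          vox <- glia_vox[[gch]][sample.int(n_glia[[gch]], 1)]
          iz <- (vox - 1L) %% d[1] + 1L
          iy <- ((vox - 1L) %/% d[1]) %% d[2] + 1L
          ix <- (vox - 1L) %/% (d[1] * d[2]) + 1L
          centers[i, ] <- (c(iz, iy, ix) - 1 + stats::runif(3)) * vs
          engulfed_by[i] <- if (gch == "IBA1") "microglia" else "astrocyte"
        }
      }
    }

    # --- rasterize synapses and their amyloid cores ---
    # an amyloid-positive terminal is amyloid across its footprint: cores
    # share the punctum radius (sub-punctum cores would be below the PSF)
    core_r <- params$synapse_radius_um
    for (i in seq_len(n_syn)) {
      masks$Synapsin1[sphere_voxels(d, vs, centers[i, ],
                                    params$synapse_radius_um)] <- TRUE
      if (ab_pos[i])
        masks$Abeta4G8[sphere_voxels(d, vs, centers[i, ], core_r)] <- TRUE
    }
    masks$Abeta4G8 <- masks$Abeta4G8 | plaque_mask

    punctum_table <- data.frame(
      punctum_id = seq_len(n_syn),
      z_um = centers[, 1][seq_len(n_syn)],
      y_um = centers[, 2][seq_len(n_syn)],
      x_um = centers[, 3][seq_len(n_syn)],
      radius_um = rep(params$synapse_radius_um, n_syn),
      ab_positive = ab_pos, near_plaque = near,
      engulfed_by = engulfed_by, stringsAsFactors = FALSE)

    truth <- truth_from_masks(masks, punctum_table, plaque_mask)

    # --- render intensities: geometry -> PSF -> noise -> background ---
    voxarr <- array(0, dim = c(4L, d))
    sigma_vox <- params$psf_sigma_um / vs
    for (ci in seq_along(STUDY_CHANNELS)) {
      ch <- STUDY_CHANNELS[ci]
      img <- array(as.numeric(masks[[ch]]), dim = d)
      if (ch == "Abeta4G8" && !is.null(plaque_density))
        img <- pmax(img, plaque_density)
      img <- img * FOREGROUND_LEVEL
      img <- gaussian_blur3(img, sigma_vox)
      if (is.finite(params$photon_scale))  # photon_scale = Inf: no shot noise
        img <- stats::rpois(nvox, params$photon_scale * img) / params$photon_scale
      if (params$read_noise_sd > 0)
        img <- img + stats::rnorm(nvox, sd = params$read_noise_sd)
      img <- img + params$background_level
      voxarr[ci, , , ] <- pmax(img, 0)
    }
    list(stack = image_stack(voxarr, STUDY_CHANNELS, vs,
                             provenance = sprintf("synthetic seed=%d", seed)),
         truth = truth)
  })
}
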