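# Per-channel 3D segmentation. The original analysis used unpublished
# ImageJ/MATLAB scripts; the documented stand-in here is whole-stack
# thresholding (Otsu by default, fixed or percentile alternatives) followed
# by optional removal of small connected components.

#' Segmentation configuration
#'
#' @param method `"otsu"` (parameter-free, default), `"fixed"` (absolute
#'   intensity threshold) or `"percentile"` (threshold at an intensity
#'   percentile of the channel).
#' @param fixed_threshold threshold intensity for `method = "fixed"`.
#' @param percentile percentile in (0, 100) for `method = "percentile"`.
#' @param min_object_voxels connected components (under `connectivity`)
#'   smaller than this are removed; 0 (default) disables filtering, since
#'   the source analysis states no size filter.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(method = c("otsu", "fixed", "percentile"),
                                fixed_threshold = NULL, percentile = NULL,
                                min_object_voxels = 0L,
                                connectivity = 6L) {
  method <- match.arg(method)
  if (method == "fixed" && (is.null(fixed_threshold) || !is.finite(fixed_threshold)))
    abort_field("fixed_threshold", "required (finite) for method = 'fixed'")
  if (method == "percentile") {
    if (is.null(percentile) || percentile <= 0 || percentile >= 100)
      abort_field("percentile", "must lie in (0, 100)")
  }
  if (min_object_voxels < 0)
    abort_field("min_object_voxels", "must be >= 0")
  if (!connectivity %in% c(6L, 26L))
    abort_field("connectivity", "must be 6 or 26")
  structure(list(method = method, fixed_threshold = fixed_threshold,
                 percentile = percentile,
                 min_object_voxels = as.integer(min_object_voxels),
                 connectivity = as.integer(connectivity)),
            class = "segmentation_config")
}

#' Otsu's threshold for a 3D channel
#'
#' Maximizes between-class variance on a 256-bin histogram over the
#' intensity range; returns the bin-upper-edge threshold (voxels strictly
#' above it are foreground). Errors on a constant channel, where no
#' data-driven threshold exists.
#'
#' @param x numeric array or vector of intensities.
#' @param n_bins histogram resolution.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("degenerate input: channel intensity is constant, Otsu threshold undefined",
         call. = FALSE)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE,
                             all.inside = TRUE), n_bins)
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  br[which.max(sigma_b) + 1L]
}

# 3D connected-component labelling via igraph: nodes are positive voxels,
# edges join neighbours under the requested connectivity.
neighbour_offsets <- function(connectivity) {
  offs <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    v <- c(dz, dy, dx)
    if (all(v == 0)) next
    if (connectivity == 6L && sum(abs(v)) != 1L) next
    offs[[length(offs) + 1L]] <- v
  }
  # keep one direction per axis pair (undirected edges)
  keep <- vapply(offs, function(v) {
    nz <- which(v != 0)[1]
    v[nz] > 0
  }, logical(1))
  offs[keep]
}

#' Label connected components of a 3D logical mask
#'
#' @param mask logical 3D array `(z, y, x)`.
#' @param connectivity 6 or 26.
#' @return integer array of the same shape: 0 = background, components
#'   numbered from 1.
#' @export
label_components <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  pos <- which(mask)
  lab <- array(0L, dim = d)
  if (!length(pos)) return(lab)
  node <- integer(prod(d))
  node[pos] <- seq_along(pos)
  iz <- (pos - 1L) %% d[1] + 1L
  iy <- ((pos - 1L) %/% d[1]) %% d[2] + 1L
  ix <- (pos - 1L) %/% (d[1] * d[2]) + 1L
  edges <- list()
  for (off in neighbour_offsets(connectivity)) {
    jz <- iz + off[1]; jy <- iy + off[2]; jx <- ix + off[3]
    ok <- jz >= 1L & jz <= d[1] & jy >= 1L & jy <= d[2] & jx >= 1L & jx <= d[3]
    if (!any(ok)) next
    nb <- jz[ok] + (jy[ok] - 1L) * d[1] + (jx[ok] - 1L) * d[1] * d[2]
    hit <- node[nb] > 0L
    if (!any(hit)) next
    edges[[length(edges) + 1L]] <-
      rbind(node[pos[ok]][hit], node[nb][hit])
  }
  g <- igraph::make_empty_graph(n = length(pos), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  comp <- igraph::components(g)$membership
  lab[pos] <- as.integer(comp)
  lab
}

remove_small_objects <- function(mask, min_voxels, connectivity) {
  if (min_voxels <= 1L || !any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep & mask, dim = dim(mask))
}

#' Segment one channel of a stack into a binary mask
#'
#' Resolves the threshold per whole stack (imaging parameters are assumed
#' constant within a stack), marks voxels with intensity strictly above it,
#' then removes connected components below `min_object_voxels`.
#' Deterministic.
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @param config a [segmentation_config()].
#' @return a `binary_mask`: list of `mask` (logical `(z,y,x)` array),
#'   `channel_name`, `voxel_size_um` and `method_record` (method, resolved
#'   threshold, min object size, connectivity).
#' @export
segment_channel <- function(stack, channel, config = segmentation_config()) {
  stopifnot(inherits(config, "segmentation_config"))
  arr <- get_channel(stack, channel)
  thr <- switch(config$method,
    otsu = otsu_threshold(arr),
    fixed = config$fixed_threshold,
    percentile = as.numeric(stats::quantile(arr, config$percentile / 100)))
  mask <- arr > thr
  mask <- remove_small_objects(mask, config$min_object_voxels,
                               config$connectivity)
  binary_mask(mask, canonical_channel(channel), stack$voxel_size_um,
              method_record = list(method = config$method, threshold = thr,
                                   min_object_voxels = config$min_object_voxels,
                                   connectivity = config$connectivity))
}

#' Construct a binary mask object
#'
#' @param mask logical 3D array `(z, y, x)`.
#' @param channel_name source channel label.
#' @param voxel_size_um voxel size `(z, y, x)` in micrometres.
#' @param method_record provenance of the segmentation (method, threshold,
#'   min object size).
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(mask, channel_name, voxel_size_um,
                        method_record = list(method = "manual",
                                             threshold = NA_real_,
                                             min_object_voxels = 0L)) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    abort_field("mask", "must be a logical 3D array (z, y, x)")
  check_positive(voxel_size_um, "voxel_size_um", len = 3L)
  structure(list(mask = mask, channel_name = channel_name,
                 voxel_size_um = as.numeric(voxel_size_um),
                 method_record = method_record),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<binary_mask> '%s' %d x %d x %d, %d positive voxels (%.3f%%), method %s (thr %.4g)\n",
              x$channel_name, d[1], d[2], d[3], sum(x$mask),
              100 * mean(x$mask), x$method_record$method,
              x$method_record$threshold))
  invisible(x)
}

#' No-primary negative-control QC
#'
#' Segments every channel of a designated control stack and fails the check
#' if any channel's percent-volume burden exceeds `max_burden_pct`,
#' flagging non-specific staining. With a data-driven method the threshold
#' should come from a matched stained stack; pass it via a `"fixed"`
#' config (per channel thresholds via `thresholds`).
#'
#' @param stack the control [image_stack()].
#' @param config a [segmentation_config()] applied to each channel.
#' @param max_burden_pct maximum tolerated burden (percent) per channel.
#' @param thresholds optional named per-channel fixed thresholds overriding
#'   `config` (e.g. carried over from stained stacks of the same batch).
#' @return list of class `qc_report`: `pass` (logical), `max_burden_pct`,
#'   `burdens` (named percent per channel).
#' @export
qc_negative_control <- function(stack, config = segmentation_config(),
                                max_burden_pct = 0.5, thresholds = NULL) {
  burdens <- vapply(stack$channel_names, function(ch) {
    cfg <- config
    if (!is.null(thresholds) && ch %in% names(thresholds))
      cfg <- segmentation_config(method = "fixed",
                                 fixed_threshold = thresholds[[ch]],
                                 min_object_voxels = config$min_object_voxels,
                                 connectivity = config$connectivity)
    burden(segment_channel(stack, ch, cfg))
  }, numeric(1))
  structure(list(pass = all(burdens <= max_burden_pct),
                 max_burden_pct = max_burden_pct, burdens = burdens),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s (limit %.3g%%)\n",
              if (x$pass) "PASS" else "FAIL", x$max_burden_pct))
  for (ch in names(x$burdens))
    cat(sprintf("  %-10s %8.4f%%\n", ch, x$burdens[[ch]]))
  invisible(x)
}
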