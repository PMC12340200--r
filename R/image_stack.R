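#' Multi-channel 3D image stack
#'
#' The unit of imaging for the whole pipeline: a 4D numeric array of
#' fluorescence intensities ordered `(channel, z, y, x)`, with named channels
#' and physical voxel dimensions in micrometres. Study stacks carry exactly
#' the four channels returned by [study_channels()]; arbitrary channel sets
#' are allowed for generic use.
#'
#' @param voxels numeric 4D array ordered `(channel, z, y, x)`; all values
#'   must be finite and non-negative.
#' @param channel_names character vector, one label per channel. Variant
#'   labels are canonicalized via [canonical_channel()].
#' @param voxel_size_um numeric length-3, physical voxel size `(z, y, x)` in
#'   micrometres; all strictly positive.
#' @param provenance free-form string recording the source path or generator
#'   seed.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, channel_names, voxel_size_um,
                        provenance = "unknown") {
  if (!is.array(voxels) || length(dim(voxels)) != 4L)
    abort_field("voxels", "must be a 4D array ordered (channel, z, y, x)")
  if (!all(is.finite(voxels)) || any(voxels < 0))
    abort_field("voxels", "all intensities must be finite and >= 0")
  channel_names <- canonical_channel(as.character(channel_names))
  if (length(channel_names) != dim(voxels)[1L])
    abort_field("channel_names", "length must equal the number of channels")
  if (anyDuplicated(channel_names))
    abort_field("channel_names", "must be unique")
  check_positive(voxel_size_um, "voxel_size_um", len = 3L)
  structure(
    list(voxels = voxels, channel_names = channel_names,
         voxel_size_um = as.numeric(voxel_size_um),
         provenance = as.character(provenance)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d channel(s) [%s], %d x %d x %d voxels (z,y,x)\n",
              d[1], paste(x$channel_names, collapse = ", "), d[2], d[3], d[4]))
  cat(sprintf("  voxel size (um): %s | provenance: %s\n",
              paste(signif(x$voxel_size_um, 4), collapse = " x "), x$provenance))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Extract one channel of a stack as a 3D array
#'
#' @param stack an [image_stack()].
#' @param channel channel name (aliases accepted).
#' @return numeric 3D array `(z, y, x)`.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  channel <- canonical_channel(channel)
  i <- match(channel, stack$channel_names)
  if (is.na(i))
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(stack$channel_names, collapse = ", ")), call. = FALSE)
  arr <- stack$voxels[i, , , , drop = FALSE]
  dim(arr) <- dim(stack$voxels)[2:4]
  arr
}

#' Validate that a stack carries the four study channels
#'
#' @param stack an [image_stack()].
#' @return the stack, invisibly; errors if any study channel is missing.
#' @export
validate_study_stack <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  missing <- setdiff(STUDY_CHANNELS, stack$channel_names)
  if (length(missing))
    stop(sprintf(
      "study analysis requires the 4 channels %s; missing: %s",
      paste(STUDY_CHANNELS, collapse = ", "),
      paste(missing, collapse = ", ")), call. = FALSE)
  invisible(stack)
}
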