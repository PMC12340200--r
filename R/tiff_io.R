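# Minimal baseline TIFF backend.
#
# No TIFF library ships with this R installation, so stacks are stored as
# little-endian, uncompressed, single-strip, multi-page baseline TIFF
# (64-bit float for intensities, 8-bit for masks). Channel names, voxel size
# and provenance travel in the first page's ImageDescription as JSON, the
# same slot ImageJ/OME use for metadata. The subset written here is readable
# by standard tools (tifffile, ImageJ); the reader accepts the same subset.

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

tiff_tag <- function(code, type, count, value_raw4) {
  c(writeBin(as.integer(code), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    value_raw4)
}

tiff_val_short <- function(x)
  c(writeBin(as.integer(x), raw(), size = 2, endian = "little"), raw(2))
tiff_val_long <- function(x)
  writeBin(as.integer(x), raw(), size = 4, endian = "little")

#' Write an image stack to a multi-page TIFF
#'
#' Pages are ordered channel-major (all z planes of channel 1, then channel
#' 2, ...). Intensities are stored as 64-bit IEEE floats, so round-trips
#' are bit-exact; metadata (axes,
#' shape, channel names, voxel size, provenance) is serialized as JSON in
#' the first page's ImageDescription, so [read_stack()] round-trips the
#' stack bit-exactly.
#'
#' @param stack an [image_stack()].
#' @param path output file path (created/overwritten).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)  # (c, z, y, x)
  desc <- jsonlite::toJSON(list(
    axes = "CZYX", shape = d, channels = stack$channel_names,
    voxel_size_um = stack$voxel_size_um, provenance = stack$provenance),
    auto_unbox = TRUE, digits = NA)
  write_tiff_pages(
    path,
    pages = lapply(seq_len(d[1] * d[2]), function(p) {
      ch <- ((p - 1L) %/% d[2]) + 1L
      z <- ((p - 1L) %% d[2]) + 1L
      plane <- stack$voxels[ch, z, , ]
      dim(plane) <- d[3:4]
      plane
    }),
    bits = 64L, description = as.character(desc))
  invisible(path)
}

#' Write a binary mask to an 8-bit TIFF (0/255)
#'
#' A plain-text sidecar `<path>.method.json` records the segmentation
#' method, resolved threshold and minimum object size for audit.
#'
#' @param mask a [binary_mask()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$mask)
  desc <- jsonlite::toJSON(list(
    axes = "ZYX", shape = d, channels = mask$channel_name,
    mask = TRUE), auto_unbox = TRUE)
  write_tiff_pages(
    path,
    pages = lapply(seq_len(d[1]), function(z) {
      plane <- ifelse(mask$mask[z, , ], 255, 0)
      dim(plane) <- d[2:3]
      plane
    }),
    bits = 8L, description = as.character(desc))
  jsonlite::write_json(mask$method_record, paste0(path, ".method.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# pages: list of (y, x) matrices; bits: 8 (unsigned) or 64 (float)
write_tiff_pages <- function(path, pages, bits, description) {
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  npages <- length(pages)
  bytes_px <- bits %/% 8L
  page_bytes <- h * w * bytes_px

  desc_raw <- c(charToRaw(description), as.raw(0L))
  if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0L))
  desc_off <- 8L
  data_off0 <- desc_off + length(desc_raw)
  ifd0_off <- data_off0 + npages * page_bytes

  ntags <- function(p) if (p == 1L) 11L else 10L
  ifd_size <- function(p) 2L + ntags(p) * 12L + 4L
  ifd_offs <- integer(npages)
  off <- ifd0_off
  for (p in seq_len(npages)) { ifd_offs[p] <- off; off <- off + ifd_size(p) }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd0_off, con, size = 4, endian = "little")
  writeBin(desc_raw, con)
  for (p in seq_len(npages)) {
    vals <- as.vector(t(pages[[p]]))  # row-major: x fastest
    if (bits == 64L)
      writeBin(as.numeric(vals), con, size = 8, endian = "little")
    else
      writeBin(as.raw(pmin(pmax(round(vals), 0), 255)), con)
  }
  for (p in seq_len(npages)) {
    tags <- list(
      tiff_tag(256L, 4L, 1L, tiff_val_long(w)),
      tiff_tag(257L, 4L, 1L, tiff_val_long(h)),
      tiff_tag(258L, 3L, 1L, tiff_val_short(bits)),
      tiff_tag(259L, 3L, 1L, tiff_val_short(1L)),   # no compression
      tiff_tag(262L, 3L, 1L, tiff_val_short(1L)))   # BlackIsZero
    if (p == 1L)
      tags <- c(tags, list(
        tiff_tag(270L, 2L, length(desc_raw), tiff_val_long(desc_off))))
    tags <- c(tags, list(
      tiff_tag(273L, 4L, 1L, tiff_val_long(data_off0 + (p - 1L) * page_bytes)),
      tiff_tag(277L, 3L, 1L, tiff_val_short(1L)),
      tiff_tag(278L, 4L, 1L, tiff_val_long(h)),
      tiff_tag(279L, 4L, 1L, tiff_val_long(page_bytes)),
      tiff_tag(339L, 3L, 1L, tiff_val_short(if (bits == 64L) 3L else 1L))))
    writeBin(as.integer(length(tags)), con, size = 2, endian = "little")
    for (tg in tags) writeBin(tg, con)
    writeBin(if (p < npages) ifd_offs[p + 1L] else 0L, con,
             size = 4, endian = "little")
  }
  invisible(path)
}

rd_int <- function(raw, off, size) {
  # unsigned reads are only allowed for 1-2 byte ints; 4-byte offsets fit
  # in R's signed integers for any file we write
  readBin(raw[(off + 1L):(off + size)], "integer", size = size,
          endian = "little", signed = size >= 4L)
}

#' Read a multi-page TIFF into an image stack
#'
#' Reads the uncompressed little-endian TIFF subset written by
#' [write_stack()] (and equivalent files from other tools meeting that
#' subset). Channel names and voxel size come from the embedded JSON
#' metadata when present, otherwise they must be supplied; a file without
#' voxel-size metadata and without the `voxel_size_um` argument is an error,
#' since downstream geometry (plaque calls) needs physical units.
#'
#' @param path TIFF file path.
#' @param channel_names optional channel labels overriding/absent metadata.
#' @param voxel_size_um optional `(z, y, x)` voxel size in micrometres.
#' @param n_channels channel count used to fold pages when metadata is
#'   absent (default 1).
#' @param study if `TRUE`, validate that the four study channels are present
#'   and error otherwise.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, channel_names = NULL, voxel_size_um = NULL,
                       n_channels = NULL, study = FALSE) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L || rawToChar(raw[1:2]) != "II" || rd_int(raw, 2L, 2L) != 42L)
    stop("not a little-endian TIFF file: ", path, call. = FALSE)

  ifd_off <- rd_int(raw, 4L, 4L)
  pages <- list(); desc <- NULL
  while (ifd_off != 0L) {
    n <- rd_int(raw, ifd_off, 2L)
    ent <- list()
    for (i in seq_len(n)) {
      base <- ifd_off + 2L + (i - 1L) * 12L
      code <- rd_int(raw, base, 2L)
      type <- rd_int(raw, base + 2L, 2L)
      count <- rd_int(raw, base + 4L, 4L)
      tsize <- TIFF_TYPE_SIZES[[as.character(type)]] %||% 1L
      nbytes <- tsize * count
      voff <- if (nbytes <= 4L) base + 8L else rd_int(raw, base + 8L, 4L)
      ent[[as.character(code)]] <- list(type = type, count = count, off = voff)
    }
    gv <- function(code, default = NULL) {
      e <- ent[[as.character(code)]]
      if (is.null(e)) return(default)
      ts <- TIFF_TYPE_SIZES[[as.character(e$type)]]
      vapply(seq_len(e$count) - 1L, function(k)
        rd_int(raw, e$off + k * ts, ts), integer(1))
    }
    if (!is.null(ent[["259"]]) && gv(259L) != 1L)
      stop("compressed TIFF not supported by this reader", call. = FALSE)
    w <- gv(256L); h <- gv(257L)
    bits <- gv(258L, 8L); sf <- gv(339L, 1L)
    e270 <- ent[["270"]]
    if (is.null(desc) && !is.null(e270)) {
      db <- raw[(e270$off + 1L):(e270$off + e270$count)]
      db <- db[db != as.raw(0L)]
      desc <- rawToChar(db)
    }
    soff <- gv(273L); scnt <- gv(279L, h * w * bits %/% 8L)
    strip <- unlist(lapply(seq_along(soff), function(k)
      raw[(soff[k] + 1L):(soff[k] + scnt[k])]))
    vals <- if (bits %in% c(32L, 64L) && sf == 3L)
      readBin(strip, "numeric", n = w * h, size = bits %/% 8L,
              endian = "little")
    else if (bits == 8L)
      as.numeric(readBin(strip, "integer", n = w * h, size = 1, signed = FALSE))
    else if (bits == 16L)
      as.numeric(readBin(strip, "integer", n = w * h, size = 2,
                         endian = "little", signed = FALSE))
    else stop(sprintf("unsupported TIFF sample layout (%d bits, format %d)",
                      bits, sf), call. = FALSE)
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    ifd_off <- rd_int(raw, ifd_off + 2L + n * 12L, 4L)
  }

  meta <- if (!is.null(desc) && grepl("^\\s*\\{", desc))
    tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL) else NULL
  channel_names <- channel_names %||% meta$channels
  voxel_size_um <- voxel_size_um %||% meta$voxel_size_um
  if (is.null(voxel_size_um))
    stop(paste0("no voxel size in TIFF metadata of '", path,
                "'; supply voxel_size_um = c(z, y, x) explicitly"),
         call. = FALSE)
  nc <- if (!is.null(meta$shape)) meta$shape[1]
  else if (!is.null(n_channels)) n_channels
  else if (length(channel_names)) length(channel_names)
  else 1L
  nz <- length(pages) %/% nc
  if (nz * nc != length(pages))
    stop(sprintf("page count %d not divisible by channel count %d",
                 length(pages), nc), call. = FALSE)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(0, dim = c(nc, nz, h, w))
  for (p in seq_along(pages)) {
    ch <- ((p - 1L) %/% nz) + 1L
    z <- ((p - 1L) %% nz) + 1L
    arr[ch, z, , ] <- pages[[p]]
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  st <- image_stack(arr, channel_names, voxel_size_um,
                    provenance = meta$provenance %||% path)
  if (study) validate_study_stack(st)
  st
}
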