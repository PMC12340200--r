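# Voxel-level burden and colocalization. All quantities are percentages of
# total stack voxels (binary co-occupancy, not intensity correlation),
# except the engulfment fractions, which use conditional denominators.

as_mask_array <- function(m) {
  if (inherits(m, "binary_mask")) m$mask else m
}

check_same_shape <- function(...) {
  shapes <- lapply(list(...), function(m) dim(as_mask_array(m)))
  if (length(unique(vapply(shapes, paste, character(1), collapse = "x"))) != 1L)
    stop("mask shape mismatch: ", paste(vapply(shapes, paste, character(1),
                                               collapse = "x"), collapse = " vs "),
         call. = FALSE)
}

#' Percent-volume burden of a mask
#'
#' `100 * positive voxels / total voxels`.
#'
#' @param mask a `binary_mask` or logical 3D array.
#' @return percentage in `[0, 100]`.
#' @export
burden <- function(mask) {
  m <- as_mask_array(mask)
  if (!length(m)) stop("empty mask array", call. = FALSE)
  100 * sum(m) / length(m)
}

#' Pairwise voxel colocalization
#'
#' `100 * |A AND B| / total voxels`; symmetric in its arguments.
#'
#' @param maskA,maskB `binary_mask`es or logical arrays of identical shape.
#' @return percentage in `[0, 100]`.
#' @export
pairwise_coloc <- function(maskA, maskB) {
  check_same_shape(maskA, maskB)
  a <- as_mask_array(maskA); b <- as_mask_array(maskB)
  100 * sum(a & b) / length(a)
}

#' Triple voxel colocalization
#'
#' `100 * |A AND B AND C| / total voxels`; invariant to argument order.
#'
#' @param maskA,maskB,maskC `binary_mask`es or logical arrays of identical
#'   shape.
#' @return percentage in `[0, 100]`.
#' @export
triple_coloc <- function(maskA, maskB, maskC) {
  check_same_shape(maskA, maskB, maskC)
  a <- as_mask_array(maskA); b <- as_mask_array(maskB); c <- as_mask_array(maskC)
  100 * sum(a & b & c) / length(a)
}

#' Conditional engulfment enrichment
#'
#' Of the synaptic voxels that do / do not colocalize with amyloid-beta,
#' what fraction lies inside the glial volume, and their ratio:
#' `frac_ab_pos = |syn & ab & glia| / |syn & ab|`,
#' `frac_ab_neg = |syn & !ab & glia| / |syn & !ab|`,
#' `enrichment_ratio = frac_ab_pos / frac_ab_neg`. A ratio above 1 means
#' amyloid-containing synapses are preferentially inside glia. Zero
#' denominators yield `NA` components (flagged in `defined`), never
#' fabricated numbers.
#'
#' @param syn_mask,ab_mask,glia_mask masks of identical shape.
#' @return list `frac_ab_pos_syn_in_glia`, `frac_ab_neg_syn_in_glia`,
#'   `enrichment_ratio`, `defined` (logical), `n_syn_ab_pos`,
#'   `n_syn_ab_neg` voxel counts.
#' @export
engulfment_enrichment <- function(syn_mask, ab_mask, glia_mask) {
  check_same_shape(syn_mask, ab_mask, glia_mask)
  syn <- as_mask_array(syn_mask); ab <- as_mask_array(ab_mask)
  gl <- as_mask_array(glia_mask)
  n_pos <- sum(syn & ab)
  n_neg <- sum(syn & !ab)
  f_pos <- if (n_pos > 0) sum(syn & ab & gl) / n_pos else NA_real_
  f_neg <- if (n_neg > 0) sum(syn & !ab & gl) / n_neg else NA_real_
  ratio <- if (!is.na(f_pos) && !is.na(f_neg) && f_neg > 0)
    f_pos / f_neg else NA_real_
  list(frac_ab_pos_syn_in_glia = f_pos,
       frac_ab_neg_syn_in_glia = f_neg,
       enrichment_ratio = ratio,
       defined = !is.na(ratio),
       n_syn_ab_pos = n_pos, n_syn_ab_neg = n_neg)
}

measurement_colnames <- function() {
  c("case_id", "roi_pair_id", "stack_id", "plaque_status",
    paste0("burden_", STUDY_CHANNELS),
    paste0("pair_", gsub("&", "_", all_pair_keys())),
    paste0("triple_", gsub("&", "_", all_triple_keys())),
    unlist(lapply(GLIAL_CHANNELS, function(g)
      paste0("eng_", g, "_", c("frac_ab_pos", "frac_ab_neg", "ratio")))))
}

#' Measure one study stack
#'
#' Segments the four study channels and computes every quantity of the
#' analysis: per-channel burden, all pairwise and triple colocalization
#' percentages, and the conditional engulfment enrichment for each glial
#' channel. Deterministic given the config.
#'
#' @param stack a study [image_stack()] (or a `ground_truth` object, whose
#'   exact binary geometry is then measured directly, bypassing
#'   segmentation).
#' @param config a [segmentation_config()].
#' @param case_id,roi_pair_id,stack_id,plaque_status nesting keys copied
#'   into the output row.
#' @return one-row data.frame (class `roi_measurement`) with columns
#'   `burden_<ch>`, `pair_<a>_<b>`, `triple_<a>_<b>_<c>`,
#'   `eng_<glia>_{frac_ab_pos,frac_ab_neg,ratio}` plus the keys.
#' @export
measure_stack <- function(stack, config = segmentation_config(),
                          case_id = NA_character_, roi_pair_id = NA_character_,
                          stack_id = NA_character_,
                          plaque_status = NA_character_) {
  masks <- if (inherits(stack, "ground_truth")) {
    stack$masks
  } else {
    validate_study_stack(stack)
    stats::setNames(lapply(STUDY_CHANNELS, function(ch)
      segment_channel(stack, ch, config)$mask), STUDY_CHANNELS)
  }
  row <- list(case_id = case_id, roi_pair_id = roi_pair_id,
              stack_id = stack_id, plaque_status = plaque_status)
  for (ch in STUDY_CHANNELS)
    row[[paste0("burden_", ch)]] <- burden(masks[[ch]])
  for (p in as.data.frame(utils::combn(STUDY_CHANNELS, 2),
                          stringsAsFactors = FALSE))
    row[[paste0("pair_", p[1], "_", p[2])]] <-
      pairwise_coloc(masks[[p[1]]], masks[[p[2]]])
  for (p in as.data.frame(utils::combn(STUDY_CHANNELS, 3),
                          stringsAsFactors = FALSE))
    row[[paste0("triple_", p[1], "_", p[2], "_", p[3])]] <-
      triple_coloc(masks[[p[1]]], masks[[p[2]]], masks[[p[3]]])
  for (g in GLIAL_CHANNELS) {
    e <- engulfment_enrichment(masks$Synapsin1, masks$Abeta4G8, masks[[g]])
    row[[paste0("eng_", g, "_frac_ab_pos")]] <- e$frac_ab_pos_syn_in_glia
    row[[paste0("eng_", g, "_frac_ab_neg")]] <- e$frac_ab_neg_syn_in_glia
    row[[paste0("eng_", g, "_ratio")]] <- e$enrichment_ratio
  }
  out <- as.data.frame(row, stringsAsFactors = FALSE)
  class(out) <- c("roi_measurement", "data.frame")
  out
}

#' Write a measurement table as tidy tab-separated text
#'
#' @param measurements data.frame of [measure_stack()] rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  utils::write.table(measurements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a measurement table written by [write_measurements()]
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
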