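# Sampling logic of the study: plaque detection in segmented amyloid
# masks, paired plaque/adjacent ROI plans, random field selection for
# plaque-free cases, top-k stack selection by amyloid burden, and cohort
# demographics with the study's matching tests.

#' Detect amyloid plaques in a segmented amyloid mask
#'
#' Connected amyloid components whose equivalent spherical diameter
#' (diameter of the sphere with the same voxel volume) reaches
#' `min_diameter_um` are called plaques; the stack is plaque-positive iff
#' at least one exists. The default 10 um separates diffuse deposits from
#' punctate synaptic amyloid; the source protocol states no size
#' criterion, so this is a documented convention.
#'
#' @param ab_mask a `binary_mask` of the amyloid channel (voxel size
#'   required) or a logical array plus `voxel_size_um`.
#' @param voxel_size_um `(z, y, x)` micrometres; taken from the mask when
#'   absent.
#' @param min_diameter_um minimum equivalent spherical diameter.
#' @param connectivity component connectivity (6 or 26).
#' @return list `plaque_positive` (logical), `regions` (data.frame:
#'   `label`, `n_voxels`, `volume_um3`, `equiv_diameter_um`, centroid
#'   coordinates in um), `labels` (integer array of plaque components
#'   only).
#' @export
detect_plaque <- function(ab_mask, voxel_size_um = NULL, min_diameter_um = 10,
                          connectivity = 6L) {
  m <- as_mask_array(ab_mask)
  if (inherits(ab_mask, "binary_mask"))
    voxel_size_um <- voxel_size_um %||% ab_mask$voxel_size_um
  if (is.null(voxel_size_um))
    stop("voxel_size_um required to convert voxel counts to physical size",
         call. = FALSE)
  vvol <- prod(voxel_size_um)
  lab <- label_components(m, connectivity)
  n_comp <- max(lab)
  if (n_comp == 0L)
    return(list(plaque_positive = FALSE,
                regions = empty_regions(), labels = lab))
  sizes <- tabulate(lab[lab > 0L], n_comp)
  vol <- sizes * vvol
  eqd <- 2 * (3 * vol / (4 * pi))^(1 / 3)
  keep <- which(eqd >= min_diameter_um)
  if (!length(keep))
    return(list(plaque_positive = FALSE,
                regions = empty_regions(), labels = array(0L, dim(m))))
  d <- dim(m)
  pos <- which(lab %in% keep)
  lv <- lab[pos]
  iz <- (pos - 1L) %% d[1] + 1L
  iy <- ((pos - 1L) %/% d[1]) %% d[2] + 1L
  ix <- (pos - 1L) %/% (d[1] * d[2]) + 1L
  cen <- function(i, a) tapply((i - 0.5) * voxel_size_um[a], lv, mean)
  regions <- data.frame(
    label = sort(keep), n_voxels = sizes[sort(keep)],
    volume_um3 = vol[sort(keep)], equiv_diameter_um = eqd[sort(keep)],
    centroid_z_um = as.numeric(cen(iz, 1)),
    centroid_y_um = as.numeric(cen(iy, 2)),
    centroid_x_um = as.numeric(cen(ix, 3)))
  out_lab <- array(0L, dim = d)
  out_lab[pos] <- lv
  list(plaque_positive = TRUE, regions = regions, labels = out_lab)
}

empty_regions <- function() {
  data.frame(label = integer(0), n_voxels = integer(0),
             volume_um3 = numeric(0), equiv_diameter_um = numeric(0),
             centroid_z_um = numeric(0), centroid_y_um = numeric(0),
             centroid_x_um = numeric(0))
}

#' Build the ROI sampling plan for a cohort
#'
#' Plaque-positive cases keep their (plaque, adjacent no-plaque) pairs,
#' coupled by `roi_pair_id`; plaque-free cases contribute `n_random`
#' randomly chosen stacks (all of them, with a recorded shortfall, if
#' fewer are available). Deterministic given `seed`.
#'
#' @param manifest data.frame with at least `case_id`, `stack_id`,
#'   `roi_pair_id` (may be `NA` for unpaired stacks).
#' @param plaque_calls named logical vector: plaque call per `stack_id`.
#' @param n_random stacks to sample per plaque-free case (default 10).
#' @param seed RNG seed for the random selection.
#' @return data.frame (class `roi_plan`): `case_id`, `stack_id`,
#'   `roi_pair_id`, `plaque_status` (`plaque`/`no_plaque`/`random`),
#'   `selection_rule` (`paired`/`random`), `shortfall`.
#' @export
build_roi_plan <- function(manifest, plaque_calls, n_random = 10L, seed = 1L) {
  need <- c("case_id", "stack_id")
  if (!all(need %in% names(manifest)))
    stop("manifest must contain columns case_id, stack_id", call. = FALSE)
  if (nrow(manifest) == 0L)
    stop("manifest has zero rows: every case needs at least one stack",
         call. = FALSE)
  if (!all(manifest$stack_id %in% names(plaque_calls)))
    stop("every stack needs a plaque call; missing: ",
         paste(utils::head(setdiff(manifest$stack_id, names(plaque_calls))),
               collapse = ", "), call. = FALSE)
  plans <- list()
  for (cid in unique(manifest$case_id)) {
    sub <- manifest[manifest$case_id == cid, , drop = FALSE]
    if (nrow(sub) == 0L) stop("case with zero stacks: ", cid, call. = FALSE)
    calls <- plaque_calls[sub$stack_id]
    if (any(calls)) {
      # paired design: every plaque stack is coupled to the no-plaque
      # partner sharing its roi_pair_id
      rp <- sub$roi_pair_id %||% rep(NA_character_, nrow(sub))
      status <- ifelse(calls, "plaque", "no_plaque")
      plans[[cid]] <- data.frame(
        case_id = cid, stack_id = sub$stack_id, roi_pair_id = rp,
        plaque_status = status, selection_rule = "paired",
        shortfall = 0L, stringsAsFactors = FALSE)
    } else {
      k <- min(n_random, nrow(sub))
      sel <- with_seed(seed + match(cid, unique(manifest$case_id)),
                       sort(sample.int(nrow(sub), k)))
      plans[[cid]] <- data.frame(
        case_id = cid, stack_id = sub$stack_id[sel],
        roi_pair_id = sub$stack_id[sel],
        plaque_status = "random", selection_rule = "random",
        shortfall = as.integer(n_random - k), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, plans)
  rownames(out) <- NULL
  class(out) <- c("roi_plan", "data.frame")
  out
}

#' Select each case's top-k stacks by amyloid burden
#'
#' Per case, keeps the `k` measurement rows with the highest
#' `burden_Abeta4G8`; ties are broken by lexicographic `stack_id` (lowest
#' first); cases with fewer than `k` rows keep all of them.
#'
#' @param measurements measurement data.frame with `case_id`, `stack_id`,
#'   `burden_Abeta4G8`.
#' @param k rows to retain per case (>= 1).
#' @return the selected subset, original column set preserved.
#' @export
select_top_k_by_ab <- function(measurements, k = 10L) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  need <- c("case_id", "stack_id", "burden_Abeta4G8")
  if (!all(need %in% names(measurements)))
    stop("measurements must contain ", paste(need, collapse = ", "),
         call. = FALSE)
  keep <- unlist(lapply(split(seq_len(nrow(measurements)),
                              measurements$case_id), function(idx) {
    o <- order(-measurements$burden_Abeta4G8[idx],
               measurements$stack_id[idx])
    idx[o[seq_len(min(k, length(idx)))]]
  }))
  out <- measurements[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohort demographics with matching tests
#'
#' Group sizes, sex counts and percentages, per-group mean ages, a
#' Wilcoxon rank-sum test of age between the CDS and Aged groups
#' (mid-ranks for ties, normal approximation when ties are present) and a
#' Fisher exact test of the sex-by-group table excluding unknown-sex
#' cases.
#'
#' @param records a `case_table` data.frame ([parse_case_table()]).
#' @return list of class `demographics`: `group_counts`, `sex_counts`,
#'   `sex_pct`, `age_means`, `age_test` (htest or NULL with `notes`),
#'   `sex_test`, `notes`.
#' @export
demographics <- function(records) {
  if (nrow(records) < 1L) stop("need at least one case record", call. = FALSE)
  notes <- character(0)
  group_counts <- table(factor(records$group, levels = GROUP_LEVELS))
  sex_counts <- table(factor(records$sex, levels = SEX_LEVELS))
  sex_pct <- 100 * as.numeric(sex_counts) / nrow(records)
  names(sex_pct) <- names(sex_counts)
  age_means <- tapply(records$age_years,
                      factor(records$group, levels = GROUP_LEVELS), mean)

  age_test <- NULL
  if (group_counts[["CDS"]] > 0 && group_counts[["Aged"]] > 0) {
    a <- records$age_years[records$group == "Aged"]
    b <- records$age_years[records$group == "CDS"]
    age_test <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                    correct = TRUE))
  } else notes <- c(notes, "age-match test skipped: CDS or Aged group absent")

  sex_test <- NULL
  known <- records[records$sex != "Unknown", , drop = FALSE]
  tab <- table(droplevels(factor(known$group, levels = GROUP_LEVELS)),
               droplevels(factor(known$sex, levels = c("F", "M"))))
  if (nrow(tab) >= 2 && ncol(tab) >= 2) {
    sex_test <- stats::fisher.test(tab)
  } else notes <- c(notes, "sex-match test skipped: insufficient groups or sexes")

  structure(list(group_counts = group_counts, sex_counts = sex_counts,
                 sex_pct = sex_pct, age_means = age_means,
                 age_test = age_test, sex_test = sex_test, notes = notes),
            class = "demographics")
}

#' @export
print.demographics <- function(x, ...) {
  cat("<demographics>\n  groups: ",
      paste(sprintf("%s=%d", names(x$group_counts), x$group_counts),
            collapse = ", "), "\n", sep = "")
  cat("  sex:    ",
      paste(sprintf("%s=%d (%.0f%%)", names(x$sex_counts), x$sex_counts,
                    x$sex_pct), collapse = ", "), "\n", sep = "")
  cat("  mean ages: ",
      paste(sprintf("%s=%.2f", names(x$age_means), x$age_means),
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$age_test))
    cat(sprintf("  CDS vs Aged age: Wilcoxon W = %.1f, p = %.3f\n",
                x$age_test$statistic, x$age_test$p.value))
  if (!is.null(x$sex_test))
    cat(sprintf("  sex x group: Fisher exact p = %.3f (Unknown excluded)\n",
                x$sex_test$p.value))
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}
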