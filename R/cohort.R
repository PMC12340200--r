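# Nested synthetic cohorts: stacks within paired ROIs within cases within
# groups, mirroring the study design (plaque-bearing cases imaged as
# plaque/adjacent pairs, plaque-free cases as random fields).

#' Cohort specification for the synthetic generator
#'
#' Defaults mirror the study cohort: 7 young, 10 aged and 8
#' CDS-affected cases, 10 stacks per case, with per-group plaque prevalence
#' taken from the packaged case table's extracellular amyloid scores
#' (3/7 young, 7/10 aged, 4/8 CDS). Group effect multipliers scale the base
#' scene's synaptic-amyloid fraction, glial density and engulfment fraction,
#' and set the amyloid bias of engulfment; the defaults encode the study's
#' qualitative findings (elevated synaptic amyloid and engulfment in aged
#' and CDS animals, amyloid-biased microglial engulfment) at magnitudes
#' chosen once as realistic, documented in the methods vignette.
#'
#' @param n_young,n_aged,n_cds cases per group (each >= 1).
#' @param stacks_per_case stacks per case; even, since plaque-bearing cases
#'   are imaged in (plaque, adjacent) pairs.
#' @param plaque_prevalence named probabilities a case of each group bears
#'   plaques.
#' @param group_effects named list per group with multipliers
#'   `ab_in_synapse`, `glial_density`, `engulfment` (>= 0) and the group's
#'   `engulfment_ab_bias`.
#' @param base_params a [scene_params()] used for every stack before group
#'   multipliers.
#' @param seed master seed; per-stack child seeds are spawned from it by a
#'   single deterministic `sample.int()` draw (see [generate_cohort()]).
#' @return a validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_young = 7L, n_aged = 10L, n_cds = 8L,
                        stacks_per_case = 10L,
                        plaque_prevalence = c(Young = 3 / 7, Aged = 7 / 10,
                                              CDS = 4 / 8),
                        group_effects = list(
                          Young = c(ab_in_synapse = 1, glial_density = 1,
                                    engulfment = 1, engulfment_ab_bias = 1),
                          Aged = c(ab_in_synapse = 2, glial_density = 1.3,
                                   engulfment = 1.5, engulfment_ab_bias = 2.5),
                          CDS = c(ab_in_synapse = 2.5, glial_density = 1.5,
                                  engulfment = 2, engulfment_ab_bias = 2.5)),
                        base_params = scene_params(),
                        seed = 1L) {
  for (f in c("n_young", "n_aged", "n_cds")) {
    v <- get(f)
    if (!is.numeric(v) || v < 1) abort_field(f, "must be >= 1")
  }
  if (stacks_per_case < 1 || stacks_per_case %% 2 != 0)
    abort_field("stacks_per_case", "must be a positive even count (paired design)")
  if (!all(GROUP_LEVELS %in% names(plaque_prevalence)))
    abort_field("plaque_prevalence", "must be named for Young, Aged, CDS")
  for (g in GROUP_LEVELS) {
    check_fraction(plaque_prevalence[[g]], paste0("plaque_prevalence[", g, "]"))
    ge <- group_effects[[g]]
    need <- c("ab_in_synapse", "glial_density", "engulfment", "engulfment_ab_bias")
    if (is.null(ge) || !all(need %in% names(ge)) || any(ge[need] < 0))
      abort_field(paste0("group_effects[", g, "]"),
                  sprintf("must contain non-negative %s", paste(need, collapse = ", ")))
  }
  stopifnot(inherits(base_params, "scene_params"))
  structure(list(n_young = as.integer(n_young), n_aged = as.integer(n_aged),
                 n_cds = as.integer(n_cds),
                 stacks_per_case = as.integer(stacks_per_case),
                 plaque_prevalence = plaque_prevalence,
                 group_effects = group_effects, base_params = base_params,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

apply_group_effects <- function(base, ge) {
  p <- unclass(base)
  p$ab_in_synapse_fraction <- min(1, p$ab_in_synapse_fraction * ge[["ab_in_synapse"]])
  p$engulfment_fraction <- min(1, p$engulfment_fraction * ge[["engulfment"]])
  p$engulfment_ab_bias <- ge[["engulfment_ab_bias"]]
  gm <- ge[["glial_density"]]
  for (gch in GLIAL_CHANNELS) {
    gp <- p$glia[[gch]]
    gp$soma_count <- as.integer(round(gp$soma_count * gm))
    p$glia[[gch]] <- gp
  }
  class(p) <- "scene_params"
  p
}

#' Generate a nested synthetic cohort
#'
#' Deterministic under the spec's master seed: one `sample.int()` stream
#' seeded by it yields case-level draws (age, sex, plaque status) and one
#' child seed per stack. Plaque-bearing cases receive
#' `stacks_per_case / 2` (plaque, adjacent no-plaque) pairs sharing a
#' `roi_pair_id`; plaque-free cases receive `stacks_per_case` random
#' fields.
#'
#' @param spec a [cohort_spec()].
#' @param stack_handler optional `function(stack, truth, manifest_row)`
#'   called for each generated stack. When supplied, stacks are not
#'   retained in memory (use this to write a large cohort to disk or
#'   measure on the fly); when `NULL`, all stacks are returned.
#' @return list with `cases` (data.frame of case records: `case_id`,
#'   `group`, `age_years`, `sex`, `ab_score`, `tau_score`,
#'   `plaque_bearing`), `manifest` (one row per stack: `case_id`, `group`,
#'   `stack_id`, `roi_pair_id`, `plaque_status`, `seed`) and, without a
#'   handler, `stacks`: a list of `list(stack, truth)` aligned with the
#'   manifest rows.
#' @export
generate_cohort <- function(spec, stack_handler = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(GROUP_LEVELS, c(spec$n_young, spec$n_aged, spec$n_cds))
  n_cases <- length(groups)
  n_stacks <- n_cases * spec$stacks_per_case
  seeds <- spawn_seeds(spec$seed, n_stacks + 3L * n_cases)
  stack_seeds <- seeds[seq_len(n_stacks)]
  case_seeds <- seeds[n_stacks + seq_len(3L * n_cases)]

  age_range <- list(Young = c(2, 7), Aged = c(14, 25), CDS = c(10, 19))
  cases <- data.frame(
    case_id = sprintf("SC%03d", seq_len(n_cases)),
    group = factor(groups, levels = GROUP_LEVELS),
    age_years = NA_real_, sex = NA_character_, plaque_bearing = NA,
    stringsAsFactors = FALSE)
  for (i in seq_len(n_cases)) {
    rng <- age_range[[groups[i]]]
    cases$age_years[i] <- with_seed(case_seeds[3 * i - 2],
                                    round(stats::runif(1, rng[1], rng[2]), 1))
    cases$sex[i] <- with_seed(case_seeds[3 * i - 1],
                              sample(c("F", "M"), 1, prob = c(2, 1)))
    cases$plaque_bearing[i] <- with_seed(case_seeds[3 * i],
      stats::runif(1) < spec$plaque_prevalence[[groups[i]]])
  }
  cases$sex <- factor(cases$sex, levels = SEX_LEVELS)
  cases$ab_score <- factor(ifelse(cases$plaque_bearing, "mild", "none"),
                           levels = SCORE_LEVELS, ordered = TRUE)
  cases$tau_score <- factor("none", levels = SCORE_LEVELS, ordered = TRUE)

  manifest <- vector("list", n_stacks)
  stacks <- if (is.null(stack_handler)) vector("list", n_stacks) else NULL
  row <- 0L
  for (i in seq_len(n_cases)) {
    ge <- spec$group_effects[[groups[i]]]
    par_case <- apply_group_effects(spec$base_params, ge)
    for (s in seq_len(spec$stacks_per_case)) {
      row <- row + 1L
      if (cases$plaque_bearing[i]) {
        pair <- (s + 1L) %/% 2L
        status <- if (s %% 2L == 1L) "plaque" else "no_plaque"
        roi <- sprintf("%s_P%02d", cases$case_id[i], pair)
      } else {
        status <- "random"
        roi <- sprintf("%s_R%02d", cases$case_id[i], s)
      }
      p <- unclass(par_case)
      p$plaque_present <- status == "plaque"
      p$plaque_center_um <- if (p$plaque_present)
        p$shape_vox * p$voxel_size_um / 2 else NULL
      class(p) <- "scene_params"
      mrow <- data.frame(case_id = cases$case_id[i], group = groups[i],
                         stack_id = sprintf("%s_S%02d", cases$case_id[i], s),
                         roi_pair_id = roi, plaque_status = status,
                         seed = stack_seeds[row], stringsAsFactors = FALSE)
      manifest[[row]] <- mrow
      sc <- generate_scene(p, stack_seeds[row])
      if (is.null(stack_handler)) stacks[[row]] <- sc
      else stack_handler(sc$stack, sc$truth, mrow)
    }
  }
  manifest <- do.call(rbind, manifest)
  out <- list(cases = cases, manifest = manifest)
  if (is.null(stack_handler)) out$stacks <- stacks
  out
}

#' Simulate a measurement-level cohort for inference calibration
#'
#' Draws an outcome table directly at the measurement level (no imaging):
#' `y = grand_mean + group_effect + plaque_effect (+ interaction) +
#' case intercept + ROI intercept + residual`, with the study's nesting
#' (stacks in ROI pairs in cases in groups). This is the stated world for
#' the type-I-error, power and transformation-selection checks of the
#' inference layer, where simulating full image stacks for hundreds of
#' cohorts would be wasteful; the image pipeline itself is validated by the
#' ground-truth and engulfment criteria.
#'
#' @param n_cases_per_group named or unnamed integer(3) cases for Young,
#'   Aged, CDS.
#' @param n_pairs ROI pairs per case; each contributes one plaque and one
#'   no-plaque stack.
#' @param grand_mean intercept of the outcome.
#' @param group_effects numeric(3) additive effects per group (default all
#'   zero = null).
#' @param plaque_effect additive effect of plaque status, in outcome units
#'   (applied to plaque stacks; default 0).
#' @param case_sd,roi_sd,resid_sd standard deviations of the case random
#'   intercept, ROI-within-case intercept and residual.
#' @param link `"identity"` or `"exp"`; `"exp"` exponentiates the linear
#'   predictor, giving a log-normal outcome.
#' @param seed RNG seed.
#' @return data.frame with `case_id`, `group`, `roi_pair_id`, `stack_id`,
#'   `plaque_status`, `y`.
#' @export
simulate_lmem_cohort <- function(n_cases_per_group = c(8L, 8L, 8L),
                                 n_pairs = 3L, grand_mean = 10,
                                 group_effects = c(0, 0, 0),
                                 plaque_effect = 0,
                                 case_sd = 1, roi_sd = 0.5, resid_sd = 1,
                                 link = c("identity", "exp"), seed = 1L) {
  link <- match.arg(link)
  with_seed(seed, {
    groups <- rep(GROUP_LEVELS, n_cases_per_group)
    eff <- stats::setNames(group_effects, GROUP_LEVELS)
    rows <- list()
    for (i in seq_along(groups)) {
      cid <- sprintf("C%03d", i)
      b_case <- stats::rnorm(1, sd = case_sd)
      for (r in seq_len(n_pairs)) {
        b_roi <- stats::rnorm(1, sd = roi_sd)
        for (st in c("plaque", "no_plaque")) {
          mu <- grand_mean + eff[[groups[i]]] +
            (st == "plaque") * plaque_effect + b_case + b_roi
          rows[[length(rows) + 1L]] <- data.frame(
            case_id = cid, group = groups[i],
            roi_pair_id = sprintf("%s_P%02d", cid, r),
            stack_id = sprintf("%s_P%02d_%s", cid, r, st),
            plaque_status = st,
            y = mu + stats::rnorm(1, sd = resid_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    out$group <- factor(out$group, levels = GROUP_LEVELS)
    out$plaque_status <- factor(out$plaque_status,
                                levels = c("no_plaque", "plaque"))
    if (link == "exp") out$y <- exp(out$y / 5)
    out
  })
}
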