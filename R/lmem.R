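# Linear mixed-effects inference: REML fits with case (or ROI-in-case)
# random intercepts, AIC/BIC from an ML refit for model comparison,
# residual diagnostics standing in for the visual QQ/residual checks,
# estimated-marginal-mean contrasts with Tukey studentized-range
# adjustment, and case-level Spearman correlations.
#
# Denominator degrees of freedom use the containment (between-within)
# rule, with the method recorded in every contrast: the Kenward-Roger
# implementation is not available in this dependency set. For the
# balanced between-case contrasts of this design, containment reproduces
# n_cases - n_groups (e.g. 22 for 25 cases in 3 groups), which Kenward-
# Roger also gives on balanced data.

#' Model specification for the mixed-effects layer
#'
#' The two study formulas ready-made: `fixed = "group"` is
#' `y ~ Group + (1|Case)`; `fixed = "plaque_by_group"` is
#' `y ~ PlaqueStatus * Group + (1|Case/ROI)` when `random = "nested"`.
#'
#' @param outcome outcome column name in the measurement table.
#' @param fixed `"group"` or `"plaque_by_group"`.
#' @param random `"case_intercept"` (`(1|case_id)`) or `"nested"`
#'   (`(1|case_id) + (1|case_id:roi_pair_id)`).
#' @param transformation outcome transformation (see
#'   [apply_transformation()]).
#' @param lambda Tukey-ladder exponent when `transformation = "tukey"`.
#' @param include_age add `age_years` as a fixed covariate (requires an
#'   `age_years` column; inclusion is normally decided by AIC/BIC via
#'   [compare_age_adjustment()]).
#' @return a `model_spec` list.
#' @export
model_spec <- function(outcome, fixed = c("group", "plaque_by_group"),
                       random = c("case_intercept", "nested"),
                       transformation = "identity", lambda = NULL,
                       include_age = FALSE) {
  fixed <- match.arg(fixed)
  random <- match.arg(random)
  transformation <- match.arg(transformation, TRANSFORMATIONS)
  structure(list(outcome = outcome, fixed = fixed, random = random,
                 transformation = transformation, lambda = lambda,
                 include_age = isTRUE(include_age)),
            class = "model_spec")
}

spec_formula <- function(spec) {
  fx <- switch(spec$fixed, group = "group",
               plaque_by_group = "plaque_status * group")
  if (spec$include_age) fx <- paste(fx, "+ age_years")
  rnd <- switch(spec$random,
                case_intercept = "(1 | case_id)",
                nested = "(1 | case_id) + (1 | case_id:roi_pair_id)")
  stats::as.formula(paste(".y_transformed ~", fx, "+", rnd))
}

#' Fit a linear mixed-effects model per a model spec
#'
#' REML fit (lme4) of the spec's transformed outcome with its random
#' structure. AIC/BIC come from an ML refit, so they are comparable across
#' fixed-effect structures. Residual diagnostics operationalize the visual
#' assumption checks: a Shapiro-Wilk statistic on residuals (subsampled to
#' at most 5000) for normality, and a Spearman test of |residual| against
#' fitted values for homoscedasticity. Singular or non-converged fits are
#' flagged, not hidden.
#'
#' @param measurements data.frame with the outcome column plus `case_id`,
#'   `group` and (for nested/plaque models) `roi_pair_id`,
#'   `plaque_status`. Rows with missing outcome are dropped listwise.
#' @param spec a [model_spec()].
#' @return object of class `model_fit`: the lme4 `fit`, `spec`,
#'   `transformation_record`, `beta`, `vcov`, `AIC`/`BIC` (ML), `REML`
#'   log-likelihood, `diagnostics`, `n_obs`, `n_cases`, `n_roi`,
#'   `singular`, `converged`, `data` (the analysis frame).
#' @export
fit_lmem <- function(measurements, spec) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c(spec$outcome, "case_id", "group")
  if (spec$fixed == "plaque_by_group") need <- c(need, "plaque_status")
  if (spec$random == "nested") need <- c(need, "roi_pair_id")
  if (spec$include_age) need <- c(need, "age_years")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("measurement table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(measurements)[, unique(need), drop = FALSE]
  df <- df[!is.na(df[[spec$outcome]]), , drop = FALSE]
  if (length(unique(df$case_id)) < 2)
    stop("need >= 2 cases to fit a case random intercept", call. = FALSE)
  y <- df[[spec$outcome]]
  if (stats::var(y) == 0)
    stop("degenerate outcome: '", spec$outcome, "' is constant", call. = FALSE)
  yt <- apply_transformation(y, spec$transformation, lambda = spec$lambda)
  df$.y_transformed <- as.numeric(yt)
  df$group <- factor(df$group, levels = intersect(GROUP_LEVELS,
                                                  unique(as.character(df$group))))
  if ("plaque_status" %in% names(df))
    df$plaque_status <- factor(df$plaque_status,
                               levels = intersect(c("no_plaque", "plaque", "random"),
                                                  unique(as.character(df$plaque_status))))
  form <- spec_formula(spec)
  fit <- tryCatch(
    suppressMessages(lme4::lmer(form, data = df, REML = TRUE,
                                control = lme4::lmerControl(calc.derivs = FALSE))),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("LMEM failed to fit: ", conditionMessage(fit), call. = FALSE)
  singular <- lme4::isSingular(fit, tol = 1e-4)
  conv_msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(conv_msgs)
  fit_ml <- tryCatch(suppressMessages(lme4::refitML(fit)),
                     error = function(e) NULL)

  res <- stats::residuals(fit)
  fitted_v <- stats::fitted(fit)
  sub <- if (length(res) > 5000) sample(seq_along(res), 5000) else seq_along(res)
  sw <- if (length(unique(res[sub])) > 2 && length(sub) >= 3)
    tryCatch(stats::shapiro.test(res[sub]), error = function(e) NULL) else NULL
  het <- if (length(res) >= 4 && stats::sd(abs(res)) > 0 && stats::sd(fitted_v) > 0)
    suppressWarnings(stats::cor.test(abs(res), fitted_v, method = "spearman",
                                     exact = FALSE)) else NULL
  X <- stats::model.matrix(fit)
  structure(list(
    fit = fit, spec = spec,
    transformation_record = attr(yt, "record"),
    beta = lme4::fixef(fit), vcov = as.matrix(stats::vcov(fit)),
    AIC = if (!is.null(fit_ml)) stats::AIC(fit_ml) else NA_real_,
    BIC = if (!is.null(fit_ml)) stats::BIC(fit_ml) else NA_real_,
    logLik_REML = as.numeric(stats::logLik(fit)),
    varcomp = as.data.frame(lme4::VarCorr(fit)),
    diagnostics = list(
      shapiro_W = if (!is.null(sw)) unname(sw$statistic) else NA_real_,
      shapiro_p = if (!is.null(sw)) sw$p.value else NA_real_,
      hetero_rho = if (!is.null(het)) unname(het$estimate) else NA_real_,
      hetero_p = if (!is.null(het)) het$p.value else NA_real_),
    n_obs = nrow(df), n_cases = length(unique(df$case_id)),
    n_roi = if ("roi_pair_id" %in% names(df))
      length(unique(paste(df$case_id, df$roi_pair_id))) else NA_integer_,
    singular = singular, converged = converged,
    X_assign = attr(X, "assign"), data = df),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s ~ %s [%s], transformation = %s\n",
              x$spec$outcome, x$spec$fixed, x$spec$random,
              x$transformation_record$transformation))
  cat(sprintf("  n_obs = %d, n_cases = %d%s | AIC(ML) = %.2f, BIC = %.2f%s%s\n",
              x$n_obs, x$n_cases,
              if (!is.na(x$n_roi)) sprintf(", n_roi = %d", x$n_roi) else "",
              x$AIC, x$BIC,
              if (x$singular) " | SINGULAR" else "",
              if (!x$converged) " | NOT CONVERGED" else ""))
  cat(sprintf("  residual normality W = %.4f (p = %.3g), |res|~fitted rho = %.3f (p = %.3g)\n",
              x$diagnostics$shapiro_W, x$diagnostics$shapiro_p,
              x$diagnostics$hetero_rho, x$diagnostics$hetero_p))
  invisible(x)
}

# containment df: columns of the fixed design that vary within the finest
# random grouping get within-group df, the rest between-case df
containment_df <- function(fit_obj, L) {
  df_data <- fit_obj$data
  X <- stats::model.matrix(fit_obj$fit)
  grp_fine <- if (fit_obj$spec$random == "nested")
    paste(df_data$case_id, df_data$roi_pair_id) else df_data$case_id
  varies_within <- vapply(seq_len(ncol(X)), function(j) {
    any(tapply(X[, j], grp_fine, function(v) length(unique(v)) > 1L))
  }, logical(1))
  p_within <- sum(varies_within)
  p_between <- ncol(X) - p_within
  n_groups_fine <- length(unique(grp_fine))
  involves_within <- any(abs(L[varies_within]) > 1e-12)
  if (involves_within)
    max(1, fit_obj$n_obs - n_groups_fine - p_within)
  else
    max(1, fit_obj$n_cases - p_between)
}

#' Wald F test of a fixed-effect term
#'
#' Joint test that all coefficients of `term` are zero, with containment
#' denominator degrees of freedom.
#'
#' @param fit_obj a `model_fit`.
#' @param term fixed-effect term label (e.g. `"group"`,
#'   `"plaque_status"`, `"plaque_status:group"`).
#' @return list `F`, `df1`, `df2`, `p`, `term`, `df_method`.
#' @export
lmem_fixed_test <- function(fit_obj, term) {
  stopifnot(inherits(fit_obj, "model_fit"))
  labs <- attr(stats::terms(fit_obj$fit), "term.labels")
  k <- match(term, labs)
  if (is.na(k))
    stop(sprintf("term '%s' absent from model (have: %s)", term,
                 paste(labs, collapse = ", ")), call. = FALSE)
  idx <- which(fit_obj$X_assign == k)
  if (!length(idx)) stop("term has no estimated coefficients", call. = FALSE)
  b <- fit_obj$beta[idx]
  V <- fit_obj$vcov[idx, idx, drop = FALSE]
  Fst <- as.numeric(t(b) %*% solve(V, b)) / length(idx)
  L <- rep(0, length(fit_obj$beta)); L[idx] <- 1
  df2 <- containment_df(fit_obj, L)
  list(F = Fst, df1 = length(idx), df2 = df2,
       p = stats::pf(Fst, length(idx), df2, lower.tail = FALSE),
       term = term, df_method = "containment")
}

# reference grid of fixed-effect cells with covariates at their mean
reference_grid <- function(fit_obj) {
  df <- fit_obj$data
  cells <- if (fit_obj$spec$fixed == "plaque_by_group")
    expand.grid(plaque_status = levels(df$plaque_status),
                group = levels(df$group), stringsAsFactors = FALSE)
  else
    data.frame(group = levels(df$group), stringsAsFactors = FALSE)
  if (fit_obj$spec$include_age) cells$age_years <- mean(df$age_years)
  tt <- stats::delete.response(stats::terms(fit_obj$fit))
  cells$group <- factor(cells$group, levels = levels(df$group))
  if ("plaque_status" %in% names(cells))
    cells$plaque_status <- factor(cells$plaque_status,
                                  levels = levels(df$plaque_status))
  X <- stats::model.matrix(tt, cells)
  list(cells = cells, X = X)
}

tukey_p <- function(t_abs, n_means, df) {
  stats::ptukey(t_abs * sqrt(2), nmeans = n_means, df = df,
                lower.tail = FALSE)
}

#' Post-hoc pairwise contrasts with Tukey adjustment
#'
#' Estimated marginal means over the fixed-effect grid (covariates at
#' their mean, equal weights over the other factor), all pairwise
#' differences in the requested family, studentized-range (Tukey)
#' adjustment and containment degrees of freedom, with the df method
#' recorded in every row.
#'
#' * `"group_pairs"`: the C(g,2) pairwise group differences, Tukey over g
#'   marginal means.
#' * `"plaque_within_group"`: the plaque minus no-plaque difference within
#'   each group; each within-group subfamily has two means, so the Tukey
#'   adjustment reduces to the unadjusted two-sided p, as in the
#'   corresponding `emmeans` call conditioning on group.
#'
#' @param fit_obj a `model_fit`.
#' @param family `"group_pairs"` or `"plaque_within_group"`.
#' @return data.frame of class `contrast_result`: `comparison`,
#'   `estimate` (transformed scale), `se`, `t`, `df`, `df_method`,
#'   `p_unadjusted`, `p_adjusted`, `adjustment`, `transformation`.
#' @export
posthoc_contrasts <- function(fit_obj,
                              family = c("group_pairs", "plaque_within_group")) {
  stopifnot(inherits(fit_obj, "model_fit"))
  family <- match.arg(family)
  rg <- reference_grid(fit_obj)
  X <- rg$X; cells <- rg$cells
  b <- fit_obj$beta; V <- fit_obj$vcov

  rows <- list()
  if (family == "group_pairs") {
    glv <- levels(fit_obj$data$group)
    emmL <- lapply(glv, function(g) colMeans(X[cells$group == g, , drop = FALSE]))
    cmb <- utils::combn(length(glv), 2)
    n_means <- length(glv)
    for (j in seq_len(ncol(cmb))) {
      hi <- cmb[2, j]; lo <- cmb[1, j]
      L <- emmL[[hi]] - emmL[[lo]]
      rows[[j]] <- contrast_row(sprintf("%s - %s", glv[hi], glv[lo]), L,
                                b, V, fit_obj, n_means)
    }
  } else {
    if (fit_obj$spec$fixed != "plaque_by_group")
      stop("family 'plaque_within_group' needs a plaque_status * group model",
           call. = FALSE)
    glv <- levels(fit_obj$data$group)
    plv <- levels(fit_obj$data$plaque_status)
    if (!all(c("no_plaque", "plaque") %in% plv))
      stop("model lacks plaque/no_plaque levels", call. = FALSE)
    for (j in seq_along(glv)) {
      g <- glv[j]
      L <- X[cells$group == g & cells$plaque_status == "plaque", ] -
        X[cells$group == g & cells$plaque_status == "no_plaque", ]
      rows[[j]] <- contrast_row(sprintf("plaque - no_plaque | %s", g), L,
                                b, V, fit_obj, n_means = 2L)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contrast_result", "data.frame")
  out
}

contrast_row <- function(label, L, b, V, fit_obj, n_means) {
  est <- sum(L * b)
  se <- sqrt(as.numeric(t(L) %*% V %*% L))
  tval <- est / se
  df <- containment_df(fit_obj, L)
  p_un <- 2 * stats::pt(-abs(tval), df)
  p_adj <- min(1, max(p_un, tukey_p(abs(tval), n_means, df)))
  data.frame(comparison = label, estimate = est, se = se, t = tval,
             df = df, df_method = "containment",
             p_unadjusted = p_un, p_adjusted = p_adj,
             adjustment = sprintf("tukey (%d means)", n_means),
             transformation = fit_obj$transformation_record$transformation,
             stringsAsFactors = FALSE)
}

#' Choose an outcome transformation by residual diagnostics
#'
#' Fits the model on the identity scale first; if residual normality
#' (Shapiro-Wilk) and homoscedasticity (Spearman |residual| vs fitted)
#' both pass at `alpha`, identity is kept. Otherwise the candidates
#' square root, log, arcsine square root (when the outcome is a percent or
#' proportion) and the best-normality Tukey-ladder exponent from a fixed
#' grid are fitted, and the passing candidate with the highest
#' Shapiro-Wilk W is chosen; if none passes, the best-W candidate is
#' returned with `assumptions_met = FALSE`. The full per-candidate trail
#' is recorded.
#'
#' @param measurements measurement table.
#' @param spec a [model_spec()] (its `transformation` field is ignored).
#' @param alpha diagnostic significance threshold (default 0.05).
#' @param lambda_grid Tukey-ladder search grid.
#' @return list of class `transformation_selection`: `transformation`,
#'   `lambda`, `fit` (the chosen `model_fit`), `assumptions_met`, `trail`
#'   (data.frame over candidates).
#' @export
select_transformation <- function(measurements, spec, alpha = 0.05,
                                  lambda_grid = seq(-2, 2, by = 0.25)) {
  y <- measurements[[spec$outcome]]
  y <- y[!is.na(y)]
  if (!length(y) || stats::var(y) == 0)
    stop("degenerate outcome: '", spec$outcome,
         "' is constant or empty; no transformation can help", call. = FALSE)
  try_fit <- function(tr, lambda = NULL) {
    sp <- spec; sp$transformation <- tr; sp$lambda <- lambda
    f <- tryCatch(fit_lmem(measurements, sp), error = function(e) e)
    if (inherits(f, "error"))
      return(list(fit = NULL, row = data.frame(
        candidate = tr, lambda = lambda %||% NA_real_, shapiro_W = NA_real_,
        shapiro_p = NA_real_, hetero_p = NA_real_, converged = FALSE,
        pass = FALSE, note = conditionMessage(f), stringsAsFactors = FALSE)))
    dg <- f$diagnostics
    pass <- isTRUE(f$converged) && !is.na(dg$shapiro_p) &&
      dg$shapiro_p >= alpha && (is.na(dg$hetero_p) || dg$hetero_p >= alpha)
    list(fit = f, row = data.frame(
      candidate = tr, lambda = lambda %||% NA_real_,
      shapiro_W = dg$shapiro_W, shapiro_p = dg$shapiro_p,
      hetero_p = dg$hetero_p, converged = f$converged, pass = pass,
      note = "", stringsAsFactors = FALSE))
  }
  id <- try_fit("identity")
  trail <- id$row
  if (isTRUE(id$row$pass))
    return(structure(list(transformation = "identity", lambda = NULL,
                          fit = id$fit, assumptions_met = TRUE, trail = trail),
                     class = "transformation_selection"))
  cands <- list(try_fit("sqrt"), try_fit("log"))
  if (all(y >= 0) && max(y) <= 100)
    cands <- c(cands, list(try_fit("arcsine_sqrt")))
  # Tukey ladder: pick the grid lambda maximizing residual normality
  lam_rows <- lapply(lambda_grid, function(l) try_fit("tukey", lambda = l))
  lam_W <- vapply(lam_rows, function(r) r$row$shapiro_W %||% NA_real_, numeric(1))
  if (any(!is.na(lam_W)))
    cands <- c(cands, list(lam_rows[[which.max(replace(lam_W, is.na(lam_W), -Inf))]]))
  trail <- do.call(rbind, c(list(trail), lapply(cands, `[[`, "row")))
  ok <- vapply(cands, function(cd) isTRUE(cd$row$pass), logical(1))
  pool <- if (any(ok)) cands[ok] else
    cands[!vapply(cands, function(cd) is.null(cd$fit), logical(1))]
  if (!length(pool))
    stop("no transformation candidate could be fitted; trail:\n",
         paste(utils::capture.output(print(trail)), collapse = "\n"),
         call. = FALSE)
  W <- vapply(pool, function(cd) cd$row$shapiro_W, numeric(1))
  best <- pool[[which.max(replace(W, is.na(W), -Inf))]]
  structure(list(transformation = best$row$candidate,
                 lambda = if (is.na(best$row$lambda)) NULL else best$row$lambda,
                 fit = best$fit, assumptions_met = any(ok), trail = trail),
            class = "transformation_selection")
}

#' Decide age adjustment by information criteria
#'
#' Fits the spec with and without `age_years` as a fixed covariate and
#' keeps age only if it improves the ML AIC by more than 2 (ties go to
#' the simpler model).
#'
#' @param measurements measurement table (needs `age_years`).
#' @param spec a [model_spec()].
#' @return list `include_age`, `delta_AIC` (AIC_without - AIC_with),
#'   `fit` (the chosen `model_fit`).
#' @export
compare_age_adjustment <- function(measurements, spec) {
  sp0 <- spec; sp0$include_age <- FALSE
  sp1 <- spec; sp1$include_age <- TRUE
  f0 <- fit_lmem(measurements, sp0)
  f1 <- fit_lmem(measurements, sp1)
  delta <- f0$AIC - f1$AIC
  include <- is.finite(delta) && delta > 2
  list(include_age = include, delta_AIC = delta, fit = if (include) f1 else f0)
}

#' Case-level Spearman correlations
#'
#' Per group, averages each variable over a case's included stacks and
#' correlates the case means (Spearman). Groups with fewer than 3 cases
#' are skipped with a notice row (`NA` rho).
#'
#' @param measurements measurement table with `case_id`, `group` and the
#'   variable columns.
#' @param pairs list of character pairs `c(var_x, var_y)`; default
#'   correlates amyloid burden with each glial synapse-colocalization and
#'   triple-colocalization readout.
#' @param by_group split by `group` (default TRUE; FALSE pools all cases).
#' @return data.frame of class `correlation_result`: `group`, `var_x`,
#'   `var_y`, `rho`, `p`, `n_cases`, `note`.
#' @export
case_level_correlations <- function(measurements,
                                    pairs = default_correlation_pairs(),
                                    by_group = TRUE) {
  groups <- if (by_group) split(measurements, measurements$group,
                                drop = TRUE)
  else list(all = measurements)
  rows <- list()
  for (g in names(groups)) {
    sub <- groups[[g]]
    for (pr in pairs) {
      mx <- tapply(sub[[pr[1]]], sub$case_id, mean, na.rm = TRUE)
      my <- tapply(sub[[pr[2]]], sub$case_id, mean, na.rm = TRUE)
      ok <- is.finite(mx) & is.finite(my)
      n <- sum(ok)
      if (n < 3) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, var_x = pr[1], var_y = pr[2], rho = NA_real_,
          p = NA_real_, n_cases = n,
          note = "skipped: fewer than 3 cases", stringsAsFactors = FALSE)
        next
      }
      ct <- suppressWarnings(stats::cor.test(mx[ok], my[ok],
                                             method = "spearman",
                                             exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, var_x = pr[1], var_y = pr[2],
        rho = unname(ct$estimate), p = ct$p.value, n_cases = n, note = "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("correlation_result", "data.frame")
  out
}

default_correlation_pairs <- function() {
  list(c("burden_Abeta4G8", "pair_Synapsin1_IBA1"),
       c("burden_Abeta4G8", "pair_GFAP_Synapsin1"),
       c("burden_Abeta4G8", "triple_Abeta4G8_Synapsin1_IBA1"),
       c("burden_Abeta4G8", "triple_GFAP_Abeta4G8_Synapsin1"))
}
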