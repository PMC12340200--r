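test_that("transformations match their closed forms and record metadata", {
  x <- c(0.04, 0.25, 0.81)
  expect_identical(apply_transformation(x, "identity")[1:3], x)
  expect_equal(as.numeric(apply_transformation(0.25, "arcsine_sqrt")),
               asin(0.5))
  expect_equal(as.numeric(apply_transformation(x, "tukey", lambda = 1)), x)
  expect_equal(as.numeric(apply_transformation(x, "tukey", lambda = 0)),
               log(x))
  expect_equal(as.numeric(apply_transformation(x, "tukey", lambda = -1)),
               -1 / x)
  # negative lambda stays order-preserving
  expect_true(all(diff(apply_transformation(x, "tukey", lambda = -0.5)) > 0))
  # percent inputs are rescaled for arcsine
  y <- apply_transformation(c(25, 100), "arcsine_sqrt")
  expect_true(attr(y, "record")$rescaled)
  expect_equal(as.numeric(y), asin(sqrt(c(0.25, 1))))
  # zeros under log get a recorded half-minimum offset
  z <- apply_transformation(c(0, 2, 8), "log")
  expect_equal(attr(z, "record")$offset, 1)
  expect_equal(as.numeric(z)[1], log(1))
})

test_that("transformation domain violations name the offending values", {
  expect_error(apply_transformation(c(1, -2), "sqrt"), "-2")
  expect_error(apply_transformation(c(1, -2), "log"), "negative")
  expect_error(apply_transformation(150, "arcsine_sqrt"), "150")
  expect_error(apply_transformation(1, "tukey"), "lambda")
})

test_that("balanced one-way fits recover group means of case means", {
  d <- simulate_lmem_cohort(c(6, 6, 6), n_pairs = 2, group_effects = c(0, 1, 2),
                            seed = 61)
  f <- fit_lmem(d, model_spec("y", "group", "case_intercept"))
  # brute force: per-case means, then per-group means of those
  case_means <- tapply(d$y, d$case_id, mean)
  case_group <- tapply(as.character(d$group), d$case_id, `[`, 1)
  brute <- tapply(case_means, case_group, mean)[c("Young", "Aged", "CDS")]
  rg <- gliaquant:::reference_grid(f)
  fitted_means <- as.numeric(rg$X %*% f$beta)
  expect_equal(fitted_means, as.numeric(brute), tolerance = 1e-6)
})

test_that("posthoc families have the right size and adjustment behaviour", {
  d <- simulate_lmem_cohort(c(5, 5, 5), n_pairs = 2, seed = 62)
  f <- fit_lmem(d, model_spec("y", "group", "case_intercept"))
  cr <- posthoc_contrasts(f, "group_pairs")
  expect_equal(nrow(cr), 3L)  # C(3,2)
  expect_true(all(cr$p_adjusted >= cr$p_unadjusted - 1e-12))
  expect_true(all(cr$df_method == "containment"))
  expect_equal(cr$df, rep(f$n_cases - 3, 3))
  fp <- fit_lmem(d, model_spec("y", "plaque_by_group", "nested"))
  cp <- posthoc_contrasts(fp, "plaque_within_group")
  expect_equal(nrow(cp), 3L)
  # two means per subfamily: Tukey reduces to the unadjusted p
  expect_equal(cp$p_adjusted, cp$p_unadjusted, tolerance = 1e-10)
  expect_error(posthoc_contrasts(f, "plaque_within_group"), "plaque")
})

test_that("tukey studentized-range p is monotone in family size", {
  p <- vapply(2:6, function(k) gliaquant:::tukey_p(2.5, k, 30), numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("wald test errors on absent terms and detects real effects", {
  d <- simulate_lmem_cohort(c(6, 6, 6), n_pairs = 2, group_effects = c(0, 3, 3),
                            seed = 63)
  f <- fit_lmem(d, model_spec("y", "group", "case_intercept"))
  expect_error(lmem_fixed_test(f, "plaque_status"), "absent")
  expect_lt(lmem_fixed_test(f, "group")$p, 0.01)
})

test_that("fixed-effect recovery: nominal +/-2 SE coverage of plaque effect", {
  true_eff <- 1.5
  n_sim <- 60
  covered <- vapply(seq_len(n_sim), function(s) {
    d <- simulate_lmem_cohort(c(4, 4, 4), n_pairs = 3,
                              plaque_effect = true_eff, seed = 700 + s)
    f <- fit_lmem(d, model_spec("y", "plaque_by_group", "nested"))
    cp <- posthoc_contrasts(f, "plaque_within_group")
    all(abs(cp$estimate - true_eff) <= 2 * cp$se)
  }, logical(1))
  # nominal ~95% per contrast; joint over 3 contrasts is lower, so test
  # against a 3-SE binomial lower bound of a conservative 88% target
  expect_gt(mean(covered), 0.88 - 3 * sqrt(0.88 * 0.12 / n_sim))
})

test_that("zero simulated case variance: estimate near zero, AIC prefers lm", {
  d <- simulate_lmem_cohort(c(6, 6, 6), n_pairs = 2, case_sd = 0, roi_sd = 0,
                            seed = 64)
  f <- fit_lmem(d, model_spec("y", "group", "case_intercept"))
  vc <- f$varcomp
  expect_lt(vc$sdcor[vc$grp == "case_id"], 0.2)
  # the random intercept buys nothing: the fixed-effects-only model wins on AIC
  expect_lt(stats::AIC(stats::lm(y ~ group, data = d)), f$AIC)
})

test_that("AIC model choice: age covariate kept only when it earns its keep", {
  d <- simulate_lmem_cohort(c(6, 6, 6), n_pairs = 2, seed = 65)
  ages <- stats::setNames(round(runif(length(unique(d$case_id)), 2, 20), 1),
                          unique(d$case_id))
  d$age_years <- ages[d$case_id]
  cmp <- compare_age_adjustment(d, model_spec("y", "group", "case_intercept"))
  expect_false(cmp$include_age)  # outcome independent of age by construction
  d2 <- d; d2$y <- d2$y + 0.8 * d2$age_years
  cmp2 <- compare_age_adjustment(d2, model_spec("y", "group", "case_intercept"))
  expect_true(cmp2$include_age)
})

test_that("degenerate outcomes raise errors, not silent fits", {
  d <- simulate_lmem_cohort(c(4, 4, 4), n_pairs = 2, seed = 66)
  d$y <- 5
  expect_error(fit_lmem(d, model_spec("y", "group", "case_intercept")),
               "constant")
  expect_error(select_transformation(d, model_spec("y", "group",
                                                   "case_intercept")),
               "degenerate")
  expect_error(fit_lmem(d, model_spec("nope", "group", "case_intercept")),
               "nope")
})

test_that("case-level correlations: monotone means, skip rule, grouping", {
  d <- data.frame(case_id = rep(sprintf("c%d", 1:5), each = 2),
                  group = "CDS",
                  burden_Abeta4G8 = rep(1:5, each = 2) + c(-0.1, 0.1),
                  pair_Synapsin1_IBA1 = rep(c(2, 4, 6, 8, 10), each = 2))
  cr <- case_level_correlations(d, pairs = list(c("burden_Abeta4G8",
                                                  "pair_Synapsin1_IBA1")))
  expect_equal(cr$rho, 1)
  expect_equal(cr$n_cases, 5L)
  small <- d[d$case_id %in% c("c1", "c2"), ]
  cr2 <- case_level_correlations(small, pairs = list(c("burden_Abeta4G8",
                                                       "pair_Synapsin1_IBA1")))
  expect_true(is.na(cr2$rho))
  expect_match(cr2$note, "fewer than 3")
})

test_that("designed amyloid-coupled engulfment shows up only in CDS", {
  # case-mean world: CDS couples engulfment to amyloid, Aged does not
  hits <- vapply(1:20, function(s) {
    set.seed(900 + s)
    n <- 9
    ab_cds <- runif(n, 0, 4); ab_aged <- runif(n, 0, 4)
    d <- data.frame(
      case_id = c(sprintf("cds%d", 1:n), sprintf("ag%d", 1:n)),
      group = rep(c("CDS", "Aged"), each = n),
      burden_Abeta4G8 = c(ab_cds, ab_aged),
      pair_Synapsin1_IBA1 = c(0.5 + 0.6 * ab_cds + rnorm(n, 0, 0.3),
                              rnorm(n, 1.7, 0.8)))
    cr <- case_level_correlations(d, pairs = list(c("burden_Abeta4G8",
                                                    "pair_Synapsin1_IBA1")))
    (cr$p[cr$group == "CDS"] < 0.05) && (cr$p[cr$group == "Aged"] >= 0.05)
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})
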