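test_that("plaque detection calls spheres by equivalent diameter", {
  d <- c(24L, 48L, 48L); vs <- c(1, 1, 1)
  m <- array(FALSE, dim = d)
  ctr <- c(12, 24, 24)
  m[gliaquant:::sphere_voxels(d, vs, ctr, 10)] <- TRUE  # 20 um sphere
  bm <- binary_mask(m, "Abeta4G8", vs)
  res <- detect_plaque(bm, min_diameter_um = 10)
  expect_true(res$plaque_positive)
  expect_equal(nrow(res$regions), 1L)
  expect_equal(res$regions$equiv_diameter_um, 20, tolerance = 0.05)
  expect_equal(res$regions$n_voxels,
               brute_union_sphere_count(d, vs, matrix(ctr, 1), 10))
  expect_equal(res$regions$centroid_y_um, 24, tolerance = 0.5)
})

test_that("empty and sub-threshold masks are plaque-negative", {
  d <- c(8L, 20L, 20L)
  empty <- binary_mask(array(FALSE, d), "Abeta4G8", c(1, 1, 1))
  expect_false(detect_plaque(empty)$plaque_positive)
  scatter <- array(FALSE, d)
  scatter[cbind(sample(8, 20, TRUE), sample(20, 20, TRUE),
                sample(20, 20, TRUE))] <- TRUE
  bm <- binary_mask(scatter, "Abeta4G8", c(1, 1, 1))
  expect_false(detect_plaque(bm, min_diameter_um = 10)$plaque_positive)
  expect_error(detect_plaque(scatter), "voxel_size_um")
})

test_that("roi plans pair plaque cases and subsample plaque-free cases", {
  man <- data.frame(
    case_id = rep(c("A", "B"), c(6, 12)),
    stack_id = sprintf("S%02d", 1:18),
    roi_pair_id = c(rep(c("A_P1", "A_P2", "A_P3"), each = 2),
                    sprintf("B_R%02d", 1:12)))
  calls <- stats::setNames(c(rep(c(TRUE, FALSE), 3), rep(FALSE, 12)),
                           man$stack_id)
  plan <- build_roi_plan(man, calls, n_random = 10, seed = 7)
  a <- plan[plan$case_id == "A", ]
  expect_equal(nrow(a), 6L)
  expect_true(all(a$selection_rule == "paired"))
  expect_true(all(tapply(a$plaque_status, a$roi_pair_id,
                         function(v) setequal(v, c("plaque", "no_plaque")))))
  b <- plan[plan$case_id == "B", ]
  expect_equal(nrow(b), 10L)
  expect_true(all(b$plaque_status == "random"))
  plan2 <- build_roi_plan(man, calls, n_random = 10, seed = 7)
  expect_identical(plan, plan2)
  # shortfall: fewer candidates than requested
  man7 <- man[man$case_id == "B", ][1:7, ]
  plan7 <- build_roi_plan(man7, calls, n_random = 10, seed = 7)
  expect_equal(nrow(plan7), 7L)
  expect_true(all(plan7$shortfall == 3L))
  expect_error(build_roi_plan(man[0, ], calls), "zero rows")
})

test_that("top-k selection honours ranks, ties and shortage", {
  mm <- data.frame(case_id = "A", stack_id = c("s1", "s2", "s3"),
                   burden_Abeta4G8 = c(5, 3, 1))
  expect_equal(select_top_k_by_ab(mm, 2)$burden_Abeta4G8, c(5, 3))
  ties <- data.frame(case_id = "A", stack_id = c("s3", "s1", "s2"),
                     burden_Abeta4G8 = c(2, 2, 2))
  expect_setequal(select_top_k_by_ab(ties, 2)$stack_id, c("s1", "s2"))
  expect_equal(nrow(select_top_k_by_ab(mm, 10)), 3L)
  # per-case behaviour on multiple cases
  mm2 <- rbind(mm, data.frame(case_id = "B", stack_id = c("t1", "t2"),
                              burden_Abeta4G8 = c(9, 8)))
  out <- select_top_k_by_ab(mm2, 2)
  expect_equal(as.vector(table(out$case_id)), c(2L, 2L))
})

test_that("demographics reproduces the cohort arithmetic of the fixture", {
  rec <- parse_case_table(case_table_fixture())
  d <- demographics(rec)
  expect_equal(as.vector(d$group_counts), c(7L, 10L, 8L))
  expect_equal(as.vector(d$sex_counts), c(16L, 8L, 1L))
  expect_equal(as.vector(d$sex_pct)[1:2], c(64, 32))
  expect_equal(as.vector(d$age_means), c(33 / 7, 17.1, 16.75))
  expect_false(is.null(d$age_test))
  expect_gt(d$age_test$p.value, 0.05)  # age-matched
  expect_gt(d$sex_test$p.value, 0.05)  # sex-matched, Unknown excluded
})

test_that("identical age lists give Wilcoxon p = 1 and absent groups notice", {
  rec <- data.frame(case_id = sprintf("c%d", 1:6),
                    group = factor(rep(c("Aged", "CDS"), each = 3),
                                   levels = c("Young", "Aged", "CDS")),
                    age_years = rep(c(10, 12, 14), 2),
                    sex = factor(rep(c("F", "M"), 3),
                                 levels = c("F", "M", "Unknown")),
                    ab_score = factor("none", gliaquant:::SCORE_LEVELS,
                                      ordered = TRUE),
                    tau_score = factor("none", gliaquant:::SCORE_LEVELS,
                                       ordered = TRUE))
  d <- demographics(rec)
  expect_equal(d$age_test$p.value, 1)
  young_only <- rec[1, ]
  young_only$group <- factor("Young", levels(rec$group))
  d2 <- demographics(young_only)
  expect_null(d2$age_test)
  expect_match(paste(d2$notes, collapse = " "), "skipped")
})
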