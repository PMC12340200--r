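test_that("parameter validation names the offending field", {
  expect_error(scene_params(ab_in_synapse_fraction = 1.5),
               "ab_in_synapse_fraction")
  expect_error(scene_params(synapse_radius_um = -1), "synapse_radius_um")
  expect_error(scene_params(plaque_present = TRUE,
                            plaque_center_um = c(-5, 0, 0)),
               "plaque_center_um")
  expect_error(scene_params(near_plaque_multipliers = c(glial_density = -1)),
               "near_plaque_multipliers")
  expect_error(cohort_spec(n_young = 0), "n_young")
  expect_error(cohort_spec(stacks_per_case = 5), "stacks_per_case")
})

test_that("empty scene yields zero burdens and background-plus-noise only", {
  p <- tiny_params(
    synapse_density_per_um3 = 0, plaque_present = FALSE,
    glia = list(IBA1 = glia_params(soma_count = 0),
                GFAP = glia_params(soma_count = 0)))
  sc <- generate_scene(p, seed = 1)
  expect_true(all(sc$truth$true_burden_pct == 0))
  expect_true(all(sc$truth$true_pairwise_pct == 0))
  expect_equal(nrow(sc$truth$punctum_table), 0L)
  # intensities hover around the constant background
  expect_equal(mean(sc$stack$voxels), p$background_level, tolerance = 0.05)
  expect_lt(max(sc$stack$voxels), p$background_level + 0.5)
})

test_that("engulfment_fraction 1 relocates every punctum into glia", {
  sc <- generate_scene(tiny_params(engulfment_fraction = 1,
                                   engulfment_ab_bias = 1), seed = 2)
  pt <- sc$truth$punctum_table
  expect_gt(nrow(pt), 0)
  expect_true(all(pt$engulfed_by != "none"))
  expect_setequal(unique(pt$engulfed_by), c("microglia", "astrocyte"))
})

test_that("synapsin rasterization matches the brute-force sphere oracle", {
  p <- noiseless_params(shape_vox = c(10L, 24L, 24L),
                        voxel_size_um = c(0.2, 0.2, 0.2),
                        synapse_density_per_um3 = 0.1,
                        ab_in_synapse_fraction = 0, engulfment_fraction = 0,
                        background_level = 0,
                        glia = list(IBA1 = glia_params(soma_count = 0),
                                    GFAP = glia_params(soma_count = 0)))
  sc <- generate_scene(p, seed = 3)
  pt <- sc$truth$punctum_table
  expect_gt(nrow(pt), 0)
  oracle <- brute_union_sphere_count(
    p$shape_vox, p$voxel_size_um,
    as.matrix(pt[, c("z_um", "y_um", "x_um")]), p$synapse_radius_um)
  expect_identical(sum(sc$truth$masks$Synapsin1), oracle)
  # and with zero PSF/noise the rendered channel is the mask itself
  expect_identical(sum(get_channel(sc$stack, "Synapsin1") > 0.5), oracle)
})

test_that("identical seeds give bit-identical stacks, different seeds differ", {
  a <- generate_scene(tiny_params(), seed = 9)
  b <- generate_scene(tiny_params(), seed = 9)
  cc <- generate_scene(tiny_params(), seed = 10)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$punctum_table, b$truth$punctum_table)
  expect_false(identical(a$stack$voxels, cc$stack$voxels))
})

test_that("expected synapsin burden increases with synapse density", {
  densities <- c(0.02, 0.08, 0.2)
  mean_burden <- vapply(densities, function(dn) {
    mean(vapply(1:6, function(s)
      generate_scene(tiny_params(synapse_density_per_um3 = dn),
                     seed = 100 + s)$truth$true_burden_pct[["Synapsin1"]],
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_burden) > 0))
})

test_that("noiseless rendering recovers ground-truth masks at half intensity", {
  sc <- generate_scene(noiseless_params(), seed = 4)
  for (ch in study_channels()) {
    rec <- get_channel(sc$stack, ch) > sc$stack$voxels[1, 1, 1, 1] + 0.5
    expect_identical(rec, sc$truth$masks[[ch]], label = ch)
  }
})

test_that("independently placed channels obey the product law", {
  # engulfment and synaptic amyloid off -> synapsin and glia independent
  p <- scene_params(shape_vox = c(16L, 256L, 256L),
                    ab_in_synapse_fraction = 0, engulfment_fraction = 0)
  rel_err <- vapply(1:10, function(s) {
    tr <- generate_scene(p, seed = 200 + s)$truth
    obs <- tr$true_pairwise_pct[["Synapsin1&IBA1"]]
    expected <- tr$true_burden_pct[["Synapsin1"]] *
      tr$true_burden_pct[["IBA1"]] / 100
    (obs - expected) / expected
  }, numeric(1))
  expect_lt(abs(mean(rel_err)), 0.10)
})

test_that("cohort manifest counts, nesting and determinism", {
  spec <- cohort_spec(n_young = 2, n_aged = 2, n_cds = 2,
                      stacks_per_case = 4, base_params = tiny_params(),
                      seed = 5)
  coh <- generate_cohort(spec)
  expect_equal(nrow(coh$manifest), 24L)
  expect_equal(nrow(coh$cases), 6L)
  expect_equal(length(coh$stacks), 24L)
  # paired cases: every plaque stack shares its roi_pair_id with a no_plaque one
  man <- coh$manifest
  for (cid in coh$cases$case_id[coh$cases$plaque_bearing]) {
    sub <- man[man$case_id == cid, ]
    expect_setequal(unique(table(sub$roi_pair_id)), 2L)
    expect_true(all(tapply(sub$plaque_status, sub$roi_pair_id,
                           function(v) setequal(v, c("plaque", "no_plaque")))))
  }
  for (cid in coh$cases$case_id[!coh$cases$plaque_bearing])
    expect_true(all(man$plaque_status[man$case_id == cid] == "random"))
  coh2 <- generate_cohort(spec)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(coh$stacks[[1]]$stack$voxels, coh2$stacks[[1]]$stack$voxels)
})

test_that("null cohort (all multipliers 1) shows no systematic group effect", {
  nul <- stats::setNames(lapply(c("Young", "Aged", "CDS"), function(g)
    c(ab_in_synapse = 1, glial_density = 1, engulfment = 1,
      engulfment_ab_bias = 1)), c("Young", "Aged", "CDS"))
  spec <- cohort_spec(n_young = 2, n_aged = 2, n_cds = 2, stacks_per_case = 2,
                      plaque_prevalence = c(Young = 0, Aged = 0, CDS = 0),
                      group_effects = nul,
                      base_params = tiny_params(), seed = 6)
  coh <- generate_cohort(spec)
  tb <- vapply(coh$stacks, function(s)
    s$truth$true_burden_pct[["Synapsin1"]], numeric(1))
  grp <- coh$manifest$group
  gm <- tapply(tb, grp, mean)
  expect_lt(diff(range(gm)), 3 * sd(tb))  # only sampling noise
})

test_that("CDS engulfment elevation at plaques is recovered across seeds", {
  # CDS doubles engulfment (vs Young at 1); small fast stacks, 20 cohorts
  eff <- list(
    Young = c(ab_in_synapse = 1, glial_density = 1, engulfment = 1,
              engulfment_ab_bias = 1),
    Aged = c(ab_in_synapse = 1, glial_density = 1, engulfment = 1,
             engulfment_ab_bias = 1),
    CDS = c(ab_in_synapse = 1, glial_density = 1, engulfment = 2,
            engulfment_ab_bias = 1))
  base <- scene_params(shape_vox = c(8L, 48L, 48L),
                       engulfment_fraction = 0.15)
  delta <- vapply(1:20, function(s) {
    spec <- cohort_spec(n_young = 1, n_aged = 1, n_cds = 1,
                        stacks_per_case = 4,
                        plaque_prevalence = c(Young = 1, Aged = 1, CDS = 1),
                        group_effects = eff, base_params = base, seed = 300 + s)
    coh <- generate_cohort(spec)
    ov <- vapply(coh$stacks, function(x)
      x$truth$true_pairwise_pct[["Synapsin1&IBA1"]] +
        x$truth$true_pairwise_pct[["GFAP&Synapsin1"]], numeric(1))
    man <- coh$manifest
    at_plaque <- man$plaque_status == "plaque"
    cds <- man$group == "CDS"
    (mean(ov[cds & at_plaque]) - mean(ov[cds & !at_plaque])) -
      (mean(ov[!cds & at_plaque]) - mean(ov[!cds & !at_plaque]))
  }, numeric(1))
  expect_gt(mean(delta), 0)
})
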