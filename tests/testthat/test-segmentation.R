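make_stack <- function(arr3, channel = "Synapsin1") {
  arr <- array(arr3, dim = c(1, dim(arr3)))
  image_stack(arr, channel, c(0.4, 0.3, 0.3))
}

test_that("Otsu separates a clean bimodal channel exactly", {
  set.seed(1)
  truth <- rand_mask(c(6, 20, 20), 0.2, seed = 21)
  img <- ifelse(truth, 200, 10)
  st <- make_stack(img)
  bm <- segment_channel(st, "Synapsin1")
  expect_identical(bm$mask, truth)
  expect_true(bm$method_record$threshold > 10 && bm$method_record$threshold < 200)
})

test_that("fixed threshold above the maximum yields an empty mask", {
  st <- make_stack(array(runif(600, 0, 1), dim = c(6, 10, 10)))
  bm <- segment_channel(st, "Synapsin1",
                        segmentation_config("fixed", fixed_threshold = 2))
  expect_false(any(bm$mask))
})

test_that("constant channel with Otsu raises a degenerate-input error", {
  st <- make_stack(array(7, dim = c(4, 8, 8)))
  expect_error(segment_channel(st, "Synapsin1"), "degenerate")
})

test_that("raising a fixed threshold never increases the positive count", {
  st <- make_stack(array(runif(2400), dim = c(6, 20, 20)))
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(thr)
    sum(segment_channel(st, "Synapsin1",
                        segmentation_config("fixed", fixed_threshold = thr))$mask),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("percentile method thresholds at the requested quantile", {
  arr <- array(seq_len(1000) / 1000, dim = c(10, 10, 10))
  st <- make_stack(arr)
  bm <- segment_channel(st, "Synapsin1",
                        segmentation_config("percentile", percentile = 90))
  expect_equal(sum(bm$mask), 100L)
})

test_that("connected-component labelling matches hand-built geometry", {
  m <- array(FALSE, dim = c(3, 5, 5))
  m[1, 1:2, 1] <- TRUE          # component A: face-connected pair
  m[2, 5, 5] <- TRUE; m[3, 5, 5] <- TRUE  # component B: face-connected pair
  m[1, 4, 4] <- TRUE            # corner-diagonal neighbour of [2,5,5]
  lab6 <- label_components(m, 6L)
  expect_equal(max(lab6), 3L)   # diagonal stays separate under 6-connectivity
  lab26 <- label_components(m, 26L)
  expect_equal(max(lab26), 2L)  # ...but joins B under 26
  expect_equal(lab6[1, 1, 1], lab6[1, 2, 1])
})

test_that("small-object removal is idempotent and size-selective", {
  m <- array(FALSE, dim = c(4, 10, 10))
  m[2, 2:4, 2] <- TRUE   # 3-voxel object
  m[3, 8, 8] <- TRUE     # singleton
  r1 <- gliaquant:::remove_small_objects(m, 2L, 6L)
  expect_equal(sum(r1), 3L)
  r2 <- gliaquant:::remove_small_objects(r1, 2L, 6L)
  expect_identical(r1, r2)
  st <- make_stack(ifelse(m, 100, 0))
  bm <- segment_channel(st, "Synapsin1",
                        segmentation_config("fixed", fixed_threshold = 50,
                                            min_object_voxels = 2L))
  expect_identical(bm$mask, r1)
})

test_that("noiseless scenes segment to ground truth for any in-gap threshold", {
  sc <- generate_scene(noiseless_params(), seed = 31)
  for (thr in c(0.3, 0.6, 0.9)) {
    bm <- segment_channel(sc$stack, "IBA1",
                          segmentation_config("fixed", fixed_threshold = thr))
    expect_identical(bm$mask, sc$truth$masks$IBA1, label = paste("thr", thr))
  }
})

test_that("negative-control QC passes noise and fails signal", {
  p_ctrl <- tiny_params(
    synapse_density_per_um3 = 0, plaque_present = FALSE,
    glia = list(IBA1 = glia_params(soma_count = 0),
                GFAP = glia_params(soma_count = 0)))
  ctrl <- generate_scene(p_ctrl, seed = 41)$stack
  stained <- generate_scene(tiny_params(), seed = 42)$stack
  # thresholds carried over from the matched stained stack of the batch
  thr <- sapply(study_channels(), function(ch)
    gliaquant:::otsu_threshold(get_channel(stained, ch)))
  rep_ctrl <- qc_negative_control(ctrl, max_burden_pct = 0.5, thresholds = thr)
  expect_true(rep_ctrl$pass)
  rep_bad <- qc_negative_control(stained, max_burden_pct = 0.5, thresholds = thr)
  expect_false(rep_bad$pass)
  expect_true(qc_negative_control(stained, max_burden_pct = 100,
                                  thresholds = thr)$pass)
  expect_named(rep_ctrl$burdens, study_channels())
})
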