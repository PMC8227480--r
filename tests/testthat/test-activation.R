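test_that("segment_blocks rejects degenerate or overrunning designs", {
  expect_error(segment_blocks(build_task_design(walk_s = 0,
                                                rest_s = 60),
                              default_design$n_samples),
               class = "invalid_design")
  expect_error(segment_blocks(default_design, 500), class = "invalid_design")
})

test_that("block_auc is a plain sample sum", {
  w <- 10:20
  expect_equal(block_auc(rep(0, 30), w), 0)
  expect_equal(block_auc(rep(2.5, 30), w), 2.5 * 11)
  set.seed(13)
  x <- rnorm(200)
  win <- 50:153
  acc <- 0
  for (k in win) acc <- acc + x[k]   # scalar-loop oracle
  expect_equal(block_auc(x, win), acc, tolerance = 1e-12)
  # sign preserved
  expect_lt(block_auc(rep(-1, 30), w), 0)
  expect_error(block_auc(x, integer(0)), class = "invalid_input")
  expect_error(block_auc(x, 190:210), class = "invalid_input")
})

test_that("mean_block_auc is the arithmetic mean", {
  expect_equal(mean_block_auc(c(1, 2, 3, 4)), 2.5)
  expect_equal(mean_block_auc(rep(7.7, 4)), 7.7)
  expect_error(mean_block_auc(numeric(0)), class = "invalid_input")
})

test_that("affected-hemisphere mapping is contralateral", {
  expect_equal(assign_affected_hemisphere("right")[["MAff"]], "left")
  expect_equal(assign_affected_hemisphere("right")[["LAff"]], "right")
  expect_equal(assign_affected_hemisphere("left")[["MAff"]], "right")
  expect_error(assign_affected_hemisphere(NA_character_),
               class = "invalid_metadata")
  expect_error(assign_affected_hemisphere("both"),
               class = "invalid_metadata")
})

test_that("hemispheric aggregation reproduces the published totals", {
  # patient column: hemisphere sums 218,637 (MAff) and 163,797 (LAff)
  aucs <- setNames(numeric(48), default_montage$channel)
  aucs[default_montage$hemisphere == "left"] <- 218637 / 24
  aucs[default_montage$hemisphere == "right"] <- 163797 / 24
  res <- aggregate_activation(aucs, default_montage,
                              c(MAff = "left", LAff = "right"))
  expect_equal(res$maff_auc, 218637)
  expect_equal(res$laff_auc, 163797)
  expect_equal(res$tot_auc, 382434)
  expect_identical(res$tot_auc, res$maff_auc + res$laff_auc)
  # healthy column: 26,428 + 15,543 = 41,971
  aucs[default_montage$hemisphere == "left"] <- 26428 / 24
  aucs[default_montage$hemisphere == "right"] <- 15543 / 24
  res2 <- aggregate_activation(aucs, default_montage,
                               c(MAff = "left", LAff = "right"))
  expect_equal(res2$tot_auc, 41971)
  # all-zero channels
  res0 <- aggregate_activation(setNames(numeric(48),
                                        default_montage$channel),
                               default_montage,
                               c(MAff = "left", LAff = "right"))
  expect_equal(c(res0$maff_auc, res0$laff_auc, res0$tot_auc), c(0, 0, 0))
})

test_that("aggregation is invariant to channel permutation within hemisphere", {
  set.seed(17)
  aucs <- setNames(runif(48, -5, 20), default_montage$channel)
  res <- aggregate_activation(aucs, default_montage,
                              c(MAff = "left", LAff = "right"))
  left <- default_montage$hemisphere == "left"
  perm <- aucs
  perm[left] <- sample(aucs[left])
  names(perm) <- default_montage$channel
  res_p <- aggregate_activation(perm, default_montage,
                                c(MAff = "left", LAff = "right"))
  expect_equal(res_p$maff_auc, res$maff_auc)
  expect_equal(res_p$tot_auc, res$tot_auc)
})

test_that("rescale_missing compensates hemisphere sums for excluded channels", {
  gains <- rep(1L, 48)
  gains[1:4] <- 8L   # four left-hemisphere channels excluded
  rec <- make_flat_recording(gains = gains)
  qc <- qc_channels(rec)
  aucs <- setNames(rep(10, 48), default_montage$channel)
  plain <- aggregate_activation(aucs, default_montage,
                                c(MAff = "left", LAff = "right"), qc)
  expect_equal(plain$maff_auc, 200)      # 20 retained x 10
  expect_equal(plain$retained_per_hemisphere[["MAff"]], 20)
  resc <- aggregate_activation(aucs, default_montage,
                               c(MAff = "left", LAff = "right"), qc,
                               rescale_missing = TRUE)
  expect_equal(resc$maff_auc, 200 * 24 / 20)
  expect_true(resc$rescaled)
})

test_that("zero retained channels in a hemisphere is an error", {
  gains <- rep(1L, 48)
  gains[default_montage$hemisphere == "left"] <- 8L
  rec <- make_flat_recording(gains = gains)
  qc <- qc_channels(rec)
  # subject itself is excluded (24 > 8); force subject-level pass to probe
  # the hemisphere guard
  attr(qc, "subject_status") <- "included"
  aucs <- setNames(rep(1, 48), default_montage$channel)
  expect_error(aggregate_activation(aucs, default_montage,
                                    c(MAff = "left", LAff = "right"), qc),
               class = "invalid_subject")
})

test_that("biomarker scales linearly with the oxy-Hb traces", {
  tr <- ground_truth(default_montage, graded_amps())
  rec <- simulate_subject_recording(default_montage, default_design, tr,
                                    noise_none(), seed = 23)
  hemo <- process_recording(rec, band = NULL, clean = FALSE)
  act1 <- compute_activation(hemo, "right", hemo$qc)
  hemo2 <- hemo
  hemo2$hbo <- hemo$hbo * 3
  act3 <- compute_activation(hemo2, "right", hemo2$qc)
  expect_equal(act3$tot_auc, 3 * act1$tot_auc, tolerance = 1e-12)
  expect_equal(act3$maff_auc, 3 * act1$maff_auc, tolerance = 1e-12)
  expect_equal(act3$laff_auc, 3 * act1$laff_auc, tolerance = 1e-12)
})

test_that("per-channel mean AUC equals the mean of its block AUCs", {
  tr <- ground_truth(default_montage, graded_amps())
  rec <- simulate_subject_recording(default_montage, default_design, tr,
                                    noise_model(), seed = 29)
  hemo <- process_recording(rec)
  act <- compute_activation(hemo, "left", hemo$qc)
  keep <- hemo$retained
  expect_equal(unname(act$channel_aucs[keep]),
               unname(rowMeans(act$block_aucs[keep, , drop = FALSE])))
  # composition oracle: brute-force per-block sums match the result
  w <- segment_blocks(default_design, nrow(hemo$hbo))
  ch <- which(keep)[1]
  manual <- mean(vapply(w, function(ix) sum(hemo$hbo[ix, ch] * 1000),
                        numeric(1)))
  expect_equal(unname(act$channel_aucs[ch]), manual, tolerance = 1e-12)
})
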