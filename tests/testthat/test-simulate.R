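test_that("identical config and seed give bit-identical datasets", {
  cfg <- tiny_sim()
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a, b)
})

test_that("run counts and labels are balanced across classes and subjects", {
  cfg <- sim_config(n_subjects = 4, n_parcels = 60, n_classes = 7,
                    n_timepoints = 20, seed = 2)
  runs <- simulate_dataset(cfg)
  expect_length(runs, 28)
  expect_equal(unname(table(run_labels(runs, "class"))), rep(4L, 7),
               ignore_attr = TRUE)
  expect_equal(length(unique(run_labels(runs, "subject"))), 4)
  expect_true(all(run_labels(runs, "group") %in% 0:1))
  expect_true(all(vapply(runs, function(r) all(is.finite(r$series)), logical(1))))
})

test_that("invalid configurations are rejected with diagnostics", {
  expect_error(sim_config(n_subjects = 2, n_classes = 1), "n_classes")
  expect_error(sim_config(n_subjects = 2, effect_size = -1), "effect_size")
  expect_error(sim_config(n_subjects = 2, ar_coefficient = 1), "ar_coefficient")
  # every class needs a designated block, and blocks need >= 2 parcels
  expect_error(sim_config(n_subjects = 2, n_classes = 7, n_blocks = 3),
               "n_blocks")
  expect_error(sim_config(n_subjects = 2, n_parcels = 14, n_classes = 7,
                          n_blocks = 7), "smallest block")
  # over-strong effect makes the covariance non-PD
  cfg <- tiny_sim(effect = 0.94)
  cfg$group_effect <- 5
  expect_error(simulate_dataset(cfg), "positive-definite")
})

test_that("empirical correlation converges to the planted block structure", {
  errs <- sapply(c(200, 2000), function(T) {
    cfg <- sim_config(n_subjects = 1, n_parcels = 12, n_classes = 2,
                      n_timepoints = T, effect_size = 0.5, n_blocks = 3,
                      subject_sd = 0, seed = 11)
    run <- simulate_dataset(cfg)[[1]]
    planted <- cov2cor(conndecode:::class_covariance(cfg, run$class_label + 1L,
                                                     run$group_label, 0))
    emp <- cor(run$series)
    sqrt(sum((emp - planted)^2))
  })
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 1)
})

test_that("class-conditional connectivity differs between classes iff effect_size > 0", {
  mean_block_gap <- function(effect, seed) {
    cfg <- sim_config(n_subjects = 8, n_parcels = 16, n_classes = 2,
                      n_timepoints = 150, effect_size = effect, n_blocks = 4,
                      subject_sd = 0, seed = seed)
    runs <- simulate_dataset(cfg)
    # edges inside class 1's designated block separate class 1 from class 2
    blocks <- conndecode:::block_partition(cfg)
    in1 <- blocks == 1
    disc <- outer(in1, in1, "&") & upper.tri(diag(16))
    z <- vapply(runs, function(r) {
      mean(fisher_z(pearson_connectivity(r$series))[disc])
    }, numeric(1))
    cls <- run_labels(runs, "class")
    t.test(z[cls == 0], z[cls == 1])$p.value
  }
  expect_lt(mean_block_gap(0.6, 5), 0.01)
  expect_gt(mean_block_gap(0, 5), 0.05)
})

test_that("group_effect induces a detectable group difference in within-block weight", {
  cfg <- sim_config(n_subjects = 12, n_parcels = 16, n_classes = 2,
                    n_timepoints = 150, effect_size = 0.3, group_effect = 1,
                    n_blocks = 4, subject_sd = 0, seed = 13)
  runs <- simulate_dataset(cfg)
  b <- conndecode:::block_partition(cfg)
  mask <- outer(b, b, "==") & upper.tri(diag(16))
  within <- vapply(runs, function(r) {
    mean(fisher_z(pearson_connectivity(r$series))[mask])
  }, numeric(1))
  grp <- run_labels(runs, "group")
  expect_lt(t.test(within[grp == 0], within[grp == 1])$p.value, 0.01)
  expect_lt(mean(within[grp == 0]), mean(within[grp == 1]))
})

test_that("effect_size = 0 yields chance-level decodability downstream", {
  cfg <- sim_config(n_subjects = 12, n_parcels = 16, n_classes = 3,
                    n_timepoints = 80, effect_size = 0, n_blocks = 4,
                    seed = 21)
  runs <- simulate_dataset(cfg)
  # all classes share one covariance: a connectivity classifier sits at
  # chance (MCC ~ 0 averaged over repeated subsampled fits, accuracy ~ 1/3)
  mccs <- vapply(1:20, function(s) connectivity_centroid_mcc(runs, s),
                 numeric(1))
  expect_lt(abs(mean(mccs)), 0.2)
  bl <- logistic_baseline(run_feature_table(runs, "connectivity"),
                          run_labels(runs, "class"), seed = 1)
  expect_lte(bl$test_accuracy, 4 / 6) # chance 1/3 on the 6-run test split
})

test_that("voxel simulation supports exact recovery and noise degrades it", {
  cfg <- tiny_sim(n_subjects = 1, n_classes = 2, T = 60, parcels = 8,
                  blocks = 2)
  noiseless <- simulate_voxel_runs(cfg, voxels_per_parcel = 1,
                                   voxel_noise_sd = 0)[[1]]
  expect_equal(length(noiseless$parcel_assignment), 8)
  rec <- average_voxel_timeseries(noiseless$voxel_series,
                                  noiseless$parcel_assignment)
  expect_equal(unname(rec), unname(noiseless$parcel_series), tolerance = 1e-12)

  v3 <- simulate_voxel_runs(cfg, voxels_per_parcel = 3, voxel_noise_sd = 0.5)[[1]]
  expect_equal(length(v3$parcel_assignment), 24)

  # Monte-Carlo: recovered-vs-true correlation decreases with voxel noise
  mean_recovery_cor <- function(noise_sd) {
    r <- simulate_voxel_runs(cfg, voxels_per_parcel = 2,
                             voxel_noise_sd = noise_sd)[[1]]
    rec <- average_voxel_timeseries(r$voxel_series, r$parcel_assignment)
    mean(diag(cor(rec, r$parcel_series)))
  }
  cors <- vapply(c(0.1, 1, 4), mean_recovery_cor, numeric(1))
  expect_true(all(diff(cors) < 0))
})

test_that("runs round-trip through the CSV + manifest format", {
  cfg <- tiny_sim(n_subjects = 2, n_classes = 2, T = 20, parcels = 6,
                  blocks = 2)
  runs <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_runs(runs, dir)
  back <- read_runs(dir)
  expect_equal(length(back), length(runs))
  expect_equal(back[[3]]$series, runs[[3]]$series, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(run_labels(back, "class"), run_labels(runs, "class"))
  expect_identical(run_labels(back, "group"), run_labels(runs, "group"))
})
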