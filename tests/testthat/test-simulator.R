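test_that("trajectories conserve mass and satisfy the resolution identity", {
  for (e in c(1, 2, 9, 44, 112, 1e6)) {
    traj <- simulate_resolution(e, stop_conversion = 0.6, n_points = 12)
    expect_true(all(diff(traj$conversion) > 0))
    balance <- traj$conversion - (1 - (traj$frac_fast + traj$frac_slow) / 2)
    expect_lt(max(abs(balance)), 1e-10)
    # c = ee_s / (ee_s + ee_p) wherever both are defined
    with_sel <- traj[traj$ee_product > 0, ]
    expect_equal(with_sel$ee_substrate /
                   (with_sel$ee_substrate + with_sel$ee_product),
                 with_sel$conversion, tolerance = 1e-9)
  }
})

test_that("closed-form and ODE integration agree to 1e-8 in product ee", {
  for (e in c(2, 9, 112)) {
    cf <- simulate_resolution(e, stop_conversion = 0.5, n_points = 6)
    od <- simulate_resolution(e, stop_conversion = 0.5, n_points = 6,
                              method = "ode")
    expect_lt(max(abs(cf$ee_product - od$ee_product)), 1e-8)
  }
})

test_that("the Chen-Sih formula recovers the true E along noise-free trajectories", {
  for (e in c(2, 9, 44, 112, 500)) {
    traj <- simulate_resolution(e, stop_conversion = 0.45, n_points = 8)
    est <- e_from_conversion_ee(traj$conversion, traj$ee_product)
    expect_lt(max(abs(est - e) / e), 1e-6)
  }
})

test_that("limiting behaviors: no selectivity and near-perfect selectivity", {
  flat <- simulate_resolution(1, stop_conversion = 0.8, n_points = 5)
  expect_equal(flat$ee_product, rep(0, 5))
  sharp <- simulate_resolution(1e6, stop_conversion = 0.4, n_points = 4)
  expect_gt(min(sharp$ee_product), 0.999)
})

test_that("noisy sampling is reproducible and exact at zero noise", {
  traj <- simulate_resolution(44, 0.4, 10)
  clean <- sample_noisy_observations(traj, 0, 0, seed = 1)
  expect_equal(clean$conversion, traj$conversion)
  expect_equal(clean$ee_product, traj$ee_product)
  a <- sample_noisy_observations(traj, 0.01, 0.01, n = 50, seed = 7)
  b <- sample_noisy_observations(traj, 0.01, 0.01, n = 50, seed = 7)
  expect_identical(a, b)
  c <- sample_noisy_observations(traj, 0.01, 0.01, n = 50, seed = 8)
  expect_false(identical(a$conversion, c$conversion))
  # observations stay inside the feasible domain
  expect_true(all(a$conversion > 0 & a$conversion < 1))
  expect_true(all(a$ee_product >= 0))
  expect_true(all(a$conversion * (1 + a$ee_product) < 1))
})

test_that("fabricated docking tables round-trip through the selectivity engine", {
  worked <- generate_docking_table(
    data.frame(substrate_id = "3F", ez = "E", ddg = 1.98,
               preferred_config = "S")
  )
  pred <- predict_selectivity(worked)
  expect_equal(pred$ddg, 1.98)
  expect_equal(pred$predicted_config, "S")
  # zero ddG is a tie
  tie <- predict_selectivity(generate_docking_table(
    data.frame(substrate_id = "X", ez = "Z", ddg = 0, preferred_config = "R")
  ))
  expect_equal(tie$predicted_config, "none")
  set.seed(23)
  design <- tibble::tibble(
    substrate_id = sprintf("S%d", 1:8),
    ez = rep(c("E", "Z"), 4),
    ddg = round(runif(8, 0, 3), 3),
    preferred_config = sample(c("R", "S"), 8, replace = TRUE)
  )
  pred <- predict_selectivity(generate_docking_table(design, base_dg = -8.5))
  joined <- dplyr::inner_join(design, pred, by = c("substrate_id", "ez"))
  expect_equal(joined$ddg.y, joined$ddg.x, tolerance = 1e-12)
  nonzero <- joined$ddg.x > 0
  expect_equal(joined$predicted_config[nonzero],
               joined$preferred_config[nonzero])
})

test_that("pose ensembles carry exact ground truth for the pharmacophore filter", {
  ens <- generate_pose_ensemble(5, 5, seed = 42)
  truth <- attr(ens, "ground_truth")
  got <- filter_poses(ens)
  expect_equal(got$overall, truth$valid)
  expect_equal(sum(got$overall), 5)
  # decoys cycle through all five descriptors
  expect_setequal(unique(stats::na.omit(truth$violated)),
                  c("fe_n_dist", "o_ser_dist", "o_his_dist",
                    "his_o_ser_angle", "c_n_o_o_dihedral"))
  # no valid pose -> no best pose
  expect_null(select_best_valid_pose(generate_pose_ensemble(0, 3, seed = 5)))
})

test_that("ensembles and bundles are byte-deterministic under a fixed seed", {
  t1 <- withr::local_tempfile(fileext = ".pdb")
  t2 <- withr::local_tempfile(fileext = ".pdb")
  write_poses(generate_pose_ensemble(3, 2, seed = 9), t1)
  write_poses(generate_pose_ensemble(3, 2, seed = 9), t2)
  expect_identical(readLines(t1), readLines(t2))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_bundle(d1, true_e = 44, seed = 12, n_obs = 10)
  simulate_bundle(d2, true_e = 44, seed = 12, n_obs = 10)
  for (f in c("trajectory.tsv", "observations.tsv", "docking.tsv", "poses.pdb",
              "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("a full bundle supports end-to-end recovery of its ground truth", {
  dir <- withr::local_tempdir()
  b <- simulate_bundle(dir, true_e = 44, seed = 31, n_obs = 200)
  expect_true(all(file.exists(unlist(b$files))))
  manifest <- jsonlite::read_json(b$files$manifest, simplifyVector = TRUE)
  expect_equal(manifest$seed, 31)
  expect_equal(manifest$true_e, 44)
  # resolution observations -> E estimates around the true value
  obs <- read_resolution_table(b$files$observations)
  est <- median(e_from_conversion_ee(obs$conversion, obs$ee_product))
  expect_lt(abs(est - 44) / 44, 0.1)
  # docking table -> the designed ddG and preference
  pred <- predict_selectivity(read_docking_table(b$files$docking))
  des <- manifest$docking_design
  joined <- dplyr::inner_join(pred, des, by = c("substrate_id", "ez"))
  expect_equal(joined$ddg.x, joined$ddg.y, tolerance = 1e-9)
  expect_equal(joined$predicted_config, joined$preferred_config)
  # pose ensemble -> the recorded validity
  poses <- read_poses(b$files$poses)
  expect_equal(filter_poses(poses)$overall, manifest$pose_ground_truth$valid)
})
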