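test_that("identical seeds reproduce identical cohorts; different seeds differ", {
  a <- simulate_feature_cohort(synthetic_config(rng_seed = 42))
  b <- simulate_feature_cohort(synthetic_config(rng_seed = 42))
  expect_identical(a, b)
  c <- simulate_feature_cohort(synthetic_config(rng_seed = 43))
  expect_false(identical(a$ADCmean, c$ADCmean))
})

test_that("per-patient substreams are stable when the cohort is extended", {
  small <- synthetic_config(n_grade3 = 3, n_grade4 = 2, rng_seed = 9)
  big <- synthetic_config(n_grade3 = 3, n_grade4 = 10, rng_seed = 9)
  a <- simulate_feature_cohort(small)
  b <- simulate_feature_cohort(big)
  strip <- function(x) {
    attr(x, "ground_truth") <- NULL
    x
  }
  expect_identical(strip(a)[1:5, ], strip(b)[1:5, ])
  expect_identical(attr(a, "ground_truth")[1:5, ],
                   attr(b, "ground_truth")[1:5, ])
})

test_that("zero-variance configuration yields identical constant-lesion patients", {
  cfg <- synthetic_config(
    n_grade3 = 3, n_grade4 = 0,
    grade3 = list(location_mean = 120e-5, location_sd = 0,
                  within_sd_mean = 0, within_sd_sd = 0))
  co <- simulate_feature_cohort(cfg)
  expect_equal(nrow(co), 3)
  expect_equal(unique(co$ADCmean), 120)
  expect_equal(unique(co$ADCsd), 0)
  expect_equal(unique(co$Entropy), 0)
  expect_true(all(is.na(co$Skewness)))
  expect_equal(co[1, c("ADCmean", "ADCsd", "Entropy")],
               co[2, c("ADCmean", "ADCsd", "Entropy")])
})

test_that("planted per-tumor mean and SD are recovered at n_voxels = 1e5", {
  cfg <- synthetic_config(rng_seed = 31)
  for (idx in c(2, 20, 40)) { # one grade III, two grade IV
    p <- simulate_patient_params(cfg, idx)
    set.seed(p$seed + 7)
    v <- adchist:::draw_patient_voxels(p, n = 1e5)
    se_mean <- p$planted_sd / sqrt(1e5)
    expect_lt(abs(mean(v) - p$planted_mean), 3 * se_mean)
    m2 <- mean((v - mean(v))^2)
    se_sd <- sd(v) * sqrt((mean((v - mean(v))^4) / m2^2 - 1) / (4 * 1e5))
    expect_lt(abs(sd(v) - p$planted_sd), 3 * se_sd + 1e-7)
  }
})

test_that("the default cohort reproduces the configured population structure over seeds", {
  ens <- default_cohort_ensemble(50)
  sd_gap <- vapply(ens, function(co) {
    mean(co$ADCsd[co$who_grade == "IV"]) > mean(co$ADCsd[co$who_grade == "III"])
  }, TRUE)
  expect_gte(mean(sd_gap), 0.95)

  sp <- vapply(ens, function(co) {
    cor(co$ADCsd, co$ki67, method = "spearman")
  }, 0)
  expect_gte(mean(sp >= 0.25 & sp <= 0.65), 0.90)

  # grade IV is the more heterogeneous class in every directional sense
  co <- ens[[1]]
  g <- function(p, gr) mean(co[[p]][co$who_grade == gr])
  expect_lt(g("ADCmin", "IV"), g("ADCmin", "III"))
  expect_lt(g("ADCp10", "IV"), g("ADCp10", "III"))
  expect_gt(g("ADCmax", "IV"), g("ADCmax", "III"))
  expect_gt(g("Skewness", "IV"), g("Skewness", "III"))
  expect_true(all(co$ki67 >= 0 & co$ki67 <= 100))
})

test_that("cohort-level profile means recover the generator's population means", {
  co <- simulate_feature_cohort(synthetic_config(rng_seed = 12))
  truth <- attr(co, "ground_truth")
  # per-patient observed mean vs planted mean, pooled over the cohort
  expect_equal(nrow(co), 56)
  diffs <- co$ADCmean - truth$planted_mean / 1e-5
  se <- (truth$planted_sd / 1e-5) / sqrt(truth$n_voxels)
  expect_gte(mean(abs(diffs) <= 3 * se), 0.95)
  # group mean of planted grade III locations ~ 137 (3 SE of the between SD)
  m3 <- mean(truth$planted_mean[truth$who_grade == "III"]) / 1e-5
  expect_lt(abs(m3 - 137), 3 * 22 / sqrt(11))
})

test_that("rendered volumes match the analytic ellipsoid and the feature-level draw", {
  cfg <- synthetic_config(rng_seed = 8)
  p <- simulate_patient_params(cfg, 30) # grade IV
  vol <- simulate_volume(p, cfg)

  # mask voxel count = lattice points inside the ellipsoid
  geo <- cfg$geometry
  centre <- (geo$grid - 1) / 2
  idx <- expand.grid(i = seq_len(geo$grid[1]) - 1,
                     j = seq_len(geo$grid[2]) - 1,
                     k = seq_len(geo$grid[3]) - 1)
  n_inside <- sum(((idx$i - centre[1]) / geo$semi_axes[1])^2 +
                  ((idx$j - centre[2]) / geo$semi_axes[2])^2 +
                  ((idx$k - centre[3]) / geo$semi_axes[3])^2 <= 1)
  expect_equal(sum(vol$mask$voxels), n_inside)

  # two-path consistency: volume-rendered marginal vs direct draw
  s <- extract_sample(vol$adc, vol$mask)
  set.seed(1234)
  direct <- adchist:::draw_patient_voxels(p, n = 5e4)
  se <- p$planted_sd / sqrt(s$n_voxels)
  expect_lt(abs(mean(s$values) - mean(direct)), 3 * se + 1e-7)
  expect_lt(abs(sd(s$values) - sd(direct)) / sd(direct), 0.10)

  # zero-variance patient renders a constant lesion with zero entropy
  cfg0 <- synthetic_config(
    n_grade3 = 2, n_grade4 = 0,
    grade3 = list(location_mean = 100e-5, location_sd = 0,
                  within_sd_mean = 0, within_sd_sd = 0),
    rng_seed = 5)
  v0 <- simulate_volume(simulate_patient_params(cfg0, 1), cfg0)
  s0 <- extract_sample(v0$adc, v0$mask)
  expect_equal(unique(s0$values), 100e-5)
  p0 <- suppressWarnings(compute_profile(s0))
  expect_equal(p0$Entropy, 0)

  # ellipsoid larger than the grid is a geometry error
  cfg_big <- synthetic_config(
    geometry = list(grid = c(10L, 10L, 10L), semi_axes = c(8, 8, 8),
                    spacing = c(1, 1, 1), field_sigma = 1, background = 0))
  expect_error(simulate_volume(simulate_patient_params(cfg_big, 1), cfg_big),
               class = "adchist_geometry_error")
})

test_that("fixture sets are reproducible, checksummed and analysable end to end", {
  cfg <- synthetic_config(n_grade3 = 5, n_grade4 = 7, rng_seed = 21,
                          n_voxels_range = c(500, 2000))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  man1 <- write_fixture_set(cfg, d1, volumes = TRUE)
  man2 <- write_fixture_set(cfg, d2, volumes = TRUE)
  expect_true(verify_fixture_set(d1))
  expect_identical(readLines(file.path(d1, "features.csv")),
                   readLines(file.path(d2, "features.csv")))
  expect_identical(man1$md5, man2$md5)

  # full pipeline on the written fixtures: extract -> profile -> compare
  adc_paths <- file.path(d1, sprintf("adc_P%03d.nii", 1:12))
  mask_paths <- file.path(d1, sprintf("mask_P%03d.nii", 1:12))
  prof <- suppressMessages(
    run_extract(adc_paths, mask_paths,
                patient_ids = sprintf("P%03d", 1:12),
                config = run_config(unit_scale_in = "mm2/s")))
  expect_equal(nrow(prof), 12)
  truth <- readr::read_csv(file.path(d1, "ground_truth.csv"),
                           show_col_types = FALSE)
  co <- dplyr::inner_join(prof,
                          truth[, c("patient_id", "who_grade", "ki67", "mgmt")],
                          by = "patient_id")
  cmp <- tidy(compare_groups(co, "grade", "ADCsd"))
  expect_lt(cmp$p_value, 0.05) # the planted SD effect is detectable
})
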