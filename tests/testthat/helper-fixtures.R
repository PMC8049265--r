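# Shared fixtures built in code. The 50-seed default-cohort ensemble is
# expensive, so it is generated once per test run and reused by every test
# that needs it.

.fixture_cache <- new.env(parent = emptyenv())

default_cohort_ensemble <- function(n_seeds = 50) {
  key <- paste0("ens", n_seeds)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- lapply(seq_len(n_seeds), function(s) {
      simulate_feature_cohort(synthetic_config(rng_seed = s))
    })
  }
  .fixture_cache[[key]]
}

# small deterministic cohort tibble built directly from numbers (no RNG),
# for exercising the statistics layer without the generator
toy_cohort <- function() {
  set.seed(421)
  n3 <- 8; n4 <- 12
  tibble::tibble(
    patient_id = sprintf("T%02d", 1:(n3 + n4)),
    who_grade = rep(c("III", "IV"), c(n3, n4)),
    ADCmean = c(rnorm(n3, 137, 10), rnorm(n4, 137, 10)),
    ADCmin = c(rnorm(n3, 60, 8), rnorm(n4, 34, 8)),
    ADCmax = c(rnorm(n3, 232, 20), rnorm(n4, 300, 20)),
    ADCp10 = c(rnorm(n3, 108, 8), rnorm(n4, 92, 8)),
    ADCp25 = c(rnorm(n3, 121, 10), rnorm(n4, 107, 10)),
    ADCp75 = c(rnorm(n3, 153, 12), rnorm(n4, 164, 12)),
    ADCp90 = c(rnorm(n3, 167, 12), rnorm(n4, 192, 12)),
    ADCmedian = c(rnorm(n3, 136, 10), rnorm(n4, 132, 10)),
    ADCmode = c(rnorm(n3, 136, 15), rnorm(n4, 129, 15)),
    ADCsd = c(rnorm(n3, 23, 3), rnorm(n4, 40, 6)),
    Kurtosis = c(rnorm(n3, 4, 1), rnorm(n4, 5, 1)),
    Skewness = c(rnorm(n3, 0.1, 0.3), rnorm(n4, 0.9, 0.3)),
    Entropy = c(rnorm(n3, 4.8, 0.3), rnorm(n4, 4.7, 0.3)),
    n_voxels = 5000L, bin_count = 128L,
    ki67 = pmin(pmax(c(rnorm(n3, 15, 8), rnorm(n4, 28, 10)), 0), 100),
    mgmt = rep(c("methylated", "unmethylated"), 10)
  )
}

# tiny planted-distribution ADC volume + mask pair on disk
write_nifti_pair <- function(dir, mean = 130e-5, sd = 25e-5, n_side = 12,
                             seed = 99) {
  set.seed(seed)
  grid <- c(n_side, n_side, 6)
  vox <- array(pmax(rnorm(prod(grid), mean, sd), 0), dim = grid)
  mask <- array(0L, dim = grid)
  mask[3:(n_side - 2), 3:(n_side - 2), 2:5] <- 1L
  aff <- diag(c(2, 2, 4, 1))
  ap <- file.path(dir, "adc.nii.gz")
  mp <- file.path(dir, "mask.nii.gz")
  write_volume_nifti(adc_volume(vox, aff), ap, unit_scale = "mm2/s")
  write_volume_nifti(lesion_mask(mask, aff), mp)
  list(adc = ap, mask = mp, mean = mean, sd = sd,
       n_fg = sum(mask), voxels = vox, mask_arr = mask)
}
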