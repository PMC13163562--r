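test_that("cohorts are deterministic under a fixed seed and differ across seeds", {
  a <- generate_cohort(sim_config(n = 30, seed = 5))
  b <- generate_cohort(sim_config(n = 30, seed = 5))
  c <- generate_cohort(sim_config(n = 30, seed = 6))
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$scan_ctdivol_mgy, c$scan_ctdivol_mgy)))
})

test_that("growing a cohort appends patients without reshuffling earlier ones", {
  small <- generate_cohort(sim_config(n = 20, seed = 3))
  large <- generate_cohort(sim_config(n = 50, seed = 3))
  expect_identical(small, large[1:20, ])
})

test_that("the generator leaves the caller's RNG state untouched", {
  set.seed(101)
  before <- .Random.seed
  invisible(generate_cohort(sim_config(n = 5, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("generated values respect every truncation bound", {
  exams <- generate_cohort(sim_config(n = 500, seed = 21))
  prof <- anthropometric_profile()
  in_bounds <- function(x, b) all(x >= b[1] & x <= b[2])
  expect_true(in_bounds(exams$age_years, prof$bounds$age))
  expect_true(in_bounds(exams$weight_kg, prof$bounds$weight))
  expect_true(in_bounds(exams$height_cm, prof$bounds$height))
  expect_true(in_bounds(exams$lat_dim_a_cm, prof$bounds$lat_dim_a))
  expect_true(in_bounds(exams$ap_dim_b_cm, prof$bounds$ap_dim_b))
  topo <- topogram_protocol()
  expect_true(in_bounds(exams$topo_ctdivol_mgy, topo$ctdi_bounds))
  expect_true(in_bounds(exams$topo_dlp_mgycm, topo$dlp_bounds))
  expect_true(in_bounds(exams$topo_length_mm, topo$length_bounds))
  expect_true(in_bounds(exams$scan_length_mm, c(341, 445)))
  expect_true(all(exams$sex %in% c("F", "M")))
  # scan DLP consistent with CTDIvol x length up to the multiplicative jitter
  ratio <- exams$scan_dlp_mgycm /
    (exams$scan_ctdivol_mgy * exams$scan_length_mm / 10)
  expect_true(all(abs(log(ratio)) < 5 * 0.02))
})

test_that("a noise-free patient at the reference diameter gets the baseline CTDIvol", {
  eps <- 1e-9
  prof <- anthropometric_profile(
    male = list(age = c(60, eps), weight = c(80, eps), height = c(175, eps),
                lat_dim_a = c(29.41, eps), ap_dim_b = c(29.41, eps)),
    female = list(age = c(60, eps), weight = c(61, eps), height = c(158, eps),
                  lat_dim_a = c(29.41, eps), ap_dim_b = c(29.41, eps)),
    bounds = list(age = c(31.22, 77.92), weight = c(52, 106),
                  height = c(152, 193), lat_dim_a = c(26.47, 39.78),
                  ap_dim_b = c(21.56, 31.05))
  )
  tcm <- tcm_model(baseline_ctdi = 1.27, lognormal_noise_sd = 0)
  exams <- generate_cohort(sim_config(n = 3, seed = 1, profile = prof,
                                      tcm = tcm))
  expect_equal(exams$scan_ctdivol_mgy, rep(1.27, 3), tolerance = 1e-6)
})

test_that("the TCM exponent is recovered exactly from a noise-free cohort", {
  cfg <- sim_config(n = 60, seed = 8,
                    tcm = tcm_model(size_exponent = 0.08,
                                    lognormal_noise_sd = 0),
                    dlp_jitter_sd = 0)
  fit <- fit_tcm_exponent(generate_cohort(cfg))
  expect_equal(fit$estimate, 0.08, tolerance = 1e-6)
})

test_that("a size-independent protocol yields a slope CI covering zero", {
  cfg <- sim_config(n = 221, seed = 12,
                    tcm = tcm_model(size_exponent = 0,
                                    lognormal_noise_sd = 0.15))
  fit <- fit_tcm_exponent(generate_cohort(cfg))
  expect_true(fit$conf_int[1] <= 0 && 0 <= fit$conf_int[2])
})

test_that("degenerate designs and bad configurations are rejected", {
  exams <- make_exams(n = 12)  # constant chest dimensions
  expect_error(fit_tcm_exponent(exams), class = "ctdose_singular_design")
  expect_error(fit_tcm_exponent(make_exams(n = 5)),
               class = "ctdose_insufficient_data")
  expect_error(sim_config(n = 0), class = "ctdose_config_error")
  expect_error(tcm_model(baseline_ctdi = -1), class = "ctdose_config_error")
  expect_error(anthropometric_profile(male_fraction = 1.2),
               class = "ctdose_config_error")
  expect_error(topogram_protocol(ctdi_bounds = c(0.2, 0.1)),
               class = "ctdose_config_error")
  # config error messages list every violation
  err <- tryCatch(sim_config(n = -1, seed = 1.5), condition = identity)
  expect_match(conditionMessage(err), "`n` must be")
  expect_match(conditionMessage(err), "`seed` must be")
})

test_that("weight and chest dimensions share the latent size factor", {
  exams <- generate_cohort(sim_config(n = 600, seed = 33))
  males <- exams[exams$sex == "M", ]
  expect_gt(cor(males$weight_kg, males$lat_dim_a_cm), 0.35)
  expect_gt(cor(males$lat_dim_a_cm, males$ap_dim_b_cm), 0.35)
})
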