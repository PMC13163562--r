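test_that("BMI, effective diameter and dose products match hand-computed values", {
  expect_equal(compute_bmi(100, 200), 25.0)
  expect_equal(compute_bmi(72.70, 168.15), 25.71228, tolerance = 1e-6)
  expect_equal(compute_bmi(52, 152), 22.50693, tolerance = 1e-6)

  expect_equal(compute_effective_diameter(30, 30), 30)
  expect_equal(compute_effective_diameter(34.06, 25.43), 29.43036,
               tolerance = 1e-6)
  expect_equal(compute_effective_diameter(26.47, 21.56), 23.88919,
               tolerance = 1e-6)

  expect_equal(compute_ssde(1.0, 1.26), 1.26)
  expect_equal(compute_ssde(2.14, 1.0), 2.14)
  expect_equal(compute_ssde(1.33, k_factor(29.41)), 1.673262,
               tolerance = 1e-5)

  expect_equal(compute_dlpss(50, 1.0), 50)
  expect_equal(compute_dlpss(24.00, 1.53), 36.72)
  expect_equal(compute_dlpss(10, 1.5), 15)

  expect_equal(compute_effective_dose(50.35), 0.7049)
  expect_equal(compute_effective_dose(286.51), 4.01114)
  expect_equal(compute_effective_dose(0), 0)

  expect_equal(topogram_contribution(5.15, 50.35), 10.2284, tolerance = 1e-5)
  expect_equal(topogram_contribution(5.28, 286.51), 1.842868,
               tolerance = 1e-5)
  expect_equal(topogram_contribution(5, 5), 100)
})

test_that("invalid physical inputs are rejected by name", {
  expect_error(compute_bmi(-70, 170), class = "ctdose_invalid_input")
  expect_error(compute_bmi(70, 0), "height_cm",
               class = "ctdose_invalid_input")
  expect_error(compute_effective_diameter(-1, 20),
               class = "ctdose_invalid_input")
  expect_error(compute_ssde(-0.1, 1.2), class = "ctdose_invalid_input")
  expect_error(compute_ssde(1.0, 0), class = "ctdose_invalid_input")
  expect_error(compute_dlpss(-5, 1.2), class = "ctdose_invalid_input")
  expect_error(compute_effective_dose(-1), class = "ctdose_invalid_input")
  expect_error(topogram_contribution(5, 0), class = "ctdose_invalid_input")
  expect_error(dose_coefficients(0), class = "ctdose_invalid_input")
})

test_that("effective diameter is symmetric and dose products are linear", {
  set.seed(11)
  a <- runif(50, 20, 40)
  b <- runif(50, 18, 32)
  expect_equal(compute_effective_diameter(a, b),
               compute_effective_diameter(b, a))
  alpha <- runif(50, 0, 3)
  dlp <- runif(50, 10, 90)
  k <- runif(50, 1, 1.6)
  expect_equal(compute_dlpss(alpha * dlp, k), alpha * compute_dlpss(dlp, k))
})

test_that("derive_exams composes the per-exam chain and keeps the k identity", {
  exams <- make_exams(n = 4, scan_dlp_mgycm = c(50, 60, 24, 86))
  d <- derive_exams(exams)
  expect_equal(d$deff_cm, rep(29.43036, 4), tolerance = 1e-6)
  expect_equal(d$dlpss_mgycm, exams$scan_dlp_mgycm * k_factor(29.43036),
               tolerance = 1e-6)
  # conservation of the size-correction ratio
  expect_equal(d$dlpss_mgycm / d$scan_dlp_mgycm, d$k, tolerance = 1e-9)
  expect_equal(d$ssde_mgy / d$scan_ctdivol_mgy, d$k, tolerance = 1e-9)
  expect_equal(d$delta_length_mm, rep(403 - 386.55, 4))
  expect_equal(d$effective_dose_msv, exams$scan_dlp_mgycm * 0.014)
  expect_equal(d$topogram_fraction_pct,
               100 * exams$topo_dlp_mgycm / exams$scan_dlp_mgycm)
})

test_that("a unit conversion factor propagates doses unchanged", {
  # model constructed so k(Deff) = 1 exactly at the fixture's diameter
  deff <- compute_effective_diameter(34.06, 25.43)
  b <- 0.03671937
  model <- k_factor_model(coeff_a = exp(b * deff), coeff_b = b)
  d <- derive_exams(make_exams(), model = model)
  expect_equal(d$ssde_mgy, d$scan_ctdivol_mgy, tolerance = 1e-12)
  expect_equal(d$dlpss_mgycm, d$scan_dlp_mgycm, tolerance = 1e-12)
})

test_that("derive_exams names the offending patient on range errors", {
  exams <- make_exams(n = 2, lat_dim_a_cm = c(34.06, 300),
                      ap_dim_b_cm = c(25.43, 300))
  expect_error(derive_exams(exams), "P002", class = "ctdose_range_error")
  d <- suppressWarnings(derive_exams(exams, clamp_deff = TRUE))
  expect_equal(d$k[2], k_factor(45))
})
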