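test_that("a single noise-free power-law component is returned analytically", {
  m <- emulsion_model(power_law(2, 3), q_range = c(1e-3, 1e-1), n_points = 50)
  cv <- generate_emulsion_curve(m)
  expect_equal(cv$intensity, 2 * cv$q^-3, tolerance = 1e-12)
})

test_that("generation is deterministic given the seed", {
  m1 <- emulsion_model(power_law(1, 2), noise = 0.05, seed = 5,
                       q_range = c(1e-3, 1e-1), n_points = 60)
  a <- generate_emulsion_curve(m1)
  b <- generate_emulsion_curve(m1)
  expect_identical(a$intensity, b$intensity)
  m2 <- emulsion_model(power_law(1, 2), noise = 0.05, seed = 6,
                       q_range = c(1e-3, 1e-1), n_points = 60)
  expect_false(identical(generate_emulsion_curve(m2)$intensity, a$intensity))
})

test_that("invalid models are rejected with the offending fields", {
  expect_error(emulsion_model(power_law(1, 7)), "exponent",
               class = "scatterprint_validation_error")
  expect_error(emulsion_model(gaussian_peak(10, 0.1, 1), q_range = c(1e-3, 1)),
               "position", class = "scatterprint_validation_error")
  expect_error(emulsion_model(power_law(-1, 2)), "amplitude",
               class = "scatterprint_validation_error")
})

test_that("sphere curves carry a -4 slope after desmearing and recover the radius", {
  cv <- sphere_fixture()
  sm <- slit_smear(cv, 0.015)
  ds <- desmear(sm)
  sel <- ds$q >= 1.5e-3
  slope <- coef(lm(log(ds$intensity[sel]) ~ log(ds$q[sel])))[[2]]
  expect_equal(slope, -4, tolerance = 0.1 / 4)
  res <- specific_surface(porod_plateau(ds), 7.7e-7, 0.05)
  # truth for the lognormal: r_eq = 3 / S with S from the analytic moments
  r_true <- 3 / lognormal_specific_surface_cm(0.5, 0.2) * 1e4
  expect_equal(res$equivalent_radius_um, r_true, tolerance = 0.05)
})

test_that("generated composition tables satisfy the reader's schema", {
  set <- generate_sample_set(n_samples = 29, seed = 3, n_points = 60)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(set$composition, path, row.names = FALSE)
  back <- read_composition_table(path)
  expect_equal(nrow(back), 29L)
  expect_setequal(unique(back$category), c("milk", "yoghurt", "cream"))
  expect_true(all(back$fat >= 1 & back$fat <= 36))
  expect_true(all(back$carbohydrate >= 0 & back$carbohydrate <= 13))
  expect_true(all(back$protein >= 0.1 & back$protein <= 5))
})

test_that("planted noise degrades the fat correlation as the oracle predicts", {
  noise <- 1.2
  # oracle: the same composition panel and multiplicative noise applied at
  # the intensity level, 10000 replicates
  withr::with_seed(21, {
    oracle <- replicate(10000, {
      f <- numeric(29)
      f[21:29] <- seq(3, 36, length.out = 9)[sample.int(9)]
      f[1:20] <- seq(1, 2.8, length.out = 20)[sample.int(20)]
      cor(f, f * exp(rnorm(29, 0, noise)), method = "spearman")
    })
  })
  ci <- quantile(oracle, c(0.025, 0.975))
  expect_lt(abs(mean(oracle) - 0.6), 0.1) # calibrated regime
  set <- generate_sample_set(n_samples = 29, noise = noise, seed = 8, n_points = 150)
  rep <- correlate_composition(set$curves, set$composition)
  rho <- rep$rho[rep$q_probe == 0.0003]
  expect_gt(rho, ci[1])
  expect_lt(rho, ci[2])
})

test_that("monodisperse DLS correlation functions decay at D q^2", {
  g2 <- generate_dls_correlation(median_radius = 1500, spread = 0)
  cf <- cumulant_pdi(g2)
  expect_lt(cf$pdi, 1e-3)
  # independent: Stokes-Einstein rate at the backscatter optics
  kb <- 1.380649e-23
  D <- kb * 298.15 / (6 * pi * 8.9e-4 * 1500e-10)
  qv <- 4 * pi * 1.33 * sin(173 / 2 * pi / 180) / 633e-9
  expect_equal(cf$a1, D * qv^2, tolerance = 1e-3)
})

test_that("polydisperse DLS recovers the intensity-weighted rate variance", {
  g2 <- generate_dls_correlation(median_radius = 1500, spread = 0.3)
  cf <- cumulant_pdi(g2)
  # oracle: direct numeric integration over the planted size distribution,
  # independent of the generator's internal weights
  z <- seq(-6, 6, length.out = 4001)
  w <- dnorm(z); w <- w / sum(w)
  r <- 1500 * exp(0.3 * z)
  wi <- w * r^6; wi <- wi / sum(wi)
  kb <- 1.380649e-23
  qv <- 4 * pi * 1.33 * sin(173 / 2 * pi / 180) / 633e-9
  gam <- kb * 298.15 / (6 * pi * 8.9e-4 * r * 1e-10) * qv^2
  gm <- sum(wi * gam)
  relvar <- sum(wi * (gam - gm)^2) / gm^2
  expect_equal(cf$pdi, relvar, tolerance = 0.1)
})

test_that("DLS generation validates optics and is seed-deterministic", {
  expect_error(generate_dls_correlation(median_radius = -5),
               class = "scatterprint_domain_error")
  expect_error(generate_dls_correlation(wavelength = 0),
               class = "scatterprint_domain_error")
  a <- generate_dls_correlation(noise = 0.01, seed = 4)
  b <- generate_dls_correlation(noise = 0.01, seed = 4)
  expect_identical(a$g2, b$g2)
})

test_that("generated curves pass downstream preconditions end to end", {
  set <- generate_sample_set(n_samples = 6, seed = 13, n_points = 150)
  for (cv in set$curves) {
    expect_s3_class(cv, "scattering_curve")
    g <- resample_loglog(cv, 50)
    expect_true(all(is.finite(g$intensity)))
  }
  fp <- build_fingerprint(set$curves, n_points = 60)
  expect_equal(length(fp$samples), 6L)
})
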