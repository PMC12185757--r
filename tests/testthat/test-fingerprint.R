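test_that("power laws resample exactly and the grid hits the curve endpoints", {
  cv <- power_law_curve(A = 3, p = 2.5, q_range = c(1e-3, 1e-1), n = 87)
  g <- resample_loglog(cv, n_points = 100)
  expect_equal(nrow(g), 100L)
  expect_equal(g$intensity, 3 * g$q^(-2.5), tolerance = 1e-12)
  expect_equal(g$q[1], min(cv$q))
  expect_equal(g$q[100], max(cv$q))
  # constant ratio between neighbours
  expect_lt(diff(range(diff(log(g$q)))), 1e-12)
})

test_that("resampling rejects narrow or fully masked curves", {
  narrow <- power_law_curve(q_range = c(0.01, 0.05), n = 30)
  expect_error(resample_loglog(narrow), class = "scatterprint_range_error")
  q <- exp(seq(log(0.01), log(1), length.out = 20))
  dead <- scattering_curve(q, rep(-1, 20))
  expect_error(resample_loglog(dead), class = "scatterprint_nodata_error")
})

test_that("log-log gradients of power laws and constants are exact", {
  cv <- power_law_curve(A = 1, p = 4, q_range = c(1e-3, 1e-1), n = 60)
  g <- loglog_gradient(resample_loglog(cv, 50))
  expect_equal(nrow(g), 49L)
  expect_true(all(abs(g$gradient + 4) < 1e-9))
  expect_true(all(abs(g$modulus - 4) < 1e-9))
  const <- scattering_curve(cv$q, rep(2, 60))
  gc <- loglog_gradient(resample_loglog(const, 50))
  expect_true(all(abs(gc$gradient) < 1e-9))
})

test_that("the gradient changes sign at a planted peak apex", {
  m <- emulsion_model(power_law(0.01, 2), gaussian_peak(0.15, 0.015, 10),
                      q_range = c(0.01, 1), n_points = 500)
  cv <- generate_emulsion_curve(m)
  g <- loglog_gradient(resample_loglog(cv, 200))
  step <- diff(log(g$q))[1]
  near <- which(abs(log(g$q / 0.15)) < 3 * step)
  expect_true(any(g$gradient[near] > 0) && any(g$gradient[near] < 0))
  # modulus has a local maximum on each flank of the peak
  flank_lo <- g$modulus[g$q > 0.09 & g$q < 0.14]
  expect_gt(max(flank_lo), max(g$modulus[g$q < 0.09]))
})

test_that("normalisation maps to [0,1] and ignores intensity scale", {
  cv <- sphere_fixture(q_range = c(3e-4, 5e-2), n = 80)
  g <- resample_loglog(cv, 60)
  nm <- normalize_intensity(g)
  expect_equal(min(nm$intensity), 0)
  expect_equal(max(nm$intensity), 1)
  g2 <- g; g2$intensity <- g2$intensity * 123
  expect_equal(normalize_intensity(g2)$intensity, nm$intensity)
  # monotone input stays monotone
  mono <- tibble::tibble(q = g$q, intensity = sort(g$intensity))
  expect_true(all(diff(normalize_intensity(mono)$intensity) >= 0))
  flatg <- tibble::tibble(q = g$q, intensity = rep(2, nrow(g)))
  expect_error(normalize_intensity(flatg), class = "scatterprint_normalization_error")
})

test_that("gradients classify into the conventional scattering regimes", {
  expect_equal(classify_regime(-4), "porod_surface")
  expect_equal(classify_regime(-3.2), "smeared_surface_or_steep")
  expect_equal(classify_regime(-2), "mass_fractal")
  expect_equal(classify_regime(0), "plateau")
  expect_equal(classify_regime(2), "rising_peak_flank")
  expect_equal(classify_regime(c(-3.5, -3, -1, 1)),
               c("porod_surface", "smeared_surface_or_steep", "mass_fractal",
                 "rising_peak_flank"))
})

test_that("fingerprint rows are deterministic and scale-invariant", {
  cv <- sphere_fixture(q_range = c(3e-4, 3e-2), n = 120)
  cv2 <- scattering_curve(cv$q, cv$intensity * 50, sample_id = "twin")
  fp <- build_fingerprint(list(a = cv, b = cv), n_points = 60)
  expect_equal(fp$normalized_intensity[1, ], fp$normalized_intensity[2, ])
  expect_equal(fp$gradient[1, ], fp$gradient[2, ])
  fps <- build_fingerprint(list(a = cv, b = cv2), n_points = 60)
  expect_equal(fps$normalized_intensity[1, ], fps$normalized_intensity[2, ])
  expect_equal(fps$gradient_modulus[1, ], fps$gradient_modulus[2, ])
})

test_that("a single power-law sample gives a uniform gradient row", {
  cv <- power_law_curve(A = 1, p = 3, q_range = c(1e-3, 1e-1), n = 100)
  fp <- build_fingerprint(list(s = cv), n_points = 50)
  expect_true(all(abs(fp$gradient_modulus[1, ] - 3) < 1e-9))
})

test_that("the lamellar band appears only in the cream-like fingerprint row", {
  base <- list(porod_sphere(0.5, 0.2, 0.05, 7.7e-7), water_halo(2, 0.3, 0.5),
               flat_background(0.01))
  milk <- generate_emulsion_curve(do.call(emulsion_model,
    c(base, list(q_range = c(3e-4, 3), n_points = 300))), sample_id = "milk - 1")
  cream <- generate_emulsion_curve(do.call(emulsion_model,
    c(base, list(list(type = "gaussian_peak", position = 0.15, width = 0.01, amplitude = 2)),
      list(q_range = c(3e-4, 3), n_points = 300))), sample_id = "cream - 2")
  fp <- build_fingerprint(list(`milk - 1` = milk, `cream - 2` = cream), n_points = 100)
  band <- abs(log(fp$q_mid / 0.15)) < 0.15
  expect_gt(max(fp$gradient_modulus[2, band]), 4)      # bright band in cream
  expect_lt(max(fp$gradient_modulus[1, band]), 2.5)    # absent in milk
})

test_that("rows are ordered by trailing sample number", {
  cv <- power_law_curve(q_range = c(1e-3, 1e-1), n = 50)
  fp <- build_fingerprint(list(`s - 10` = cv, `s - 2` = cv), n_points = 40)
  expect_equal(fp$samples, c("s - 2", "s - 10"))
})

test_that("inconsistent q-ranges are reported with the offending sample", {
  a <- power_law_curve(q_range = c(1e-3, 1e-1), n = 50, sample_id = "a")
  b <- power_law_curve(q_range = c(1e-3, 5e-2), n = 50, sample_id = "b")
  expect_error(build_fingerprint(list(a = a, b = b)), "b",
               class = "scatterprint_range_error")
})

test_that("grid refinement does not move gradients on smooth curves", {
  cv <- sphere_fixture(q_range = c(3e-4, 3e-2), n = 200)
  g50 <- loglog_gradient(resample_loglog(cv, 50))
  g100 <- loglog_gradient(resample_loglog(cv, 100))
  # compare on the coarse midpoints via interpolation of the fine result
  fine_at <- approx(log(g100$q), g100$gradient, xout = log(g50$q), rule = 2)$y
  expect_lt(max(abs(fine_at - g50$gradient)), 0.2)
})

test_that("tidy and autoplot expose both fingerprint layers", {
  cv <- power_law_curve(q_range = c(1e-3, 1e-1), n = 50)
  fp <- build_fingerprint(list(`x - 1` = cv), n_points = 40)
  td <- tidy(fp)
  expect_setequal(unique(td$layer), c("normalized_intensity", "gradient_modulus"))
  expect_equal(nrow(td), 40 + 39)
  p <- autoplot(fp)
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(fp, layer = "intensity"), "ggplot")
})
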