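test_that("intensity read-out is exact at nodes and for power laws", {
  cv <- power_law_curve(A = 2, p = 3, q_range = c(1e-3, 1e-1), n = 90)
  expect_equal(intensity_at_q(cv, cv$q[37]), cv$intensity[37])
  expect_equal(intensity_at_q(cv, 0.0123), 2 * 0.0123^-3, tolerance = 1e-12)
  expect_error(intensity_at_q(cv, 1e-4), class = "scatterprint_range_error")
})

test_that("perfect monotone relations give rho of +-1", {
  x <- c(0.3, 1.2, 2.8, 5.5, 9.1, 12)
  expect_equal(spearman_correlation(x, exp(x))$rho, 1)
  expect_equal(spearman_correlation(x, -x^3)$rho, -1)
})

test_that("exact permutation p-values match a brute-force enumeration oracle", {
  # oracle: loop over every permutation explicitly (independent of the
  # package's vectorised enumeration)
  brute_p <- function(x, y) {
    n <- length(x)
    rho_obs <- cor(x, y, method = "spearman")
    perms <- NULL
    gen <- function(v) if (length(v) == 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i) lapply(gen(v[-i]), function(p) c(v[i], p))))
    all_p <- gen(seq_len(n))
    hits <- vapply(all_p, function(p) {
      abs(cor(x, y[p], method = "spearman")) >= abs(rho_obs) - 1e-12
    }, logical(1))
    mean(hits)
  }
  x <- 1:5; y <- c(2, 1, 4, 3, 5)
  res <- spearman_correlation(x, y, method = "exact")
  expect_equal(res$rho, 0.8)
  expect_equal(res$p_value, brute_p(x, y))

  withr::with_seed(7, {
    for (k in 1:3) {
      xs <- rnorm(6); ys <- rnorm(6)
      expect_equal(spearman_correlation(xs, ys, method = "exact")$p_value,
                   brute_p(xs, ys))
    }
    # ties handled by midranks in both routes
    xt <- c(1, 2, 2, 3, 4, 5); yt <- rnorm(6)
    expect_equal(spearman_correlation(xt, yt, method = "exact")$p_value,
                 brute_p(xt, yt))
  })
})

test_that("exact and t-approximate p-values agree within a factor of 2 at n = 9", {
  withr::with_seed(11, {
    for (k in 1:5) {
      x <- rnorm(9); y <- rnorm(9)
      pe <- spearman_correlation(x, y, method = "exact")$p_value
      pt_ <- spearman_correlation(x, y, method = "t_approx")$p_value
      expect_lt(max(pe / pt_, pt_ / pe), 2)
    }
  })
})

test_that("spearman is a rank statistic and rejects degenerate input", {
  withr::with_seed(3, { x <- rnorm(12); y <- rnorm(12) })
  a <- spearman_correlation(x, y)
  b <- spearman_correlation(rank(x), rank(y))
  expect_equal(a$rho, b$rho)
  expect_error(spearman_correlation(rep(1, 6), rnorm(6)),
               class = "scatterprint_undefined_error")
  expect_error(spearman_correlation(1:3, 1:3), class = "scatterprint_format_error")
})

test_that("line fits recover exact lines and flag curvature", {
  x <- seq(0, 10, length.out = 20)
  lf <- linear_fit(x, 2 * x + 1)
  expect_equal(lf$slope, 2)
  expect_equal(lf$intercept, 1)
  expect_lt(max(abs(lf$residuals)), 1e-12)
  expect_equal(tidy(lf)$estimate, c(1, 2))
  expect_equal(glance(lf)$n, 20)

  quad <- linear_fit(x, x^2)
  expect_gt(max(abs(quad$residuals)), 1)

  withr::with_seed(5, {
    y <- 3 * x - 2 + rnorm(20, 0, 0.5)
    fit <- linear_fit(x, y)
    expect_lt(abs(fit$slope - 3), 2 * fit$slope_se)
  })
  expect_error(linear_fit(rep(1, 5), 1:5), class = "scatterprint_singular_error")
})

test_that("peak probes can correlate intensity above the local baseline", {
  set <- generate_sample_set(n_samples = 8, noise = 0, seed = 6, n_points = 200)
  probes <- tibble::tibble(q = 0.15, variable = "fat", baseline_subtract = TRUE)
  rep <- correlate_composition(set$curves, set$composition, probes)
  pairs <- rep$pairs[[1]]
  expect_true(all(pairs$intensity <= pairs$intensity_raw + 1e-12))
  # milk samples carry no lamellar peak: excess above baseline is negligible
  milk <- set$composition$sample[set$composition$category != "cream"]
  cream <- set$composition$sample[set$composition$category == "cream"]
  expect_lt(max(pairs$intensity[pairs$sample %in% milk]),
            min(pairs$intensity[pairs$sample %in% cream]))
})

test_that("planted monotone composition links are recovered exactly at zero noise", {
  set <- generate_sample_set(n_samples = 29, noise = 0, seed = 42, n_points = 200)
  rep <- correlate_composition(set$curves, set$composition)
  expect_equal(rep$rho[rep$q_probe == 0.0003], 1, tolerance = 1e-12)
  expect_equal(rep$rho[rep$q_probe == 0.10], 1, tolerance = 1e-12)
  expect_true(all(rep$p_value < 0.05))
})
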