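test_that("intensity histogram: explicit edges, conservation, tally oracle", {
  h <- intensity_histogram(c(1, 1, 1), breaks = c(0, 2))
  expect_equal(h$counts, 3)

  set.seed(3)
  x <- c(rnorm(600, 43000, 2000), rnorm(400, 86000, 3000))
  h2 <- intensity_histogram(x)
  expect_equal(sum(h2$counts), 1000)

  # counts match direct per-bin tallying on the same edges
  tally <- vapply(seq_len(length(h2$edges) - 1), function(i) {
    lo <- h2$edges[i]; hi <- h2$edges[i + 1]
    if (i == 1) sum(x >= lo & x <= hi) else sum(x > lo & x <= hi)
  }, numeric(1))
  expect_equal(h2$counts, tally)

  expect_error(intensity_histogram(numeric(0)), "at least one")
})

test_that("single-population limit collapses to K = 1", {
  set.seed(10)
  x <- rnorm(500, 43000, 0.05 * 43000)
  fit <- fit_multiplicity_mixture(x, K_max = 4, seed = 1)
  expect_equal(fit$K, 1L)
  expect_equal(fit$mu1, 43000, tolerance = 0.02)
  expect_equal(fit$fractions_pct, 100)
})

test_that("constrained mixture recovers a planted aggregate composition", {
  d <- draw_intensities(522, seed = 14)
  fit <- fit_multiplicity_mixture(d$x, K_max = 4, seed = 14)
  expect_equal(fit$mu1, 43000, tolerance = 0.05)
  truth_pct <- 100 * tabulate(d$k, 4) / length(d$k)
  expect_lt(abs(fit$fractions_pct[1] - truth_pct[1]), 3)
  expect_lt(abs(fit$fractions_pct[2] - truth_pct[2]), 3)
  # class means are hard-locked to integer multiples
  expect_equal(fit$means, seq_len(fit$K) * fit$mu1)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  # deterministic given seed
  fit2 <- fit_multiplicity_mixture(d$x, K_max = 4, seed = 14)
  expect_identical(fit$mu1, fit2$mu1)
  expect_identical(fit$weights, fit2$weights)
})

test_that("posterior classification agrees with direct density evaluation", {
  d <- draw_intensities(400, seed = 5, cv = 0.05)
  fit <- fit_multiplicity_mixture(d$x, K_max = 4, seed = 5)

  expect_equal(classify_multiplicity(fit, fit$mu1)$class, 1L)
  if (fit$K >= 2) {
    expect_equal(classify_multiplicity(fit, 2 * fit$mu1)$class, 2L)
  }

  got <- classify_multiplicity(fit, d$x)
  brute <- vapply(d$x, function(xi) {
    dens <- fit$weights * dnorm(xi, fit$means, fit$sigmas)
    which.max(dens)
  }, integer(1))
  expect_identical(got$class, brute)
  expect_true(all(got$posterior >= 0 & got$posterior <= 1))

  # at CV 5% the posterior rule agrees with nearest-integer-multiple of the
  # true mean in >= 99% of cases (both rules restricted to the fitted
  # classes: the classifier cannot emit a multiplicity beyond K)
  nearest <- pmin(fit$K, pmax(1, round(d$x / 43000)))
  expect_gte(mean(got$class == nearest), 0.99)

  expect_error(classify_multiplicity(fit, NaN), "non-finite")
})

test_that("mixture is scale-equivariant", {
  d <- draw_intensities(522, seed = 23)
  f1 <- fit_multiplicity_mixture(d$x, K_max = 4, seed = 23)
  f2 <- fit_multiplicity_mixture(d$x * 3, K_max = 4, seed = 23)
  expect_equal(f2$K, f1$K)
  expect_equal(f2$mu1 / f1$mu1, 3, tolerance = 1e-3)
  expect_equal(f2$sigmas / f1$sigmas, rep(3, f1$K), tolerance = 0.02)
  expect_equal(f2$weights, f1$weights, tolerance = 0.01)
})

test_that("BIC selects the planted number of classes when separated", {
  # two well-populated, well-separated classes: CV 5%, 150 objects each
  hits <- 0L
  for (seed in 1:20) {
    x <- withr::with_seed(seed, {
      k <- rep(1:2, each = 150)
      rnorm(300, k * 43000, 0.05 * k * 43000)
    })
    f <- fit_multiplicity_mixture(x, K_max = 4, seed = seed)
    hits <- hits + (f$K == 2L)
  }
  expect_gte(hits / 20, 0.95)
})

test_that("mu1 recovery is nearly unbiased at the study composition", {
  mu1s <- vapply(1:20, function(seed) {
    d <- draw_intensities(500, seed = 100 + seed)
    fit_multiplicity_mixture(d$x, K_max = 4, seed = seed)$mu1
  }, numeric(1))
  expect_lt(abs(mean(mu1s) / 43000 - 1), 0.02)
})

test_that("intensity-volume regression: exact line and closed form", {
  exact <- data.frame(volume_um3 = c(1, 2, 3, 4),
                      integrated_density = c(2, 4, 6, 8))
  # suppress lm's note about an exactly collinear fit
  f <- suppressWarnings(fit_intensity_volume(exact))
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  # closed-form least squares on a small noisy set
  set.seed(9)
  df <- data.frame(volume_um3 = runif(20, 0.05, 0.5))
  df$integrated_density <- 9e4 * df$volume_um3 + rnorm(20, 0, 500)
  f2 <- fit_intensity_volume(df)
  vx <- df$volume_um3 - mean(df$volume_um3)
  vy <- df$integrated_density - mean(df$integrated_density)
  slope_cf <- sum(vx * vy) / sum(vx^2)
  expect_equal(f2$slope, slope_cf, tolerance = 1e-10)
  expect_equal(f2$intercept,
               mean(df$integrated_density) - slope_cf * mean(df$volume_um3),
               tolerance = 1e-10)
  expect_equal(f2$r_squared, cor(df$volume_um3, df$integrated_density)^2,
               tolerance = 1e-12)

  expect_error(fit_intensity_volume(exact[1:2, ]), "at least 3")
  same <- data.frame(volume_um3 = rep(1, 5), integrated_density = 1:5)
  expect_error(fit_intensity_volume(same), "identical")
})

test_that("rendered objects show a strong intensity-volume correlation", {
  # noiseless field mixing multiplicities 1..3: integrated density grows
  # with apparent volume. The relation is strongly linear but mildly
  # convex by construction — a thresholded Gaussian spot's apparent volume
  # scales as (ln(peak/threshold))^(3/2) while its integrated density
  # scales as k — so r^2 sits a little below 1 even without noise.
  sc <- simulate_scene(spot_field_spec(30, seed = 77, min_sep = 2,
                                       dims = c(15, 384, 384),
                                       multiplicity_probs = c(.5, .3, .2, 0),
                                       read_noise_sd = 0,
                                       background_level = 0))
  objs <- segment_objects(get_channel(sc$stack, "reflection"),
                          filter_params(1), segmentation_params(),
                          sc$stack$spacing)
  expect_equal(nrow(objs), 30)
  f <- fit_intensity_volume(objs)
  expect_gte(f$r_squared, 0.95)
  expect_gt(f$slope, 0)
  # brightness terciles are ordered in apparent volume too
  vol_by_class <- tapply(objs$volume_um3,
                         cut(objs$integrated_density, 3), mean)
  expect_true(all(diff(na.omit(vol_by_class)) > 0))
})

test_that("area-ratio reporting mode matches weights for separated peaks", {
  d <- draw_intensities(522, seed = 31)
  fit <- fit_multiplicity_mixture(d$x, K_max = 4, seed = 31)
  expect_equal(area_fractions(fit), fit$fractions_pct, tolerance = 1e-9)
})
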