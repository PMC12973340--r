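test_that("fc_from_timeseries computes Pearson correlations with sentinels", {
  set.seed(1)
  x <- rnorm(50)
  series <- cbind(a = x, b = 2 * x + 1, c = -x, d = rnorm(50))
  fc <- fc_from_timeseries(series)
  expect_equal(unclass(fc)[1, 2], 1)
  expect_equal(unclass(fc)[1, 3], -1)
  expect_true(all(diag(fc) == 0))

  # long independent series have near-zero correlation
  set.seed(2)
  s2 <- cbind(rnorm(1e4), rnorm(1e4), rnorm(1e4))
  fc2 <- fc_from_timeseries(s2)
  expect_lt(max(abs(vectorize_upper(fc2))), 0.05)

  # constant series -> sentinel + warning
  s3 <- cbind(rnorm(20), rep(1, 20), rnorm(20))
  expect_warning(fc3 <- fc_from_timeseries(s3), "constant")
  expect_true(all(is.na(unclass(fc3)[2, -2])))

  # excluded parcels -> sentinel rows
  fc4 <- fc_from_timeseries(series, exclude = c(FALSE, TRUE, FALSE, FALSE))
  expect_true(all(is.na(unclass(fc4)[2, -2])))

  expect_error(fc_from_timeseries(series[1:2, ]),
               class = "connvae_format_error")
})

test_that("SC count normalization divides by total tracts and zeroes singletons", {
  counts <- matrix(0, 4, 4)
  counts[1, 2] <- counts[2, 1] <- 2000
  counts[1, 3] <- counts[3, 1] <- 1     # singleton -> 0
  counts[2, 4] <- counts[4, 2] <- 0
  sc <- normalize_sc_counts(counts, total_streamlines = 1e7)
  expect_equal(unclass(sc)[1, 2], 2e-4)
  expect_equal(unclass(sc)[1, 3], 0)
  expect_equal(unclass(sc)[2, 4], 0)
  counts[1, 4] <- counts[4, 1] <- -5
  expect_error(normalize_sc_counts(counts), class = "connvae_format_error")
})

test_that("the power-law exponent is recovered by the KS grid search", {
  set.seed(3)
  sc <- rlnorm(4000, meanlog = log(2e-4), sdlog = 1)
  # planted exponent 0.5
  fc_planted <- (sc / max(sc))^0.5
  fit <- fit_civier_exponent(sc, fc_planted)
  expect_lt(abs(fit$alpha - 0.5), 0.05)
  # already matched distributions need no transform
  fit1 <- fit_civier_exponent(sc, sc / max(sc))
  expect_lt(abs(fit1$alpha - 1), 0.05)
  # degenerate sample
  expect_warning(fit2 <- fit_civier_exponent(rep(0.1, 10), fc_planted),
                 "identical")
  expect_equal(fit2$alpha, 1)
  expect_error(fit_civier_exponent(c(0, sc), fc_planted),
               class = "connvae_format_error")
  # refitting the same inputs is deterministic
  expect_identical(fit$alpha, fit_civier_exponent(sc, fc_planted)$alpha)
})

test_that("KS distance agrees with the stats::ks.test oracle", {
  set.seed(4)
  x <- rnorm(300); y <- rnorm(400, mean = 0.3)
  d_pkg <- connvae:::ks_distance(x, y)
  d_oracle <- unname(suppressWarnings(stats::ks.test(x, y)$statistic))
  expect_equal(d_pkg, d_oracle, tolerance = 1e-12)
})

test_that("power transform is zero-preserving, bounded and monotone", {
  set.seed(5)
  counts <- matrix(0, 8, 8)
  ut <- upper.tri(counts)
  counts[ut] <- rpois(sum(ut), 40) * (runif(sum(ut)) < 0.6)
  counts <- counts + t(counts)
  sc <- normalize_sc_counts(counts, 1e5)
  params <- norm_params(alpha = 0.4, sc_max = max(unclass(sc)))
  out <- apply_power_transform(sc, params)
  expect_true(all(unclass(out)[unclass(sc) == 0] == 0))
  nz <- unclass(sc) > 0
  expect_true(all(unclass(out)[nz] > 0 & unclass(out)[nz] <= 1 - 1e-6))
  # ordering preserved
  v_in <- unclass(sc)[ut]; v_out <- unclass(out)[ut]
  expect_identical(order(v_in), order(v_out))
  # alpha = 1 is a pure rescale
  p1 <- norm_params(alpha = 1, sc_max = max(unclass(sc)))
  out1 <- apply_power_transform(sc, p1)
  expect_equal(unclass(out1)[nz],
               unclass(sc)[nz] / p1$sc_max * p1$sc_scale, tolerance = 1e-12)
  # zero matrix stays zero
  z <- conn_matrix(matrix(0, 4, 4), "SC")
  expect_true(all(unclass(apply_power_transform(z, params)) == 0))
})

test_that("artanh normalization matches the closed form and round-trips", {
  expect_equal(artanh_normalize(0), 0)
  expect_equal(artanh_normalize(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(artanh_normalize(0.5), log((1 + 0.5) / (1 - 0.5)) / 2)
  x <- c(-0.9, -0.1, 0.3, 0.8)
  expect_equal(tanh_denormalize(artanh_normalize(x)), x, tolerance = 1e-9)
  # clipping keeps the boundary finite
  expect_true(is.finite(artanh_normalize(1)))
  expect_error(artanh_normalize(Inf), class = "connvae_format_error")
})

test_that("upper-triangle vectorization is row-major and invertible", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 10; m[1, 3] <- m[3, 1] <- 20
  m[2, 3] <- m[3, 2] <- 30
  expect_equal(vectorize_upper(m), c(10, 20, 30))  # (1,2),(1,3),(2,3)
  expect_equal(devectorize_upper(c(10, 20, 30), 3), m)
  expect_length(vectorize_upper(matrix(0, 210, 210)), 21945L)
  expect_length(vectorize_upper(matrix(0, 2, 2)), 1L)
  r <- random_sym(9, seed = 6)
  expect_equal(devectorize_upper(vectorize_upper(r), 9), r)
  expect_error(devectorize_upper(1:5, 4), class = "connvae_format_error")
})

test_that("model vectors concatenate zFC then zSC", {
  p <- 4
  zfc <- random_sym(p, 7); zsc <- abs(random_sym(p, 8))
  v <- build_model_vector(zfc, zsc)
  expect_length(v, 12L)
  half <- length(v) / 2
  expect_equal(v[seq_len(half)], vectorize_upper(zfc))
  expect_equal(v[half + seq_len(half)], vectorize_upper(zsc))
  big <- matrix(0, 210, 210)
  expect_length(build_model_vector(big, big), 43890L)
  expect_error(build_model_vector(zfc, matrix(0, 5, 5)),
               class = "connvae_format_error")
})

test_that("the full SC chain is invertible away from clip boundaries", {
  spec <- tiny_sim_spec(seed = 19)
  tpl <- simulate_group_template(spec)
  s <- simulate_healthy_subject(tpl, spec, 77)
  sc <- normalize_sc_counts(s$sc_counts, spec$total_streamlines)
  params <- norm_params(alpha = 0.5, sc_max = max(unclass(sc)))
  sct <- apply_power_transform(sc, params)
  z <- artanh_normalize(sct, params$epsilon_clip)
  v <- vectorize_upper(z)
  back <- tanh_denormalize(devectorize_upper(v, nrow(z)))
  expect_equal(back, unclass(sct)[, ], tolerance = 1e-6)
})
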