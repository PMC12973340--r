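test_that("architecture mirrors the configuration", {
  cfg <- vae_config(input_length = 43890, seed = 5)
  expect_equal(cfg$beta_norm, 8 / 43890)
  vae <- build_vae(cfg)
  expect_equal(dim(vae$params$enc[[1]]$W), c(43890L, 512L))
  expect_equal(dim(vae$params$mu$W), c(128L, 8L))
  expect_equal(dim(vae$params$lv$W), c(128L, 8L))
  expect_equal(dim(vae$params$out$W), c(512L, 43890L))
  expect_length(vae$params$out$b, 43890L)
  # deterministic initialization
  vae2 <- build_vae(vae_config(input_length = 43890, seed = 5))
  expect_identical(vae$params, vae2$params)
})

test_that("the loss matches the closed-form KL and MSE terms", {
  cfg <- vae_config(input_length = 4, latent_dim = 1,
                    encoder_widths = c(3, 2))
  x <- matrix(c(0.1, 0.2, 0.3, 0.4), nrow = 1)
  # matched Gaussians: KL = 0; perfect reconstruction: recon = 0
  l0 <- vae_loss(x, x, matrix(0), matrix(0), cfg)
  expect_equal(l0$total, 0)
  expect_equal(l0$kl_term, 0)
  # one dimension, mean 1, logvar 0: KL = 0.5
  l1 <- vae_loss(x, x, matrix(1), matrix(0), cfg)
  expect_equal(l1$kl_term, 0.5)
  expect_equal(l1$total, cfg$beta_norm * 0.5)
  # beta_norm = 0 reduces to a plain autoencoder objective
  cfg0 <- vae_config(input_length = 4, latent_dim = 1,
                     encoder_widths = c(3, 2), beta = 0)
  l2 <- vae_loss(x, x + 0.1, matrix(1), matrix(0.3), cfg0)
  expect_identical(l2$total, l2$recon_term)
})

test_that("backpropagated gradients match numerical differentiation", {
  cfg <- vae_config(input_length = 6, latent_dim = 2,
                    encoder_widths = c(5, 4), seed = 9)
  vae <- build_vae(cfg)
  set.seed(10)
  X <- matrix(rnorm(3 * 6), 3, 6)
  eps <- matrix(rnorm(3 * 2), 3, 2)
  loss_at <- function(params) {
    f <- connvae:::vae_forward(params, cfg, X, eps)
    vae_loss(X, f$xhat, f$mu, f$lv, cfg)$total
  }
  gr <- connvae:::vae_grad(vae$params, cfg, X, eps)
  h <- 1e-6
  check_leaf <- function(get, set, grad_val, idx) {
    p_plus <- set(vae$params, get(vae$params)[idx] + h, idx)
    p_minus <- set(vae$params, get(vae$params)[idx] - h, idx)
    num <- (loss_at(p_plus) - loss_at(p_minus)) / (2 * h)
    expect_equal(grad_val[idx], num, tolerance = 1e-4)
  }
  # encoder first-layer weight
  check_leaf(function(p) p$enc[[1]]$W,
             function(p, v, i) { p$enc[[1]]$W[i] <- v; p },
             gr$grads$enc[[1]]$W, 7)
  # log-variance head weight (touches both KL and sampling paths)
  check_leaf(function(p) p$lv$W,
             function(p, v, i) { p$lv$W[i] <- v; p },
             gr$grads$lv$W, 3)
  # decoder weight and output bias
  check_leaf(function(p) p$dec[[2]]$W,
             function(p, v, i) { p$dec[[2]]$W[i] <- v; p },
             gr$grads$dec[[2]]$W, 11)
  check_leaf(function(p) p$out$b,
             function(p, v, i) { p$out$b[i] <- v; p },
             gr$grads$out$b, 2)
})

make_toy_data <- function(n, seed, input_length = 20) {
  set.seed(seed)
  base <- rnorm(input_length)
  t(vapply(seq_len(n), function(i) base + rnorm(input_length, sd = 0.1),
           numeric(input_length)))
}

test_that("training reduces validation loss and is seed-deterministic", {
  train <- make_toy_data(24, 1)
  val <- make_toy_data(8, 2)
  cfg <- vae_config(input_length = 20, latent_dim = 2,
                    encoder_widths = c(16, 8), max_epochs = 60,
                    patience = 60, batch_size = 8, seed = 4)
  m1 <- train_vae(train, val, cfg)
  expect_lt(m1$best_val_loss, m1$history$val_total[1])
  expect_equal(m1$provenance, "healthy_trained")
  m2 <- train_vae(train, val, cfg)
  expect_identical(m1$history, m2$history)
})

test_that("early stopping honors the patience budget", {
  train <- make_toy_data(16, 3)
  val <- make_toy_data(6, 4)
  cfg <- vae_config(input_length = 20, latent_dim = 2,
                    encoder_widths = c(8, 4), max_epochs = 100, patience = 5,
                    learning_rate = 0, seed = 6)  # lr 0: loss never improves
  m <- train_vae(train, val, cfg)
  expect_lte(nrow(m$history), 6L)
})

test_that("fine-tuning adapts a healthy model to a shifted domain", {
  train <- make_toy_data(24, 5)
  val <- make_toy_data(8, 6)
  cfg <- vae_config(input_length = 20, latent_dim = 2,
                    encoder_widths = c(16, 8), max_epochs = 50, patience = 50,
                    seed = 7)
  healthy <- train_vae(train, val, cfg)
  # patient domain: constant shift
  ptrain <- make_toy_data(7, 8) + 0.8
  pval <- make_toy_data(3, 9) + 0.8
  before <- connvae:::eval_split(healthy$params, healthy$config, pval)$total
  tuned <- fine_tune(healthy, ptrain, pval,
                     config_override = list(max_epochs = 50, patience = 50))
  expect_equal(tuned$provenance, "fine_tuned")
  expect_lte(tuned$best_val_loss, before)
  # zero-epoch fine-tuning keeps the weights
  same <- fine_tune(healthy, ptrain, pval,
                    config_override = list(max_epochs = 0))
  expect_identical(same$params, healthy$params)
  # only healthy-trained models may be fine-tuned
  expect_error(fine_tune(tuned, ptrain, pval),
               class = "connvae_format_error")
})

test_that("reconstruction respects the output-domain contracts", {
  p <- 8
  input_length <- p * (p - 1)
  cfg <- vae_config(input_length = input_length, latent_dim = 2,
                    encoder_widths = c(12, 6), max_epochs = 10, patience = 10,
                    seed = 11)
  train <- make_toy_data(12, 12, input_length)
  m <- train_vae(train, make_toy_data(4, 13, input_length), cfg)
  rec <- reconstruct_subject(m, train[1, ], p)
  expect_true(all(abs(unclass(rec$fc_recon)) < 1))
  expect_true(all(unclass(rec$sc_recon) >= 0))
  expect_true(all(unclass(rec$sc_recon) < 1))
  expect_true(all(diag(rec$fc_recon) == 0))
  # inference is deterministic
  rec2 <- reconstruct_subject(m, train[1, ], p)
  expect_identical(unclass(rec$fc_recon)[, ], unclass(rec2$fc_recon)[, ])
  expect_error(reconstruct_subject(m, train[1, ], p + 1),
               class = "connvae_format_error")
})

test_that("reconstruction quality matches direct oracles", {
  m <- random_sym(7, seed = 14)
  q <- reconstruction_quality(m, m)
  expect_equal(q$mse, 0)
  expect_equal(q$rank_correlation, 1)
  q2 <- reconstruction_quality(m, -m)
  expect_equal(q2$rank_correlation, -1)
  # brute-force Spearman on a small perturbed case
  set.seed(15)
  noise <- random_sym(7, seed = 16) * 0.3
  r <- m + noise
  o <- vectorize_upper(m); rr <- vectorize_upper(r)
  rho_oracle <- 1 - 6 * sum((rank(o) - rank(rr))^2) /
    (length(o) * (length(o)^2 - 1))
  q3 <- reconstruction_quality(m, r)
  expect_equal(q3$rank_correlation, rho_oracle, tolerance = 1e-12)
  expect_equal(q3$mse, mean((o - rr)^2))
  # constant matrix -> undefined sentinel
  expect_true(is.na(reconstruction_quality(matrix(0, 4, 4), m[1:4, 1:4])$rank_correlation))
})

test_that("tidy and glance summarize a fitted model", {
  train <- make_toy_data(12, 17)
  cfg <- vae_config(input_length = 20, latent_dim = 2,
                    encoder_widths = c(8, 4), max_epochs = 5, patience = 5,
                    seed = 18)
  m <- train_vae(train, make_toy_data(4, 18), cfg)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(m$history))
  gl <- glance(m)
  expect_equal(gl$epochs_trained, nrow(td))
  expect_equal(gl$provenance, "healthy_trained")
  expect_s3_class(autoplot(m), "ggplot")
})
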