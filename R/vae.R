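#' Configuration of the beta-normalized variational autoencoder
#'
#' Mirrors the reference architecture: fully connected encoder
#' (input -> 512 -> 256 -> 128) with leaky-ReLU activations, two linear heads
#' for the 8 latent means and log-variances, mirrored decoder with a linear
#' output layer, Adam at learning rate 1e-3, batch size 8, up to 2000 epochs
#' with early-stopping patience 750. The KL weight is the normalized
#' `beta_norm = beta * M / N` where `M` is the latent size and `N` the input
#' length, making `beta` comparable across input sizes.
#'
#' @param input_length Length `N` of the concatenated zFC/zSC model vector.
#' @param latent_dim Latent size `M`.
#' @param encoder_widths Hidden-layer widths; the decoder mirrors them.
#' @param beta Raw KL weight (1 in the reference setting).
#' @param leaky_slope Negative-side slope of the leaky-ReLU.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param max_epochs,patience Training length and early-stopping patience.
#' @param finetune_lr Reduced learning rate used by [fine_tune()].
#' @param freeze_encoder If `TRUE`, [fine_tune()] updates only decoder/head
#'   parameters.
#' @param seed Seed controlling initialization, shuffling and sampling.
#' @return A list of class `connvae_vae_config`.
#' @export
vae_config <- function(input_length, latent_dim = 8,
                       encoder_widths = c(512, 256, 128),
                       beta = 1, leaky_slope = 0.01,
                       learning_rate = 1e-3, batch_size = 8,
                       max_epochs = 2000, patience = 750,
                       finetune_lr = 1e-4, freeze_encoder = FALSE,
                       seed = 1) {
  stopifnot(input_length > 0, latent_dim > 0, all(encoder_widths > 0),
            batch_size >= 1, max_epochs >= 0, patience >= 1)
  structure(list(
    input_length = as.integer(input_length),
    latent_dim = as.integer(latent_dim),
    encoder_widths = as.integer(encoder_widths),
    beta = beta,
    beta_norm = beta * latent_dim / input_length,
    leaky_slope = leaky_slope,
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    finetune_lr = finetune_lr, freeze_encoder = freeze_encoder,
    seed = seed
  ), class = "connvae_vae_config")
}

lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

init_layer <- function(fan_in, fan_out, gain = 2) {
  list(W = matrix(rnorm(fan_in * fan_out, sd = sqrt(gain / fan_in)),
                  fan_in, fan_out),
       b = rep(0, fan_out))
}

#' Build an untrained VAE
#'
#' Weight initialization is He-style for leaky-ReLU layers and Xavier-style
#' for the linear heads/output, deterministic under the config seed.
#'
#' @param config A `connvae_vae_config`.
#' @return A `connvae_vae` with provenance `"untrained"`.
#' @export
build_vae <- function(config) {
  stopifnot(inherits(config, "connvae_vae_config"))
  set.seed(derive_seed(config$seed, "init"))
  enc_dims <- c(config$input_length, config$encoder_widths)
  dec_widths <- rev(config$encoder_widths)
  dec_dims <- c(config$latent_dim, dec_widths)
  params <- list(
    enc = lapply(seq_along(config$encoder_widths), function(l)
      init_layer(enc_dims[l], enc_dims[l + 1])),
    mu = init_layer(tail0(enc_dims), config$latent_dim, gain = 1),
    lv = init_layer(tail0(enc_dims), config$latent_dim, gain = 1),
    dec = lapply(seq_along(dec_widths), function(l)
      init_layer(dec_dims[l], dec_dims[l + 1])),
    out = init_layer(tail0(dec_dims), config$input_length, gain = 1)
  )
  structure(list(params = params, config = config, history = NULL,
                 provenance = "untrained"),
            class = "connvae_vae")
}

tail0 <- function(x) x[length(x)]

# forward pass; returns activations needed for backprop.
# eps = NULL means deterministic inference (z = mu).
vae_forward <- function(params, config, X, eps = NULL) {
  slope <- config$leaky_slope
  h <- X
  enc_in <- list(); enc_pre <- list()
  for (l in seq_along(params$enc)) {
    enc_in[[l]] <- h
    a <- sweep(h %*% params$enc[[l]]$W, 2L, params$enc[[l]]$b, "+")
    enc_pre[[l]] <- a
    h <- lrelu(a, slope)
  }
  mu <- sweep(h %*% params$mu$W, 2L, params$mu$b, "+")
  lv <- sweep(h %*% params$lv$W, 2L, params$lv$b, "+")
  z <- if (is.null(eps)) mu else mu + eps * exp(0.5 * lv)
  g <- z
  dec_in <- list(); dec_pre <- list()
  for (l in seq_along(params$dec)) {
    dec_in[[l]] <- g
    a <- sweep(g %*% params$dec[[l]]$W, 2L, params$dec[[l]]$b, "+")
    dec_pre[[l]] <- a
    g <- lrelu(a, slope)
  }
  xhat <- sweep(g %*% params$out$W, 2L, params$out$b, "+")
  list(h = h, mu = mu, lv = lv, z = z, g = g, xhat = xhat,
       enc_in = enc_in, enc_pre = enc_pre,
       dec_in = dec_in, dec_pre = dec_pre)
}

#' The beta-normalized VAE objective
#'
#' `total = mean squared reconstruction error + beta_norm * KL`, with the
#' reconstruction error averaged over batch and features and the KL term the
#' batch mean of the closed-form divergence against a standard normal,
#' `0.5 * sum(exp(logvar) + mean^2 - 1 - logvar)` per sample.
#'
#' @param input,reconstruction Matrices (batch x features).
#' @param latent_mean,latent_logvar Matrices (batch x latent).
#' @param config A `connvae_vae_config` (supplies `beta_norm`).
#' @return List with `total`, `recon_term`, `kl_term`.
#' @export
vae_loss <- function(input, reconstruction, latent_mean, latent_logvar,
                     config) {
  input <- rbind(input); reconstruction <- rbind(reconstruction)
  latent_mean <- rbind(latent_mean); latent_logvar <- rbind(latent_logvar)
  recon <- mean((reconstruction - input)^2)
  kl <- mean(0.5 * rowSums(exp(latent_logvar) + latent_mean^2 - 1 -
                             latent_logvar))
  total <- recon + config$beta_norm * kl
  if (!is.finite(total)) {
    abort("non-finite VAE loss", class = "connvae_numeric_error")
  }
  list(total = total, recon_term = recon, kl_term = kl)
}

# loss + gradients for one mini-batch (one reparameterized sample per input)
vae_grad <- function(params, config, X, eps) {
  B <- nrow(X); N <- ncol(X)
  f <- vae_forward(params, config, X, eps)
  loss <- vae_loss(X, f$xhat, f$mu, f$lv, config)
  slope <- config$leaky_slope
  grads <- list(enc = vector("list", length(params$enc)),
                dec = vector("list", length(params$dec)))

  d <- 2 * (f$xhat - X) / (B * N)
  grads$out <- list(W = crossprod(f$g, d), b = colSums(d))
  dg <- tcrossprod(d, params$out$W)
  for (l in rev(seq_along(params$dec))) {
    da <- dg * lrelu_grad(f$dec_pre[[l]], slope)
    grads$dec[[l]] <- list(W = crossprod(f$dec_in[[l]], da), b = colSums(da))
    dg <- tcrossprod(da, params$dec[[l]]$W)
  }
  dz <- dg
  kl_w <- config$beta_norm / B
  dmu <- dz + kl_w * f$mu
  dlv <- dz * eps * 0.5 * exp(0.5 * f$lv) + kl_w * 0.5 * (exp(f$lv) - 1)
  grads$mu <- list(W = crossprod(f$h, dmu), b = colSums(dmu))
  grads$lv <- list(W = crossprod(f$h, dlv), b = colSums(dlv))
  dh <- tcrossprod(dmu, params$mu$W) + tcrossprod(dlv, params$lv$W)
  for (l in rev(seq_along(params$enc))) {
    da <- dh * lrelu_grad(f$enc_pre[[l]], slope)
    grads$enc[[l]] <- list(W = crossprod(f$enc_in[[l]], da), b = colSums(da))
    if (l > 1L) dh <- tcrossprod(da, params$enc[[l]]$W)
  }
  list(loss = loss, grads = grads)
}

# flatten/unflatten param trees so Adam state handling stays generic
param_leaves <- function(p, prefix = "") {
  if (is.list(p) && !is.null(p$W)) {
    out <- list(p$W, p$b)
    names(out) <- paste0(prefix, c("W", "b"))
    return(out)
  }
  out <- list()
  keys <- names(p)
  if (is.null(keys)) keys <- as.character(seq_along(p))
  for (i in seq_along(p)) {
    out <- c(out, param_leaves(p[[i]], paste0(prefix, keys[i], ".")))
  }
  out
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                      freeze = character(0)) {
  pl <- param_leaves(params); gl <- param_leaves(grads)
  for (k in names(pl)) {
    if (length(freeze) && any(startsWith(k, freeze))) next
    g <- gl[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^t)
    vhat <- state$v[[k]] / (1 - beta2^t)
    pl[[k]] <- pl[[k]] - lr * mhat / (sqrt(vhat) + adam_eps)
  }
  list(params = relist_params(params, pl), state = state)
}

relist_params <- function(tree, leaves, prefix = "") {
  if (is.list(tree) && !is.null(tree$W)) {
    tree$W <- leaves[[paste0(prefix, "W")]]
    tree$b <- leaves[[paste0(prefix, "b")]]
    return(tree)
  }
  keys <- names(tree)
  if (is.null(keys)) keys <- as.character(seq_along(tree))
  for (i in seq_along(tree)) {
    tree[[i]] <- relist_params(tree[[i]], leaves, paste0(prefix, keys[i], "."))
  }
  tree
}

zero_like <- function(params) lapply(param_leaves(params), function(x) x * 0)

eval_split <- function(params, config, X) {
  f <- vae_forward(params, config, X, eps = NULL)
  vae_loss(X, f$xhat, f$mu, f$lv, config)
}

run_training <- function(model, train_X, val_X, config, provenance) {
  params <- model$params
  state <- list(m = zero_like(params), v = zero_like(params))
  freeze <- if (isTRUE(config$freeze_encoder)) c("enc.", "mu.", "lv.")
            else character(0)
  set.seed(derive_seed(config$seed, paste0("train_", provenance)))
  n <- nrow(train_X)
  best <- list(params = params, val = eval_split(params, config, val_X)$total,
               epoch = 0L)
  history <- vector("list", config$max_epochs)
  since_improve <- 0L
  t_step <- 0L
  n_epochs <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tr_tot <- tr_rec <- tr_kl <- 0
    for (bi in batches) {
      Xb <- train_X[bi, , drop = FALSE]
      eps <- matrix(rnorm(length(bi) * config$latent_dim),
                    length(bi), config$latent_dim)
      gr <- vae_grad(params, config, Xb, eps)
      if (!is.finite(gr$loss$total)) {
        abort(sprintf("training diverged at epoch %d", epoch),
              class = "connvae_numeric_error")
      }
      t_step <- t_step + 1L
      upd <- adam_step(params, gr$grads, state, config$learning_rate, t_step,
                       freeze = freeze)
      params <- upd$params; state <- upd$state
      w <- length(bi) / n
      tr_tot <- tr_tot + gr$loss$total * w
      tr_rec <- tr_rec + gr$loss$recon_term * w
      tr_kl <- tr_kl + gr$loss$kl_term * w
    }
    vl <- eval_split(params, config, val_X)
    history[[epoch]] <- tibble(
      epoch = epoch, train_total = tr_tot, train_recon = tr_rec,
      train_kl = tr_kl, val_total = vl$total, val_recon = vl$recon_term,
      val_kl = vl$kl_term)
    n_epochs <- epoch
    if (vl$total < best$val) {
      best <- list(params = params, val = vl$total, epoch = epoch)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= config$patience) break
    }
  }
  model$params <- best$params
  model$config <- config
  model$history <- bind_rows(history[seq_len(n_epochs)])
  model$best_epoch <- best$epoch
  model$best_val_loss <- best$val
  model$provenance <- provenance
  model
}

#' Train the VAE on healthy model vectors
#'
#' Mini-batch Adam optimization of the beta-normalized objective with one
#' reparameterized latent sample per input during training and deterministic
#' (latent-mean) validation. Early stopping halts training once the
#' validation total loss has not improved for `patience` consecutive epochs;
#' the best-validation weights are kept.
#'
#' @param train_X,val_X Numeric matrices, one model vector per row.
#' @param config A `connvae_vae_config`.
#' @return A trained `connvae_vae` with provenance `"healthy_trained"` and a
#'   per-epoch history tibble.
#' @export
train_vae <- function(train_X, val_X, config) {
  train_X <- rbind(train_X); val_X <- rbind(val_X)
  if (!nrow(train_X) || !nrow(val_X)) {
    abort("empty training or validation split", class = "connvae_format_error")
  }
  if (ncol(train_X) != config$input_length ||
        ncol(val_X) != config$input_length) {
    abort("vector length does not match config input_length",
          class = "connvae_format_error")
  }
  model <- build_vae(config)
  run_training(model, train_X, val_X, config, "healthy_trained")
}

#' Fine-tune a healthy-trained VAE on a patient domain
#'
#' Transfer learning: optimization continues from the healthy weights at a
#' reduced learning rate (default `finetune_lr`, 1e-4) with the same
#' early-stopping rule. The full network is updated unless
#' `freeze_encoder = TRUE` in the config/override.
#'
#' @param model A `connvae_vae` with provenance `"healthy_trained"`.
#' @param patient_train_X,patient_val_X Patient model vectors (rows).
#' @param config_override Named list of config fields to override (e.g.
#'   `learning_rate`, `max_epochs`, `patience`, `freeze_encoder`).
#' @return A `connvae_vae` with provenance `"fine_tuned"`.
#' @export
fine_tune <- function(model, patient_train_X, patient_val_X,
                      config_override = list()) {
  stopifnot(inherits(model, "connvae_vae"))
  if (!identical(model$provenance, "healthy_trained")) {
    abort("fine_tune requires a healthy-trained model",
          class = "connvae_format_error")
  }
  patient_train_X <- rbind(patient_train_X)
  patient_val_X <- rbind(patient_val_X)
  if (!nrow(patient_train_X) || !nrow(patient_val_X)) {
    abort("empty patient split", class = "connvae_format_error")
  }
  config <- model$config
  config$learning_rate <- config$finetune_lr
  for (nm in names(config_override)) config[[nm]] <- config_override[[nm]]
  config$beta_norm <- config$beta * config$latent_dim / config$input_length
  if (config$max_epochs == 0L) {
    model$provenance <- "fine_tuned"
    model$config <- config
    return(model)
  }
  run_training(model, patient_train_X, patient_val_X, config, "fine_tuned")
}

# batch reconstruction in the artanh (model) domain; deterministic (z = mu)
vae_reconstruct <- function(model, X) {
  X <- rbind(X)
  if (ncol(X) != model$config$input_length) {
    abort("vector length does not match model input_length",
          class = "connvae_format_error")
  }
  vae_forward(model$params, model$config, X, eps = NULL)$xhat
}

#' Reconstruct one subject's FC and SC matrices
#'
#' Decodes the latent mean (inference never samples), splits the output into
#' its zFC and zSC blocks, rebuilds the symmetric matrices and applies the
#' hyperbolic tangent to return to the connectivity domain. Reconstructed SC
#' values slightly below zero are set to 0; SC stays in the power-transformed
#' domain.
#'
#' @param model A trained `connvae_vae`.
#' @param model_vector Concatenated zFC/zSC vector (length `P(P-1)`).
#' @param p Parcel count.
#' @return List with `fc_recon` and `sc_recon` (`conn_matrix` objects).
#' @export
reconstruct_subject <- function(model, model_vector, p) {
  xhat <- drop(vae_reconstruct(model, matrix(model_vector, nrow = 1)))
  half <- length(xhat) / 2
  if (half != p * (p - 1) / 2) {
    abort("model vector length does not match parcel count",
          class = "connvae_format_error")
  }
  sid <- attr(model_vector, "subject_id") %||% NA_character_
  fc <- tanh_denormalize(devectorize_upper(xhat[seq_len(half)], p))
  sc <- tanh_denormalize(devectorize_upper(xhat[half + seq_len(half)], p))
  sc[sc < 0] <- 0
  fc_m <- conn_matrix(fc, "FC_recon", subject_id = sid)
  sc_m <- conn_matrix(sc, "SC_recon", subject_id = sid)
  attr(sc_m, "domain") <- "transformed"
  list(fc_recon = fc_m, sc_recon = sc_m)
}

#' Reconstruction quality of a connectivity matrix
#'
#' Mean squared error and Spearman rank correlation over the strict upper
#' triangle.
#'
#' @param orig,recon Same-dimension square matrices.
#' @return List with `mse` and `rank_correlation` (`NA` when either triangle
#'   is constant).
#' @export
reconstruction_quality <- function(orig, recon) {
  o <- vectorize_upper(orig); r <- vectorize_upper(recon)
  keep <- !is.na(o) & !is.na(r)
  o <- o[keep]; r <- r[keep]
  mse <- mean((o - r)^2)
  rc <- if (sd(o) == 0 || sd(r) == 0) NA_real_
        else cor(o, r, method = "spearman")
  list(mse = mse, rank_correlation = rc)
}

#' @export
print.connvae_vae <- function(x, ...) {
  cat(sprintf(
    "<connvae_vae %s: N=%d, M=%d, widths=%s, beta_norm=%.3g, epochs=%d>\n",
    x$provenance, x$config$input_length, x$config$latent_dim,
    paste(x$config$encoder_widths, collapse = "-"), x$config$beta_norm,
    if (is.null(x$history)) 0L else nrow(x$history)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted VAE
#' @param x A `connvae_vae`.
#' @param ... Unused.
#' @return Tibble with one row per epoch (train/validation total,
#'   reconstruction and KL losses).
#' @method tidy connvae_vae
#' @export
tidy.connvae_vae <- function(x, ...) {
  x$history %||% tibble(epoch = integer(), train_total = numeric(),
                        train_recon = numeric(), train_kl = numeric(),
                        val_total = numeric(), val_recon = numeric(),
                        val_kl = numeric())
}

#' One-row summary of a fitted VAE
#' @param x A `connvae_vae`.
#' @param ... Unused.
#' @return Tibble with provenance, architecture and best-validation loss.
#' @method glance connvae_vae
#' @export
glance.connvae_vae <- function(x, ...) {
  tibble(
    provenance = x$provenance,
    input_length = x$config$input_length,
    latent_dim = x$config$latent_dim,
    beta_norm = x$config$beta_norm,
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    best_epoch = x$best_epoch %||% NA_integer_,
    best_val_loss = x$best_val_loss %||% NA_real_
  )
}

#' Training-history plot
#' @param object A `connvae_vae`.
#' @param ... Unused.
#' @return A ggplot of train/validation total loss by epoch.
#' @method autoplot connvae_vae
#' @export
autoplot.connvae_vae <- function(object, ...) {
  h <- tidy(object) |>
    tidyr::pivot_longer(c("train_total", "val_total"),
                        names_to = "split", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(train_total = "#1b9e77", val_total = "#d95f02"),
      labels = c(train_total = "train", val_total = "validation")) +
    ggplot2::labs(x = "epoch", y = "total loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
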