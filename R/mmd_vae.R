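#' Maximum mean discrepancy between two sample sets
#'
#' The plug-in three-term estimator
#' `E_pp[k] - 2 E_qp[k] + E_qq[k]` with a Gaussian kernel
#' `k(z, z') = exp(-||z - z'||^2 / (2 sigma2))`. Expectations are means
#' over all pairs including the diagonal, so two identical sample multisets
#' give exactly 0. Used during training to pull the latent distribution
#' towards the standard Gaussian prior; the kernel bandwidth defaults to
#' the latent dimension (1).
#'
#' @param q Numeric vector (or one-column matrix) of latent samples.
#' @param p Numeric vector of prior samples.
#' @param sigma2 Kernel bandwidth (variance), default 1.
#' @return A single number; near 0 when the distributions match, with an
#'   upper limit of 2 for point masses separated by many bandwidths.
#' @export
compute_mmd <- function(q, p, sigma2 = 1) {
  q <- as.numeric(q); p <- as.numeric(p)
  if (length(q) == 0L || length(p) == 0L) stop_cfg("empty sample set")
  kmean <- function(a, b) mean(exp(-outer(a, b, "-")^2 / (2 * sigma2)))
  kmean(p, p) - 2 * kmean(q, p) + kmean(q, q)
}

relu <- function(x) (x > 0) * x

vae_init <- function(d_in, hidden, latent) {
  he <- function(n_in, n_out) matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)),
                                     n_in, n_out)
  list(W1 = he(d_in, hidden), b1 = numeric(hidden),
       Wm = he(hidden, latent), bm = numeric(latent),
       Wl = matrix(0, hidden, latent), bl = numeric(latent),
       W2 = he(latent, hidden), b2 = numeric(hidden),
       W3 = he(hidden, d_in), b3 = numeric(d_in))
}

vae_forward_mu <- function(w, X) {
  H1 <- relu(sweep(X %*% w$W1, 2L, w$b1, "+"))
  sweep(H1 %*% w$Wm, 2L, w$bm, "+")
}

vae_decode <- function(w, z) {
  H2 <- relu(sweep(z %*% w$W2, 2L, w$b2, "+"))
  sweep(H2 %*% w$W3, 2L, w$b3, "+")
}

# deterministic loss (z = mu, fixed prior draws) used for validation
vae_eval_loss <- function(w, X, lambda, prior) {
  mu <- vae_forward_mu(w, X)
  Xh <- vae_decode(w, mu)
  mse <- mean((X - Xh)^2)
  mmd <- if (lambda > 0) compute_mmd(mu[, 1L], prior) else 0
  mse + lambda * mmd
}

#' Train a per-cluster MMD variational autoencoder
#'
#' A small VAE (one hidden layer of 5 ReLU units in encoder and decoder, a
#' single latent node) trained with reconstruction mean squared error plus
#' `lambda` times the maximum mean discrepancy between the batch latents
#' and standard-normal prior draws (one draw per batch element). Training
#' uses a seeded 75:25 train/validation split, Adam updates, batch size 16,
#' at most 100 epochs, and early stopping once the validation loss has not
#' improved by more than `min_delta` for `patience` consecutive epochs
#' (the best-validation weights are kept). Everything is deterministic
#' given `seed`.
#'
#' @param X Numeric matrix of training vectors (rows) x 7 features.
#' @param seed Integer seed for initialisation, split, shuffling, and the
#'   reparameterisation/prior draws.
#' @param hidden,latent Layer sizes (defaults 5 and 1).
#' @param lambda MMD weight (default 0.1; 0 gives a plain autoencoder).
#' @param lr Adam learning rate (default 0.005).
#' @param batch_size,max_epochs,patience,val_frac,min_delta Training
#'   schedule controls.
#' @return An object of class `sircle_vae`: weights, the per-epoch
#'   validation-loss trace, and the training configuration.
#' @export
train_cluster_vae <- function(X, seed = 1L, hidden = 5L, latent = 1L,
                              lambda = 0.1, lr = 0.005, batch_size = 16L,
                              max_epochs = 100L, patience = 3L,
                              val_frac = 0.25, min_delta = 1e-6) {
  X <- as.matrix(X)
  if (nrow(X) < 8L) stop_cfg("need at least 8 training vectors, got %d", nrow(X))
  if (any(!is.finite(X))) stop_cfg("training matrix contains non-finite values")
  d <- ncol(X)
  with_seed(seed, {
    w <- vae_init(d, hidden, latent)
    n <- nrow(X)
    n_val <- max(1L, round(val_frac * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]
    Xval <- X[val_idx, , drop = FALSE]
    val_prior <- stats::rnorm(nrow(Xval))

    # Adam state
    m <- lapply(w, function(p) p * 0)
    v <- lapply(w, function(p) p * 0)
    b1a <- 0.9; b2a <- 0.999; epsa <- 1e-8; t_step <- 0L

    best <- list(loss = Inf, w = w, epoch = 0L)
    bad <- 0L
    trace <- numeric(0)
    ntr <- nrow(Xtr)

    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(ntr)
      starts <- seq(1L, ntr, by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, ntr)]
        xb <- Xtr[idx, , drop = FALSE]
        nb <- nrow(xb)

        H1a <- sweep(xb %*% w$W1, 2L, w$b1, "+")
        H1 <- relu(H1a)
        mu <- sweep(H1 %*% w$Wm, 2L, w$bm, "+")
        lv <- sweep(H1 %*% w$Wl, 2L, w$bl, "+")
        sdv <- exp(0.5 * lv)
        eps <- matrix(stats::rnorm(nb * ncol(mu)), nb)
        z <- mu + sdv * eps
        H2a <- sweep(z %*% w$W2, 2L, w$b2, "+")
        H2 <- relu(H2a)
        Xh <- sweep(H2 %*% w$W3, 2L, w$b3, "+")

        pr <- stats::rnorm(nb)

        if (!all(is.finite(Xh))) stop_cfg("training diverged at epoch %d", epoch)

        # reconstruction gradient: loss = mean((X - Xh)^2)
        dXh <- 2 * (Xh - xb) / (nb * d)
        dW3 <- crossprod(H2, dXh); db3 <- colSums(dXh)
        dH2 <- (dXh %*% t(w$W3)) * (H2a > 0)
        dW2 <- crossprod(z, dH2); db2 <- colSums(dH2)
        dz <- dH2 %*% t(w$W2)

        # MMD gradient (V-statistic, Gaussian kernel, sigma2 = 1)
        if (lambda > 0) {
          zv <- z[, 1L]
          Dqq <- outer(zv, zv, "-")
          Kqq <- exp(-Dqq^2 / 2)
          Dqp <- outer(zv, pr, "-")
          Kqp <- exp(-Dqp^2 / 2)
          gz <- -(2 / nb^2) * rowSums(Kqq * Dqq) + (2 / (nb * nb)) * rowSums(Kqp * Dqp)
          dz <- dz + lambda * gz
        }

        dmu <- dz
        dlv <- dz * eps * 0.5 * sdv
        dWm <- crossprod(H1, dmu); dbm <- colSums(dmu)
        dWl <- crossprod(H1, dlv); dbl <- colSums(dlv)
        dH1 <- (dmu %*% t(w$Wm) + dlv %*% t(w$Wl)) * (H1a > 0)
        dW1 <- crossprod(xb, dH1); db1 <- colSums(dH1)

        grads <- list(W1 = dW1, b1 = db1, Wm = dWm, bm = dbm, Wl = dWl,
                      bl = dbl, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
        t_step <- t_step + 1L
        corr1 <- 1 - b1a^t_step; corr2 <- 1 - b2a^t_step
        for (nm in names(w)) {
          g <- grads[[nm]]
          m[[nm]] <- b1a * m[[nm]] + (1 - b1a) * g
          v[[nm]] <- b2a * v[[nm]] + (1 - b2a) * g^2
          w[[nm]] <- w[[nm]] - lr * (m[[nm]] / corr1) /
            (sqrt(v[[nm]] / corr2) + epsa)
        }
      }

      val_loss <- vae_eval_loss(w, Xval, lambda, val_prior)
      if (!is.finite(val_loss)) stop_cfg("training diverged at epoch %d", epoch)
      trace <- c(trace, val_loss)
      if (val_loss < best$loss - min_delta) {
        best <- list(loss = val_loss, w = w, epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }

    structure(list(weights = best$w, loss_trace = trace,
                   best_epoch = best$epoch, best_loss = best$loss,
                   config = list(hidden = hidden, latent = latent,
                                 lambda = lambda, lr = lr,
                                 batch_size = batch_size,
                                 max_epochs = max_epochs, patience = patience,
                                 val_frac = val_frac, seed = seed,
                                 d_in = d)),
              class = "sircle_vae")
  })
}

#' @export
print.sircle_vae <- function(x, ...) {
  cat(sprintf("MMD-VAE: %d -> %d -> %d latent | lambda %.3g | best val loss %.4g (epoch %d/%d)\n",
              x$config$d_in, x$config$hidden, x$config$latent,
              x$config$lambda, x$best_loss, x$best_epoch, length(x$loss_trace)))
  invisible(x)
}

#' Encode feature vectors to their latent value
#'
#' Inference-time encoding is the posterior mean `mu` (no
#' reparameterisation noise), so repeated calls are deterministic and
#' identical vectors get identical encodings. Vectors excluded from
#' training (outliers) are encodable like any other.
#'
#' @param model A `sircle_vae` from [train_cluster_vae()].
#' @param X Matrix of vectors (rows) with the model's input width.
#' @return Numeric vector of latent values, one per row of `X`.
#' @export
vae_encode <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$config$d_in) {
    stop_cfg("expected %d features, got %d", model$config$d_in, ncol(X))
  }
  as.numeric(vae_forward_mu(model$weights, X))
}
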