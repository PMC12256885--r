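## Dense variational autoencoder trained with Adam, written directly on
## matrix operations so it runs quickly on a single CPU.  The encoder maps
## the fused waveform to a hidden tanh layer and then to the posterior
## mean and log-variance of the latent code; the decoder mirrors it.  The
## objective is the standard beta-VAE loss: per-sample summed squared
## reconstruction error plus beta times the KL divergence from the
## standard-normal prior.  Setting `variational = FALSE` and `beta = 0`
## yields the plain (convolutional-autoencoder-style) deterministic
## baseline with the same topology.

#' VAE configuration
#'
#' @param latent_dim Latent dimensionality (>= 1).
#' @param hidden Width of the single hidden layer in encoder and decoder
#'   (the decoder is the mirror image of the encoder).
#' @param beta KL rescaling factor of the beta-VAE objective.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs (>= 1); the checkpoint with the lowest
#'   validation loss is kept, so generous budgets are benign.
#' @param batch_size Minibatch size.
#' @param seed Integer seed; training is deterministic given the seed.
#' @param variational If `FALSE`, disable stochastic sampling of the
#'   latent (with `beta = 0` this is the plain autoencoder baseline).
#' @return List of class `vae_config`.
#' @export
vae_config <- function(latent_dim, hidden = 96, beta = 1e-3,
                       learning_rate = 1e-3, epochs = 60, batch_size = 256,
                       seed = 1, variational = TRUE) {
  if (latent_dim < 1) mr_stop("latent_dim must be >= 1")
  if (epochs < 1) mr_stop("epochs must be >= 1")
  structure(list(latent_dim = as.integer(latent_dim), hidden = hidden,
                 beta = beta, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = batch_size,
                 seed = seed, variational = variational),
            class = "vae_config")
}

as_input_matrix <- function(x) {
  if (inherits(x, "fused_tensor")) x$data else as.matrix(x)
}

#' Train a (beta-)VAE on fused waveforms
#'
#' Minimizes per-sample summed squared reconstruction error plus
#' `beta` times the KL divergence to a standard-normal prior, using Adam.
#' The weights with the lowest validation loss across epochs are the
#' returned checkpoint.  Deterministic given `config$seed`.
#'
#' @param train,val Fused tensors (or plain matrices) with disjoint
#'   samples; `val` drives checkpoint selection and the disentanglement
#'   metric.
#' @param config A [vae_config()].
#' @return A `model_candidate`: list with `model` (weights + config),
#'   `val_recon_loss` (per-element validation MSE at the selected
#'   checkpoint), `max_abs_corr` (maximum absolute off-diagonal
#'   correlation of validation embeddings) and `config`.
#' @export
train_vae <- function(train, val, config) {
  stopifnot(inherits(config, "vae_config"))
  x <- as_input_matrix(train)
  xv <- as_input_matrix(val)
  ids_tr <- rownames(x); ids_v <- rownames(xv)
  if (!is.null(ids_tr) && length(intersect(ids_tr, ids_v)))
    mr_stop("train and val sets must be disjoint by sample id")
  n <- nrow(x); d <- ncol(x)
  k <- config$latent_dim; h <- config$hidden
  if (k >= d) mr_stop("latent_dim must be smaller than the input length")
  beta <- config$beta; lr <- config$learning_rate
  with_seed(config$seed, {
    init <- function(p, q) matrix(stats::rnorm(p * q, sd = sqrt(2 / (p + q))), p, q)
    w <- list(W1 = init(d, h), b1 = rep(0, h),
              Wm = init(h, k), bm = rep(0, k),
              Wv = init(h, k), bv = rep(0, k),
              W2 = init(k, h), b2 = rep(0, h),
              W3 = init(h, d), b3 = rep(0, d))
    mom <- lapply(w, function(z) z * 0); vel <- mom; tstep <- 0
    best <- list(loss = Inf, w = w, epoch = 0L)
    history <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (i0 in seq(1, n, by = config$batch_size)) {
        idx <- ord[i0:min(i0 + config$batch_size - 1, n)]
        xb <- x[idx, , drop = FALSE]
        m <- nrow(xb)
        h1 <- tanh(sweep(xb %*% w$W1, 2, w$b1, "+"))
        mu <- sweep(h1 %*% w$Wm, 2, w$bm, "+")
        lv <- pmin(pmax(sweep(h1 %*% w$Wv, 2, w$bv, "+"), -10), 10)
        if (config$variational) {
          eps <- matrix(stats::rnorm(m * k), m, k)
          z <- mu + exp(lv / 2) * eps
        } else {
          eps <- matrix(0, m, k); z <- mu
        }
        h2 <- tanh(sweep(z %*% w$W2, 2, w$b2, "+"))
        xh <- sweep(h2 %*% w$W3, 2, w$b3, "+")
        if (any(!is.finite(xh)))
          mr_stop(sprintf("NaN/Inf in reconstruction at epoch %d; try a lower learning rate", ep))
        g <- list()
        dxh <- 2 * (xh - xb) / m
        g$W3 <- crossprod(h2, dxh); g$b3 <- colSums(dxh)
        dh2 <- (dxh %*% t(w$W3)) * (1 - h2^2)
        g$W2 <- crossprod(z, dh2); g$b2 <- colSums(dh2)
        dz <- dh2 %*% t(w$W2)
        dmu <- dz + beta * mu / m
        dlv <- dz * eps * exp(lv / 2) / 2 + beta * (exp(lv) - 1) / (2 * m)
        g$Wm <- crossprod(h1, dmu); g$bm <- colSums(dmu)
        g$Wv <- crossprod(h1, dlv); g$bv <- colSums(dlv)
        dh1 <- (dmu %*% t(w$Wm) + dlv %*% t(w$Wv)) * (1 - h1^2)
        g$W1 <- crossprod(xb, dh1); g$b1 <- colSums(dh1)
        tstep <- tstep + 1
        for (nm in names(w)) {
          mom[[nm]] <- 0.9 * mom[[nm]] + 0.1 * g[[nm]]
          vel[[nm]] <- 0.999 * vel[[nm]] + 0.001 * g[[nm]]^2
          w[[nm]] <- w[[nm]] -
            lr * (mom[[nm]] / (1 - 0.9^tstep)) /
            (sqrt(vel[[nm]] / (1 - 0.999^tstep)) + 1e-8)
        }
      }
      vloss <- vae_recon_mse(w, xv)
      history[ep] <- vloss
      if (!is.finite(vloss)) mr_stop("non-finite validation loss")
      if (vloss < best$loss) best <- list(loss = vloss, w = w, epoch = ep)
    }
    model <- structure(list(weights = best$w, config = config,
                            input_dim = d, best_epoch = best$epoch,
                            history = history),
                       class = "vae_model")
    emb_v <- encode(model, xv)
    structure(list(model = model,
                   val_recon_loss = best$loss,
                   max_abs_corr = max_abs_offdiag_cor(emb_v$values),
                   config = config),
              class = "model_candidate")
  })
}

vae_recon_mse <- function(w, x) {
  h1 <- tanh(sweep(x %*% w$W1, 2, w$b1, "+"))
  mu <- sweep(h1 %*% w$Wm, 2, w$bm, "+")
  h2 <- tanh(sweep(mu %*% w$W2, 2, w$b2, "+"))
  xh <- sweep(h2 %*% w$W3, 2, w$b3, "+")
  mean((xh - x)^2)
}

#' Maximum absolute off-diagonal correlation
#'
#' The disentanglement metric used for model selection.
#'
#' @param values Numeric matrix (rows = samples).
#' @return Scalar in \[0, 1\]; 0 for a single column.
#' @export
max_abs_offdiag_cor <- function(values) {
  if (ncol(values) < 2) return(0)
  sds <- apply(values, 2, stats::sd)
  keep <- sds > 0
  if (sum(keep) < 2) return(0)
  cc <- stats::cor(values[, keep, drop = FALSE])
  max(abs(cc[upper.tri(cc)]))
}

#' Encode samples to posterior-mean embeddings
#'
#' Inference uses the posterior mean (no sampling), so embeddings are
#' deterministic phenotypes for downstream association testing.
#'
#' @param object A `model_candidate`, `vae_model`, or `pca_model`.
#' @param data Fused tensor or matrix matching the model's input shape.
#' @param ... Unused.
#' @return An `embedding_matrix`: list with `sample_ids`, `values`
#'   (n x d matrix) and `provenance`.
#' @export
encode <- function(object, data, ...) UseMethod("encode")

#' @export
encode.model_candidate <- function(object, data, ...) encode(object$model, data, ...)

#' @export
encode.vae_model <- function(object, data, ...) {
  x <- as_input_matrix(data)
  if (ncol(x) != object$input_dim) mr_stop("input shape mismatch")
  w <- object$weights
  h1 <- tanh(sweep(x %*% w$W1, 2, w$b1, "+"))
  mu <- sweep(h1 %*% w$Wm, 2, w$bm, "+")
  embedding_matrix(mu, rownames(x),
                   provenance = list(model = "vae",
                                     latent_dim = object$config$latent_dim,
                                     seed = object$config$seed))
}

#' Decode embeddings back to waveform space
#'
#' @param object A `model_candidate`, `vae_model`, or `pca_model`.
#' @param embedding An `embedding_matrix` or plain matrix of latent
#'   coordinates.
#' @param ... Unused.
#' @return Matrix in the fused input space.
#' @export
decode <- function(object, embedding, ...) UseMethod("decode")

#' @export
decode.model_candidate <- function(object, embedding, ...) decode(object$model, embedding, ...)

#' @export
decode.vae_model <- function(object, embedding, ...) {
  z <- if (inherits(embedding, "embedding_matrix")) embedding$values else
    as.matrix(embedding)
  if (ncol(z) != object$config$latent_dim) mr_stop("embedding shape mismatch")
  w <- object$weights
  h2 <- tanh(sweep(z %*% w$W2, 2, w$b2, "+"))
  sweep(h2 %*% w$W3, 2, w$b3, "+")
}

#' Embedding matrix container
#'
#' @param values n x d numeric matrix of posterior means.
#' @param sample_ids Character ids (default rownames).
#' @param provenance List recording model id, fusion mode, seed.
#' @return List of class `embedding_matrix`.
#' @export
embedding_matrix <- function(values, sample_ids = rownames(values),
                             provenance = list()) {
  values <- as.matrix(values)
  if (!is.null(sample_ids)) rownames(values) <- sample_ids
  colnames(values) <- paste0("e", seq_len(ncol(values)))
  structure(list(sample_ids = sample_ids, values = values,
                 provenance = provenance),
            class = "embedding_matrix")
}

#' Concatenate unimodal embeddings into one representation
#'
#' The U-style representation: per-modality embeddings joined column-wise
#' (e.g. 12 leads x 8 dims = 96, or 8 + 4 = 12 for ECG lead I + PPG).
#'
#' @param embeddings List of `embedding_matrix` objects over identical
#'   samples.
#' @return A single `embedding_matrix`.
#' @export
concat_embeddings <- function(embeddings) {
  ids <- embeddings[[1]]$sample_ids
  vals <- do.call(cbind, lapply(embeddings, function(e) {
    if (!identical(e$sample_ids, ids)) mr_stop("sample id mismatch")
    e$values
  }))
  embedding_matrix(vals, ids,
                   provenance = list(model = "concat",
                                     parts = length(embeddings)))
}

#' Select a model candidate by disentanglement then validation loss
#'
#' Filters candidates to `max_abs_corr <= corr_threshold`, then picks the
#' lowest validation reconstruction loss; ties break toward smaller
#' `max_abs_corr` then earlier position.  If no candidate passes the
#' threshold, falls back to the global minimum `max_abs_corr` with a
#' warning.
#'
#' @param candidates List of `model_candidate` objects.
#' @param corr_threshold Threshold on the maximum absolute off-diagonal
#'   correlation (default 0.1).
#' @return The selected `model_candidate`.
#' @export
select_model <- function(candidates, corr_threshold = 0.1) {
  if (!length(candidates)) mr_stop("empty candidate list")
  corr <- vapply(candidates, function(c) c$max_abs_corr, numeric(1))
  loss <- vapply(candidates, function(c) c$val_recon_loss, numeric(1))
  pass <- corr <= corr_threshold
  if (!any(pass)) {
    warning("no candidate passed the correlation threshold; ",
            "falling back to the least-correlated model")
    return(candidates[[order(corr, loss)[1]]])
  }
  idx <- which(pass)
  idx <- idx[order(loss[idx], corr[idx])]
  candidates[[idx[1]]]
}

#' Compare multimodal vs unimodal reconstruction error
#'
#' The overall unimodal loss is the length-weighted average of the
#' per-modality MSEs, `sum(L_m * MSE_m) / sum(L_m)`, for concatenation
#' fusion, and the plain mean across modalities for channel stacking
#' (where all modalities share one length).
#'
#' @param m_mse Overall MSE of the multimodal model.
#' @param u_mses Named per-modality MSEs of the unimodal models.
#' @param lengths Named per-modality waveform lengths.
#' @param mode `"concatenate"` or `"channel_stack"`.
#' @param m_dims,u_dims Optional total latent dimensions; a warning is
#'   emitted when they differ (the comparison is still computed).
#' @return List with `m_mse`, `u_overall`, `ratio` (M/U) and
#'   `reduction_pct` (positive when the multimodal model is better).
#' @export
reconstruction_compare <- function(m_mse, u_mses, lengths,
                                   mode = c("concatenate", "channel_stack"),
                                   m_dims = NULL, u_dims = NULL) {
  mode <- match.arg(mode)
  if (!is.null(m_dims) && !is.null(u_dims) && m_dims != u_dims)
    warning("total latent dimensions differ between M and U configurations")
  u_mses <- u_mses[names(lengths)]
  u_overall <- if (mode == "concatenate")
    sum(lengths * u_mses) / sum(lengths) else mean(u_mses)
  list(m_mse = m_mse, u_overall = u_overall, per_modality = u_mses,
       ratio = m_mse / u_overall,
       reduction_pct = 100 * (1 - m_mse / u_overall))
}

#' Interpolate or perturb along one latent coordinate and decode
#'
#' Interpolation mode (both endpoints given): coordinate `dim` moves
#' linearly from `e_start[dim]` to `e_end[dim]` in `steps` evenly spaced
#' values while all other coordinates stay at `e_start`.  Perturbation
#' mode (`e_end = NULL`): start from the all-zero embedding (the prior
#' mean) and sweep coordinate `dim` over `range_sd` (default -2 to 2,
#' i.e. two prior standard deviations).
#'
#' @param candidate Model to decode with.
#' @param e_start Numeric embedding vector (ignored except as the base in
#'   interpolation mode; defaults to zero in perturbation mode).
#' @param e_end Optional embedding vector supplying the endpoint value of
#'   coordinate `dim`.
#' @param dim Coordinate to vary (1-based).
#' @param steps Number of decoded waveforms (>= 2).
#' @param range_sd Perturbation range in prior standard deviations.
#' @return Matrix with `steps` rows of decoded waveforms, plus attribute
#'   `"values"` holding the swept coordinate values.
#' @export
perturb_and_interpolate <- function(candidate, e_start = NULL, e_end = NULL,
                                    dim = 1L, steps = 20L,
                                    range_sd = c(-2, 2)) {
  if (steps < 2) mr_stop("steps must be >= 2")
  k <- if (inherits(candidate, "model_candidate"))
    candidate$config$latent_dim else candidate$config$latent_dim
  if (dim > k) mr_stop("dim exceeds latent dimension")
  if (is.null(e_start)) e_start <- rep(0, k)
  vals <- if (is.null(e_end))
    seq(range_sd[1], range_sd[2], length.out = steps)
  else seq(e_start[dim], e_end[dim], length.out = steps)
  z <- matrix(rep(e_start, each = steps), steps, k)
  z[, dim] <- vals
  out <- decode(candidate, z)
  attr(out, "values") <- vals
  out
}
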