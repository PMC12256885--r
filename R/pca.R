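## PCA baseline with the same encode/decode surface as the VAE.

#' Fit a PCA embedding model
#'
#' Mean-centred projection onto the top-`k` right singular vectors.  The
#' sign of each component is fixed so its largest-magnitude loading is
#' positive, stabilizing results against the sign indeterminacy of PCA.
#'
#' @param data Fused tensor or matrix (rows = samples).
#' @param k Number of components, `k <= min(n, ncol)`.
#' @return List of class `pca_model` with `rotation`, `center`,
#'   `sdev`, `var_explained` (cumulative fraction per component) and the
#'   training embedding as `$embedding`.
#' @export
pca_embed <- function(data, k) {
  x <- as_input_matrix(data)
  if (k > min(nrow(x), ncol(x))) mr_stop("k exceeds min(n, input length)")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = 0, nv = k)
  rot <- sv$v[, seq_len(k), drop = FALSE]
  ## sign convention: largest |loading| positive
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  d2 <- sv$d^2
  scores <- xc %*% rot
  model <- structure(list(rotation = rot, center = ctr,
                          sdev = sv$d[seq_len(k)] / sqrt(max(1, nrow(x) - 1)),
                          var_explained = d2[seq_len(k)] / sum(d2),
                          config = list(latent_dim = k, model = "pca"),
                          input_dim = ncol(x)),
                     class = "pca_model")
  model$embedding <- embedding_matrix(scores, rownames(x),
                                      provenance = list(model = "pca", k = k))
  model
}

#' @export
encode.pca_model <- function(object, data, ...) {
  x <- as_input_matrix(data)
  if (ncol(x) != object$input_dim) mr_stop("input shape mismatch")
  embedding_matrix(sweep(x, 2, object$center) %*% object$rotation,
                   rownames(x), provenance = list(model = "pca"))
}

#' @export
decode.pca_model <- function(object, embedding, ...) {
  z <- if (inherits(embedding, "embedding_matrix")) embedding$values else
    as.matrix(embedding)
  sweep(z %*% t(object$rotation), 2, object$center, "+")
}
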