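## Waveform preprocessing: FIR filtering, quality control, scaling,
## deterministic splits, and fusion of modalities into model-ready tensors.
##
## Waveform collections are represented as named lists of numeric matrices,
## one matrix per modality, with one row per individual (rownames are sample
## ids) and one column per time point.

#' Default modality registry
#'
#' Maps modality names to their fixed waveform lengths.  ECG median
#' complexes have 600 points per lead and PPG median beats 100 points;
#' spirogram curves default to 300 points.
#'
#' @param leads Character vector of ECG lead names to register at 600
#'   points each.
#' @return Named integer vector of per-modality lengths.
#' @export
modality_registry <- function(leads = c("I", "II", "III", "aVR", "aVL", "aVF",
                                        "V1", "V2", "V3", "V4", "V5", "V6")) {
  ecg <- stats::setNames(rep(600L, length(leads)), paste0("ECG_lead", leads))
  c(ecg, PPG = 100L, SPIRO = 300L)
}

#' Design a zero-phase windowed-sinc band-pass FIR filter
#'
#' Hamming-windowed sinc design.  Because the default low cutoff
#' (0.05 Hz) lies far below the frequency resolution of a 255-tap filter
#' at 500 Hz (about 2 Hz), the DC gain is additionally nulled exactly by
#' subtracting a scaled copy of the window, which only perturbs the
#' response below the resolution limit.  The filter is symmetric
#' (linear phase), so applying it with group-delay compensation yields a
#' zero-phase result.
#'
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < sampling_hz / 2`.
#' @param sampling_hz Sampling rate in Hz.
#' @param taps Odd number of filter coefficients.
#' @return Numeric vector of `taps` coefficients with zero DC gain and
#'   unit gain at the band centre.
#' @export
fir_design_bandpass <- function(low_hz = 0.05, high_hz = 40,
                                sampling_hz = 500, taps = 255L) {
  if (taps %% 2 != 1) mr_stop("`taps` must be odd", "mregle_invalid_parameter")
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < sampling_hz / 2))
    mr_stop("cutoffs must satisfy 0 < low < high < Nyquist",
            "mregle_invalid_parameter")
  M <- taps - 1L
  n <- 0:M
  m <- n - M / 2
  sinc_lp <- function(fc) {
    h <- ifelse(m == 0, 2 * fc, sin(2 * pi * fc * m) / (pi * m))
    h
  }
  h <- sinc_lp(high_hz / sampling_hz) - sinc_lp(low_hz / sampling_hz)
  w <- 0.54 - 0.46 * cos(2 * pi * n / M)
  b <- h * w
  b <- b - sum(b) * w / sum(w)  # exact DC null
  fmid <- (low_hz + high_hz) / 2
  gain <- abs(sum(b * exp(-2i * pi * fmid / sampling_hz * n)))
  b / gain
}

#' Frequency response magnitude of an FIR filter
#'
#' @param b Filter coefficients.
#' @param freq_hz Frequencies (Hz) at which to evaluate.
#' @param sampling_hz Sampling rate in Hz.
#' @return `|H(f)|` at each requested frequency.
#' @export
fir_response <- function(b, freq_hz, sampling_hz = 500) {
  n <- seq_along(b) - 1
  vapply(freq_hz, function(f) abs(sum(b * exp(-2i * pi * f / sampling_hz * n))),
         numeric(1))
}

#' Band-pass filter waveforms with zero phase
#'
#' Applies the windowed-sinc band-pass of [fir_design_bandpass()] to each
#' waveform with reflection padding at the edges and exact group-delay
#' compensation (the filter is symmetric, so the result is zero phase).
#' The operation is linear and length preserving.
#'
#' @param x Numeric vector (one waveform) or matrix (one waveform per row).
#' @param low_hz,high_hz,sampling_hz,taps Filter design parameters; see
#'   [fir_design_bandpass()].
#' @return Filtered object of the same shape as `x`.
#' @export
fir_bandpass <- function(x, low_hz = 0.05, high_hz = 40,
                         sampling_hz = 500, taps = 255L) {
  b <- fir_design_bandpass(low_hz, high_hz, sampling_hz, taps)
  if (is.matrix(x)) {
    out <- t(apply(x, 1, fir_apply_zerophase, b = b))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  fir_apply_zerophase(x, b)
}

fir_apply_zerophase <- function(x, b) {
  if (any(!is.finite(x))) mr_stop("waveform contains non-finite values")
  d <- (length(b) - 1L) / 2L
  L <- length(x)
  if (L < 2L) mr_stop("waveform too short to filter")
  ridx <- function(i) {            # reflect indices into 1..L
    i <- abs(i - 1L) %% (2L * (L - 1L))
    ifelse(i >= L, 2L * (L - 1L) - i, i) + 1L
  }
  xp <- x[ridx((1L - d):(L + d))]
  y <- stats::filter(xp, b, method = "convolution", sides = 2)
  as.numeric(y[(d + 1L):(d + L)])
}

#' Percentile-based waveform quality control
#'
#' For each waveform the minimum, maximum, mean, and median are computed
#' and compared with the distribution of the same statistic over all
#' waveforms of the same modality.  A waveform is dropped iff at least one
#' statistic falls strictly outside the inclusive
#' `[pct_low, pct_high]` percentile interval.  Percentiles are type 7
#' (linear interpolation), with the bounds snapped outward to the nearest
#' attained data values so interval endpoints are always attainable and
#' degenerate datasets (constant records, two records) survive.
#' Waveforms with non-finite values are always dropped.
#'
#' @param waves Named list of per-modality matrices (rows = samples), or a
#'   single matrix.
#' @param pct_low,pct_high Percentile cutoffs (defaults 0.1 and 99.9).
#' @param bounds Optional frozen bounds from a previous run (the
#'   `bounds` element of the returned list); when supplied, cutoffs are
#'   not recomputed, so re-applying a run's bounds to its kept set drops
#'   nothing (idempotence).
#' @return List with `kept` (sample ids passing QC in every modality),
#'   `dropped` (data.frame of sample_id, modality, statistic, reason)
#'   and `bounds` (the per-modality, per-statistic cutoffs used).
#' @export
qc_filter <- function(waves, pct_low = 0.1, pct_high = 99.9, bounds = NULL) {
  if (is.matrix(waves)) waves <- list(modality = waves)
  if (length(waves) == 0L || any(vapply(waves, nrow, 1L) == 0L))
    mr_stop("empty input to qc_filter")
  dropped <- list()
  keep_ids <- NULL
  out_bounds <- list()
  for (mod in names(waves)) {
    m <- waves[[mod]]
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
    if (nrow(m) < 2L && is.null(bounds))
      mr_stop("need at least 2 records per modality")
    finite <- apply(m, 1, function(r) all(is.finite(r)))
    if (any(!finite)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        sample_id = rownames(m)[!finite], modality = mod,
        statistic = NA_character_, reason = "non-finite")
    }
    mf <- m[finite, , drop = FALSE]
    stats_tab <- cbind(min = apply(mf, 1, min), max = apply(mf, 1, max),
                       mean = rowMeans(mf), median = apply(mf, 1, stats::median))
    bad <- rep(FALSE, nrow(mf))
    bad_stat <- rep(NA_character_, nrow(mf))
    mod_bounds <- bounds[[mod]]
    new_bounds <- matrix(NA_real_, 2, 4,
                         dimnames = list(c("lo", "hi"), colnames(stats_tab)))
    for (s in colnames(stats_tab)) {
      v <- stats_tab[, s]
      if (is.null(mod_bounds)) {
        lo <- pctl(v, pct_low / 100)
        hi <- pctl(v, pct_high / 100)
        ## snap outward to the nearest attained values so the interval
        ## endpoints are real data points (degenerate small-n sets,
        ## including two records or all-identical records, survive)
        lo <- if (any(v <= lo)) max(v[v <= lo]) else min(v)
        hi <- if (any(v >= hi)) min(v[v >= hi]) else max(v)
      } else {
        lo <- mod_bounds["lo", s]
        hi <- mod_bounds["hi", s]
      }
      new_bounds[, s] <- c(lo, hi)
      out <- v < lo | v > hi          # inclusive interval is kept
      bad_stat[out & !bad] <- s
      bad <- bad | out
    }
    out_bounds[[mod]] <- new_bounds
    if (any(bad)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        sample_id = rownames(mf)[bad], modality = mod,
        statistic = bad_stat[bad], reason = "percentile")
    }
    ok <- rownames(mf)[!bad]
    keep_ids <- if (is.null(keep_ids)) ok else intersect(keep_ids, ok)
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(sample_id = character(), modality = character(),
               statistic = character(), reason = character())
  list(kept = keep_ids, dropped = dropped, bounds = out_bounds)
}

#' Per-modality waveform scale factor
#'
#' The 90th percentile (type-7) of the per-waveform maximum absolute
#' value, computed on the training split only.  Dividing every waveform
#' of the modality by this factor puts roughly 90% of training waveforms
#' inside \[-1, 1\].
#'
#' @param training_waves Numeric matrix of training waveforms (rows =
#'   samples).
#' @return Positive scalar scale factor.
#' @export
compute_scale_factor <- function(training_waves) {
  if (is.null(dim(training_waves)))
    training_waves <- matrix(training_waves, nrow = 1)
  if (nrow(training_waves) == 0L) mr_stop("empty training set")
  f <- pctl(apply(abs(training_waves), 1, max), 0.9)
  if (!is.finite(f) || f <= 0)
    mr_stop("scale factor is zero; all-zero training waveforms?")
  f
}

#' Deterministic train/validation/test split from sample ids
#'
#' Hashes each id with a platform-independent FNV-1a 32-bit hash, takes
#' the value modulo 1000, and maps 0-699 to train, 700-899 to validation
#' and 900-999 to test (for the default 70/20/10 fractions).  The same id
#' always receives the same split, independent of presentation order.
#'
#' @param sample_ids Character vector of ids.
#' @param fractions Numeric vector of three fractions summing to 1.
#' @return Factor with levels train, val, test.
#' @export
assign_split <- function(sample_ids, fractions = c(0.70, 0.20, 0.10)) {
  if (any(!nzchar(sample_ids))) mr_stop("empty sample id")
  if (abs(sum(fractions) - 1) > 1e-8) mr_stop("fractions must sum to 1")
  h <- fnv1a32(as.character(sample_ids)) %% 1000
  cuts <- round(cumsum(fractions) * 1000)
  split <- ifelse(h < cuts[1], "train", ifelse(h < cuts[2], "val", "test"))
  factor(split, levels = c("train", "val", "test"))
}

#' Fusion specification
#'
#' @param strategy `"channel_stack"` (all modalities share one length and
#'   become channels, as for 12-lead ECG) or `"concatenate"` (modalities
#'   are joined end to end into one channel, as for ECG lead I + PPG).
#' @param modality_order Character vector naming each fused modality
#'   exactly once, in order.
#' @param scale_factors Named positive numerics, one per modality.
#' @return An object of class `fusion_spec`.
#' @export
fusion_spec <- function(strategy = c("channel_stack", "concatenate"),
                        modality_order, scale_factors) {
  strategy <- match.arg(strategy)
  if (anyDuplicated(modality_order))
    mr_stop("modality_order must cover every modality exactly once")
  if (!all(modality_order %in% names(scale_factors)))
    mr_stop("missing scale factor for some modality")
  sf <- unlist(scale_factors)[modality_order]
  if (any(!is.finite(sf)) || any(sf <= 0))
    mr_stop("scale factors must be strictly positive")
  structure(list(strategy = strategy, modality_order = modality_order,
                 scale_factors = sf),
            class = "fusion_spec")
}

#' Fuse scaled multimodal waveforms into a model-ready tensor
#'
#' Each modality is divided by its scale factor, then either stacked as
#' channels (`channel_stack`; all modalities must share one length, e.g.
#' 600 points x 12 ECG leads) or concatenated into a single channel
#' (`concatenate`; e.g. 600-point ECG lead I + 100-point PPG = 700
#' points).  The data matrix stores one row per sample; for channel
#' stacking, columns are grouped by channel in `modality_order`.
#'
#' @param waves Named list of per-modality matrices with identical
#'   rownames (sample ids).
#' @param spec A [fusion_spec()].
#' @return An object of class `fused_tensor` with elements `sample_ids`,
#'   `data`, `spec`, `points`, `channels`.
#' @export
fuse <- function(waves, spec) {
  stopifnot(inherits(spec, "fusion_spec"))
  ids <- rownames(waves[[spec$modality_order[1]]])
  blocks <- lapply(spec$modality_order, function(mod) {
    m <- waves[[mod]]
    if (is.null(m))
      mr_stop(sprintf("missing modality '%s'", mod), "mregle_missing_modality")
    if (!identical(rownames(m), ids)) {
      if (is.null(rownames(m)) || !setequal(rownames(m), ids))
        mr_stop(sprintf("modality '%s' does not cover all samples", mod),
                "mregle_missing_modality")
      m <- m[ids, , drop = FALSE]
    }
    m / spec$scale_factors[[mod]]
  })
  lens <- vapply(blocks, ncol, 1L)
  if (spec$strategy == "channel_stack") {
    if (length(unique(lens)) != 1L)
      mr_stop("channel_stack requires all modalities to share one length")
    points <- lens[1]
    channels <- length(blocks)
  } else {
    points <- sum(lens)
    channels <- 1L
  }
  data <- do.call(cbind, blocks)
  rownames(data) <- ids
  structure(list(sample_ids = ids, data = data, spec = spec,
                 points = points, channels = channels,
                 modality_lengths = stats::setNames(lens, spec$modality_order)),
            class = "fused_tensor")
}

#' Split a fused tensor back into scaled per-modality matrices
#'
#' Exact inverse of [fuse()] on the scaled waveforms; with
#' `rescale = TRUE` the original amplitude scale is restored.
#'
#' @param fused A `fused_tensor`.
#' @param rescale Multiply each modality back by its scale factor.
#' @return Named list of per-modality matrices.
#' @export
unfuse <- function(fused, rescale = FALSE) {
  stopifnot(inherits(fused, "fused_tensor"))
  spec <- fused$spec
  lens <- fused$modality_lengths
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  out <- lapply(seq_along(lens), function(i) {
    m <- fused$data[, starts[i]:ends[i], drop = FALSE]
    if (rescale) m <- m * spec$scale_factors[[i]]
    m
  })
  stats::setNames(out, spec$modality_order)
}

#' @export
print.fused_tensor <- function(x, ...) {
  cat(sprintf("<fused_tensor> %d samples, %d points x %d channel(s), strategy=%s\n",
              length(x$sample_ids), x$points, x$channels, x$spec$strategy))
  invisible(x)
}
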