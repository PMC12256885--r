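## Synthetic data generators: genotypes in Hardy-Weinberg equilibrium,
## correlated latent factors, the two-modality toy model, and multimodal
## waveforms driven by shared + modality-specific latent factors.
## Every generator is a pure function of (parameters, seed).

#' Simulate a Hardy-Weinberg genotype matrix
#'
#' Dosages are drawn independently as Binomial(2, maf) per variant, i.e.
#' exact Hardy-Weinberg proportions.  Variant metadata (chrom, pos, maf,
#' imputation info, missingness, HWE p from an exact test) is filled in
#' consistently so the matrix can flow through [variant_qc()].
#'
#' @param n Number of individuals.
#' @param p Number of variants.
#' @param maf Minor allele frequency, scalar or length-`p` vector in
#'   (0, 0.5].
#' @param seed Integer seed.
#' @param chrom Chromosome label(s) recycled across variants.
#' @param pos_start,pos_step 1-based positions are
#'   `pos_start + (0:(p-1)) * pos_step` (non-decreasing).
#' @param ld_rho Optional AR(1) correlation between adjacent variants'
#'   underlying haplotype draws (0 = independent).  Used by the clumping
#'   tests; not a full LD model.
#' @return An object of class `genotype_matrix`: list with `dosages`
#'   (n x p matrix in \[0, 2\]), `variants` (data.frame with id, chrom, pos,
#'   ref, alt, maf, info, missing_frac, hwe_p, monomorphic).
#' @export
simulate_genotypes <- function(n, p, maf = 0.3, seed = 1, chrom = "1",
                               pos_start = 1e6, pos_step = 5e3,
                               ld_rho = 0) {
  if (any(maf <= 0 | maf > 0.5)) mr_stop("maf must lie in (0, 0.5]")
  maf <- rep_len(maf, p)
  with_seed(seed, {
    if (ld_rho > 0) {
      ## two correlated latent haplotype series -> correlated dosages
      dos <- matrix(0, n, p)
      for (h in 1:2) {
        z <- matrix(stats::rnorm(n * p), n, p)
        for (j in 2:p) z[, j] <- ld_rho * z[, j - 1] +
            sqrt(1 - ld_rho^2) * z[, j]
        thr <- stats::qnorm(maf)
        dos <- dos + sweep(z, 2, thr, `<`)
      }
    } else {
      dos <- matrix(stats::rbinom(n * p, 2L, rep(maf, each = n)), n, p)
    }
    storage.mode(dos) <- "double"
    ids <- sprintf("rs%06d", seq_len(p))
    colnames(dos) <- ids
    rownames(dos) <- sprintf("S%06d", seq_len(n))
    obs_maf <- colMeans(dos) / 2
    obs_maf <- pmin(obs_maf, 1 - obs_maf)
    hwe_p <- vapply(seq_len(p), function(j) {
      tab <- tabulate(dos[, j] + 1, nbins = 3)
      hwe_exact_p(tab[2], tab[1], tab[3])
    }, numeric(1))
    variants <- data.frame(
      id = ids, chrom = rep_len(as.character(chrom), p),
      pos = pos_start + (seq_len(p) - 1) * pos_step,
      ref = "A", alt = "G",
      maf = obs_maf, info = 1, missing_frac = 0, hwe_p = hwe_p,
      monomorphic = apply(dos, 2, function(g) length(unique(g)) == 1L),
      stringsAsFactors = FALSE)
    structure(list(dosages = dos, variants = variants),
              class = "genotype_matrix")
  })
}

#' Exact Hardy-Weinberg equilibrium test p value
#'
#' Exact conditional test (sum of probabilities of heterozygote counts no
#' more likely than the observed one, given allele counts).
#'
#' @param n_ab Observed heterozygotes.
#' @param n_aa,n_bb Observed homozygotes.
#' @return Two-sided exact p value.
#' @export
hwe_exact_p <- function(n_ab, n_aa, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  ## log-probability of each heterozygote count under the exact
  ## conditional distribution given the allele counts
  logp <- vapply(hets, function(h) {
    naa <- (n_a - h) / 2; nbb <- (n_b - h) / 2
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) + lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_ab)
  min(1, sum(pr[pr <= pr[obs] + 1e-12]))
}

#' Simulate correlated latent factors with one genetic factor
#'
#' Draws `m` factors per individual as `F_j = X * b_j + e_j` where only
#' the first factor carries genetic signal (`b_1 = b1`, the rest zero) and
#' the noise rows are multivariate normal with unit variances and constant
#' pairwise correlation `rho` (compound-symmetric covariance
#' `(1 - rho) I + rho J`).
#'
#' @param x Numeric genotype dosage vector (one variant), length `n`.
#' @param m Number of factors (default 10).
#' @param rho Common noise correlation, in \[0, 1).
#' @param b1 Effect of the variant on factor 1 (0 under the null).
#' @param seed Integer seed.
#' @return `n x m` factor matrix.
#' @export
simulate_correlated_factors <- function(x, m = 10, rho = 0, b1 = 0.001,
                                        seed = 1) {
  if (rho < 0 || rho >= 1) mr_stop("rho must lie in [0, 1)")
  n <- length(x)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * m), n, m)
    shared <- stats::rnorm(n)
    e <- sqrt(1 - rho) * z + sqrt(rho) * shared
    f <- e
    f[, 1] <- f[, 1] + b1 * x
    f
  })
}

#' Simulate the two-modality toy model
#'
#' Two shared non-genetic factors `F` (n x 2) and one genetic factor `s`
#' drive two three-column modalities:
#' `M1 = [F, 0.1 s] + N(0, I)`, `M2 = [F, 0.2 s] + N(0, I)`, and the
#' phenotype `Y = 0.05 s + F %*% f_combiner + 0.8 e`.  All latent draws
#' are independent standard normal.
#'
#' @param n Number of individuals (>= 2).
#' @param seed Integer seed.
#' @param f_combiner How the two columns of `F` enter the scalar
#'   phenotype; defaults to the column sum `c(1, 1)`.
#' @param noise_sd Observation noise standard deviation for M1/M2
#'   (default 1; 0 gives the noise-free limit).
#' @return List with `F` (n x 2), `s`, `M1`, `M2` (n x 3 each), `Y`, and
#'   the seed used.
#' @export
simulate_toy_two_modality <- function(n, seed = 1, f_combiner = c(1, 1),
                                      noise_sd = 1) {
  if (n < 2) mr_stop("n must be >= 2")
  with_seed(seed, {
    f <- matrix(stats::rnorm(n * 2), n, 2)
    s <- stats::rnorm(n)
    m1 <- cbind(f, 0.1 * s) + matrix(stats::rnorm(n * 3, sd = noise_sd), n, 3)
    m2 <- cbind(f, 0.2 * s) + matrix(stats::rnorm(n * 3, sd = noise_sd), n, 3)
    y <- 0.05 * s + drop(f %*% f_combiner) + 0.8 * stats::rnorm(n)
    list(F = f, s = s, M1 = m1, M2 = m2, Y = y, rng_seed = seed)
  })
}

#' Latent factor model for multimodal waveform simulation
#'
#' @param k_shared Number of factors shared across all modalities.
#' @param k_specific Named integer vector (or scalar recycled) of
#'   modality-specific factor counts.
#' @param shared_sd,specific_sd Factor standard deviations.
#' @param noise_sd Per-point observation noise standard deviation.
#' @param genetic_fraction Fraction of shared factors driven by genotype.
#' @param h2 Variance of each genetic shared factor explained by its
#'   causal variants.
#' @param n_causal Causal variants per genetic factor.
#' @return List of class `latent_factor_model`.
#' @export
latent_factor_model <- function(k_shared = 4, k_specific = 8,
                                shared_sd = 1, specific_sd = 0.6,
                                noise_sd = 0.05,
                                genetic_fraction = 0, h2 = 0.3,
                                n_causal = 5) {
  if (k_shared < 0) mr_stop("k_shared must be >= 0")
  structure(list(k_shared = k_shared, k_specific = k_specific,
                 shared_sd = shared_sd, specific_sd = specific_sd,
                 noise_sd = noise_sd, genetic_fraction = genetic_fraction,
                 h2 = h2, n_causal = n_causal),
            class = "latent_factor_model")
}

#' Smooth waveform loading basis
#'
#' Gaussian bumps plus low-order harmonics: abstract but smooth,
#' PQRST-like shapes.  Realism is a non-goal; the statistical structure
#' (a full-column-rank linear loading of latent factors) is the contract.
#'
#' @param length_pts Waveform length.
#' @param k Number of basis columns needed.
#' @param n_bumps,n_harmonics Components available (their total must be
#'   >= `k`).
#' @param phase Deterministic phase offset so different modalities get
#'   different shapes.
#' @return `length_pts x k` full-column-rank loading matrix.
#' @export
waveform_basis <- function(length_pts, k, n_bumps = 8, n_harmonics = 4,
                           phase = 0) {
  if (k > n_bumps + n_harmonics)
    mr_stop("not enough basis components for requested factors")
  t0 <- seq(0, 1, length.out = length_pts)
  cols <- vector("list", n_bumps + n_harmonics)
  for (j in seq_len(n_bumps)) {
    ctr <- ((j - 1) / n_bumps + phase) %% 1
    cols[[j]] <- exp(-((t0 - ctr) / 0.06)^2)
  }
  for (j in seq_len(n_harmonics)) {
    cols[[n_bumps + j]] <- sin(2 * pi * j * t0 + 2 * pi * phase)
  }
  b <- do.call(cbind, cols)
  ## deterministic mixing so every factor touches several components
  mix <- outer(seq_len(ncol(b)), seq_len(k),
               function(i, j) cos(i * j + phase + i))
  out <- b %*% mix
  out <- scale(out, center = FALSE,
               scale = sqrt(colMeans(out^2)) * sqrt(length_pts))
  if (qr(out)$rank < k) mr_stop("waveform basis is rank deficient")
  out
}

#' Simulate multimodal waveforms from shared and specific latent factors
#'
#' `waveform_m = B_m %*% t([u, v_m]) + noise`, with `u` shared across
#' modalities and `v_m` modality specific.  Optionally the first
#' `round(genetic_fraction * k_shared)` shared factors are genetically
#' driven: `u_j = sqrt(h2) * standardized(X %*% b_j) + sqrt(1 - h2) * z`.
#'
#' @param n Number of individuals.
#' @param model A [latent_factor_model()].
#' @param modality_lengths Named integer vector of waveform lengths
#'   (default ECG lead I 600 points + PPG 100 points).
#' @param genotypes Optional `genotype_matrix` supplying `X` (required
#'   when `genetic_fraction > 0`).
#' @param seed Integer seed.
#' @return List with `waves` (named list of n x L matrices), `latents`
#'   (`u` plus per-modality `v`), `causal` (data.frame of factor, variant
#'   id, effect), and `sample_ids`.
#' @export
simulate_multimodal_waveforms <- function(n, model = latent_factor_model(),
                                          modality_lengths = c(ECG_leadI = 600L,
                                                               PPG = 100L),
                                          genotypes = NULL, seed = 1) {
  ks <- model$k_shared
  kspec <- rep_len(model$k_specific, length(modality_lengths))
  names(kspec) <- names(modality_lengths)
  n_gen <- round(model$genetic_fraction * ks)
  if (n_gen > 0 && is.null(genotypes))
    mr_stop("genetic factors requested but no genotypes supplied")
  with_seed(seed, {
    ids <- if (!is.null(genotypes)) rownames(genotypes$dosages)[seq_len(n)]
           else sprintf("S%06d", seq_len(n))
    u <- matrix(stats::rnorm(n * ks, sd = model$shared_sd), n, ks)
    causal <- NULL
    if (n_gen > 0) {
      x <- genotypes$dosages[seq_len(n), , drop = FALSE]
      p <- ncol(x)
      for (j in seq_len(n_gen)) {
        cv <- sample.int(p, model$n_causal)
        b <- stats::rnorm(model$n_causal)
        g <- drop(x[, cv, drop = FALSE] %*% b)
        g <- (g - mean(g)) / stats::sd(g)
        u[, j] <- model$shared_sd *
          (sqrt(model$h2) * g + sqrt(1 - model$h2) * stats::rnorm(n))
        causal <- rbind(causal, data.frame(
          factor = j, id = colnames(x)[cv], effect = b))
      }
    }
    waves <- list(); latents <- list(u = u)
    for (i in seq_along(modality_lengths)) {
      mod <- names(modality_lengths)[i]
      L <- modality_lengths[[i]]
      v <- matrix(stats::rnorm(n * kspec[i], sd = model$specific_sd),
                  n, kspec[i])
      b_m <- waveform_basis(L, ks + kspec[i], phase = (i - 1) * 0.37)
      w <- cbind(u, v) %*% t(b_m) * sqrt(L) +
        matrix(stats::rnorm(n * L, sd = model$noise_sd), n, L)
      rownames(w) <- ids
      waves[[mod]] <- w
      latents[[paste0("v_", mod)]] <- v
    }
    list(waves = waves, latents = latents, causal = causal,
         sample_ids = ids)
  })
}

#' Simulate a covariate table
#'
#' Age, sex, BMI, smoking status, genotyping array indicator, and 15
#' genetic principal components, drawn independently of the waveforms
#' (the association engine adjusts for them regardless).
#'
#' @param n Number of individuals.
#' @param sample_ids Optional ids (default S000001...).
#' @param seed Integer seed.
#' @return data.frame with rownames = sample ids.
#' @export
simulate_covariates <- function(n, sample_ids = NULL, seed = 1) {
  with_seed(seed, {
    ids <- sample_ids %||% sprintf("S%06d", seq_len(n))
    pcs <- matrix(stats::rnorm(n * 15), n, 15,
                  dimnames = list(NULL, paste0("PC", 1:15)))
    out <- data.frame(age = stats::rnorm(n, 58, 8),
                      sex = stats::rbinom(n, 1, 0.5),
                      bmi = stats::rnorm(n, 27, 4),
                      smoking = stats::rbinom(n, 1, 0.45),
                      array = stats::rbinom(n, 1, 0.9))
    out <- cbind(out, pcs)
    rownames(out) <- ids
    out
  })
}
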