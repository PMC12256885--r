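## Methodological experiments: CCA complementarity screening, the
## calibration/power simulation comparing the naive summed chi-squared,
## the PCA-decorrelated summed chi-squared, and MANOVA, the two-modality
## toy study contrasting M-style and U-style embeddings, and the
## end-to-end synthetic benchmark.

#' First canonical correlation between two data blocks
#'
#' Whitened cross-covariance SVD after mean-centring; measures shared
#' information between modalities (0 = no overlap, 1 = complete overlap).
#' Rank-deficient blocks are ridge-regularized with a warning.  A
#' bootstrap standard error over sample resampling is attached.
#'
#' @param x,y Numeric matrices over the same samples (`n > p + q`).
#' @param n_boot Bootstrap replicates (default 100).
#' @param seed Integer seed for the bootstrap.
#' @return List with `cor` (first canonical correlation) and `se`.
#' @export
cca_max_corr <- function(x, y, n_boot = 100, seed = 1) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (n != nrow(y)) mr_stop("blocks must share samples")
  if (n <= ncol(x) + ncol(y)) mr_stop("need n > p + q")
  first_cc <- function(xi, yi) {
    xc <- scale(xi, scale = FALSE); yc <- scale(yi, scale = FALSE)
    sxx <- crossprod(xc) / (n - 1); syy <- crossprod(yc) / (n - 1)
    sxy <- crossprod(xc, yc) / (n - 1)
    inv_sqrt <- function(s) {
      e <- eigen(s, symmetric = TRUE)
      vals <- e$values
      if (min(vals) < 1e-10 * max(vals)) {
        warning("rank-deficient block; ridge regularized")
        vals <- vals + 1e-8 * max(vals)
      }
      e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
    }
    k <- inv_sqrt(sxx) %*% sxy %*% inv_sqrt(syy)
    min(1, svd(k, nu = 0, nv = 0)$d[1])
  }
  cc <- first_cc(x, y)
  se <- NA_real_
  if (n_boot > 0) {
    reps <- with_seed(seed, vapply(seq_len(n_boot), function(r) {
      i <- sample.int(n, replace = TRUE)
      suppressWarnings(first_cc(x[i, , drop = FALSE], y[i, , drop = FALSE]))
    }, numeric(1)))
    se <- stats::sd(reps)
  }
  list(cor = cc, se = se)
}

## Vectorized per-column simple regression chi-squared of Y on x.
sum_chi2_columns <- function(y, x) {
  n <- length(x)
  xc <- x - mean(x)
  xss <- sum(xc^2)
  yc <- sweep(y, 2, colMeans(y))
  xy <- drop(crossprod(yc, xc))
  beta <- xy / xss
  rss <- colSums(yc^2) - beta * xy
  s2 <- rss / (n - 2)
  beta^2 * xss / s2
}

#' Power-study configuration
#'
#' @param rho_list Noise correlations to study (default 0, 0.2, 0.3).
#' @param m Number of factors (default 10).
#' @param n Individuals per replicate (default 5000).
#' @param replicates Monte-Carlo replicates per cell (>= 100 for
#'   reported tables; default 1000).
#' @param alpha Test level (default 0.05).
#' @param maf Variant minor allele frequency (default 0.3).
#' @param b1 Reference genetic effect on factor 1 (default 0.001, the
#'   documented reference parameterization).
#' @param effect_scale Multiplier applied to `b1` under the alternative.
#'   The default 70 is derived from the noncentral chi-squared power
#'   function so that the MANOVA test has power near 0.5 at `n = 5000`:
#'   the noncentrality is `n * (b1 * effect_scale)^2 * 2 maf (1 - maf)`.
#' @param seed Integer seed.
#' @return List of class `power_study_config`.
#' @export
power_study_config <- function(rho_list = c(0, 0.2, 0.3), m = 10, n = 5000,
                               replicates = 1000, alpha = 0.05, maf = 0.3,
                               b1 = 0.001, effect_scale = 70, seed = 1) {
  if (alpha <= 0 || alpha >= 1) mr_stop("alpha must lie in (0, 1)")
  structure(list(rho_list = rho_list, m = m, n = n,
                 replicates = replicates, alpha = alpha, maf = maf,
                 b1 = b1, effect_scale = effect_scale, seed = seed),
            class = "power_study_config")
}

#' Calibration and power study: naive vs PCA-combined vs MANOVA
#'
#' For each noise correlation `rho` and each replicate, draws one variant
#' and `m` correlated factors via [simulate_correlated_factors()], then
#' applies three tests of the variant against the factor set: the naive
#' summed chi-squared over the raw (correlated) factors, the summed
#' chi-squared over the sample PCs of the factors, and Wilks' MANOVA.
#' Each test is run under the null (`b1 = 0`) and the alternative
#' (`b1 * effect_scale`), giving type-I error and power with binomial
#' Monte-Carlo standard errors.
#'
#' @param config A [power_study_config()].
#' @return List of class `study_report` with `rates` (data.frame: method,
#'   rho, scenario, rate, se, replicates), `equivalence` (paired
#'   PCA-vs-MANOVA rate differences with paired SEs) and the config.
#' @export
run_power_study <- function(config = power_study_config()) {
  stopifnot(inherits(config, "power_study_config"))
  m <- config$m; n <- config$n; alpha <- config$alpha
  reps <- config$replicates
  methods <- c("naive", "pca", "manova")
  rates <- list(); equiv <- list()
  for (rho in config$rho_list) {
    rej <- array(FALSE, c(reps, 3, 2),
                 dimnames = list(NULL, methods, c("null", "alt")))
    for (r in seq_len(reps)) {
      s0 <- child_seed(config$seed, r * 7 + round(rho * 1000))
      x <- with_seed(s0, stats::rbinom(n, 2, config$maf))
      for (scen in c("null", "alt")) {
        b1 <- if (scen == "null") 0 else config$b1 * config$effect_scale
        f <- simulate_correlated_factors(x, m = m, rho = rho, b1 = b1,
                                         seed = child_seed(s0, 13))
        chi_naive <- sum(sum_chi2_columns(f, x))
        fc <- sweep(f, 2, colMeans(f))
        pcs <- fc %*% svd(fc, nu = 0)$v
        chi_pca <- sum(sum_chi2_columns(pcs, x))
        mano <- manova_oracle(f, x)
        rej[r, "naive", scen] <- chisq_sf(chi_naive, m) < alpha
        rej[r, "pca", scen] <- chisq_sf(chi_pca, m) < alpha
        rej[r, "manova", scen] <- mano$p_chisq < alpha
      }
    }
    for (scen in c("null", "alt")) for (meth in methods) {
      rate <- mean(rej[, meth, scen])
      rates[[length(rates) + 1L]] <- data.frame(
        method = meth, rho = rho, scenario = scen, rate = rate,
        se = sqrt(rate * (1 - rate) / reps), replicates = reps)
    }
    for (scen in c("null", "alt")) {
      d <- rej[, "pca", scen] - rej[, "manova", scen]
      equiv[[length(equiv) + 1L]] <- data.frame(
        rho = rho, scenario = scen, diff = mean(d),
        se_paired = stats::sd(d) / sqrt(reps))
    }
  }
  structure(list(rates = do.call(rbind, rates),
                 equivalence = do.call(rbind, equiv),
                 config = config),
            class = "study_report")
}

#' Two-modality toy study: M-style vs U-style embeddings
#'
#' Draws the printed toy model via [simulate_toy_two_modality()].  The
#' U-style embedding is PCA(2) of each modality, concatenated (4 dims);
#' the M-style embedding is PCA of the concatenated modalities truncated
#' to the leading `k_keep` components (default: number of shared factors
#' + 1 = 3, the dimensions that can carry `[F, s]`).  Per replicate the
#' study reports (a) the correlation between the two styles' linear
#' in-sample predictions of the phenotype and (b) the maximum
#' association chi-squared between the genetic factor `s` and any
#' embedding coordinate, per style.
#'
#' @param n Individuals per replicate (default 50000).
#' @param replicates Number of replicates (default 200).
#' @param seed Integer seed.
#' @param k_keep M-style truncation (default 3).
#' @return List of class `study_report` with `draws` (per-replicate
#'   data.frame) and `summary`.
#' @export
run_mu_toy_study <- function(n = 50000, replicates = 200, seed = 1,
                             k_keep = 3) {
  pca_scores <- function(x, k) {
    xc <- sweep(x, 2, colMeans(x))
    xc %*% svd(xc, nu = 0)$v[, seq_len(k), drop = FALSE]
  }
  lm_pred <- function(y, emb) qr.fitted(qr(cbind(1, emb)), y)
  draws <- lapply(seq_len(replicates), function(r) {
    toy <- simulate_toy_two_modality(n, seed = child_seed(seed, r))
    emb_u <- cbind(pca_scores(toy$M1, 2), pca_scores(toy$M2, 2))
    emb_m <- pca_scores(cbind(toy$M1, toy$M2), k_keep)
    pred_corr <- stats::cor(lm_pred(toy$Y, emb_u), lm_pred(toy$Y, emb_m))
    chi_u <- max(sum_chi2_columns(emb_u, toy$s))
    chi_m <- max(sum_chi2_columns(emb_m, toy$s))
    data.frame(replicate = r, pred_corr = pred_corr,
               s_chi2_m = chi_m, s_chi2_u = chi_u)
  })
  draws <- do.call(rbind, draws)
  summary <- data.frame(
    mean_pred_corr = mean(draws$pred_corr),
    se_pred_corr = stats::sd(draws$pred_corr) / sqrt(replicates),
    median_s_chi2_m = stats::median(draws$s_chi2_m),
    median_s_chi2_u = stats::median(draws$s_chi2_u),
    frac_m_gt_u = mean(draws$s_chi2_m > draws$s_chi2_u),
    replicates = replicates)
  structure(list(draws = draws, summary = summary,
                 config = list(n = n, replicates = replicates,
                               k_keep = k_keep, seed = seed)),
            class = "study_report")
}

#' End-to-end benchmark configuration
#'
#' Defaults define the small synthetic preset: 2000 individuals, 500
#' variants, two modalities (ECG lead I + PPG, concatenation fusion),
#' a latent budget of 4 per modality, and two of the four shared latent
#' factors genetically driven.
#'
#' @param n,p_variants Cohort and variant counts.
#' @param maf Variant minor allele frequency.
#' @param k_per_modality Latent dimensions per modality (U-style);
#'   M-style uses the matched total.
#' @param genetic If `FALSE`, remove all genetic signal (b = 0 null run).
#' @param h2,n_causal Genetic architecture of each genetic shared factor.
#' @param m_epochs,u_epochs,hidden,beta,batch_size VAE training budget.
#' @param p_thresh,r2_thresh,merge_gap_bp Hits/loci thresholds.
#' @param run_prs Fit and evaluate a risk score when >= 2 hits are found.
#' @param seed Integer seed.
#' @return List of class `e2e_config`.
#' @export
e2e_config <- function(n = 2000, p_variants = 500, maf = 0.3,
                       k_per_modality = 4, genetic = TRUE, h2 = 0.3,
                       n_causal = 5, m_epochs = 60, u_epochs = 30,
                       hidden = 64, beta = 1e-3, batch_size = 250,
                       p_thresh = 5e-8, r2_thresh = 0.1,
                       merge_gap_bp = 250000, run_prs = TRUE, seed = 1) {
  structure(as.list(environment()), class = "e2e_config")
}

#' Run the full synthetic pipeline end to end
#'
#' Generates genotypes, genetically driven multimodal waveforms,
#' covariates and a binary phenotype; preprocesses (QC, deterministic
#' split, training-split scale factors, fusion); trains the multimodal
#' VAE and the per-modality unimodal VAEs; encodes the combined
#' train+validation set; orthogonalizes; runs the covariate-adjusted
#' association scan per coordinate; combines, clumps and builds loci for
#' both styles; and optionally fits an elastic-net risk score on the hit
#' dosages.  Deterministic given the config seed.
#'
#' @param config An [e2e_config()].
#' @param out_dir Optional directory for TSV artifacts.
#' @return List with per-style results (`m`, `u`: hits, loci, combined,
#'   embeddings, prs) plus `truth` (causal variants) and `config`.
#' @export
run_end_to_end <- function(config = e2e_config(), out_dir = NULL) {
  stopifnot(inherits(config, "e2e_config"))
  seed <- config$seed
  lengths <- c(ECG_leadI = 600L, PPG = 100L)
  ## -- simulate ------------------------------------------------------
  geno <- simulate_genotypes(config$n, config$p_variants, maf = config$maf,
                             seed = child_seed(seed, 1))
  model <- latent_factor_model(k_shared = 4, k_specific = 8,
                               genetic_fraction = if (config$genetic) 0.5 else 0,
                               h2 = config$h2, n_causal = config$n_causal)
  sim <- simulate_multimodal_waveforms(config$n, model, lengths,
                                       genotypes = geno,
                                       seed = child_seed(seed, 2))
  covs <- simulate_covariates(config$n, sim$sample_ids,
                              seed = child_seed(seed, 3))
  liab <- with_seed(child_seed(seed, 4), {
    gcols <- if (config$genetic) 1:2 else 1:2  # same liability structure
    drop(sim$latents$u[, gcols] %*% c(1, 1)) + stats::rnorm(config$n)
  })
  pheno <- as.integer(liab > pctl(liab, 0.9))
  names(pheno) <- sim$sample_ids
  ## -- preprocess ----------------------------------------------------
  qc <- qc_filter(sim$waves)
  waves <- lapply(sim$waves, function(w) w[qc$kept, , drop = FALSE])
  split <- assign_split(qc$kept)
  names(split) <- qc$kept
  train_ids <- qc$kept[split == "train"]
  val_ids <- qc$kept[split == "val"]
  test_ids <- qc$kept[split == "test"]
  sf <- vapply(waves, function(w)
    compute_scale_factor(w[train_ids, , drop = FALSE]), numeric(1))
  spec_m <- fusion_spec("concatenate", names(lengths), as.list(sf))
  subset_waves <- function(ids) lapply(waves, function(w) w[ids, , drop = FALSE])
  fuse_ids <- function(ids, spec) fuse(subset_waves(ids), spec)
  ## -- train ---------------------------------------------------------
  k <- config$k_per_modality
  cfg_m <- vae_config(2 * k, hidden = config$hidden, beta = config$beta,
                      epochs = config$m_epochs, batch_size = config$batch_size,
                      seed = child_seed(seed, 5))
  cand_m <- train_vae(fuse_ids(train_ids, spec_m), fuse_ids(val_ids, spec_m),
                      cfg_m)
  cands_u <- lapply(seq_along(lengths), function(i) {
    mod <- names(lengths)[i]
    spec_u <- fusion_spec("concatenate", mod, as.list(sf[mod]))
    cfg_u <- vae_config(k, hidden = config$hidden, beta = config$beta,
                        epochs = config$u_epochs,
                        batch_size = config$batch_size,
                        seed = child_seed(seed, 6 + i))
    train_vae(fuse_ids(train_ids, spec_u), fuse_ids(val_ids, spec_u), cfg_u)
  })
  names(cands_u) <- names(lengths)
  ## -- embed + associate (train + validation set, as the GWAS set) ---
  gwas_ids <- c(train_ids, val_ids)
  emb_m <- encode(cand_m, fuse_ids(gwas_ids, spec_m))
  emb_u <- concat_embeddings(lapply(names(lengths), function(mod) {
    spec_u <- fusion_spec("concatenate", mod, as.list(sf[mod]))
    encode(cands_u[[mod]], fuse_ids(gwas_ids, spec_u))
  }))
  run_style <- function(emb) {
    pc <- orthogonalize(emb)
    at <- assoc_scan_all(pc, geno$dosages[gwas_ids, , drop = FALSE],
                         covs[gwas_ids, , drop = FALSE])
    combined <- combine_chi2(at)
    hits <- clump(combined, geno, p_thresh = config$p_thresh,
                  r2_thresh = config$r2_thresh)
    loci <- build_loci(hits, geno, r2_span = config$r2_thresh,
                       merge_gap_bp = config$merge_gap_bp)
    prs <- NULL
    if (config$run_prs && nrow(hits) >= 2) {
      dos_tr <- geno$dosages[train_ids, hits$id, drop = FALSE]
      prs_fit <- fit_prs(dos_tr, pheno[train_ids],
                         seed = child_seed(seed, 20))
      sc_test <- score_prs(prs_fit, geno$dosages[test_ids, , drop = FALSE])
      prs <- list(model = prs_fit,
                  eval = evaluate_scores(sc_test, pheno[test_ids],
                                         seed = child_seed(seed, 21)))
    }
    list(embedding = emb, pc = pc, combined = combined, hits = hits,
         loci = loci, prs = prs)
  }
  res_m <- run_style(emb_m)
  res_u <- run_style(emb_u)
  out <- list(m = res_m, u = res_u,
              truth = sim$causal, config = config,
              split = split, n_gwas = length(gwas_ids))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(res_m$combined, file.path(out_dir, "combined_m.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res_u$combined, file.path(out_dir, "combined_u.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res_m$hits, file.path(out_dir, "hits_m.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res_u$hits, file.path(out_dir, "hits_u.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res_m$loci, file.path(out_dir, "loci_m.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res_u$loci, file.path(out_dir, "loci_u.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}
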