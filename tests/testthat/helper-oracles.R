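## Independent brute-force oracles and small fixture builders used across
## the suite.  These deliberately re-derive results with plain loops so
## they share no code path with the package implementations they check.

## Plain-loop greedy clumping: scan for the smallest remaining p value,
## absorb everything correlated with it, repeat.
brute_clump <- function(combined, geno, p_thresh = 5e-8, r2_thresh = 0.1,
                        radius_kb = 500) {
  v <- geno$variants
  rows <- which(!is.na(combined$combined_p) & combined$combined_p < p_thresh &
                  combined$id %in% v$id)
  ids <- combined$id[rows]
  ps <- combined$combined_p[rows]
  pos <- v$pos[match(ids, v$id)]
  chrom <- v$chrom[match(ids, v$id)]
  taken <- rep(FALSE, length(ids))
  leads <- character()
  while (!all(taken)) {
    free <- which(!taken)
    lead <- free[order(ps[free], ids[free])][1]
    leads <- c(leads, ids[lead])
    for (j in free) {
      if (chrom[j] != chrom[lead]) next
      if (abs(pos[j] - pos[lead]) > radius_kb * 1000) next
      r <- stats::cor(geno$dosages[, ids[lead]], geno$dosages[, ids[j]])
      if (j == lead || (!is.na(r) && r^2 >= r2_thresh)) taken[j] <- TRUE
    }
    taken[lead] <- TRUE
  }
  leads
}

## Plain-loop locus construction: per-hit LD span, then repeated pairwise
## merging until a fixed point is reached.
brute_loci <- function(hit_ids, geno, r2_span = 0.1, merge_gap_bp = 250000) {
  v <- geno$variants
  spans <- lapply(hit_ids, function(id) {
    lead_pos <- v$pos[v$id == id]
    lead_chr <- v$chrom[v$id == id]
    pos <- lead_pos
    for (j in seq_len(nrow(v))) {
      if (v$chrom[j] != lead_chr) next
      r <- stats::cor(geno$dosages[, id], geno$dosages[, v$id[j]])
      if (!is.na(r) && r^2 >= r2_span) pos <- c(pos, v$pos[j])
    }
    list(chrom = lead_chr, start = min(pos), end = max(pos))
  })
  repeat {
    merged <- FALSE
    for (i in seq_along(spans)) {
      for (j in seq_along(spans)) {
        if (i >= j) next
        a <- spans[[i]]; b <- spans[[j]]
        if (a$chrom != b$chrom) next
        gap <- max(a$start, b$start) - min(a$end, b$end)
        if (gap < merge_gap_bp) {
          spans[[i]] <- list(chrom = a$chrom,
                             start = min(a$start, b$start),
                             end = max(a$end, b$end))
          spans[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  out <- do.call(rbind, lapply(spans, as.data.frame))
  out[order(out$chrom, out$start), , drop = FALSE]
}

## Low-rank waveform matrix with known subspace, for representation tests.
make_lowrank_waves <- function(n, len, rank, noise_sd = 0, seed = 1) {
  set.seed(seed)
  scores <- matrix(rnorm(n * rank), n, rank)
  t0 <- seq(0, 1, length.out = len)
  basis <- sapply(seq_len(rank), function(j) sin(2 * pi * j * t0 + j))
  w <- scores %*% t(basis) / rank +
    matrix(rnorm(n * len, sd = noise_sd), n, len)
  rownames(w) <- sprintf("s%04d", seq_len(n))
  w
}

## Small multimodal dataset on the package generator, shared across tests.
make_mm_data <- function(n, seed = 1, genetic_fraction = 0, geno = NULL,
                         lengths = c(ECG_leadI = 600L, PPG = 100L)) {
  model <- latent_factor_model(genetic_fraction = genetic_fraction)
  simulate_multimodal_waveforms(n, model, lengths, genotypes = geno,
                                seed = seed)
}

## Textbook per-column simple-regression chi-squared via correlations:
## t^2 = (n - 2) r^2 / (1 - r^2), equal to the squared Wald statistic.
sum_chi2_cols_for_test <- function(y, x) {
  n <- length(x)
  r <- as.numeric(cor(x, y))
  (n - 2) * r^2 / (1 - r^2)
}

## Empty hits table matching the clump() schema.
clump_empty_for_test <- function() {
  data.frame(id = character(), chrom = character(), pos = numeric(),
             sum_chi2 = numeric(), combined_p = numeric(),
             n_members = integer(), members = character(),
             stringsAsFactors = FALSE)
}

## Seeded draw that restores the RNG state afterwards.
with_seed_for_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
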