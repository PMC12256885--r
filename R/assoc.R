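## Association engine: PCA orthogonalization of embeddings,
## covariate-adjusted per-coordinate OLS association scans, the summed
## chi-squared combined statistic with a chi-squared(m) reference, a
## Wilks-MANOVA oracle, variant QC, greedy clumping and locus merging.

#' Orthogonalize embeddings by full-retention PCA
#'
#' Projects the raw embeddings onto all their principal components so the
#' coordinate sample correlations are exactly zero (no dimension loss,
#' hence no loss of information).  Zero-variance components are dropped
#' with a loud warning since that reduces the degrees of freedom of the
#' combined statistic.  The sign convention of [pca_embed()] is applied.
#'
#' @param embeddings An `embedding_matrix` (requires `n > d`).
#' @param tol Relative variance tolerance below which a component counts
#'   as zero variance.
#' @return List of class `pc_embedding` with `values` (n x m), `rotation`
#'   (d x m), `center`, `dropped` (indices) and `m` (the downstream df).
#' @export
orthogonalize <- function(embeddings, tol = 1e-12) {
  x <- if (inherits(embeddings, "embedding_matrix")) embeddings$values else
    as.matrix(embeddings)
  n <- nrow(x); d <- ncol(x)
  if (n <= d) mr_stop("orthogonalization requires n > d")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = 0)
  keep <- sv$d^2 / max(sv$d^2) > tol & sv$d > 0
  if (!all(keep))
    warning(sprintf("dropping %d zero-variance component(s); df reduced to %d",
                    sum(!keep), sum(keep)))
  rot <- sv$v[, keep, drop = FALSE]
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  vals <- xc %*% rot
  colnames(vals) <- paste0("PC", seq_len(ncol(vals)))
  rownames(vals) <- rownames(x)
  structure(list(sample_ids = rownames(x), values = vals, rotation = rot,
                 center = ctr, dropped = which(!keep), m = ncol(vals)),
            class = "pc_embedding")
}

#' Variant quality control
#'
#' Retains variants with minor allele frequency >= 0.001, imputation INFO
#' >= 0.8, missing call fraction <= 0.05 and Hardy-Weinberg p > 1e-10
#' (inequality directions exactly as stated; the MAF bound is inclusive,
#' the HWE bound strict).  A missing column skips that filter with a
#' warning.
#'
#' @param variants data.frame with (any of) columns `maf`, `info`,
#'   `missing_frac`, `hwe_p`.
#' @param maf_min,info_min,missing_max,hwe_min Thresholds.
#' @return The filtered data.frame.
#' @export
variant_qc <- function(variants, maf_min = 0.001, info_min = 0.8,
                       missing_max = 0.05, hwe_min = 1e-10) {
  keep <- rep(TRUE, nrow(variants))
  apply_f <- function(col, f) {
    if (is.null(variants[[col]])) {
      warning(sprintf("column '%s' missing; filter skipped", col))
      keep
    } else keep & f(variants[[col]])
  }
  keep <- apply_f("maf", function(v) v >= maf_min)
  keep <- apply_f("info", function(v) v >= info_min)
  keep <- apply_f("missing_frac", function(v) v <= missing_max)
  keep <- apply_f("hwe_p", function(v) v > hwe_min)
  variants[keep, , drop = FALSE]
}

## Build the covariate design (with intercept), checking collinearity.
covariate_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  cm <- as.matrix(covariates)
  storage.mode(cm) <- "double"
  x <- cbind(`(Intercept)` = 1, cm)
  q <- qr(x)
  if (q$rank < ncol(x)) {
    bad <- colnames(x)[q$pivot[(q$rank + 1):ncol(x)]]
    mr_stop(paste0("collinear covariates: ", paste(bad, collapse = ", ")),
            "mregle_collinear")
  }
  x
}

#' Covariate-adjusted association scan of one phenotype
#'
#' Ordinary least squares of the phenotype on each variant's dosage plus
#' covariates (all models adjusted for the same covariate set), computed
#' by residualizing both sides on the covariates once and then running
#' the per-variant score regressions in vectorized form.  The Wald
#' statistic is `(beta / se)^2` with a chi-squared(1) p value.
#'
#' @param pheno Numeric phenotype vector.
#' @param genotypes `genotype_matrix` or dosage matrix (n x p).
#' @param covariates Optional data.frame/matrix of covariates.
#' @return data.frame with id, beta, se, chi2, p; monomorphic variants
#'   get NA rows.  Attributes `n` and `df_resid` record the fit size.
#' @export
assoc_scan <- function(pheno, genotypes, covariates = NULL) {
  g <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else
    as.matrix(genotypes)
  n <- length(pheno)
  stopifnot(nrow(g) == n)
  x <- covariate_design(covariates, n)
  qx <- qr(x)
  ry <- qr.resid(qx, pheno)
  rg <- qr.resid(qx, g)
  gss <- colSums(rg^2)
  mono <- gss <= 1e-12 * n
  df <- n - ncol(x) - 1L
  gy <- colSums(rg * ry)
  beta <- gy / gss
  rss <- sum(ry^2) - beta * gy
  sigma2 <- rss / df
  se <- sqrt(sigma2 / gss)
  chi2 <- (beta / se)^2
  beta[mono] <- se[mono] <- chi2[mono] <- NA_real_
  out <- data.frame(id = colnames(g) %||% paste0("v", seq_len(ncol(g))),
                    beta = beta, se = se, chi2 = chi2,
                    p = chisq_sf(chi2, 1),
                    monomorphic = mono, stringsAsFactors = FALSE)
  out$p[mono] <- NA_real_
  attr(out, "n") <- n
  attr(out, "df_resid") <- df
  attr(out, "covariates") <- colnames(x)[-1]
  out
}

#' Association scan over every coordinate of a PC embedding
#'
#' @param pc A `pc_embedding` (or plain matrix of decorrelated
#'   phenotypes).
#' @param genotypes `genotype_matrix` or dosage matrix.
#' @param covariates Optional covariates shared by every scan.
#' @return List of class `assoc_table`: `chi2` (p x m matrix), `beta`,
#'   `se`, `variants` (ids), `m`, `n`.
#' @export
assoc_scan_all <- function(pc, genotypes, covariates = NULL) {
  vals <- if (inherits(pc, "pc_embedding")) pc$values else as.matrix(pc)
  g <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else
    as.matrix(genotypes)
  scans <- lapply(seq_len(ncol(vals)), function(j)
    assoc_scan(vals[, j], g, covariates))
  chi2 <- do.call(cbind, lapply(scans, `[[`, "chi2"))
  beta <- do.call(cbind, lapply(scans, `[[`, "beta"))
  se <- do.call(cbind, lapply(scans, `[[`, "se"))
  colnames(chi2) <- colnames(beta) <- colnames(se) <-
    colnames(vals) %||% paste0("PC", seq_len(ncol(vals)))
  structure(list(chi2 = chi2, beta = beta, se = se,
                 variants = scans[[1]]$id, m = ncol(vals),
                 n = attr(scans[[1]], "n"),
                 decorrelated = inherits(pc, "pc_embedding")),
            class = "assoc_table")
}

#' Combine per-coordinate chi-squared statistics
#'
#' Sums the per-coordinate Wald chi-squared statistics for each variant
#' and refers the sum to a chi-squared distribution with `m` (the number
#' of retained, decorrelated coordinates) degrees of freedom.  The upper
#' tail is computed on the log scale; reported doubles are floored at the
#' smallest positive normal and the log10 p value is carried alongside.
#'
#' @param assoc An `assoc_table` from [assoc_scan_all()] (coordinates
#'   must be pre-decorrelated), or a p x m chi-squared matrix.
#' @param variants Optional variant ids when a bare matrix is given.
#' @return data.frame of class `combined_result` with id, sum_chi2, df,
#'   combined_p, log10_p.
#' @export
combine_chi2 <- function(assoc, variants = NULL) {
  if (inherits(assoc, "assoc_table")) {
    chi2 <- assoc$chi2
    ids <- assoc$variants
    if (!isTRUE(assoc$decorrelated))
      warning("coordinates were not orthogonalized; the chi-squared(m) ",
              "reference assumes uncorrelated phenotypes")
  } else {
    chi2 <- as.matrix(assoc)
    ids <- variants %||% rownames(chi2) %||% paste0("v", seq_len(nrow(chi2)))
    if (is.null(dim(chi2))) chi2 <- matrix(chi2, ncol = 1)
  }
  m <- ncol(chi2)
  s <- rowSums(chi2)
  out <- data.frame(id = ids, sum_chi2 = s, df = m,
                    combined_p = chisq_sf(s, m),
                    log10_p = chisq_log10sf(s, m),
                    stringsAsFactors = FALSE)
  class(out) <- c("combined_result", "data.frame")
  out
}

#' MANOVA (Wilks) oracle for a single variant
#'
#' Likelihood-ratio test of the genotype term on the m-variate outcome
#' after covariate adjustment.  Used as an independent equivalence
#' oracle for the summed chi-squared statistic.
#'
#' For a single-dosage hypothesis Wilks' lambda is `1 - R^2` with `R^2`
#' the squared multiple correlation of the residualized dosage with the
#' residualized outcomes, and `(1 - lambda) / lambda * (n - c - m - 1) / m`
#' follows an exact F(m, n - c - m - 1) distribution under normality, so
#' at `m = 1` the oracle reduces exactly to the univariate regression
#' t-test.  The Bartlett chi-squared(m) approximation is reported
#' alongside for comparison with the summed chi-squared statistic.
#'
#' @param pc `pc_embedding` or numeric outcome matrix.
#' @param g Dosage vector for one variant.
#' @param covariates Optional covariates.
#' @return List with `wilks`, `f`, `df1`, `df2`, `p` (exact F),
#'   `chi2` and `p_chisq` (Bartlett chi-squared(m) approximation).
#' @export
manova_oracle <- function(pc, g, covariates = NULL) {
  y <- if (inherits(pc, "pc_embedding")) pc$values else as.matrix(pc)
  n <- nrow(y); m <- ncol(y)
  x <- covariate_design(covariates, n)
  qx <- qr(x)
  ry <- qr.resid(qx, y)
  rg <- qr.resid(qx, g)
  gss <- sum(rg^2)
  if (gss <= 1e-12 * n) mr_stop("monomorphic genotype")
  a <- crossprod(ry)                 # m x m
  bvec <- crossprod(ry, rg)          # m x 1
  r2 <- drop(crossprod(bvec, solve(a, bvec))) / gss
  lambda <- 1 - r2
  nc <- ncol(x) - 1L                 # covariates excluding intercept
  df2 <- n - nc - m - 1
  f <- (1 - lambda) / lambda * df2 / m
  chi2 <- -(n - nc - 1 - (m + 2) / 2) * log(lambda)
  list(wilks = lambda, f = f, df1 = m, df2 = df2,
       p = stats::pf(f, m, df2, lower.tail = FALSE),
       chi2 = chi2, p_chisq = chisq_sf(chi2, m))
}

#' LD r-squared between dosage columns of a reference panel
#' @noRd
panel_r2 <- function(dos, i, js) {
  gi <- dos[, i]
  gi[is.na(gi)] <- mean(gi, na.rm = TRUE)
  sapply(js, function(j) {
    gj <- dos[, j]
    gj[is.na(gj)] <- mean(gj, na.rm = TRUE)
    if (stats::sd(gi) == 0 || stats::sd(gj) == 0) return(0)
    stats::cor(gi, gj)^2
  })
}

#' Greedy clumping of combined association results
#'
#' Repeatedly takes the most significant unassigned variant with
#' `combined_p < p_thresh` as a clump lead and assigns every unassigned
#' variant within `radius_kb` on the same chromosome with panel
#' `r^2 >= r2_thresh` to it.  Leads are the reported hits, mutually
#' independent at `r^2 < r2_thresh`.
#'
#' @param combined A `combined_result`.
#' @param ref_genotypes `genotype_matrix` reference panel covering the
#'   significant variants (dosages are mean-imputed for correlation).
#' @param p_thresh Genome-wide significance threshold (default 5e-8).
#' @param r2_thresh LD independence threshold (default 0.1).
#' @param radius_kb Window half-width in kb (default 500).
#' @return data.frame of hits: id, chrom, pos, sum_chi2, combined_p,
#'   n_members, members (comma-joined ids).
#' @export
clump <- function(combined, ref_genotypes, p_thresh = 5e-8,
                  r2_thresh = 0.1, radius_kb = 500) {
  v <- ref_genotypes$variants
  dos <- ref_genotypes$dosages
  tab <- merge(as.data.frame(combined), v[, c("id", "chrom", "pos")],
               by = "id", sort = FALSE)
  missing <- setdiff(combined$id, tab$id)
  if (length(missing))
    warning(sprintf("%d variant(s) absent from reference panel excluded",
                    length(missing)))
  sig <- tab[!is.na(tab$combined_p) & tab$combined_p < p_thresh, , drop = FALSE]
  if (!nrow(sig)) return(empty_hits())
  sig <- sig[order(sig$combined_p, sig$id), , drop = FALSE]
  assigned <- rep(FALSE, nrow(sig))
  hits <- list()
  col_of <- match(sig$id, colnames(dos))
  while (any(!assigned)) {
    lead <- which(!assigned)[1]
    cand <- which(!assigned & sig$chrom == sig$chrom[lead] &
                    abs(sig$pos - sig$pos[lead]) <= radius_kb * 1000)
    r2 <- panel_r2(dos, col_of[lead], col_of[cand])
    member <- cand[r2 >= r2_thresh | cand == lead]
    assigned[member] <- TRUE
    hits[[length(hits) + 1L]] <- data.frame(
      id = sig$id[lead], chrom = sig$chrom[lead], pos = sig$pos[lead],
      sum_chi2 = sig$sum_chi2[lead], combined_p = sig$combined_p[lead],
      n_members = length(member),
      members = paste(sig$id[member], collapse = ","),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, hits)
}

empty_hits <- function() {
  data.frame(id = character(), chrom = character(), pos = numeric(),
             sum_chi2 = numeric(), combined_p = numeric(),
             n_members = integer(), members = character(),
             stringsAsFactors = FALSE)
}

#' Build loci from clumped hits
#'
#' For each hit the locus interval is the span (min to max position,
#' 1-based inclusive) of reference-panel variants with `r^2 >= r2_span`
#' to the hit, including the hit itself.  Intervals on the same
#' chromosome separated by fewer than `merge_gap_bp` base pairs are then
#' merged transitively (a gap of exactly `merge_gap_bp` is not merged).
#'
#' @param hits data.frame from [clump()].
#' @param ref_genotypes Reference panel `genotype_matrix`.
#' @param r2_span LD threshold defining the span (default 0.1).
#' @param merge_gap_bp Merge gap in bp (default 250000).
#' @return data.frame of loci: chrom, start, end, n_hits, lead ids.
#' @export
build_loci <- function(hits, ref_genotypes, r2_span = 0.1,
                       merge_gap_bp = 250000) {
  if (!nrow(hits))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_hits = integer(),
                      hits = character(), stringsAsFactors = FALSE))
  v <- ref_genotypes$variants
  dos <- ref_genotypes$dosages
  spans <- lapply(seq_len(nrow(hits)), function(i) {
    hit <- hits[i, ]
    same <- which(v$chrom == hit$chrom)
    r2 <- panel_r2(dos, match(hit$id, colnames(dos)), same)
    inld <- same[r2 >= r2_span]
    pos <- c(v$pos[inld], hit$pos)
    data.frame(chrom = hit$chrom, start = min(pos), end = max(pos),
               hit = hit$id, stringsAsFactors = FALSE)
  })
  spans <- do.call(rbind, spans)
  spans <- spans[order(spans$chrom, spans$start, spans$end), , drop = FALSE]
  loci <- list()
  cur <- spans[1, ]
  cur_hits <- cur$hit
  for (i in seq_len(nrow(spans))[-1]) {
    s <- spans[i, ]
    if (s$chrom == cur$chrom && (s$start - cur$end) < merge_gap_bp) {
      cur$end <- max(cur$end, s$end)
      cur_hits <- c(cur_hits, s$hit)
    } else {
      loci[[length(loci) + 1L]] <- data.frame(
        chrom = cur$chrom, start = cur$start, end = cur$end,
        n_hits = length(cur_hits), hits = paste(cur_hits, collapse = ","),
        stringsAsFactors = FALSE)
      cur <- s; cur_hits <- s$hit
    }
  }
  loci[[length(loci) + 1L]] <- data.frame(
    chrom = cur$chrom, start = cur$start, end = cur$end,
    n_hits = length(cur_hits), hits = paste(cur_hits, collapse = ","),
    stringsAsFactors = FALSE)
  do.call(rbind, loci)
}

#' Expected chi-squared over known variants
#'
#' Mean and standard error (sd / sqrt(k)) of the combined chi-squared
#' statistic over the intersection of the supplied variants with a known
#' (previously reported) list — the power proxy used to compare models.
#'
#' @param combined A `combined_result` (typically restricted to hits).
#' @param known_ids Character vector of known variant ids.
#' @return List with `mean`, `se`, `k`.
#' @export
expected_chi2 <- function(combined, known_ids) {
  sel <- combined$id %in% known_ids
  if (!any(sel)) {
    warning("no overlap with the known variant list")
    return(list(mean = NA_real_, se = NA_real_, k = 0L))
  }
  x <- combined$sum_chi2[sel]
  list(mean = mean(x),
       se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
       k = length(x))
}

#' Flag loci overlapping known intervals
#'
#' A locus is known iff it overlaps any known interval by at least one
#' base pair (1-based inclusive coordinates on both sides).
#'
#' @param loci data.frame from [build_loci()].
#' @param known data.frame with chrom, start, end (1-based inclusive;
#'   use [read_bed()] for BED input).
#' @return The loci data.frame with a logical `known` column; attribute
#'   `counts` holds c(known, novel).
#' @export
overlap_known <- function(loci, known) {
  if (any(known$end < known$start))
    mr_stop(sprintf("malformed interval at line %d",
                    which(known$end < known$start)[1]))
  flag <- vapply(seq_len(nrow(loci)), function(i) {
    any(known$chrom == loci$chrom[i] &
          known$start <= loci$end[i] & known$end >= loci$start[i])
  }, logical(1))
  loci$known <- flag
  attr(loci, "counts") <- c(known = sum(flag), novel = sum(!flag))
  loci
}
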