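test_that("orthogonalization yields exactly uncorrelated coordinates", {
  set.seed(41)
  e <- matrix(rnorm(5000 * 12), 5000, 12) %*% matrix(rnorm(144), 12, 12)
  pc <- orthogonalize(embedding_matrix(e, sprintf("s%d", 1:5000)))
  cc <- cor(pc$values)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-10)
  expect_equal(pc$m, 12L)
  ## same subspace: projecting embeddings onto the rotation recovers them
  rec <- sweep(pc$values %*% t(pc$rotation), 2, -pc$center)
  expect_equal(rec, e, ignore_attr = TRUE, tolerance = 1e-8)
  ## a constant column drops one component and reduces df
  e2 <- cbind(e[, 1:5], 7)
  expect_warning(pc2 <- orthogonalize(embedding_matrix(e2)), "zero-variance")
  expect_equal(pc2$m, 5L)
  expect_error(orthogonalize(embedding_matrix(e[1:10, ])), "n > d")
})

test_that("variant QC applies the printed inequality directions", {
  clean <- data.frame(id = "ok", maf = 0.2, info = 0.99,
                      missing_frac = 0, hwe_p = 0.5)
  tab <- rbind(clean,
               data.frame(id = "maf_boundary", maf = 0.001, info = 0.99,
                          missing_frac = 0, hwe_p = 0.5),
               data.frame(id = "low_maf", maf = 0.0009, info = 0.99,
                          missing_frac = 0, hwe_p = 0.5),
               data.frame(id = "low_info", maf = 0.2, info = 0.79,
                          missing_frac = 0, hwe_p = 0.5),
               data.frame(id = "missing", maf = 0.2, info = 0.99,
                          missing_frac = 0.06, hwe_p = 0.5),
               data.frame(id = "hwe_boundary", maf = 0.2, info = 0.99,
                          missing_frac = 0, hwe_p = 1e-10))
  kept <- variant_qc(tab)
  expect_setequal(kept$id, c("ok", "maf_boundary"))
  ## boundary semantics: maf = 0.001 kept (inclusive), hwe_p = 1e-10
  ## removed (strict), info = 0.8 and missing = 0.05 kept
  tab2 <- data.frame(id = "edges", maf = 0.001, info = 0.8,
                     missing_frac = 0.05, hwe_p = 1.000001e-10)
  expect_equal(nrow(variant_qc(tab2)), 1L)
  w <- capture_warnings(variant_qc(tab[, c("id", "maf")]))
  expect_length(w, 3)  # info, missingness and HWE filters skipped
  expect_true(all(grepl("skipped", w)))
})

test_that("association scan is calibrated, exact under perfect signal, and guards inputs", {
  set.seed(42)
  n <- 1500
  g <- simulate_genotypes(n, 2000, maf = 0.25, seed = 43)
  covs <- simulate_covariates(n, rownames(g$dosages), seed = 44)
  y <- rnorm(n)  # independent of every variant
  scan <- assoc_scan(y, g, covs)
  typeI <- mean(scan$p < 0.05, na.rm = TRUE)
  ci <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(typeI - 0.05), ci)
  ## perfect association: huge chi2, underflow-guarded p
  x1 <- g$dosages[, 1]
  s1 <- assoc_scan(x1, g$dosages[, 1, drop = FALSE])
  expect_gt(s1$chi2, 1e10)
  expect_gte(s1$p, .Machine$double.xmin)
  ## monomorphic variant flagged NA
  gm <- cbind(g$dosages[, 1:2], mono = 1)
  sm <- assoc_scan(y, gm)
  expect_true(sm$monomorphic[3] && is.na(sm$chi2[3]))
  ## collinear covariates are refused by name
  covs_bad <- cbind(covs, dup_age = covs$age)
  expect_error(assoc_scan(y, g, covs_bad), class = "mregle_collinear")
})

test_that("combined statistic matches the chi-squared survival function", {
  ## m = 1 identity
  one <- combine_chi2(matrix(2.7, 1, 1), variants = "v")
  expect_equal(one$combined_p, pchisq(2.7, 1, lower.tail = FALSE))
  ## all-zero statistics give p = 1
  z <- combine_chi2(matrix(0, 3, 4))
  expect_true(all(z$combined_p == 1))
  ## df = 2 closed form exp(-x/2)
  two <- combine_chi2(matrix(c(3.84, 3.84), 1, 2))
  expect_equal(two$combined_p, exp(-7.68 / 2), tolerance = 1e-12)
  ## adding a zero-chi2 coordinate raises df and increases the p value
  base <- combine_chi2(matrix(c(5, 6), 1, 2))
  wide <- combine_chi2(matrix(c(5, 6, 0), 1, 3))
  expect_equal(wide$sum_chi2, base$sum_chi2)
  expect_gt(wide$combined_p, base$combined_p)
  ## warns when coordinates were not orthogonalized
  set.seed(45)
  raw <- assoc_scan_all(matrix(rnorm(200 * 2), 200, 2),
                        matrix(rbinom(200, 2, 0.3), 200, 1))
  expect_warning(combine_chi2(raw), "orthogonalized")
})

test_that("MANOVA oracle reduces to the univariate regression at m = 1", {
  set.seed(46)
  n <- 400
  g <- rbinom(n, 2, 0.3)
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y <- 0.15 * g + rnorm(n)
  mo <- manova_oracle(matrix(y), g, covs)
  fit <- summary(lm(y ~ g + age + sex, data = cbind(covs, y = y, g = g)))
  expect_equal(mo$p, fit$coefficients["g", 4], tolerance = 1e-10)
  expect_error(manova_oracle(matrix(y), rep(2, n)), "monomorphic")
})

test_that("combined statistic and MANOVA agree closely on null multivariate outcomes", {
  set.seed(47)
  n <- 2000; m <- 6
  reps <- 200
  diffs <- replicate(reps, {
    g <- rbinom(n, 2, 0.3)
    y <- matrix(rnorm(n * m), n, m)
    pc <- orthogonalize(embedding_matrix(y))
    chi <- sum(sum_chi2_cols_for_test(pc$values, g))
    p_sum <- pchisq(chi, m, lower.tail = FALSE)
    p_man <- manova_oracle(y, g)$p_chisq
    abs(p_sum - p_man)
  })
  expect_lt(median(diffs), 0.01)
})

test_that("genomic inflation of the combined p value is near 1 under the null", {
  set.seed(48)
  n <- 800; m <- 4
  g <- simulate_genotypes(n, 10000, maf = 0.3, seed = 49)
  emb <- matrix(rnorm(n * m), n, m) %*% matrix(rnorm(m * m), m, m)
  pc <- orthogonalize(embedding_matrix(emb, rownames(g$dosages)))
  at <- assoc_scan_all(pc, g)
  comb <- combine_chi2(at)
  lambda <- median(comb$sum_chi2) / qchisq(0.5, m)
  expect_gt(lambda, 0.95)
  expect_lt(lambda, 1.05)
})

test_that("summing chi-squared over raw correlated factors is anticonservative", {
  set.seed(50)
  n <- 2000; m <- 10; reps <- 400
  hits_naive <- hits_pca <- logical(reps)
  for (r in seq_len(reps)) {
    x <- rbinom(n, 2, 0.3)
    f <- simulate_correlated_factors(x, m = m, rho = 0.3, b1 = 0,
                                     seed = 5000 + r)
    chi_naive <- sum(sum_chi2_cols_for_test(f, x))
    pcs <- orthogonalize(embedding_matrix(f))$values
    chi_pca <- sum(sum_chi2_cols_for_test(pcs, x))
    hits_naive[r] <- pchisq(chi_naive, m, lower.tail = FALSE) < 0.05
    hits_pca[r] <- pchisq(chi_pca, m, lower.tail = FALSE) < 0.05
  }
  ## the naive sum over correlated coordinates exceeds the nominal level
  expect_gt(mean(hits_naive), 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
  ## decorrelation restores calibration
  expect_lt(abs(mean(hits_pca) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("clumping honours LD structure on constructed cases", {
  ## two significant variants in LD (r2 = 0.5 by construction): one hit
  set.seed(51)
  n <- 4000
  g1 <- rbinom(n, 2, 0.3)
  g2 <- ifelse(rbinom(n, 1, sqrt(0.5)) == 1, g1, rbinom(n, 2, 0.3))
  dos <- cbind(rs1 = g1, rs2 = as.numeric(g2))
  r2 <- cor(g1, g2)^2
  expect_gt(r2, 0.3)  # comfortably above the clump threshold
  geno <- structure(list(
    dosages = dos,
    variants = data.frame(id = c("rs1", "rs2"), chrom = "1",
                          pos = c(1e6, 1.05e6), ref = "A", alt = "G",
                          maf = 0.3, info = 1, missing_frac = 0, hwe_p = 1)),
    class = "genotype_matrix")
  comb <- data.frame(id = c("rs1", "rs2"), sum_chi2 = c(60, 50), df = 2,
                     combined_p = c(1e-13, 1e-11), log10_p = c(-13, -11))
  hits <- clump(comb, geno)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$id, "rs1")            # the smaller p leads
  expect_equal(hits$n_members, 2L)
  ## independent variants on different chromosomes: two hits
  geno$variants$chrom <- c("1", "2")
  set.seed(52)
  geno$dosages[, "rs2"] <- rbinom(n, 2, 0.3)
  hits2 <- clump(comb, geno)
  expect_equal(nrow(hits2), 2L)
  ## a single significant variant clumps alone
  comb3 <- comb; comb3$combined_p[2] <- 0.5
  expect_equal(clump(comb3, geno)$n_members, 1L)
  ## nothing significant: empty hits
  comb4 <- comb; comb4$combined_p <- c(1e-4, 1e-5)
  expect_equal(nrow(clump(comb4, geno)), 0L)
})

test_that("locus merging uses the strict 250 kb rule", {
  ## independent dosages so every span is just the hit itself
  set.seed(53)
  dos <- matrix(rbinom(4000 * 2, 2, 0.4), 4000, 2,
                dimnames = list(NULL, c("rsA", "rsB")))
  mk_geno <- function(posB) structure(list(
    dosages = dos,
    variants = data.frame(id = c("rsA", "rsB"), chrom = "1",
                          pos = c(1.2e6, posB), ref = "A", alt = "G",
                          maf = 0.4, info = 1, missing_frac = 0, hwe_p = 1)),
    class = "genotype_matrix")
  hits <- data.frame(id = c("rsA", "rsB"), chrom = "1", pos = c(1.2e6, NA),
                     sum_chi2 = c(60, 55), combined_p = c(1e-12, 1e-11),
                     n_members = 1L, members = c("rsA", "rsB"))
  ## gap 100 kb (1.3e6 vs end 1.2e6): merged into one locus
  hits$pos[2] <- 1.3e6
  loci <- build_loci(hits, mk_geno(1.3e6))
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start, 1.2e6)
  expect_equal(loci$end, 1.3e6)
  ## gap exactly 250 kb: not merged
  hits$pos[2] <- 1.45e6
  loci2 <- build_loci(hits, mk_geno(1.45e6))
  expect_equal(nrow(loci2), 2L)
  ## empty hits give empty loci
  expect_equal(nrow(build_loci(clump_empty_for_test(), mk_geno(1.3e6))), 0L)
})

test_that("greedy clumping and locus merging match brute-force enumeration", {
  for (rep in 1:25) {
    set.seed(600 + rep)
    p <- sample(10:50, 1)
    geno <- simulate_genotypes(400, p, maf = runif(1, 0.1, 0.5),
                               seed = 700 + rep, pos_step = 6e4,
                               ld_rho = runif(1, 0.3, 0.9))
    ## synthetic combined p values with a significant subset
    lp <- ifelse(runif(p) < 0.4, 10^(-runif(p, 8.1, 20)), 10^(-runif(p, 0, 6)))
    comb <- data.frame(id = geno$variants$id, sum_chi2 = qchisq(lp, 4,
                                                               lower.tail = FALSE),
                       df = 4, combined_p = lp, log10_p = log10(lp))
    hits <- clump(comb, geno)
    expect_identical(hits$id, brute_clump(comb, geno))
    if (nrow(hits)) {
      loci <- build_loci(hits, geno)
      oracle <- brute_loci(hits$id, geno)
      expect_equal(nrow(loci), nrow(oracle))
      expect_equal(loci$start, oracle$start)
      expect_equal(loci$end, oracle$end)
    }
  }
})

test_that("expected chi-squared summarizes rediscovered hits", {
  comb <- data.frame(id = c("a", "b", "c", "d"),
                     sum_chi2 = c(10, 20, 30, 999), df = 2,
                     combined_p = 1e-9, log10_p = -9)
  ec <- expected_chi2(comb, c("a", "b", "c"))
  expect_equal(ec$mean, 20)
  expect_equal(ec$se, sd(c(10, 20, 30)) / sqrt(3))
  single <- expected_chi2(comb, "a")
  expect_true(is.na(single$se))
  expect_warning(none <- expected_chi2(comb, "zzz"), "overlap")
  expect_true(is.na(none$mean))
})

test_that("known-locus overlap uses 1-based inclusive intervals", {
  loci <- data.frame(chrom = c("1", "1", "2"),
                     start = c(100, 300, 500), end = c(200, 400, 600),
                     n_hits = 1L, hits = "x")
  known <- data.frame(chrom = c("1", "2"), start = c(150, 601),
                      end = c(300, 700))
  out <- overlap_known(loci[1, ], known)
  expect_true(out$known)
  ## adjacency without overlap is not known
  out2 <- overlap_known(data.frame(chrom = "1", start = 100, end = 200,
                                   n_hits = 1L, hits = "x"),
                        data.frame(chrom = "1", start = 201, end = 300))
  expect_false(out2$known)
  ## counts over a small constructed set
  known3 <- data.frame(chrom = c("1", "2"), start = c(150, 550),
                       end = c(160, 560))
  out3 <- overlap_known(loci, known3)
  expect_equal(unname(attr(out3, "counts")), c(2, 1))
  expect_error(overlap_known(loci, data.frame(chrom = "1", start = 10,
                                              end = 5)), "malformed")
})
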