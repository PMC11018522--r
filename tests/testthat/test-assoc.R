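test_that("inverse normal transform hits the stated quantiles and is rank-invariant", {
  out <- inverse_normal_transform(c(10, 20, 30))
  expect_equal(out, qnorm(c(1, 3, 5) / 6), tolerance = 1e-12)
  expect_equal(out[2], 0)
  # monotone transform of the input gives the identical output
  expect_equal(inverse_normal_transform(exp(c(10, 20, 30) / 10)), out)
  # symmetric ranks sum to zero
  expect_equal(sum(inverse_normal_transform(c(5, 1, 9, 2, 7))), 0,
               tolerance = 1e-12)
  expect_error(inverse_normal_transform(rep(1, 5)), "constant")
  expect_error(inverse_normal_transform(c(1, 2)), "at least 3")
})

test_that("PC regression produces residuals orthogonal to the removed PCs", {
  set.seed(21)
  E <- matrix(rnorm(60 * 30), 60, 30)
  r <- regress_out_pcs(E, 10)
  pcs <- attr(r, "scores")
  expect_lt(max(abs(crossprod(r, pcs))), 1e-8)
  # n_pcs = 0 returns the centered matrix
  expect_equal(unname(regress_out_pcs(E, 0)),
               unname(scale(E, scale = FALSE)), ignore_attr = TRUE)
  # exact rank-10 matrix fully captured by 10 PCs
  low <- matrix(rnorm(60 * 10), 60, 10) %*% matrix(rnorm(10 * 30), 10, 30)
  expect_lt(max(abs(regress_out_pcs(low, 10))), 1e-8)
  expect_error(regress_out_pcs(E, 60), "n_pcs")
})

test_that("null LMM finds no genetic variance under an identity-covariance truth", {
  set.seed(22)
  n <- 120
  K <- diag(n); dimnames(K) <- list(paste0("d", 1:n), paste0("d", 1:n))
  y <- rnorm(n, sd = 2)
  f <- fit_null_lmm(y, K = K, w = rep(1, n))
  expect_lt(f$sigma2_g + f$sigma2_w, 0.15 * f$sigma2_e)
  expect_equal(f$sigma2_e * (1 + f$gamma_g + f$gamma_w), var(y),
               tolerance = 0.15)
})

test_that("variance components are recovered from data simulated under the model", {
  set.seed(23)
  n <- 400
  co <- simulate_cohort(sim_config(n_donors = n, n_genes = 30,
                                   snps_per_gene = 10, ld_block_r2 = 0,
                                   seed = 31L), make_cells = FALSE)
  K <- psd_clip(make_grm(co$genotypes), 1e-6)
  L <- chol(K)
  # cell-count-like weights: w = 1/nCells spans two orders of magnitude
  nc <- pmax(rnbinom(n, mu = 30, size = 2), 1)
  w <- 1 / nc
  s2 <- c(g = 1, w = 20, e = 0.5)
  est <- replicate(25, {
    y <- sqrt(s2["g"]) * drop(crossprod(L, rnorm(n))) +
      rnorm(n, sd = sqrt(s2["w"] * w)) + rnorm(n, sd = sqrt(s2["e"]))
    f <- fit_null_lmm(y, K = K, w = w)
    c(f$sigma2_g, f$sigma2_w, f$sigma2_e)
  })
  expect_lt(mean(abs(est - s2) / s2), 0.25)
  expect_lt(max(abs(rowMeans(est) - s2) / s2), 0.25)
})

test_that("the whitening transform decorrelates data drawn under the fitted model", {
  set.seed(24)
  n <- 150
  co <- simulate_cohort(sim_config(n_donors = n, n_genes = 20,
                                   relatedness_pairs = 20, seed = 32L),
                        make_cells = FALSE)
  K <- psd_clip(make_grm(co$genotypes), 1e-6)
  L <- chol(K)
  w <- rep(1, n)
  y <- drop(crossprod(L, rnorm(n))) + rnorm(n, sd = 0.5)
  f <- fit_null_lmm(y, K = K, w = w)
  V <- f$sigma2_g * K + f$sigma2_w * diag(w) + f$sigma2_e * diag(n)
  white <- f$T %*% V %*% t(f$T) / f$sigma2_e
  expect_lt(norm(white - diag(n), "F") / sqrt(n), 0.1)
})

test_that("with identity kinship and constant weights the LMM Wald test equals OLS", {
  set.seed(25)
  n <- 80
  y <- rnorm(n); g <- rbinom(n, 2, 0.3); C <- cbind(rnorm(n))
  K <- diag(n); dimnames(K) <- list(paste0("d", 1:n), paste0("d", 1:n))
  f <- fit_null_lmm(y, C, K = K, w = rep(2, n))
  t_lmm <- test_snp(y, g, C, f$T)
  fit <- summary(lm(y ~ C + g))$coefficients
  expect_equal(t_lmm$beta, fit["g", 1], tolerance = 1e-8)
  expect_equal(t_lmm$se, fit["g", 2], tolerance = 1e-8)
})

test_that("the Wald test is allele-flip equivariant, donor-order invariant, and skips constant dosages", {
  set.seed(26)
  n <- 60
  y <- rnorm(n); g <- rbinom(n, 2, 0.4)
  a <- test_snp(y, g)
  b <- test_snp(y, 2 - g)
  expect_equal(a$beta, -b$beta, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
  ord <- sample(n)
  c <- test_snp(y[ord], g[ord])
  expect_equal(a$beta, c$beta, tolerance = 1e-10)
  expect_null(test_snp(y, rep(1, n)))
})

test_that("null SNP tests are calibrated at nominal levels", {
  set.seed(27)
  n <- 100
  ps <- replicate(4000, {
    test_snp(rnorm(n), rbinom(n, 2, 0.3))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.012)
})

test_that("cis mapping recovers planted effects and drops genes without cis SNPs", {
  co <- small_cohort()
  cis <- cis_index(co$genes, co$genotypes$snp_meta)
  spec <- assoc_spec(n_expr_pcs = 5, min_donors = 10)
  a <- map_cis(co, co$genotypes, cis, spec)
  expect_true(all(a$se > 0))
  expect_true(all(a$p > 0 & a$p <= 1))
  expect_true(all(a$maf > 0 & a$maf <= 0.5))
  tr <- unique(co$truth[, c("gene", "snp", "cell_type", "true_beta")])
  m <- merge(a, tr)
  expect_gt(cor(m$beta, m$true_beta), 0.8)
  # a gene with no cis SNPs is absent
  cis2 <- cis
  cis2[[co$genes$gene[1]]] <- integer(0)
  a2 <- map_cis(co, co$genotypes, cis2, spec)
  expect_false(co$genes$gene[1] %in% a2$gene)
})

test_that("interaction mapping needs both disease groups and recovers planted interactions", {
  cfg <- sim_config(n_donors = 120, n_celltypes = 2, n_genes = 120,
                    snps_per_gene = 3, eqtl_fraction = 0.3,
                    interaction_fraction = 0.15, interaction_effect_sd = 1,
                    sharing_pattern_probs = c(global = 1, lineage = 0,
                                              unique = 0),
                    seed = 33L)
  co <- simulate_cohort(cfg, make_cells = FALSE)
  cis <- cis_index(co$genes, co$genotypes$snp_meta)
  # coverage is assessed without PC covariates: on a small synthetic panel
  # with no shared technical structure, PCs lock onto the largest planted
  # effects and attenuate exactly the estimates under test
  spec <- assoc_spec(n_expr_pcs = 0, quantile_normalize = FALSE,
                     min_donors = 10)
  int <- map_interaction(co, co$genotypes, cis, spec, co$donors)
  expect_true(all(c("beta_int", "se_int", "p_int") %in% names(int)))
  expect_true(all(int$maf_case > 0.05 & int$maf_control > 0.05))
  tr <- unique(co$truth[co$truth$is_interaction,
                        c("gene", "snp", "cell_type",
                          "true_beta_interaction")])
  m <- merge(int, tr)
  expect_gt(nrow(m), 5)
  covered <- abs(m$beta_int - m$true_beta_interaction) < 2 * m$se_int
  expect_gte(mean(covered), 0.9)

  # a cohort with 9 disease donors is excluded entirely
  co2 <- co
  co2$donors$disease_status <- c(rep("ILD", 9), rep("control", 111))
  expect_message(out <- map_interaction(co2, co2$genotypes, cis, spec,
                                        co2$donors),
                 "lacks 10 donors")
  expect_equal(nrow(out), 0L)
})

test_that("label permutation is seeded, invertible, and otherwise non-destructive", {
  co <- small_cohort()
  p1 <- permute_labels(co, "genotype", seed = 5L)
  p2 <- permute_labels(co, "genotype", seed = 5L)
  expect_identical(p1$genotypes$dosage, p2$genotypes$dosage)
  expect_identical(p1$pseudobulk, co$pseudobulk)
  perm <- with(list(), {set.seed(99); sample.int(nrow(co$donors))})
  fwd <- permute_labels(co, "disease", perm = perm)
  back <- permute_labels(fwd, "disease", perm = order(perm))
  expect_identical(back$donors$disease_status, co$donors$disease_status)
})
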