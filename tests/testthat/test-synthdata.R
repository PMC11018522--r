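test_that("configuration is validated", {
  expect_error(sim_config(n_donors = 1), "n_donors")
  expect_error(sim_config(frac_cases = 1.5), "fraction")
  expect_error(sim_config(sharing_pattern_probs = c(global = 0.5,
                                                    lineage = 0.4,
                                                    unique = 0.4)),
               "simplex")
  expect_error(sim_config(eqtl_fraction = 0.1, interaction_fraction = 0.2),
               "interaction_fraction")
})

test_that("simulation is fully determined by the seed", {
  a <- simulate_cohort(sim_config(n_donors = 20, n_genes = 6, seed = 9L))
  b <- simulate_cohort(sim_config(n_donors = 20, n_genes = 6, seed = 9L))
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$pseudobulk, b$pseudobulk)
  expect_identical(a$truth, b$truth)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  c <- simulate_cohort(sim_config(n_donors = 20, n_genes = 6, seed = 10L))
  expect_false(identical(a$genotypes$dosage, c$genotypes$dosage))
})

test_that("allele frequencies track the generator and relatedness shows in the GRM", {
  cfg <- sim_config(n_donors = 400, n_genes = 20, snps_per_gene = 5,
                    maf_range = c(0.5, 0.5), seed = 2L)
  g <- simulate_genotypes(cfg)$genotypes
  af <- colMeans(g$dosage) / 2
  binom_sd <- sqrt(0.5 * 0.5 / (2 * 400))
  expect_true(all(abs(af - 0.5) < 3.5 * binom_sd))

  cfg_rel <- sim_config(n_donors = 100, n_genes = 60, snps_per_gene = 5,
                        ld_block_r2 = 0, relatedness_pairs = 5, seed = 3L)
  K <- make_grm(simulate_genotypes(cfg_rel)$genotypes)
  rel <- sapply(1:5, function(k) K[2 * k - 1, 2 * k])
  expect_gt(mean(rel), 0.35)             # one shared haplotype ~ 0.5
  unrel <- K[20:60, 20:60]
  expect_lt(abs(mean(unrel[upper.tri(unrel)])), 0.03)
})

test_that("LD blocks reach the target adjacent-SNP correlation", {
  cfg <- sim_config(n_donors = 600, n_genes = 10, snps_per_gene = 8,
                    ld_block_r2 = 0.6, maf_range = c(0.3, 0.5), seed = 4L)
  g <- simulate_genotypes(cfg)$genotypes
  r2 <- sapply(seq(1, 79, by = 8), function(j)
    cor(g$dosage[, j], g$dosage[, j + 1])^2)
  expect_equal(mean(r2), 0.6, tolerance = 0.12)
})

test_that("null simulation has empty truth; noise-free pseudobulk equals the latent mean", {
  co0 <- simulate_cohort(sim_config(n_donors = 20, n_genes = 10,
                                    eqtl_fraction = 0, de_fraction = 0,
                                    seed = 6L), make_cells = FALSE)
  expect_equal(nrow(co0$truth), 0L)

  co_nf <- simulate_cohort(sim_config(n_donors = 20, n_genes = 10,
                                      noise_sd = 0, seed = 7L),
                           make_cells = FALSE)
  expect_equal(co_nf$pseudobulk, co_nf$latent)
})

test_that("planted effects are recovered without material bias by per-gene OLS", {
  cfg <- sim_config(n_donors = 200, n_celltypes = 1, n_genes = 220,
                    snps_per_gene = 4, eqtl_fraction = 1, effect_size_sd = 1,
                    noise_sd = 0.5, seed = 8L,
                    sharing_pattern_probs = c(global = 1, lineage = 0,
                                              unique = 0))
  co <- simulate_cohort(cfg, make_cells = FALSE)
  tr <- unique(co$truth[, c("gene", "snp", "true_beta")])
  est <- se <- numeric(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    y <- co$pseudobulk[[1]][, tr$gene[i]]
    x <- co$genotypes$dosage[, tr$snp[i]]
    f <- summary(lm(y ~ x))$coefficients
    est[i] <- f["x", 1]; se[i] <- f["x", 2]
  }
  # bias below 0.05 * effect_size_sd, Monte-Carlo over >= 200 genes
  expect_lt(abs(mean(est - tr$true_beta)), 0.05)
  # within 2 SEs for >= 95% of planted effects
  expect_gte(mean(abs(est - tr$true_beta) < 2 * se), 0.95)
})

test_that("mean-aggregated cell counts converge to the latent pseudobulk as nCells grows", {
  errs <- sapply(c(10, 40, 160), function(nc) {
    co <- simulate_cohort(sim_config(n_donors = 30, n_celltypes = 1,
                                     n_genes = 20, noise_sd = 0,
                                     cells_per_donor_dist = c(mean = nc,
                                                              dispersion = 1e6),
                                     seed = 11L))
    cells <- co$cells
    pbt <- normalize_aggregate(co$counts, cells, rownames(co$counts),
                               list(ct01 = unique(cells$donor_id)),
                               size_factors = "none")
    mean(abs(pbt$expr$ct01[rownames(co$latent[[1]]), ] - co$latent[[1]]))
  })
  expect_lt(errs[3], errs[1])
  # positive slope of |error| against 1/nCells
  expect_gt(coef(lm(errs ~ I(1 / c(10, 40, 160))))[2], 0)
})

test_that("fixtures round-trip through the package readers", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  export_fixture(co, dir)
  back <- read_fixture(dir)
  expect_identical(back$genotypes$dosage, co$genotypes$dosage)
  expect_identical(back$genotypes$snp_meta$pos, co$genotypes$snp_meta$pos)
  expect_equal(back$genes$start, co$genes$start)
  expect_identical(back$donors$disease_status, co$donors$disease_status)
  expect_equal(unname(back$ncells), unname(co$ncells))
  expect_equal(as.matrix(back$counts), as.matrix(co$counts))
  expect_equal(back$truth$true_beta, co$truth$true_beta)
})

test_that("an empty count matrix survives the MTX round trip", {
  dir <- withr::local_tempdir()
  m <- Matrix::Matrix(0, nrow = 0, ncol = 5, sparse = TRUE)
  colnames(m) <- paste0("c", 1:5)
  write_counts_mtx(m, file.path(dir, "m.mtx"), file.path(dir, "f.tsv"),
                   file.path(dir, "b.tsv"))
  back <- read_counts_mtx(file.path(dir, "m.mtx"), file.path(dir, "f.tsv"),
                          file.path(dir, "b.tsv"))
  expect_equal(dim(back), c(0L, 5L))
})
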