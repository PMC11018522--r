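test_that("EM mixture fitting: degenerate library, monotone likelihood, weight recovery", {
  set.seed(41)
  # single component: weight must be 1 regardless of data
  B <- matrix(rnorm(50), ncol = 1); S <- matrix(1, 50, 1)
  f1 <- fit_mixture(B, S, list(one = matrix(1, 1, 1)), omega_grid = 1)
  # components: null + one; both can carry weight, but they sum to 1
  expect_equal(sum(f1$pi), 1, tolerance = 1e-12)
  expect_true(all(f1$pi >= 0))
  # log-likelihood never decreases
  expect_true(all(diff(f1$loglik) >= -1e-8))

  # two-component truth: 0.7 null + 0.3 equal-effects with omega = 1
  R <- 5; n <- 6000
  is_sig <- runif(n) < 0.3
  b <- sapply(seq_len(n), function(i) {
    if (is_sig[i]) rep(rnorm(1), R) else rep(0, R)
  })
  Bhat <- t(b) + matrix(rnorm(n * R), n, R)
  Shat <- matrix(1, n, R)
  f2 <- fit_mixture(Bhat, Shat, list(equal = matrix(1, R, R)),
                    omega_grid = 1)
  expect_equal(unname(f2$pi["null"]), 0.7, tolerance = 0.05)
  expect_equal(sum(f2$pi[-1]), 0.3, tolerance = 0.05)
})

test_that("posterior matches the closed-form single-component shrinkage and its LFSR", {
  # one condition, prior N(0, omega), known error sd: conjugate closed form
  omega <- 2; s <- 0.5
  bhat <- c(-1.2, 0, 0.4, 3)
  B <- matrix(bhat, ncol = 1); S <- matrix(s, length(bhat), 1)
  fit <- fit_mixture(B, S, list(one = matrix(1, 1, 1)), omega_grid = omega,
                     max_iter = 1)
  fit$pi <- c(null = 0, 1)              # force the normal component
  post <- mash_posterior(B, S, fit)
  shrink <- omega / (omega + s^2)
  expect_equal(post$post_mean[, 1], bhat * shrink, tolerance = 1e-8)
  expect_equal(post$post_sd[, 1], rep(sqrt(omega * s^2 / (omega + s^2)),
                                      4), tolerance = 1e-8)
  psd <- sqrt(omega * s^2 / (omega + s^2))
  expect_equal(post$lfsr[, 1],
               pmin(pnorm(0, bhat * shrink, psd),
                    1 - pnorm(0, bhat * shrink, psd)), tolerance = 1e-8)
  # b = 0: sign maximally uncertain
  expect_equal(post$lfsr[2, 1], 0.5, tolerance = 1e-8)
  # shrinkage property: posterior magnitude never exceeds the estimate
  expect_true(all(abs(post$post_mean[, 1]) <= abs(bhat) + 1e-12))
})

test_that("forcing the null weight to one zeroes the posterior and floors the LFSR", {
  set.seed(42)
  B <- matrix(rnorm(30), 10, 3); S <- matrix(1, 10, 3)
  fit <- fit_mixture(B, S, list(identity = diag(3)), omega_grid = c(1, 2),
                     max_iter = 1)
  fit$pi <- c(1, rep(0, length(fit$pi) - 1))
  post <- mash_posterior(B, S, fit)
  expect_true(all(post$post_mean == 0))
  expect_true(all(post$lfsr >= 0.5))
})

test_that("the LFSR from the fitted mixture matches a quadrature oracle", {
  set.seed(43)
  n <- 50
  bhat <- c(rnorm(25, 0, 0.3), rnorm(25, 0, 3))
  s <- runif(n, 0.5, 1.5)
  B <- matrix(bhat, ncol = 1); S <- matrix(s, ncol = 1)
  grid <- c(0.25, 1, 4)
  fit <- fit_mixture(B, S, list(one = matrix(1, 1, 1)), omega_grid = grid)
  post <- mash_posterior(B, S, fit)
  # oracle: numerical integration of the posterior sign mass under the same
  # fitted prior (point mass + normal mixture), independent of the
  # posterior code path
  pi <- fit$pi
  for (i in seq_len(n)) {
    lik0 <- dnorm(bhat[i], 0, s[i])
    likk <- dnorm(bhat[i], 0, sqrt(grid + s[i]^2))
    w <- c(pi[1] * lik0, pi[-1] * likk)
    w <- w / sum(w)
    p_neg <- sum(w[-1] * sapply(grid, function(om) {
      f <- function(b) dnorm(b, 0, sqrt(om)) * dnorm(bhat[i], b, s[i])
      stats::integrate(f, -Inf, 0)$value /
        stats::integrate(f, -Inf, Inf)$value
    }))
    lfsr_oracle <- min(p_neg + w[1], 1 - p_neg)
    expect_equal(post$lfsr[i, 1], lfsr_oracle, tolerance = 1e-4)
  }
})

test_that("strong-test selection keeps overwhelming signals and drops null columns", {
  set.seed(44)
  n <- 300; R <- 3
  B <- matrix(rnorm(n * R, 0, 0.2), n, R)
  S <- matrix(0.5, n, R)
  strong_rows <- 1:12
  B[strong_rows, 1] <- 8                # |z| = 16
  panel <- list(Bhat = B, Shat = S,
                tests = data.frame(gene = paste0("g", 1:n), snp = "s"),
                celltypes = paste0("ct", 1:R))
  class(panel) <- "EffectPanel"
  idx <- select_strong(panel, 0.1)
  expect_true(all(strong_rows %in% idx))
  lf <- attr(idx, "lfsr")
  # a column of near-zero z-scores contributes no strong calls of its own
  expect_true(all(lf[setdiff(seq_len(n), strong_rows), 1] > 0.1 |
                    apply(B[setdiff(seq_len(n), strong_rows), , drop = FALSE],
                          1, function(x) max(abs(x))) > 2))
})

test_that("covariance library: canonical forms, PSD, and recovery of a shared covariance", {
  set.seed(45)
  # R = 1 collapses to the scalar 1
  U1 <- build_covariances(matrix(rnorm(20), ncol = 1))
  expect_true(all(vapply(U1, function(m) abs(m[1, 1] - 1) < 1e-6, TRUE)))

  R <- 4
  v <- c(1, 1, 0, 0) / sqrt(2)
  Ustar <- tcrossprod(v)
  Z <- MASS::mvrnorm(400, rep(0, R), 6 * Ustar + diag(R))
  U <- build_covariances(Z, n_pcs = 3)
  expect_true(all(c("identity", "equal", "tpca", "ed") %in% names(U)))
  for (m in U) {
    expect_equal(m, t(m), tolerance = 1e-10)
    expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
  cosfro <- function(A, B) sum(A * B) / sqrt(sum(A^2) * sum(B^2))
  expect_gt(max(cosfro(U$ed, Ustar), cosfro(U$pca_1, Ustar)), 0.9)
})

test_that("null correlation estimation: independence, duplication, PSD", {
  set.seed(46)
  n <- 500; R <- 4
  panel_of <- function(B) {
    p <- list(Bhat = B, Shat = matrix(1, nrow(B), ncol(B)))
    class(p) <- "EffectPanel"; p
  }
  V <- estimate_null_correlation(panel_of(matrix(rnorm(n * R), n, R)))
  expect_lt(max(abs(V[upper.tri(V)])), 0.15)
  z <- rnorm(n)
  Vdup <- estimate_null_correlation(panel_of(cbind(z, z + rnorm(n, 0, 0.01))))
  expect_gt(Vdup[1, 2], 0.95)
  expect_gte(min(eigen(Vdup, only.values = TRUE)$values), -1e-10)
  # too few null-like tests falls back to identity
  expect_message(
    Vid <- estimate_null_correlation(panel_of(matrix(10, 3, 4))),
    "identity")
  expect_equal(Vid, diag(4))
})

test_that("mixture weights stay on the simplex and LFSR stays in [0,1] on a full fit", {
  co <- small_cohort()
  cis <- cis_index(co$genes, co$genotypes$snp_meta)
  a <- map_cis(co, co$genotypes, cis, assoc_spec(n_expr_pcs = 5,
                                                 min_donors = 10))
  panel <- effect_panel(a)
  fit <- mash_fit(panel, seed = 1)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-9)
  expect_true(all(fit$pi >= 0))
  expect_true(all(fit$lfsr >= 0 & fit$lfsr <= 1))
  expect_true(all(is.finite(fit$post_mean)))
  expect_true(all(diff(fit$loglik) >= -1e-6))
})
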