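options(pbeqtl.quiet = TRUE)

# memoized small cohorts shared across test files
.fixtures <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- simulate_cohort(
      sim_config(n_donors = 50, n_celltypes = 3, n_genes = 12,
                 snps_per_gene = 6, eqtl_fraction = 0.5, seed = 42L),
      make_cells = TRUE)
  .fixtures$small
}

# independent enumeration oracle for the exact HWE test (direct factorials)
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (min(nA, na) == 0) return(1)
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  prob <- sapply(hets, function(h) {
    factorial(n) / (factorial((nA - h) / 2) * factorial(h) *
                      factorial((na - h) / 2)) * 2^h *
      factorial(nA) * factorial(na) / factorial(2 * n)
  })
  prob <- prob / sum(prob)
  obs <- prob[match(nAa, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

# independent enumeration oracle for Fisher's exact test
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  support <- max(0, k - n_):min(k, m)
  prob <- sapply(support, function(x)
    choose(m, x) * choose(n_, k - x) / choose(m + n_, k))
  min(1, sum(prob[prob <= prob[match(a, support)] * (1 + 1e-7)]))
}

# brute-force coloc oracle: enumerate single-causal-variant configurations
coloc_oracle <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  abf1 <- exp(labf1); abf2 <- exp(labf2)
  n <- length(abf1)
  h0 <- 1
  h1 <- p1 * sum(abf1)
  h2 <- p2 * sum(abf2)
  h3 <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) h3 <- h3 + p1 * p2 * abf1[i] * abf2[j]
  h4 <- p12 * sum(abf1 * abf2)
  pp <- c(h0, h1, h2, h3, h4)
  stats::setNames(pp / sum(pp), paste0("PP", 0:4))
}
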