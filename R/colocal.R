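#' Harmonize eQTL and GWAS summary statistics
#'
#' Intersects two summary-statistic tables on `chrom:pos`, aligning effect
#' alleles: when the effect/other alleles are swapped between the tables
#' the GWAS beta sign is flipped; mismatched allele pairs are dropped.
#' Only variable SNPs (MAF strictly inside (0, 1)) are kept. Genes sharing
#' fewer than `min_shared` SNPs are skipped.
#'
#' @param eqtl data.frame: `snp`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, optionally `maf`.
#' @param gwas data.frame with the same columns.
#' @param min_shared minimum shared SNPs; default 100.
#' @return data.frame with aligned `beta1`, `se1`, `beta2`, `se2` (and the
#'   SNP keys), or `NULL` with a message when the overlap is too small.
#' @export
harmonize <- function(eqtl, gwas, min_shared = 100) {
  key <- function(d) paste(d$chrom, d$pos, sep = ":")
  e_ok <- if ("maf" %in% names(eqtl)) eqtl$maf > 0 & eqtl$maf < 1 else TRUE
  g_ok <- if ("maf" %in% names(gwas)) gwas$maf > 0 & gwas$maf < 1 else TRUE
  eqtl <- eqtl[e_ok, , drop = FALSE]; gwas <- gwas[g_ok, , drop = FALSE]
  m <- match(key(eqtl), key(gwas))
  hit <- !is.na(m)
  e <- eqtl[hit, , drop = FALSE]; g <- gwas[m[hit], , drop = FALSE]
  same <- e$effect_allele == g$effect_allele & e$other_allele == g$other_allele
  swap <- e$effect_allele == g$other_allele & e$other_allele == g$effect_allele
  keep <- same | swap
  e <- e[keep, , drop = FALSE]; g <- g[keep, , drop = FALSE]
  flip <- swap[keep]
  out <- data.frame(snp = e$snp, chrom = e$chrom, pos = e$pos,
                    beta1 = e$beta, se1 = e$se,
                    beta2 = ifelse(flip, -g$beta, g$beta), se2 = g$se,
                    stringsAsFactors = FALSE)
  if (nrow(out) < min_shared) {
    message("only ", nrow(out), " shared variable SNPs (< ", min_shared,
            "); gene skipped")
    return(NULL)
  }
  out
}

#' Wakefield approximate Bayes factor
#'
#' `log ABF = 0.5 log(1 - r) + z^2 r / 2` with `z = beta/se` and
#' `r = W^2 / (W^2 + se^2)`; `W` is the prior SD of the effect.
#'
#' @param beta,se effect estimates and standard errors (vectorized).
#' @param W prior effect SD; default 0.15 (quantitative-trait scale; use
#'   ~0.2 on the log-odds scale for case-control traits).
#' @return log ABF vector.
#' @export
wakefield_abf <- function(beta, se, W = 0.15) {
  stopifnot(all(se > 0), W > 0)
  r <- W^2 / (W^2 + se^2)
  z <- beta / se
  0.5 * log1p(-r) + z^2 * r / 2
}

#' Five-hypothesis colocalization from log ABFs
#'
#' Enumerates the single-causal-variant hypotheses: H0 no association, H1
#' trait-1 only, H2 trait-2 only, H3 two distinct causal variants, H4 one
#' shared causal variant. Posterior probabilities are proportional to
#' `{1, p1 S1, p2 S2, p1 p2 (S1 S2 - S12), p12 S12}` with `S1 = sum
#' exp(lABF1)` etc., evaluated in log space.
#'
#' @param labf1,labf2 aligned per-SNP log ABF vectors.
#' @param p1,p2,p12 prior probabilities that a SNP is causal for trait 1,
#'   trait 2, or both; defaults 1e-4, 1e-4, 1e-5.
#' @return list of class `ColocResult`: `pp` (named PP0..PP4, sums to 1),
#'   `n_snps`, `priors`.
#' @export
coloc_abf <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  if (!length(labf1) || length(labf1) != length(labf2))
    stop("need equal-length nonempty log ABF vectors")
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  lS1 <- lse(labf1); lS2 <- lse(labf2); lS12 <- lse(labf1 + labf2)
  lH0 <- 0
  lH1 <- log(p1) + lS1
  lH2 <- log(p2) + lS2
  # S1*S2 - S12 in log space (guard tiny negatives from cancellation)
  d <- lS12 - (lS1 + lS2)
  lH3 <- log(p1) + log(p2) + lS1 + lS2 +
    if (d < 0) log1p(-exp(d)) else -Inf
  lH4 <- log(p12) + lS12
  lh <- c(lH0, lH1, lH2, lH3, lH4)
  pp <- exp(lh - lse(lh))
  names(pp) <- paste0("PP", 0:4)
  out <- list(pp = pp / sum(pp), n_snps = length(labf1),
              priors = c(p1 = p1, p2 = p2, p12 = p12))
  class(out) <- "ColocResult"
  out
}

#' @export
print.ColocResult <- function(x, ...) {
  cat("ColocResult over", x$n_snps, "SNPs:\n")
  print(round(x$pp, 4))
  invisible(x)
}

#' eQTL-side (beta, se) input for colocalization from shrinkage output
#'
#' Two modes. `"posterior"`: the eQTL side of the ABF uses the posterior
#' mean and posterior SD from the multivariate shrinkage fit. `"lfsr"`:
#' the LFSR is converted to an equivalent `|z| = qnorm(1 - lfsr)` carrying
#' the posterior-mean sign (the LFSR-in-place-of-p reading), with `se`
#' fixed at 1 so that `beta = z`.
#'
#' @param post_mean,post_sd,lfsr per-SNP posterior summaries for one gene
#'   and cell type.
#' @param mode `"posterior"` (default) or `"lfsr"`.
#' @return data.frame `beta`, `se` aligned to the input.
#' @export
lfsr_significance_input <- function(post_mean, post_sd, lfsr,
                                    mode = c("posterior", "lfsr")) {
  mode <- match.arg(mode)
  if (mode == "posterior")
    return(data.frame(beta = post_mean, se = pmax(post_sd, 1e-12)))
  lf <- pmax(pmin(lfsr, 1), 1e-300)   # lfsr = 0 capped to keep |z| finite
  z <- stats::qnorm(lf, lower.tail = FALSE)
  z <- pmax(z, 0)                     # lfsr >= 0.5 carries no sign signal
  data.frame(beta = sign(post_mean) * z, se = 1)
}

#' Colocalize one gene's eQTL signal with one GWAS
#'
#' Harmonizes the two panels, computes Wakefield log ABFs on both sides and
#' enumerates the five hypotheses. A shared-causal-variant call is
#' `PP4 >= call_threshold`.
#'
#' @param eqtl,gwas summary-statistic tables (see [harmonize()]).
#' @param W1,W2 prior effect SDs for the eQTL and GWAS sides (0.15
#'   quantitative, 0.2 case-control log-odds).
#' @param min_shared,p1,p2,p12 forwarded thresholds and priors.
#' @param call_threshold PP4 at or above which the locus is called
#'   colocalized; default 0.6.
#' @return `ColocResult` with an added `colocalized` flag, or `NULL` when
#'   the shared panel is too small.
#' @export
colocalize_gene <- function(eqtl, gwas, W1 = 0.15, W2 = 0.2,
                            min_shared = 100, p1 = 1e-4, p2 = 1e-4,
                            p12 = 1e-5, call_threshold = 0.6) {
  h <- harmonize(eqtl, gwas, min_shared)
  if (is.null(h)) return(NULL)
  res <- coloc_abf(wakefield_abf(h$beta1, h$se1, W1),
                   wakefield_abf(h$beta2, h$se2, W2), p1, p2, p12)
  res$colocalized <- unname(res$pp["PP4"] >= call_threshold)
  res
}
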