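#' Genotype containers and variant-level QC
#'
#' A `GenotypeMatrix` is a plain list with class `"GenotypeMatrix"`:
#' `dosage` (donor x SNP integer matrix in {0,1,2}, NA allowed),
#' `snp_meta` (data.frame with `id`, `chrom`, `pos` (1-based), `ref`, `alt`)
#' and the derived per-SNP minor allele frequency `maf`.
#'
#' @param dosage donor x SNP matrix of alternate-allele dosages in {0,1,2};
#'   missing genotypes as `NA`. Rownames are donor ids, colnames SNP ids.
#' @param snp_meta data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#'   one row per column of `dosage`.
#' @return An object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(dosage, snp_meta) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(snp_meta),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(snp_meta)),
            nrow(snp_meta) == ncol(dosage))
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA")
  colnames(dosage) <- snp_meta$id
  g <- list(dosage = dosage, snp_meta = as.data.frame(snp_meta),
            maf = snp_maf(dosage))
  class(g) <- "GenotypeMatrix"
  g
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d donors x %d SNPs (%d chromosome%s)\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$snp_meta$chrom)),
              if (length(unique(x$snp_meta$chrom)) == 1L) "" else "s"))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$dosage)

#' Subset a GenotypeMatrix by SNP
#'
#' @param g a [genotype_matrix()].
#' @param keep logical or integer index over SNPs, or character SNP ids.
#' @return A `GenotypeMatrix` restricted to the selected SNPs.
#' @export
subset_snps <- function(g, keep) {
  if (is.character(keep)) keep <- match(keep, g$snp_meta$id)
  genotype_matrix(g$dosage[, keep, drop = FALSE],
                  g$snp_meta[keep, , drop = FALSE])
}

#' Per-SNP minor allele frequency
#'
#' @param dosage donor x SNP dosage matrix (NA allowed).
#' @return numeric vector of MAFs in \[0, 0.5\].
#' @export
snp_maf <- function(dosage) {
  af <- colMeans(dosage, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of Hardy-Weinberg genotype proportions: given the
#' observed allele counts, the distribution of the heterozygote count under
#' HWE is enumerated and the two-sided p-value is the sum of the
#' probabilities of all configurations at most as probable as the observed
#' one. Monomorphic sites return p = 1.
#'
#' @param nAA,nAa,naa genotype counts (hom ref, het, hom alt).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(nAA, nAa, naa) {
  stopifnot(length(nAA) == 1L, length(nAa) == 1L, length(naa) == 1L)
  if (any(c(nAA, nAa, naa) < 0) || any(c(nAA, nAa, naa) != round(c(nAA, nAa, naa))))
    stop("genotype counts must be nonnegative integers")
  n <- nAA + nAa + naa
  if (n == 0) stop("no observations: all genotype counts are zero")
  nA <- 2L * nAA + nAa            # rarer-allele bookkeeping below
  na <- 2L * naa + nAa
  nMinor <- min(nA, na)
  if (nMinor == 0L) return(1)     # monomorphic
  # possible heterozygote counts share the parity of the minor allele count
  hets <- seq.int(nMinor %% 2L, nMinor, by = 2L)
  # P(nAa = h | n, nA) via log factorials
  lp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2) + hets * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- p[match(nAa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Variant-level QC mask
#'
#' Keeps biallelic autosomal SNPs with minor allele frequency strictly above
#' `maf_min` and an exact HWE p-value strictly above `hwe_alpha`.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min MAF threshold (strict `>`); default 0.05.
#' @param hwe_alpha HWE p-value threshold (strict `>`); default 1e-6.
#' @param autosomes chromosome labels treated as autosomal; anything whose
#'   label (with an optional `"chr"` prefix stripped) is not `1..22` is
#'   dropped.
#' @return logical vector over SNPs (`TRUE` = keep).
#' @export
filter_variants <- function(g, maf_min = 0.05, hwe_alpha = 1e-6,
                            autosomes = as.character(1:22)) {
  chrom <- sub("^chr", "", as.character(g$snp_meta$chrom))
  auto <- chrom %in% autosomes
  biallelic <- nchar(g$snp_meta$ref) == 1L & nchar(g$snp_meta$alt) == 1L &
    g$snp_meta$ref != g$snp_meta$alt
  hwe_p <- vapply(seq_len(ncol(g$dosage)), function(j) {
    d <- g$dosage[, j]; d <- d[!is.na(d)]
    if (!length(d)) return(1)
    hwe_exact_test(sum(d == 0), sum(d == 1), sum(d == 2))
  }, numeric(1))
  auto & biallelic & g$maf > maf_min & hwe_p > hwe_alpha
}

#' Windowed greedy LD pruning
#'
#' Mirrors the plink `--indep-pairwise` scheme: within each window of
#' `window_snps` position-sorted SNPs, while any surviving pair has squared
#' dosage correlation above `r2_max`, one member of the worst pair is
#' removed (the lower-MAF SNP; ties broken by the later position). The
#' window then slides by `step_snps`.
#'
#' @param g a [genotype_matrix()], SNPs position-sorted within chromosome.
#' @param window_snps,step_snps window size and slide, in SNPs.
#' @param r2_max maximum tolerated pairwise r-squared.
#' @return character vector of kept SNP ids.
#' @export
ld_prune <- function(g, window_snps = 250, step_snps = 50, r2_max = 0.9) {
  if (window_snps < step_snps) stop("window_snps must be >= step_snps")
  meta <- g$snp_meta
  keep <- rep(TRUE, ncol(g$dosage))
  maf <- g$maf
  for (chr in unique(meta$chrom)) {
    idx <- which(meta$chrom == chr)
    idx <- idx[order(meta$pos[idx])]
    start <- 1L
    repeat {
      win <- idx[seq.int(start, min(start + window_snps - 1L, length(idx)))]
      repeat {
        alive <- win[keep[win]]
        if (length(alive) < 2L) break
        r2 <- suppressWarnings(stats::cor(g$dosage[, alive, drop = FALSE],
                                          use = "pairwise.complete.obs"))^2
        diag(r2) <- 0; r2[is.na(r2)] <- 0
        if (max(r2) <= r2_max) break
        worst <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
        pair <- alive[worst]
        drop <- if (maf[pair[1L]] < maf[pair[2L]]) pair[1L]
          else if (maf[pair[1L]] > maf[pair[2L]]) pair[2L]
          else pair[which.max(meta$pos[pair])]
        keep[drop] <- FALSE
      }
      if (start + window_snps - 1L >= length(idx)) break
      start <- start + step_snps
    }
  }
  meta$id[keep]
}

#' Genomic relationship matrix
#'
#' Variance-standardized relationship: missing dosages are mean-imputed per
#' SNP, each SNP column is centered and scaled to unit variance, and
#' K = Z Z' / m over the m SNPs with nonzero variance (zero-variance SNPs
#' are excluded with a message).
#'
#' @param g a [genotype_matrix()].
#' @return symmetric donor x donor matrix of class `KinshipMatrix`.
#' @export
make_grm <- function(g) {
  X <- g$dosage
  if (ncol(X) < 2L) stop("need at least 2 SNPs to build a relationship matrix")
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
  }
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    message(sum(v == 0), " zero-variance SNP(s) excluded from the GRM")
    X <- X[, v > 0, drop = FALSE]
    v <- v[v > 0]
  }
  Z <- scale(X, center = TRUE, scale = sqrt(v))
  K <- tcrossprod(Z) / ncol(Z)
  K <- (K + t(K)) / 2
  rownames(K) <- colnames(K) <- rownames(g$dosage)
  class(K) <- c("KinshipMatrix", class(K))
  K
}

#' Clip a kinship matrix to positive semi-definite
#'
#' Eigenvalues below `floor` are raised to `floor`.
#'
#' @param K symmetric matrix.
#' @param floor smallest admissible eigenvalue.
#' @return PSD matrix with the same dimnames.
#' @export
psd_clip <- function(K, floor = 0) {
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) >= floor) return(K)
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  dimnames(out) <- dimnames(K)
  out
}

#' Cis-window SNP index
#'
#' Maps every gene to the SNPs on its chromosome whose 1-based position lies
#' in the closed interval `[gene_start - window, gene_end + window]`, with
#' `gene_start`/`gene_end` 1-based inclusive gene-body coordinates.
#'
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive; use [read_bed_genes()] to convert from BED).
#' @param snp_meta data.frame with `id`, `chrom`, `pos` (1-based).
#' @param window cis window in bp on each side of the gene body; default 1e6.
#' @return named list: gene -> integer vector of SNP indices into `snp_meta`.
#' @export
cis_index <- function(genes, snp_meta, window = 1e6) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(genes)))
  bychrom <- split(seq_len(nrow(snp_meta)), snp_meta$chrom)
  unknown <- setdiff(names(bychrom), unique(as.character(genes$chrom)))
  if (length(unknown))
    message("SNPs on chromosome(s) ", paste(unknown, collapse = ", "),
            " match no gene and are never tested")
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene
  for (i in seq_len(nrow(genes))) {
    idx <- bychrom[[as.character(genes$chrom[i])]]
    if (is.null(idx)) { out[[i]] <- integer(0); next }
    pos <- snp_meta$pos[idx]
    out[[i]] <- idx[pos >= genes$start[i] - window & pos <= genes$end[i] + window]
  }
  out
}
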