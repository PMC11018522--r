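#' Association model specification
#'
#' @param n_expr_pcs number of cell-type expression principal components to
#'   regress out (cis mapping) or include as fixed effects (interaction
#'   mapping); default 20.
#' @param quantile_normalize inverse-normal-transform each gene before
#'   modeling; default `TRUE`.
#' @param min_donors minimum donors for a gene/cell type to be mapped;
#'   default 40.
#' @return list of class `AssocModelSpec`.
#' @export
assoc_spec <- function(n_expr_pcs = 20, quantile_normalize = TRUE,
                       min_donors = 40) {
  out <- list(n_expr_pcs = n_expr_pcs,
              quantile_normalize = quantile_normalize,
              min_donors = min_donors)
  class(out) <- "AssocModelSpec"
  out
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles `qnorm((rank - 0.5)/n)`; ties receive
#' the average rank. Rank-invariant: any monotone transform of the input
#' yields the same output.
#'
#' @param y numeric vector, length >= 3, not constant.
#' @return transformed vector.
#' @export
inverse_normal_transform <- function(y) {
  if (length(y) < 3) stop("need at least 3 observations")
  if (length(unique(y[!is.na(y)])) < 2) stop("constant vector cannot be ranked")
  stats::qnorm((rank(y, ties.method = "average") - 0.5) / length(y))
}

#' Regress out leading expression principal components
#'
#' PCs are computed on the column-centered donor x gene matrix; every
#' gene's values are replaced by the residuals of a regression on PCs
#' 1..`n_pcs` plus intercept, so the result is orthogonal to those PCs.
#'
#' @param E donor x gene matrix.
#' @param n_pcs number of PCs; 0 returns the centered matrix.
#' @return residual matrix, same dimnames; PC scores in attribute
#'   `"scores"`.
#' @export
regress_out_pcs <- function(E, n_pcs = 20) {
  if (n_pcs >= nrow(E)) stop("n_pcs must be smaller than the donor count")
  Ec <- scale(E, center = TRUE, scale = FALSE)
  if (n_pcs == 0) return(Ec)
  pcs <- stats::prcomp(Ec, center = FALSE)$x
  pcs <- pcs[, seq_len(min(n_pcs, ncol(pcs))), drop = FALSE]
  resid <- stats::lm.fit(cbind(1, pcs), Ec)$residuals
  dimnames(resid) <- dimnames(E)
  attr(resid, "scores") <- pcs
  resid
}

#' Expression principal component scores
#'
#' @param E donor x gene matrix.
#' @param n_pcs number of components.
#' @return donor x `n_pcs` score matrix.
#' @export
expression_pcs <- function(E, n_pcs = 20) {
  if (n_pcs >= nrow(E)) stop("n_pcs must be smaller than the donor count")
  pcs <- stats::prcomp(scale(E, center = TRUE, scale = FALSE),
                       center = FALSE)$x
  pcs[, seq_len(min(n_pcs, ncol(pcs))), drop = FALSE]
}

# REML criterion for V = I + gamma_g K + gamma_w diag(w); R-side version
# used once at the optimum (it also returns the Cholesky factor and the
# profiled residual variance); the search itself calls the compiled kernel
reml_eval <- function(gg, gw, y, X, K, w) {
  n <- length(y)
  V <- gg * K
  diag(V) <- diag(V) + 1 + gw * w
  U <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(U)) return(list(ll = -Inf))
  ty <- backsolve(U, y, transpose = TRUE)
  tX <- backsolve(U, X, transpose = TRUE)
  fit <- stats::lm.fit(tX, ty)
  p <- fit$rank
  rss <- sum(fit$residuals^2)
  s2 <- rss / (n - p)
  ldV <- 2 * sum(log(diag(U)))
  XtX <- crossprod(tX[, seq_len(p), drop = FALSE])
  ll <- -0.5 * ((n - p) * log(s2) + ldV + determinant(XtX)$modulus[1])
  list(ll = ll, U = U, s2 = s2)
}

#' Fit the null linear mixed model for one gene
#'
#' Fits `y = C alpha + u_g + u_w + e` with
#' `Cov(y) = sigma2_g K + sigma2_w diag(w) + sigma2_e I` by restricted
#' maximum likelihood: the two variance ratios
#' `(gamma_g, gamma_w) = (sigma2_g, sigma2_w)/sigma2_e` are profiled over a
#' coarse log grid and refined by a Nelder-Mead simplex on the log-ratio
#' scale; when the criterion is flat (e.g. `K = I` leaves the component
#' split unidentified) the simplest model within tolerance wins.
#' Returns the fitted components together with a whitening transform `T`
#' such that `Cov(T y) = sigma2_e I` under the fitted model.
#'
#' @param y response vector (one gene's transformed expression).
#' @param C fixed-effect design matrix (an intercept is appended if no
#'   constant column is present).
#' @param K donor x donor kinship matrix aligned to `y` (clipped to PSD if
#'   needed).
#' @param w positive per-donor weights for the second random effect
#'   (typically `1/nCells`).
#' @return list with `sigma2_g`, `sigma2_w`, `sigma2_e`, `gamma_g`,
#'   `gamma_w`, `T` (whitening matrix), `reml` (criterion at optimum).
#' @export
fit_null_lmm <- function(y, C = NULL, K = NULL, w = NULL) {
  n <- length(y)
  if (is.null(C)) C <- matrix(1, n, 1)
  C <- as.matrix(C)
  if (!any(apply(C, 2, function(col) stats::sd(col) == 0))) C <- cbind(1, C)
  if (is.null(K)) K <- diag(n)
  if (is.null(w)) w <- rep(1, n)
  if (any(w <= 0)) stop("weights must be positive")
  K <- as.matrix(K)
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    message("kinship matrix not PSD; clipping negative eigenvalues")
    K <- psd_clip(K)
  }
  grid <- c(0, 10^seq(-2, 2, by = 1))
  pairs <- as.matrix(expand.grid(gg = grid, gw = grid))
  lls <- .reml_batch(y, C, K, w, pairs)
  best <- pairs[which.max(lls), ]
  # Nelder-Mead refinement on the log10(gamma + eps) scale
  eps <- 1e-4
  # ratios capped at 1e6: the criterion is asymptotically flat as a ratio
  # grows, and unbounded ratios make the whitening ill-conditioned
  gmax <- 1e6
  clamp <- function(lg) min(max(10^lg - eps, 0), gmax)
  opt <- stats::optim(log10(pmin(best, gmax) + eps), function(lg) {
    -.reml_one(y, C, K, w, clamp(lg[1]), clamp(lg[2]))
  }, method = "Nelder-Mead",
  control = list(reltol = 1e-10, maxit = 300))
  best <- c(clamp(opt$par[1]), clamp(opt$par[2]))
  # parsimony: when the criterion is flat (e.g. K = I makes the split of
  # variance between components unidentifiable), prefer the simpler model
  cand <- rbind(c(0, 0), c(best[1], 0), c(0, best[2]), best)
  clls <- .reml_batch(y, C, K, w, cand)
  best <- cand[which(clls >= max(clls) - 1e-6)[1], ]
  fin <- reml_eval(best[1], best[2], y, C, K, w)
  if (!is.finite(fin$ll))
    stop("REML optimization failed to produce a finite criterion")
  Tm <- backsolve(fin$U, diag(n), transpose = TRUE)
  list(sigma2_g = best[1] * fin$s2, sigma2_w = best[2] * fin$s2,
       sigma2_e = fin$s2, gamma_g = best[1], gamma_w = best[2],
       T = Tm, reml = fin$ll)
}

#' Wald test of one SNP under the fitted null covariance
#'
#' Generalized least squares of the whitened response on the whitened
#' covariates plus dosage; returns the Wald estimate, standard error and
#' two-sided normal p-value for the dosage coefficient. When `K = I` and
#' the weights are constant this reduces exactly to OLS.
#'
#' @param y response (same vector the null model was fitted to).
#' @param g_dosage dosage vector; missing values are mean-imputed.
#' @param C fixed-effect design (intercept appended if absent).
#' @param T whitening matrix from [fit_null_lmm()].
#' @return list `beta`, `se`, `p`; `NULL` when the dosage is constant.
#' @export
test_snp <- function(y, g_dosage, C = NULL, T = NULL) {
  n <- length(y)
  if (is.null(C)) C <- matrix(1, n, 1)
  C <- as.matrix(C)
  if (!any(apply(C, 2, function(col) stats::sd(col) == 0))) C <- cbind(1, C)
  if (anyNA(g_dosage))
    g_dosage[is.na(g_dosage)] <- mean(g_dosage, na.rm = TRUE)
  if (stats::sd(g_dosage) == 0) return(NULL)
  X <- cbind(C, g = g_dosage)
  if (!is.null(T)) { y <- T %*% y; X <- T %*% X }
  wald_last(y, X)
}

# Wald stats for the last column of X (and optionally the one before it)
wald_last <- function(y, X, k_last = 1L) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) return(NULL)
  cf <- qr.coef(qr_x, y)
  res <- qr.resid(qr_x, y)
  s2 <- sum(res^2) / (length(y) - ncol(X))
  XtXi <- chol2inv(qr.R(qr_x))
  idx <- ncol(X) - k_last + seq_len(k_last)
  beta <- cf[idx]
  se <- sqrt(s2 * diag(XtXi)[idx])
  p <- 2 * stats::pnorm(-abs(beta / se))
  list(beta = unname(beta), se = unname(se), p = unname(p))
}

#' Map cis-eQTLs per cell type with a kinship + cell-count LMM
#'
#' For every retained cell type: each gene is inverse-normal-transformed,
#' the leading expression PCs are regressed out, a null LMM with kinship
#' and `1/nCells` random effects is fitted once per gene, and every cis SNP
#' is tested by GLS under the fitted null covariance.
#'
#' @param pb a `PseudobulkTensor` (or a `SimCohort`, whose latent-scale
#'   pseudobulk and cell counts are used directly).
#' @param g a [genotype_matrix()] covering the pseudobulk donors.
#' @param cis a [cis_index()] over the pseudobulk genes.
#' @param spec an [assoc_spec()].
#' @param K kinship matrix; default [make_grm()] of `g`.
#' @return data.frame (`AssocTable`): `cell_type`, `gene`, `snp`, `beta`,
#'   `se`, `p`, `n`, `maf`.
#' @export
map_cis <- function(pb, g, cis, spec = assoc_spec(), K = NULL) {
  pb <- as_pseudobulk(pb)
  if (is.null(K)) K <- make_grm(g)
  K <- align_kinship(K, g)
  res <- list()
  for (ct in names(pb$expr)) {
    E <- pb$expr[[ct]]
    donors <- rownames(E)
    if (length(donors) < spec$min_donors) {
      message("cell type ", ct, " below min_donors; skipped"); next
    }
    if (spec$quantile_normalize) E <- apply(E, 2, inverse_normal_transform)
    Er <- regress_out_pcs(E, min(spec$n_expr_pcs, nrow(E) - 1L))
    Ksub <- K[donors, donors]
    w <- 1 / pb$ncells[donors, ct]
    dos <- g$dosage[donors, , drop = FALSE]
    for (gene in colnames(Er)) {
      snps <- cis[[gene]]
      if (is.null(snps) || !length(snps)) next
      y <- Er[, gene]
      nf <- fit_null_lmm(y, NULL, Ksub, w)
      for (j in snps) {
        gd <- dos[, j]
        maf <- min(mean(gd, na.rm = TRUE) / 2, 1 - mean(gd, na.rm = TRUE) / 2)
        t <- test_snp(y, gd, NULL, nf$T)
        if (is.null(t)) next
        res[[length(res) + 1L]] <- data.frame(
          cell_type = ct, gene = gene, snp = g$snp_meta$id[j],
          beta = t$beta, se = t$se, p = t$p, n = length(y), maf = maf,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(cell_type = character(0), gene = character(0),
                      snp = character(0), beta = numeric(0), se = numeric(0),
                      p = numeric(0), n = integer(0), maf = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Map genotype-by-disease interaction eQTLs
#'
#' Per cell type with at least `min_donors_per_group` control and disease
#' donors (each with at least `min_cells` cells): fits
#' `y = PCs + g + disease + g:disease` under the null-LMM whitening, tests
#' the interaction coefficient by Wald, and keeps records whose observed
#' per-group MAF exceeds `maf_per_group_min`. Expression PCs are included
#' as fixed effects but not regressed out, because disease status is
#' typically correlated with leading PCs.
#'
#' @param pb,g,cis,spec,K as in [map_cis()].
#' @param disease named vector (donor -> status) or data.frame with
#'   `donor_id`, `disease_status`; the non-reference level is the
#'   case/disease group.
#' @param case_label status value treated as the disease group ("ILD").
#' @param min_donors_per_group minimum donors per group; default 10.
#' @param min_cells minimum cells per donor/cell type; default 5.
#' @param maf_per_group_min SNPs kept when per-group MAF exceeds this in
#'   both groups; default 0.05.
#' @return data.frame: `cell_type`, `gene`, `snp`, `beta`, `se`, `p`,
#'   `beta_int`, `se_int`, `p_int`, `n`, `maf`.
#' @export
map_interaction <- function(pb, g, cis, spec = assoc_spec(), disease,
                            K = NULL, case_label = "ILD",
                            min_donors_per_group = 10, min_cells = 5,
                            maf_per_group_min = 0.05) {
  pb <- as_pseudobulk(pb)
  if (is.data.frame(disease))
    disease <- stats::setNames(disease$disease_status, disease$donor_id)
  if (is.null(K)) K <- make_grm(g)
  K <- align_kinship(K, g)
  res <- list()
  for (ct in names(pb$expr)) {
    E <- pb$expr[[ct]]
    donors <- rownames(E)[pb$ncells[rownames(E), ct] >= min_cells]
    d <- as.numeric(disease[donors] == case_label)
    if (sum(d == 1) < min_donors_per_group ||
        sum(d == 0) < min_donors_per_group) {
      message("cell type ", ct, " lacks ", min_donors_per_group,
              " donors per disease group; excluded")
      next
    }
    E <- E[donors, , drop = FALSE]
    if (spec$quantile_normalize) E <- apply(E, 2, inverse_normal_transform)
    n_pcs <- min(spec$n_expr_pcs, nrow(E) - 1L)
    pcs <- expression_pcs(E, n_pcs)
    Cbase <- cbind(1, pcs, d = d)
    Ksub <- K[donors, donors]
    w <- 1 / pb$ncells[donors, ct]
    dos <- g$dosage[donors, , drop = FALSE]
    # per-group MAF pre-filter: drop SNPs with MAF < threshold in either group
    af1 <- colMeans(dos[d == 1, , drop = FALSE], na.rm = TRUE) / 2
    af0 <- colMeans(dos[d == 0, , drop = FALSE], na.rm = TRUE) / 2
    maf1 <- pmin(af1, 1 - af1); maf0 <- pmin(af0, 1 - af0)
    snp_ok <- !(maf1 < maf_per_group_min | maf0 < maf_per_group_min)
    for (gene in colnames(E)) {
      snps <- cis[[gene]]
      snps <- snps[snp_ok[snps]]
      if (!length(snps)) next
      y <- E[, gene]
      nf <- fit_null_lmm(y, Cbase, Ksub, w)
      Ty <- nf$T %*% y
      TC <- nf$T %*% Cbase
      for (j in snps) {
        gd <- dos[, j]
        if (anyNA(gd)) gd[is.na(gd)] <- mean(gd, na.rm = TRUE)
        if (stats::sd(gd) == 0 || stats::sd(gd * d) == 0) next
        X <- cbind(TC, nf$T %*% cbind(gd, gd * d))
        t <- wald_last(Ty, X, k_last = 2L)
        if (is.null(t)) next
        res[[length(res) + 1L]] <- data.frame(
          cell_type = ct, gene = gene, snp = g$snp_meta$id[j],
          beta = t$beta[1], se = t$se[1], p = t$p[1],
          beta_int = t$beta[2], se_int = t$se[2], p_int = t$p[2],
          n = length(y), maf = min(mean(gd) / 2, 1 - mean(gd) / 2),
          maf_case = maf1[j], maf_control = maf0[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(cell_type = character(0), gene = character(0),
                      snp = character(0), beta = numeric(0), se = numeric(0),
                      p = numeric(0), beta_int = numeric(0),
                      se_int = numeric(0), p_int = numeric(0), n = integer(0),
                      maf = numeric(0), maf_case = numeric(0),
                      maf_control = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  # post-hoc prune: observed per-group MAF must be strictly above threshold
  out[out$maf_case > maf_per_group_min & out$maf_control > maf_per_group_min,
      , drop = FALSE]
}

align_kinship <- function(K, g) {
  if (is.null(dimnames(K)))
    dimnames(K) <- list(rownames(g$dosage), rownames(g$dosage))
  K
}

as_pseudobulk <- function(x) {
  if (inherits(x, "PseudobulkTensor")) return(x)
  if (inherits(x, "SimCohort")) {
    out <- list(expr = x$pseudobulk, ncells = x$ncells,
                donors = lapply(x$pseudobulk, rownames))
    class(out) <- "PseudobulkTensor"
    return(out)
  }
  stop("expected a PseudobulkTensor or SimCohort")
}

#' Donor-level permutation of genotype or disease labels
#'
#' Permutes the named labels at the donor level with a fixed seed (or an
#' explicit permutation), leaving everything else untouched. Used for the
#' genotype-shuffle and disease-label-shuffle calibration runs.
#'
#' @param cohort a `SimCohort` (or any list with `genotypes` and `donors`).
#' @param what `"genotype"` or `"disease"`.
#' @param seed permutation seed (ignored when `perm` is given).
#' @param perm optional explicit permutation of `1:n_donors`.
#' @return the cohort with the permuted labels.
#' @export
permute_labels <- function(cohort, what = c("genotype", "disease"),
                           seed = 1L, perm = NULL) {
  what <- match.arg(what)
  n <- nrow(cohort$donors)
  if (is.null(perm)) perm <- with_seed(seed, sample.int(n))
  stopifnot(length(perm) == n, sort(perm) == seq_len(n))
  if (what == "genotype") {
    d <- cohort$genotypes$dosage
    nm <- rownames(d)
    d <- d[perm, , drop = FALSE]
    rownames(d) <- nm
    cohort$genotypes$dosage <- d
  } else {
    cohort$donors$disease_status <- cohort$donors$disease_status[perm]
  }
  cohort
}
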