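#' Assemble an effect panel across cell types
#'
#' Reshapes a long association table into the tests x cell-types matrices
#' `Bhat` / `Shat` consumed by the multivariate shrinkage model. Only
#' (gene, snp) pairs tested in every cell type are retained.
#'
#' @param assoc an association table from [map_cis()] or
#'   [map_interaction()].
#' @param beta_col,se_col columns holding the estimate and its standard
#'   error (use `"beta_int"` / `"se_int"` for the interaction analysis).
#' @return list of class `EffectPanel`: `Bhat`, `Shat` (tests x R), `tests`
#'   (data.frame `gene`, `snp`), `celltypes`.
#' @export
effect_panel <- function(assoc, beta_col = "beta", se_col = "se") {
  stopifnot(all(c("cell_type", "gene", "snp", beta_col, se_col) %in%
                  names(assoc)))
  if (!nrow(assoc)) stop("empty association table: nothing to shrink")
  key <- paste(assoc$gene, assoc$snp, sep = "|")
  cts <- sort(unique(assoc$cell_type))
  keep <- names(which(table(key) == length(cts)))
  B <- matrix(NA_real_, length(keep), length(cts),
              dimnames = list(keep, cts))
  S <- B
  idx <- cbind(match(key, keep), match(assoc$cell_type, cts))
  ok <- !is.na(idx[, 1])
  B[idx[ok, , drop = FALSE]] <- assoc[[beta_col]][ok]
  S[idx[ok, , drop = FALSE]] <- assoc[[se_col]][ok]
  parts <- strsplit(keep, "|", fixed = TRUE)
  out <- list(Bhat = B, Shat = S,
              tests = data.frame(gene = vapply(parts, `[`, "", 1),
                                 snp = vapply(parts, `[`, "", 2),
                                 stringsAsFactors = FALSE),
              celltypes = cts)
  class(out) <- "EffectPanel"
  out
}

#' Default scaling grid for the mixture prior
#'
#' Geometric grid with ratio sqrt(2) from `min(Shat)^2 / 10` to
#' `4 * max(Bhat^2)`.
#'
#' @param Bhat,Shat effect estimates and standard errors.
#' @return numeric vector of scaling factors.
#' @export
default_omega_grid <- function(Bhat, Shat) {
  lo <- min(Shat[Shat > 0])^2 / 10
  hi <- max(4 * max(Bhat^2), lo * 2)
  n <- ceiling(log(hi / lo) / log(2) * 2) + 1
  lo * 2^(seq(0, n - 1) / 2)
}

# null slice first, then omega * U for every (U, omega) pair
build_ucube <- function(U_list, omega_grid, R) {
  K <- 1L + length(U_list) * length(omega_grid)
  cube <- array(0, dim = c(R, R, K))
  labels <- "null"
  k <- 1L
  for (ui in seq_along(U_list)) for (om in omega_grid) {
    k <- k + 1L
    cube[, , k] <- om * U_list[[ui]]
    labels <- c(labels, sprintf("%s.omega_%g", names(U_list)[ui] %||% ui, om))
  }
  dimnames(cube) <- list(NULL, NULL, labels)
  cube
}

#' Fit mixture weights by EM
#'
#' Maximizes `sum_t log sum_k pi_k N(bhat_t; 0, U_k + S_t V S_t)` over the
#' simplex, where the component list is the null matrix plus every
#' `omega * U` combination. EM runs to a relative log-likelihood change
#' below `tol` or `max_iter` iterations; the log-likelihood is
#' non-decreasing by construction.
#'
#' @param Bhat,Shat tests x R matrices.
#' @param U_list named list of R x R prior covariance matrices.
#' @param omega_grid positive scaling factors; default
#'   [default_omega_grid()].
#' @param V R x R null correlation of the errors; default identity.
#' @param subset optional row indices to fit on (the fit is then applied to
#'   all rows by [mash_posterior()]).
#' @param max_iter,tol EM controls.
#' @return list: `pi` (named weights, first = null), `loglik` (trace),
#'   `Ucube`, `V`, `converged`.
#' @export
fit_mixture <- function(Bhat, Shat, U_list, omega_grid = NULL, V = NULL,
                        subset = NULL, max_iter = 1000, tol = 1e-8) {
  Bhat <- as.matrix(Bhat); Shat <- as.matrix(Shat)
  R <- ncol(Bhat)
  if (is.null(V)) V <- diag(R)
  if (is.null(omega_grid)) omega_grid <- default_omega_grid(Bhat, Shat)
  cube <- build_ucube(U_list, omega_grid, R)
  if (!is.null(subset)) { Bhat <- Bhat[subset, , drop = FALSE]
                          Shat <- Shat[subset, , drop = FALSE] }
  L <- .mash_loglik(Bhat, Shat, V, cube)
  if (any(!is.finite(L) & !(L == -Inf)))
    stop("non-finite likelihood for test row ",
         which(!is.finite(rowSums(L)))[1])
  K <- ncol(L)
  labels <- dimnames(cube)[[3]]
  alive <- rep(TRUE, K)
  pi <- rep(1 / K, K)
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lw <- sweep(L[, alive, drop = FALSE], 2, log(pi[alive] + 1e-300), "+")
    m <- lw[cbind(seq_len(nrow(lw)), max.col(lw, ties.method = "first"))]
    w <- exp(lw - m)
    rs <- rowSums(w)
    ll <- sum(m + log(rs))
    ll_trace <- c(ll_trace, ll)
    pi_new <- pi
    pi_new[alive] <- colMeans(w / rs)
    if (it > 1 && abs(ll - ll_trace[it - 1]) <
        tol * (abs(ll_trace[it - 1]) + 1)) { pi <- pi_new; break }
    pi <- pi_new
    # components whose weight has collapsed are at a zero fixed point;
    # dropping them from the sweeps only accelerates the identical EM path
    if (it %% 25 == 0) {
      dead <- alive & pi < 1e-14
      dead[1] <- FALSE                 # keep the null component
      if (any(dead)) { pi[dead] <- 0; alive[dead] <- FALSE }
    }
  }
  pi <- pi / sum(pi)
  names(pi) <- labels
  list(pi = pi, loglik = ll_trace, Ucube = cube, V = V,
       omega_grid = omega_grid,
       converged = length(ll_trace) < max_iter)
}

#' Posterior effects and local false sign rates
#'
#' Applies a fitted mixture prior to every test: the posterior over the
#' effect vector is the responsibility-weighted mixture of the per-component
#' multivariate-normal posteriors (plus the null point mass). Per condition,
#' `lfsr = min(P(b >= 0 | data), P(b <= 0 | data))`, both sides including
#' the posterior null mass.
#'
#' @param Bhat,Shat tests x R matrices.
#' @param fit result of [fit_mixture()].
#' @return list: `post_mean`, `post_sd`, `lfsr` (tests x R, dimnames of
#'   `Bhat`).
#' @export
mash_posterior <- function(Bhat, Shat, fit) {
  Bhat <- as.matrix(Bhat); Shat <- as.matrix(Shat)
  # components with negligible weight contribute < K * 1e-10 to any
  # posterior quantity; dropping them changes nothing at test tolerance
  keep <- fit$pi > 1e-10
  keep[1] <- TRUE                      # the null component always stays
  out <- .mash_posterior(Bhat, Shat, fit$V,
                         fit$Ucube[, , keep, drop = FALSE], fit$pi[keep])
  for (nm in names(out)) dimnames(out[[nm]]) <- dimnames(Bhat)
  out
}

# univariate adaptive shrinkage: normal-mixture prior on one condition
ash_lfsr <- function(bhat, shat, max_iter = 1000) {
  B <- matrix(bhat, ncol = 1); S <- matrix(shat, ncol = 1)
  fit <- fit_mixture(B, S, list(one = matrix(1, 1, 1)),
                     max_iter = max_iter)
  mash_posterior(B, S, fit)$lfsr[, 1]
}

#' Select strong associations
#'
#' Computes a per-condition univariate adaptive-shrinkage LFSR (normal
#' mixture prior per column) and returns the tests whose minimum LFSR over
#' conditions is below `lfsr_threshold`. These "strong" rows seed the
#' data-driven covariance estimation.
#'
#' @param panel an [effect_panel()].
#' @param lfsr_threshold default 0.1.
#' @return integer row indices into the panel; the per-condition univariate
#'   LFSR matrix is attached as attribute `"lfsr"`.
#' @export
select_strong <- function(panel, lfsr_threshold = 0.1) {
  lf <- vapply(seq_len(ncol(panel$Bhat)), function(r)
    ash_lfsr(panel$Bhat[, r], panel$Shat[, r]),
    numeric(nrow(panel$Bhat)))
  lf <- matrix(lf, nrow = nrow(panel$Bhat))
  idx <- which(apply(lf, 1, min) < lfsr_threshold)
  if (!length(idx))
    stop("no strong associations at LFSR < ", lfsr_threshold,
         "; raise the threshold")
  attr(idx, "lfsr") <- lf
  idx
}

#' Canonical + data-driven covariance library
#'
#' Canonical matrices: identity (independent effects), one singleton per
#' condition (effect in that condition only) and the all-ones matrix
#' (equal effects everywhere). Data-driven matrices are built from the
#' z-scores of the strong tests: rank-1 outer products of the top `n_pcs`
#' right singular vectors, the rank-`n_pcs` PCA reconstruction, and its
#' refinement by `ed_iters` fixed-point extreme-deconvolution updates
#' (noise covariance `V` in z-space). All matrices are symmetrized,
#' PSD-clipped and scaled to unit maximum diagonal.
#'
#' @param strong_Z z-score matrix (strong tests x R); e.g.
#'   `panel$Bhat[idx,]/panel$Shat[idx,]`.
#' @param n_pcs number of principal components; default 5.
#' @param ed_iters extreme-deconvolution iterations; default 50.
#' @param V noise correlation used by the ED updates; default identity.
#' @return named list of R x R matrices.
#' @export
build_covariances <- function(strong_Z, n_pcs = 5, ed_iters = 50, V = NULL) {
  strong_Z <- as.matrix(strong_Z)
  R <- ncol(strong_Z)
  if (is.null(V)) V <- diag(R)
  U <- list(identity = diag(R))
  if (R > 1) {
    for (r in seq_len(R)) {
      M <- matrix(0, R, R); M[r, r] <- 1
      U[[paste0("singleton_", r)]] <- M
    }
    U$equal <- matrix(1, R, R)
  }
  Tn <- nrow(strong_Z)
  n_pcs <- min(n_pcs, R, Tn)
  if (Tn >= max(2, n_pcs) && stats::sd(strong_Z) > 0) {
    sv <- svd(strong_Z, nu = 0, nv = n_pcs)
    for (k in seq_len(n_pcs)) {
      v <- sv$v[, k]
      U[[paste0("pca_", k)]] <- sv$d[k]^2 * tcrossprod(v) / Tn
    }
    tpca <- sv$v %*% (sv$d[seq_len(n_pcs)]^2 * t(sv$v)) / Tn
    U$tpca <- tpca
    # extreme deconvolution: z_t ~ N(0, U + V); Bovy-style fixed point
    Ued <- tpca
    Szz <- crossprod(strong_Z) / Tn
    for (i in seq_len(ed_iters)) {
      P <- Ued %*% solve(Ued + V + 1e-10 * diag(R))
      Ued <- P %*% Szz %*% t(P) + Ued - P %*% Ued
      Ued <- (Ued + t(Ued)) / 2
    }
    U$ed <- Ued
  } else {
    message("degenerate strong set; canonical covariances only")
  }
  lapply(U, function(M) {
    M <- psd_clip_u((M + t(M)) / 2)
    mx <- max(diag(M))
    if (mx > 0) M / mx else M
  })
}

# eigenvalue floor at 1e-10 * max eigenvalue
psd_clip_u <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  floor_v <- 1e-10 * max(abs(e$values), 1e-300)
  e$vectors %*% (pmax(e$values, floor_v) * t(e$vectors))
}

#' Estimate the null correlation of the errors
#'
#' Correlation matrix of the z-scores restricted to null-like tests
#' (`max |z| < z_max` across conditions); identity when fewer than R + 1
#' such tests exist.
#'
#' @param panel an [effect_panel()].
#' @param z_max null-likeness bound; default 2.
#' @return R x R correlation matrix (PSD, unit diagonal).
#' @export
estimate_null_correlation <- function(panel, z_max = 2) {
  Z <- panel$Bhat / panel$Shat
  nulls <- apply(abs(Z), 1, max) < z_max
  R <- ncol(Z)
  if (sum(nulls) < R + 1) {
    message("too few null-like tests; using identity correlation")
    return(diag(R))
  }
  V <- stats::cor(Z[nulls, , drop = FALSE])
  V <- psd_clip_u((V + t(V)) / 2)
  stats::cov2cor(V)
}

#' Full multivariate shrinkage fit
#'
#' The eQTL-panel workflow: select strong tests (univariate LFSR < 0.1 in
#' at least one condition), build the covariance library from them,
#' estimate the null correlation, fit the mixture weights on a random
#' subset of tests (default 10,000; all tests when fewer exist), and
#' compute posterior means, SDs and LFSRs for every test.
#'
#' @param panel an [effect_panel()].
#' @param strong_lfsr strong-set threshold; default 0.1.
#' @param n_pcs,ed_iters covariance-library controls.
#' @param fit_subset_size number of tests the mixture is fitted on.
#' @param estimate_V estimate the null correlation (default `TRUE`;
#'   `FALSE` uses the identity).
#' @param seed seed for the fitting subset.
#' @return list of class `MashFit`: `pi`, `Ucube`, `V`, `omega_grid`,
#'   `post_mean`, `post_sd`, `lfsr`, `tests`, `celltypes`, `strong`.
#' @export
mash_fit <- function(panel, strong_lfsr = 0.1, n_pcs = 5, ed_iters = 50,
                     fit_subset_size = 10000, estimate_V = TRUE, seed = 1L) {
  strong <- select_strong(panel, strong_lfsr)
  V <- if (estimate_V) estimate_null_correlation(panel)
       else diag(ncol(panel$Bhat))
  Z <- panel$Bhat[strong, , drop = FALSE] /
    panel$Shat[strong, , drop = FALSE]
  U_list <- build_covariances(Z, n_pcs = n_pcs, ed_iters = ed_iters, V = V)
  n_tests <- nrow(panel$Bhat)
  subset <- if (n_tests > fit_subset_size)
    with_seed(seed, sample.int(n_tests, fit_subset_size)) else NULL
  fit <- fit_mixture(panel$Bhat, panel$Shat, U_list, V = V, subset = subset)
  post <- mash_posterior(panel$Bhat, panel$Shat, fit)
  out <- c(fit, post,
           list(tests = panel$tests, celltypes = panel$celltypes,
                strong = strong))
  class(out) <- "MashFit"
  out
}

#' @export
print.MashFit <- function(x, ...) {
  cat(sprintf("MashFit: %d tests x %d cell types; null weight %.3f\n",
              nrow(x$lfsr), ncol(x$lfsr), x$pi[["null"]]))
  invisible(x)
}

#' Serialize / restore a MashFit
#'
#' Writes the fit as a directory of plain files: JSON metadata (weights,
#' grid, component labels) and TSV matrices.
#'
#' @param fit a [mash_fit()] result.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_mash_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(pi = as.list(fit$pi), omega_grid = fit$omega_grid,
               celltypes = fit$celltypes, loglik = fit$loglik)
  jsonlite::write_json(meta, file.path(dir, "fit.json"), auto_unbox = TRUE,
                       digits = NA)
  for (nm in c("post_mean", "post_sd", "lfsr"))
    write_tsv(data.frame(fit$tests, fit[[nm]], check.names = FALSE),
              file.path(dir, paste0(nm, ".tsv.gz")))
  write_tsv(as.data.frame(fit$V), file.path(dir, "null_correlation.tsv"))
  invisible(dir)
}
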