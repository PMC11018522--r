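#' Two-tier significance calling on an LFSR matrix
#'
#' A test is significant in a condition when its LFSR there is at most
#' `primary`, or at most `secondary` provided the test reaches `primary`
#' in at least one condition (the anchored, less stringent tier that
#' reduces the impact of differential power across cell types). Rows
#' without an anchor at `primary` are entirely non-significant.
#'
#' @param lfsr tests x R matrix in \[0,1\].
#' @param primary,secondary thresholds, defaults 0.05 and 0.1.
#' @return logical matrix, same shape and dimnames.
#' @export
call_significance <- function(lfsr, primary = 0.05, secondary = 0.1) {
  if (primary > secondary) stop("primary threshold must be <= secondary")
  lfsr <- as.matrix(lfsr)
  anchor <- apply(lfsr, 1, min) <= primary
  sig <- (lfsr <= secondary) & anchor
  sig[lfsr <= primary] <- TRUE
  sig & anchor
}

#' Top eQTL per (gene, cell type)
#'
#' For every gene and cell type with at least one significant SNP, selects
#' the SNP with the lowest LFSR; ties are broken by larger absolute
#' posterior effect, then by smaller genomic position.
#'
#' @param tests data.frame with `gene`, `snp` aligned to the matrix rows;
#'   an optional `pos` column supplies the positional tie-break.
#' @param lfsr,sig,betas tests x R matrices (LFSR, [call_significance()]
#'   output, posterior effects).
#' @return data.frame: `gene`, `cell_type`, `snp`, `lfsr`, `beta`.
#' @export
select_top <- function(tests, lfsr, sig, betas) {
  pos <- tests$pos %||% rep(0, nrow(tests))
  out <- list()
  cts <- colnames(lfsr) %||% paste0("ct", seq_len(ncol(lfsr)))
  for (r in seq_len(ncol(lfsr))) {
    cand <- which(sig[, r])
    if (!length(cand)) next
    by_gene <- split(cand, tests$gene[cand])
    for (gene in names(by_gene)) {
      rows <- by_gene[[gene]]
      ord <- order(lfsr[rows, r], -abs(betas[rows, r]), pos[rows])
      best <- rows[ord[1]]
      out[[length(out) + 1L]] <- data.frame(
        gene = gene, cell_type = cts[r], snp = tests$snp[best],
        lfsr = lfsr[best, r], beta = betas[best, r],
        row = best, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene = character(0), cell_type = character(0),
                      snp = character(0), lfsr = numeric(0),
                      beta = numeric(0), row = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise sharing of top eQTLs between cell types
#'
#' For each cell-type pair (a, b): among top eQTLs significant in both, an
#' eQTL is shared when the two effects have the same sign and their
#' magnitudes are within a factor of `factor`
#' (`min(|ba|,|bb|)/max(|ba|,|bb|) >= factor`). Entries are
#' shared/eligible; the diagonal is 1; pairs with no eligible eQTL are
#' `NA`.
#'
#' @param top [select_top()] output (its `row` column indexes the
#'   matrices).
#' @param sig,betas tests x R logical and numeric matrices.
#' @param factor magnitude-ratio threshold; default 0.5.
#' @return R x R symmetric matrix of sharing fractions.
#' @export
pairwise_sharing <- function(top, sig, betas, factor = 0.5) {
  cts <- colnames(sig) %||% paste0("ct", seq_len(ncol(sig)))
  R <- ncol(sig)
  rows <- unique(top$row)
  M <- matrix(NA_real_, R, R, dimnames = list(cts, cts))
  diag(M) <- 1
  for (a in seq_len(R - 1)) for (b in (a + 1):R) {
    both <- rows[sig[rows, a] & sig[rows, b]]
    if (!length(both)) {
      message("no eligible top eQTL for pair ", cts[a], "/", cts[b])
      next
    }
    ba <- betas[both, a]; bb <- betas[both, b]
    shared <- sign(ba) == sign(bb) &
      pmin(abs(ba), abs(bb)) / pmax(abs(ba), abs(bb)) >= factor
    M[a, b] <- M[b, a] <- mean(shared)
  }
  M
}

#' Classify an eQTL as global, multi or unique
#'
#' Counts the conditions in which the eQTL is significant: 1 is `unique`,
#' at least `R - buffer` is `global` (the buffer absorbs low-powered cell
#' types; 36 of 38 cell types in the main analysis, 31 of 33 in the
#' interaction analysis), anything between is `multi`. Zero significant
#' conditions yields `none`.
#'
#' @param sig logical matrix (or vector) of significance calls.
#' @param buffer how many conditions may be missed while still counting as
#'   global; default 2.
#' @return character vector of labels, one per row.
#' @export
classify_sharing <- function(sig, buffer = 2) {
  if (is.vector(sig)) sig <- matrix(sig, nrow = 1)
  R <- ncol(sig)
  if (R < 3) stop("classification needs at least 3 conditions")
  s <- rowSums(sig)
  out <- rep("multi", nrow(sig))
  out[s == 0] <- "none"
  out[s == 1] <- "unique"
  out[s >= R - buffer] <- "global"
  out
}

#' Orient effect signs to the common direction
#'
#' Per row, the majority sign among significant conditions becomes
#' positive (ties broken by the sign of the largest absolute effect); the
#' whole row is multiplied by that orientation. Re-running on the output
#' returns it unchanged.
#'
#' @param betas tests x R effect matrix.
#' @param sig logical matrix of the same shape.
#' @return oriented matrix.
#' @export
sign_adjust <- function(betas, sig) {
  betas <- as.matrix(betas); sig <- as.matrix(sig)
  for (i in seq_len(nrow(betas))) {
    b <- betas[i, sig[i, ]]
    if (!length(b)) next
    s <- sum(sign(b))
    orient <- if (s != 0) sign(s) else sign(b[which.max(abs(b))])
    if (orient == 0) orient <- 1
    betas[i, ] <- orient * betas[i, ]
  }
  betas
}

# mean silhouette width for a labelled distance matrix
mean_silhouette <- function(D, labels) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Prune top eQTLs to representatives per gene
#'
#' Collapses a gene's top eQTLs to visually distinct representatives using
#' Euclidean distances between the centered absolute effect vectors across
#' cell types. One eQTL: kept. Two: both kept when their distance exceeds
#' `distance_threshold`, otherwise the one significant in more cell types
#' (ties: lower minimum LFSR). Three or more: all kept when every pairwise
#' distance exceeds the threshold; otherwise average-linkage hierarchical
#' clustering is cut at the k in `k_range` maximizing the mean silhouette
#' width (k capped at n - 1) and each cluster keeps its member significant
#' in most cell types.
#'
#' @param top [select_top()] output for one analysis.
#' @param betas,sig,lfsr tests x R matrices (`top$row` indexes rows).
#' @param distance_threshold default 0.2.
#' @param k_range candidate cluster counts; default `c(2, 5)`.
#' @param center `"vector"` (default): subtract each vector's mean absolute
#'   effect; `"condition"`: center each condition across the gene's eQTLs.
#' @return subset of `top` rows retained.
#' @export
prune_representatives <- function(top, betas, sig, lfsr,
                                  distance_threshold = 0.2,
                                  k_range = c(2, 5),
                                  center = c("vector", "condition")) {
  center <- match.arg(center)
  uniq <- unique(top[, c("gene", "snp", "row")])
  keep_rows <- logical(nrow(uniq))
  nsig <- rowSums(sig)
  minlfsr <- apply(lfsr, 1, min)
  pick_best <- function(rows) rows[order(-nsig[rows], minlfsr[rows])[1]]
  kept <- list()
  for (gene in unique(uniq$gene)) {
    rows <- uniq$row[uniq$gene == gene]
    if (length(rows) == 1) { kept[[gene]] <- rows; next }
    A <- abs(betas[rows, , drop = FALSE])
    A <- switch(center,
      vector = A - rowMeans(A),
      condition = scale(A, center = TRUE, scale = FALSE))
    D <- as.matrix(stats::dist(A))
    if (length(rows) == 2) {
      kept[[gene]] <- if (D[1, 2] > distance_threshold) rows
                      else pick_best(rows)
      next
    }
    if (min(D[upper.tri(D)]) > distance_threshold) {
      kept[[gene]] <- rows
      next
    }
    ks <- seq(max(2, k_range[1]), min(k_range[2], length(rows) - 1))
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    best_k <- ks[1]; best_s <- -Inf
    for (k in ks) {
      lab <- stats::cutree(hc, k = k)
      s <- mean_silhouette(D, lab)
      if (s > best_s) { best_s <- s; best_k <- k }
    }
    lab <- stats::cutree(hc, k = best_k)
    kept[[gene]] <- vapply(split(rows, lab), pick_best, numeric(1))
  }
  top[top$row %in% unlist(kept), , drop = FALSE]
}

#' Heatmap-ready matrix of sign-adjusted effects
#'
#' Genes x cell types matrix of sign-adjusted posterior effects of the
#' (pruned) top eQTLs, with non-significant cells set to zero.
#'
#' @param top [select_top()] (possibly pruned) rows.
#' @param betas,sig tests x R matrices.
#' @return numeric matrix, one row per (gene, snp) in `top`.
#' @export
effect_heatmap_matrix <- function(top, betas, sig) {
  rows <- unique(top$row)
  adj <- sign_adjust(betas[rows, , drop = FALSE],
                     sig[rows, , drop = FALSE])
  adj[!sig[rows, , drop = FALSE]] <- 0
  rownames(adj) <- paste(top$gene[match(rows, top$row)],
                         top$snp[match(rows, top$row)], sep = "|")
  adj
}
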