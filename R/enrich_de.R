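#' Fisher's exact test for a 2x2 table
#'
#' Conditional hypergeometric two-sided p-value (sum of the probabilities
#' of all tables, with the margins fixed, at most as probable as the
#' observed one) and the sample odds ratio `ad/bc` (`Inf` when `bc = 0`).
#'
#' @param a,b,c,d cell counts: rows = in-class vs null set, columns =
#'   GWAS-overlapping vs not.
#' @return list `odds_ratio`, `p`.
#' @export
fisher_exact <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("zero margin: the table is degenerate")
  m <- a + c; n_ <- b + d; k <- a + b
  support <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b * c == 0) { if (a * d == 0) NaN else Inf } else (a * d) / (b * c)
  list(odds_ratio = or, p = p)
}

#' TSS-distance-matched null set by KDE rejection sampling
#'
#' Samples `size` candidates (without replacement) from `pool_dist` so
#' that the sampled absolute-TSS-distance distribution matches
#' `target_dist`: acceptance probabilities are proportional to the ratio of
#' kernel-density estimates of target over pool, computed on
#' `log10(1 + |distance|)` with Silverman's bandwidth (distances span
#' orders of magnitude).
#'
#' @param pool_dist absolute TSS distances of the candidate (non-significant)
#'   pool; names or indices identify candidates.
#' @param target_dist absolute TSS distances of the target (significant)
#'   set.
#' @param size number of nulls to draw.
#' @param seed RNG seed.
#' @return integer indices into `pool_dist` (no candidate twice).
#' @export
matched_null <- function(pool_dist, target_dist, size, seed = 1L) {
  if (size > length(pool_dist))
    stop("requested null set larger than the candidate pool; reduce size")
  lp <- log10(1 + abs(pool_dist))
  lt <- log10(1 + abs(target_dist))
  dt <- stats::density(lt, bw = "nrd0")
  dp <- stats::density(lp, bw = "nrd0")
  f_t <- stats::approx(dt$x, dt$y, xout = lp, rule = 2)$y
  f_p <- stats::approx(dp$x, dp$y, xout = lp, rule = 2)$y
  w <- f_t / pmax(f_p, 1e-12)
  accept_p <- w / max(w)
  with_seed(seed, {
    chosen <- integer(0)
    avail <- seq_along(pool_dist)
    while (length(chosen) < size) {
      if (!length(avail))
        stop("candidate pool exhausted before reaching the requested size; ",
             "reduce size")
      u <- stats::runif(length(avail))
      acc <- avail[u < accept_p[avail]]
      need <- size - length(chosen)
      if (length(acc) > need) acc <- sample(acc, need)
      chosen <- c(chosen, acc)
      avail <- setdiff(avail, acc)
    }
    sort(chosen)
  })
}

#' Wilcoxon rank-sum test with AUC
#'
#' Rank-based U statistic with tie correction; `auc = U / (nA * nB)` is the
#' probability that a random group-A value exceeds a random group-B value
#' (ties counting one half). Two-sided normal-approximation p-value; the
#' log fold change is `mean(A) - mean(B)` of the (log-scale) input.
#'
#' @param x numeric vector of (log-scale) expression.
#' @param group logical or two-level factor; `TRUE`/first level = group A.
#' @return list `auc`, `p`, `logFC`, `U`.
#' @export
wilcoxauc <- function(x, group) {
  g <- if (is.logical(group)) group else group == sort(unique(group))[1]
  nA <- sum(g); nB <- sum(!g)
  if (nA == 0 || nB == 0) stop("both groups must be nonempty")
  r <- rank(x)
  U <- sum(r[g]) - nA * (nA + 1) / 2
  n <- nA + nB
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(nA * nB / 12 * (n + 1 - tie_term))
  z <- (U - nA * nB / 2) / sigma
  p <- if (sigma == 0) 1 else 2 * stats::pnorm(-abs(z))
  list(auc = U / (nA * nB), p = min(1, p),
       logFC = mean(x[g]) - mean(x[!g]), U = U)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via `stats::p.adjust`).
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Differential expression between disease groups, per cell type
#'
#' Applies [wilcoxauc()] to every gene of a pseudobulk matrix split by
#' disease status and BH-adjusts within cell type.
#'
#' @param pb a `PseudobulkTensor` (or `SimCohort`).
#' @param disease named donor -> status vector or donor metadata
#'   data.frame.
#' @param case_label disease-group label; default "ILD".
#' @return data.frame: `cell_type`, `gene`, `auc`, `p`, `logFC`, `p_adj`.
#' @export
de_wilcox <- function(pb, disease, case_label = "ILD") {
  pb <- as_pseudobulk(pb)
  if (is.data.frame(disease))
    disease <- stats::setNames(disease$disease_status, disease$donor_id)
  out <- list()
  for (ct in names(pb$expr)) {
    E <- pb$expr[[ct]]
    g <- disease[rownames(E)] == case_label
    if (!any(g) || all(g)) next
    res <- apply(E, 2, function(x) unlist(wilcoxauc(x, g)[c("auc", "p",
                                                            "logFC")]))
    out[[ct]] <- data.frame(cell_type = ct, gene = colnames(E),
                            auc = res["auc", ], p = res["p", ],
                            logFC = res["logFC", ],
                            p_adj = bh_adjust(res["p", ]),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enrichment of an eQTL class among GWAS variants
#'
#' Builds the 2x2 table (class vs distance-matched null, GWAS-overlapping
#' vs not) and applies [fisher_exact()]. The null set is drawn from the
#' non-significant pool with [matched_null()] to mirror the class's
#' absolute TSS-distance distribution.
#'
#' @param class_snps,class_dist SNP ids of the class and their absolute
#'   TSS distances.
#' @param pool_snps,pool_dist candidate null SNP ids and distances.
#' @param gwas_snps GWAS risk-variant ids (already thresholded, e.g.
#'   nominal p < 1e-6).
#' @param null_size null-set size; default the class size.
#' @param seed RNG seed for the null draw.
#' @return list: `table` (2x2), `odds_ratio`, `p`, `null_size`.
#' @export
enrich_gwas <- function(class_snps, class_dist, pool_snps, pool_dist,
                        gwas_snps, null_size = length(class_snps),
                        seed = 1L) {
  idx <- matched_null(pool_dist, class_dist, null_size, seed)
  null_snps <- pool_snps[idx]
  a <- sum(class_snps %in% gwas_snps); b <- length(class_snps) - a
  c_ <- sum(null_snps %in% gwas_snps); d <- length(null_snps) - c_
  ft <- fisher_exact(a, b, c_, d)
  list(table = matrix(c(a, b, c_, d), 2, byrow = TRUE,
                      dimnames = list(c("class", "null"),
                                      c("gwas", "not"))),
       odds_ratio = ft$odds_ratio, p = ft$p, null_size = null_size)
}

#' Partition interaction eGenes by differential-expression behaviour
#'
#' Per cell type, interaction eGenes fall into `DE` (adjusted p below
#' `de_padj`), `equal` (expressed in more than `min_expr_frac` of cells in
#' both disease groups and `|logFC|` below `max_lfc` — equally expressed
#' but differentially regulated), or `other`. Genes without a DE entry are
#' counted as `other` with a message.
#'
#' @param de [de_wilcox()] output.
#' @param int_egenes data.frame `cell_type`, `gene` of interaction eGenes.
#' @param expr_frac data.frame `cell_type`, `gene`, `frac_cases`,
#'   `frac_controls`: fraction of cells expressing the gene per group.
#' @param de_padj,min_expr_frac,max_lfc thresholds (defaults 0.1, 0.30,
#'   0.2).
#' @return list: `categories` (per-gene labels) and `fractions`.
#' @export
int_egene_overlap <- function(de, int_egenes, expr_frac, de_padj = 0.1,
                              min_expr_frac = 0.30, max_lfc = 0.2) {
  key <- function(d) paste(d$cell_type, d$gene)
  de_k <- key(de); ef_k <- key(expr_frac)
  lab <- character(nrow(int_egenes))
  for (i in seq_len(nrow(int_egenes))) {
    k <- paste(int_egenes$cell_type[i], int_egenes$gene[i])
    j <- match(k, de_k)
    if (is.na(j)) {
      message("no DE entry for ", k, "; counted as other")
      lab[i] <- "other"; next
    }
    if (de$p_adj[j] < de_padj) { lab[i] <- "DE"; next }
    e <- match(k, ef_k)
    if (!is.na(e) && expr_frac$frac_cases[e] > min_expr_frac &&
        expr_frac$frac_controls[e] > min_expr_frac &&
        abs(de$logFC[j]) < max_lfc) { lab[i] <- "equal"; next }
    lab[i] <- "other"
  }
  out <- cbind(int_egenes, category = lab)
  list(categories = out,
       fractions = prop.table(table(factor(lab,
                                           c("DE", "equal", "other")))))
}
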