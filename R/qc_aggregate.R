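#' Cell-level QC filter
#'
#' Removes cells whose mitochondrial read fraction exceeds `mito_max`
#' (cells exactly at the boundary are kept). Row order is preserved.
#'
#' @param cells data.frame with at least `mito_fraction`; typically the
#'   cell metadata of a cohort (`cell_id`, `donor_id`, `cell_type`,
#'   `mito_fraction`, `n_features`, `disease_status`).
#' @param mito_max maximum tolerated mitochondrial fraction, in (0, 1\];
#'   default 0.20.
#' @return the filtered cell table.
#' @export
filter_cells <- function(cells, mito_max = 0.20) {
  stopifnot(is.data.frame(cells), nrow(cells) > 0,
            "mito_fraction" %in% names(cells))
  if (!is.numeric(mito_max) || length(mito_max) != 1L ||
      mito_max <= 0 || mito_max > 1)
    stop("mito_max must lie in (0, 1]")
  keep <- cells$mito_fraction <= mito_max
  if (!any(keep)) warning("all cells removed by the mitochondrial filter")
  log_stage("filter_cells", "kept", sprintf("%d/%d", sum(keep), nrow(cells)))
  cells[keep, , drop = FALSE]
}

#' Sample-level QC filter
#'
#' Retains samples with more than `min_features` median identified features
#' or less than `mito_max` mitochondrial fraction, evaluated per sample
#' over its cells. Applied only when the metadata carries a `sample_id`.
#'
#' @param cells cell metadata with `sample_id`, `n_features`,
#'   `mito_fraction`.
#' @param min_features,mito_max sample-level thresholds (defaults 1000 and
#'   0.25).
#' @return the filtered cell table.
#' @export
filter_samples <- function(cells, min_features = 1000, mito_max = 0.25) {
  if (!"sample_id" %in% names(cells)) return(cells)
  feat <- tapply(cells$n_features, cells$sample_id, stats::median)
  mito <- tapply(cells$mito_fraction, cells$sample_id, mean)
  ok <- names(feat)[feat >= min_features | mito <= mito_max]
  log_stage("filter_samples", "kept_samples",
            sprintf("%d/%d", length(ok), length(feat)))
  cells[cells$sample_id %in% ok, , drop = FALSE]
}

#' Gene inclusion filter
#'
#' Keeps genes expressed (count > 0) in at least `min_frac_cells` of all
#' cells in the study, with mean count across all cells at least
#' `min_mean_count`, and not on any exclusion list (e.g. mitochondrial and
#' ribosomal-protein genes). Both expression filters are computed over the
#' full cell population, not per cell type.
#'
#' @param counts gene x cell count matrix (sparse ok), rownames = gene ids.
#' @param min_frac_cells minimum expressed-cell fraction; default 0.10.
#' @param min_mean_count minimum mean count; default 0.1.
#' @param exclude_lists character vector (or list of vectors) of gene ids
#'   to drop regardless of expression.
#' @return character vector of retained gene ids.
#' @export
filter_genes <- function(counts, min_frac_cells = 0.10, min_mean_count = 0.1,
                         exclude_lists = character(0)) {
  if (nrow(counts) == 0) stop("empty gene universe")
  excl <- unique(unlist(exclude_lists))
  frac <- Matrix::rowSums(counts > 0) / ncol(counts)
  meanc <- Matrix::rowMeans(counts)
  keep <- frac >= min_frac_cells & meanc >= min_mean_count &
    !(rownames(counts) %in% excl)
  log_stage("filter_genes", "kept", sprintf("%d/%d", sum(keep), nrow(counts)))
  rownames(counts)[keep]
}

#' Cell-type and donor inclusion for eQTL mapping
#'
#' A cell type enters mapping when at least `min_donors` donors contribute
#' at least `min_cells` cells of that type; within a retained cell type,
#' donors below `min_cells` are excluded.
#'
#' @param ncells donor x cell type matrix of cell counts.
#' @param min_donors minimum qualifying donors per cell type; default 40.
#' @param min_cells minimum cells per (donor, cell type); default 5.
#' @return named list per retained cell type: character vector of retained
#'   donor ids.
#' @export
select_celltypes <- function(ncells, min_donors = 40, min_cells = 5) {
  stopifnot(is.matrix(ncells), all(ncells >= 0))
  out <- list()
  for (ct in colnames(ncells)) {
    donors <- rownames(ncells)[ncells[, ct] >= min_cells]
    if (length(donors) >= min_donors) out[[ct]] <- donors
  }
  if (!length(out)) message("no cell type meets the inclusion criteria")
  log_stage("select_celltypes", "kept",
            sprintf("%d/%d", length(out), ncol(ncells)))
  out
}

#' Normalize counts and aggregate to pseudobulk
#'
#' Per cell type: per-cell size factors are computed as library size over
#' the median library size of that cell type's cells, counts are divided by
#' the size factor, log2(1 + x)-transformed and averaged over each donor's
#' cells, yielding one value per gene per donor per cell type. The number
#' of cells aggregated (`nCells`) is recorded for every retained pair.
#'
#' @param counts gene x cell count matrix (after gene filtering).
#' @param cells cell metadata aligned to `counts` columns (after cell QC).
#' @param genes character vector of retained gene ids.
#' @param celltype_donors named list from [select_celltypes()]; donors per
#'   retained cell type.
#' @param size_factors `"libsize"` (default; per-cell-type median-depth
#'   scaling) or `"none"`.
#' @return list of class `PseudobulkTensor`: `expr` (list per cell type of
#'   donor x gene matrices), `ncells` (donor x cell type, 0 when not
#'   retained), `donors` (per cell type, character vector).
#' @export
normalize_aggregate <- function(counts, cells, genes, celltype_donors,
                                size_factors = c("libsize", "none")) {
  size_factors <- match.arg(size_factors)
  stopifnot(ncol(counts) == nrow(cells))
  counts <- counts[genes, , drop = FALSE]
  cts <- names(celltype_donors)
  all_donors <- sort(unique(cells$donor_id))
  ncells <- matrix(0L, length(all_donors), length(cts),
                   dimnames = list(all_donors, cts))
  expr <- list()
  for (ct in cts) {
    in_ct <- cells$cell_type == ct & cells$donor_id %in% celltype_donors[[ct]]
    sub <- counts[, in_ct, drop = FALSE]
    donor <- cells$donor_id[in_ct]
    depth <- Matrix::colSums(sub)
    sf <- if (size_factors == "libsize") depth / stats::median(depth)
          else rep(1, ncol(sub))
    if (any(sf == 0)) sf[sf == 0] <- 1  # empty cells contribute log2(1+0)=0
    logn <- log2(1 + t(t(as.matrix(sub)) / sf))
    keep_donors <- intersect(celltype_donors[[ct]], unique(donor))
    dropped <- setdiff(celltype_donors[[ct]], keep_donors)
    if (length(dropped))
      message(length(dropped), " donor(s) with zero retained cells dropped ",
              "for ", ct)
    M <- matrix(NA_real_, length(keep_donors), nrow(sub),
                dimnames = list(keep_donors, rownames(sub)))
    for (d in keep_donors) {
      cols <- which(donor == d)
      M[d, ] <- Matrix::rowMeans(logn[, cols, drop = FALSE])
      ncells[d, ct] <- length(cols)
    }
    expr[[ct]] <- M
  }
  out <- list(expr = expr, ncells = ncells,
              donors = lapply(expr, rownames))
  class(out) <- "PseudobulkTensor"
  out
}

#' @export
print.PseudobulkTensor <- function(x, ...) {
  cat(sprintf("PseudobulkTensor: %d cell type(s), %d gene(s)\n",
              length(x$expr),
              if (length(x$expr)) ncol(x$expr[[1]]) else 0L))
  for (ct in names(x$expr))
    cat(sprintf("  %s: %d donors\n", ct, nrow(x$expr[[ct]])))
  invisible(x)
}

#' Run the full QC + aggregation stage on a cohort's cell-level data
#'
#' Convenience wrapper: [filter_cells()], [filter_genes()],
#' [select_celltypes()] on post-QC counts, then [normalize_aggregate()].
#'
#' @param counts gene x cell counts; `cells` its metadata.
#' @param cells cell metadata data.frame.
#' @param mito_max,min_frac_cells,min_mean_count,exclude_lists,min_donors,min_cells
#'   thresholds forwarded to the individual filters.
#' @return a `PseudobulkTensor`.
#' @export
qc_aggregate <- function(counts, cells, mito_max = 0.20,
                         min_frac_cells = 0.10, min_mean_count = 0.1,
                         exclude_lists = character(0), min_donors = 40,
                         min_cells = 5) {
  cells <- filter_samples(cells)       # no-op without sample_id metadata
  cells_f <- filter_cells(cells, mito_max)
  counts_f <- counts[, cells_f$cell_id, drop = FALSE]
  genes <- filter_genes(counts_f, min_frac_cells, min_mean_count,
                        exclude_lists)
  tab <- table(cells_f$donor_id, cells_f$cell_type)
  nc <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  ctd <- select_celltypes(nc, min_donors, min_cells)
  normalize_aggregate(counts_f, cells_f, genes, ctd)
}
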