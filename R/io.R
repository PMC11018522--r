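#' Write a GenotypeMatrix as VCF
#'
#' Minimal VCF v4.2 with a GT FORMAT field; one sample column per donor.
#' Positions are written 1-based as stored.
#'
#' @param g a [genotype_matrix()].
#' @param path output path (`.gz` suffix triggers gzip).
#' @return invisibly, `path`.
#' @export
write_vcf_dosage <- function(g, path) {
  meta <- g$snp_meta
  ord <- order(meta$chrom, meta$pos)
  gt_code <- c("0/0", "0/1", "1/1")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g$dosage)),
                     collapse = "\t")), con)
  for (j in ord) {
    d <- g$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    writeLines(paste(c(meta$chrom[j], meta$pos[j], meta$id[j], meta$ref[j],
                       meta$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into a GenotypeMatrix
#'
#' Parses GT fields into alternate-allele dosages via `vcfR`. Multiallelic
#' records are dropped with a message; missing genotypes become `NA`.
#'
#' @param path VCF path (plain or gzip).
#' @return a [genotype_matrix()].
#' @export
read_vcf_dosage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    message(sum(multi), " multiallelic record(s) dropped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(s) {
    ifelse(is.na(s) | s %in% c("./.", ".|.", "."), NA_integer_,
           vapply(strsplit(s, "[/|]"), function(a)
             sum(as.integer(a)), integer(1)))
  }
  dosage <- t(apply(gt, 1, count_alt))
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = nrow(gt))
  dosage <- t(matrix(as.integer(dosage), nrow = nrow(gt),
                     dimnames = list(NULL, colnames(gt))))
  meta <- data.frame(id = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  blank <- is.na(meta$id) | meta$id == "."
  meta$id[blank] <- paste0(meta$chrom[blank], ":", meta$pos[blank])
  genotype_matrix(dosage, meta)
}

#' Write gene annotations as BED
#'
#' Converts the package's 1-based inclusive gene coordinates to the BED
#' 0-based half-open convention (`start - 1`, `end`).
#'
#' @param genes data.frame with `gene`, `chrom`, `start`, `end` and
#'   optionally `strand`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed_genes <- function(genes, path) {
  bed <- data.frame(chrom = genes$chrom, start = genes$start - 1,
                    end = genes$end, name = genes$gene, score = 0,
                    strand = genes$strand %||% "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene BED file
#'
#' BED is 0-based half-open; returned coordinates are 1-based inclusive
#' (`start + 1`, `end`).
#'
#' @param path BED path (plain or gzip).
#' @return data.frame with `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
read_bed_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("BED file needs at least 4 columns: ", path)
  data.frame(gene = bed[[4]], chrom = as.character(bed[[1]]),
             start = bed[[2]] + 1, end = bed[[3]],
             strand = if (ncol(bed) >= 6) bed[[6]] else "+",
             stringsAsFactors = FALSE)
}

#' Write single-cell counts as MatrixMarket
#'
#' @param counts gene x cell matrix (coerced to sparse).
#' @param mtx,features,barcodes output paths for the matrix, the gene ids
#'   and the cell ids.
#' @return invisibly, `mtx`.
#' @export
write_counts_mtx <- function(counts, mtx, features, barcodes) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(counts, mtx)
  writeLines(rownames(counts) %||% sprintf("gene%d", seq_len(nrow(counts))),
             features)
  writeLines(colnames(counts) %||% sprintf("cell%d", seq_len(ncol(counts))),
             barcodes)
  invisible(mtx)
}

#' Read MatrixMarket single-cell counts
#'
#' @param mtx,features,barcodes paths written by [write_counts_mtx()].
#' @return sparse gene x cell dgCMatrix with dimnames.
#' @export
read_counts_mtx <- function(mtx, features, barcodes) {
  for (p in c(mtx, features, barcodes))
    if (!file.exists(p)) stop("no such file: ", p)
  counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  rn <- readLines(features); cn <- readLines(barcodes)
  if (length(rn) != nrow(counts) || length(cn) != ncol(counts))
    stop("features/barcodes do not match matrix dimensions")
  dimnames(counts) <- list(rn, cn)
  counts
}

#' Read a whole synthetic fixture directory
#'
#' Counterpart of [export_fixture()]: reads genotypes, genes, donor
#' metadata, nCells, truth and (when present) counts + cell metadata.
#'
#' @param dir fixture directory.
#' @return list with the same components as the exporting cohort.
#' @export
read_fixture <- function(dir) {
  out <- list(
    genotypes = read_vcf_dosage(file.path(dir, "genotypes.vcf")),
    genes = read_bed_genes(file.path(dir, "genes.bed")),
    donors = utils::read.table(file.path(dir, "donors.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE),
    truth = utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE))
  nc <- utils::read.table(file.path(dir, "ncells.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  out$ncells <- as.matrix(nc[, -1, drop = FALSE])
  rownames(out$ncells) <- nc[[1]]
  if (file.exists(file.path(dir, "counts.mtx"))) {
    out$counts <- read_counts_mtx(file.path(dir, "counts.mtx"),
                                  file.path(dir, "features.tsv"),
                                  file.path(dir, "barcodes.tsv"))
    out$cells <- utils::read.table(file.path(dir, "cell_metadata.tsv"),
                                   header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
  }
  out
}

write_tsv <- function(df, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
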