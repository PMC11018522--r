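#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic-cohort generator.
#' The defaults describe a desk-scale cohort patterned after a mixed
#' disease/control lung cohort: biallelic genotypes in approximate
#' Hardy-Weinberg equilibrium with block LD and optional close relatives,
#' negative-binomial per-donor per-cell-type cell counts, pseudobulk
#' log2-expression with planted cis-eQTL effects shared globally, within a
#' lineage, or uniquely in one cell type, donor disease labels independent
#' of genotype, genotype-by-disease interaction effects, and residual noise
#' whose variance scales as `noise_sd^2 * (1 + 1/nCells)`.
#'
#' @param n_donors number of donors (>= 2).
#' @param frac_cases fraction of donors labelled `ILD` (rest `control`).
#' @param n_celltypes number of cell types; partitioned into up to 4
#'   contiguous lineages.
#' @param n_genes number of genes.
#' @param snps_per_gene cis-SNPs simulated per gene (one LD block per gene).
#' @param maf_range length-2 range the per-block allele frequency is drawn
#'   from.
#' @param ld_block_r2 target r-squared between adjacent SNPs within a block.
#' @param relatedness_pairs number of donor pairs sharing one haplotype
#'   genome-wide (parent-child-like; expected GRM entry about 0.5,
#'   kinship coefficient 0.25).
#' @param eqtl_fraction fraction of genes carrying a planted cis-eQTL.
#' @param effect_size_sd SD of the per-allele effect on log2 expression.
#' @param sharing_pattern_probs named probabilities over
#'   `c(global, lineage, unique)`; must sum to 1.
#' @param interaction_fraction fraction of genes carrying a
#'   genotype-by-disease interaction effect (must be <= `eqtl_fraction`;
#'   interaction genes are drawn from the eQTL genes).
#' @param interaction_effect_sd SD of the interaction effect.
#' @param de_fraction fraction of genes with a disease main effect on
#'   expression.
#' @param de_effect_sd SD of the disease main effect.
#' @param cells_per_donor_dist `c(mean, dispersion)` of the negative-binomial
#'   cell-count draw per (donor, cell type); counts are floored at 1.
#' @param noise_sd residual SD at infinite cell count.
#' @param seed integer seed; fully determines the simulated cohort.
#' @return validated list of class `SimConfig`.
#' @export
sim_config <- function(n_donors = 100, frac_cases = 0.5, n_celltypes = 5,
                       n_genes = 100, snps_per_gene = 10,
                       maf_range = c(0.1, 0.5), ld_block_r2 = 0.5,
                       relatedness_pairs = 0, eqtl_fraction = 0.3,
                       effect_size_sd = 1,
                       sharing_pattern_probs = c(global = 0.4, lineage = 0.3,
                                                 unique = 0.3),
                       interaction_fraction = 0, interaction_effect_sd = 1,
                       de_fraction = 0.1, de_effect_sd = 0.5,
                       cells_per_donor_dist = c(mean = 50, dispersion = 5),
                       noise_sd = 0.5, seed = 1L) {
  cfg <- list(n_donors = n_donors, frac_cases = frac_cases,
              n_celltypes = n_celltypes, n_genes = n_genes,
              snps_per_gene = snps_per_gene, maf_range = maf_range,
              ld_block_r2 = ld_block_r2,
              relatedness_pairs = relatedness_pairs,
              eqtl_fraction = eqtl_fraction, effect_size_sd = effect_size_sd,
              sharing_pattern_probs = sharing_pattern_probs,
              interaction_fraction = interaction_fraction,
              interaction_effect_sd = interaction_effect_sd,
              de_fraction = de_fraction, de_effect_sd = de_effect_sd,
              cells_per_donor_dist = cells_per_donor_dist,
              noise_sd = noise_sd, seed = as.integer(seed))
  if (!is_count(n_donors) || n_donors < 2) stop("n_donors must be >= 2")
  for (f in c("frac_cases", "ld_block_r2", "eqtl_fraction",
              "interaction_fraction", "de_fraction"))
    if (!is_fraction(cfg[[f]])) stop(f, " must be a fraction in [0,1]")
  if (length(maf_range) != 2L || any(maf_range < 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing pair within [0, 0.5]")
  p <- sharing_pattern_probs
  if (!all(c("global", "lineage", "unique") %in% names(p)) ||
      any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("sharing_pattern_probs must be a simplex over global/lineage/unique")
  if (interaction_fraction > eqtl_fraction)
    stop("interaction_fraction cannot exceed eqtl_fraction")
  if (2 * relatedness_pairs > n_donors)
    stop("too many relatedness_pairs for n_donors")
  class(cfg) <- "SimConfig"
  cfg
}

# fixed contiguous partition of cell types into up to 4 lineages
celltype_lineages <- function(n_celltypes) {
  k <- min(4L, n_celltypes)
  sort(rep_len(seq_len(k), n_celltypes))
}

#' Simulate biallelic genotypes with LD blocks and relatedness
#'
#' One LD block per gene: a shared block allele frequency is drawn from
#' `maf_range`; within the block each haplotype copies the previous SNP's
#' allele with probability `sqrt(ld_block_r2)` (so adjacent-SNP r-squared is
#' approximately `ld_block_r2`) and otherwise draws a fresh allele.
#' Dosages are sums of two haplotypes, which yields approximate
#' Hardy-Weinberg proportions. For each of `relatedness_pairs` donor pairs,
#' the second donor's first haplotype is replaced by the first donor's.
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()] together with the gene annotation used to
#'   lay out blocks, as a list with elements `genotypes` and `genes`
#'   (`gene`, `chrom`, `start`, `end`, `strand`, 1-based inclusive).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_seed(cfg$seed, simulate_genotypes_impl(cfg))
}

simulate_genotypes_impl <- function(cfg) {
  n <- cfg$n_donors; s <- cfg$snps_per_gene; G <- cfg$n_genes
  copy_p <- sqrt(cfg$ld_block_r2)
  # genes split over two autosomes in blocks, 3 Mb apart so cis windows
  # separate and positions stay sorted within chromosome
  chrom <- rep(c("1", "2"), each = ceiling(G / 2))[seq_len(G)]
  slot <- stats::ave(seq_len(G), chrom, FUN = seq_along)
  spacing <- min(3e6, floor(2e9 / (max(slot) + 1)))
  start <- as.integer(spacing * slot + 1)
  genes <- data.frame(gene = sprintf("gene%04d", seq_len(G)), chrom = chrom,
                      start = start, end = start + 9999, strand = "+",
                      stringsAsFactors = FALSE)
  hap <- matrix(0L, nrow = 2L * n, ncol = s * G)
  meta <- vector("list", G)
  for (gi in seq_len(G)) {
    p <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
    block <- matrix(0L, nrow = 2L * n, ncol = s)
    block[, 1] <- stats::rbinom(2L * n, 1L, p)
    if (s > 1) for (j in 2:s) {
      copy <- stats::runif(2L * n) < copy_p
      block[, j] <- ifelse(copy, block[, j - 1], stats::rbinom(2L * n, 1L, p))
    }
    cols <- (gi - 1L) * s + seq_len(s)
    hap[, cols] <- block
    halfspan <- min(5e5, floor(spacing / 3))
    pos <- as.integer(genes$start[gi] +
                        round(seq(-halfspan, halfspan, length.out = s)))
    meta[[gi]] <- data.frame(
      id = sprintf("%s_snp%02d", genes$gene[gi], seq_len(s)),
      chrom = genes$chrom[gi], pos = pos, ref = "A", alt = "G",
      stringsAsFactors = FALSE)
  }
  if (cfg$relatedness_pairs > 0)
    for (k in seq_len(cfg$relatedness_pairs))
      hap[2L * (2L * k), ] <- hap[2L * (2L * k - 1L) - 1L, ]
  dosage <- hap[seq(1, 2L * n, by = 2), , drop = FALSE] +
    hap[seq(2, 2L * n, by = 2), , drop = FALSE]
  rownames(dosage) <- sprintf("donor%03d", seq_len(n))
  list(genotypes = genotype_matrix(dosage, do.call(rbind, meta)),
       genes = genes)
}

#' Simulate a full synthetic cohort with known ground truth
#'
#' Generates genotypes ([simulate_genotypes()]), donor disease labels
#' (independent of genotype), per-(donor, cell type) cell counts, a latent
#' pseudobulk tensor under
#' `mean = baseline(gene, ct) + beta * g + delta * disease +
#'  beta_int * g * disease + eps`,
#' `Var(eps) = noise_sd^2 * (1 + 1/nCells)`, and, optionally, cell-level
#' Poisson counts whose library-size-normalized mean aggregation
#' approximates that latent pseudobulk. All planted effects are recorded in
#' a truth table.
#'
#' @param cfg a [sim_config()].
#' @param make_cells also draw cell-level counts (needed for the QC path and
#'   fixture export; the association stage only needs the pseudobulk).
#' @return list of class `SimCohort` with elements `genotypes`
#'   ([genotype_matrix()]), `genes`, `donors` (data.frame: `donor_id`,
#'   `disease_status`), `ncells` (donor x cell type), `pseudobulk` (list per
#'   cell type of donor x gene matrices), `truth` (data.frame: `gene`,
#'   `snp`, `cell_type`, `true_beta`, `is_interaction`,
#'   `true_beta_interaction`, `pattern_label`), and when `make_cells` is
#'   `TRUE`: `counts` (gene x cell sparse matrix) and `cells`
#'   (cell metadata data.frame).
#' @export
simulate_cohort <- function(cfg, make_cells = TRUE) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_seed(cfg$seed, simulate_cohort_impl(cfg, make_cells))
}

simulate_cohort_impl <- function(cfg, make_cells) {
  geno <- simulate_genotypes_impl(cfg)
  g <- geno$genotypes; genes <- geno$genes
  n <- cfg$n_donors; C <- cfg$n_celltypes; G <- cfg$n_genes
  celltypes <- sprintf("ct%02d", seq_len(C))
  lineage <- celltype_lineages(C)
  donors <- data.frame(donor_id = rownames(g$dosage),
                       disease_status = "control", stringsAsFactors = FALSE)
  n_cases <- round(cfg$frac_cases * n)
  donors$disease_status[sample.int(n, n_cases)] <- "ILD"
  d_ind <- as.numeric(donors$disease_status == "ILD")

  ncells <- matrix(pmax(1L, stats::rnbinom(n * C,
                                           mu = cfg$cells_per_donor_dist[[1]],
                                           size = cfg$cells_per_donor_dist[[2]])),
                   nrow = n, dimnames = list(donors$donor_id, celltypes))

  # planted effects
  n_eqtl <- round(cfg$eqtl_fraction * G)
  n_int <- round(cfg$interaction_fraction * G)
  eqtl_genes <- sort(sample.int(G, n_eqtl))
  int_genes <- if (n_int > 0) sort(sample(eqtl_genes, n_int)) else integer(0)
  beta <- numeric(G); beta_int <- numeric(G)
  esnp <- character(G); pattern <- character(G)
  affected <- matrix(FALSE, G, C)
  for (gi in eqtl_genes) {
    esnp[gi] <- sample(g$snp_meta$id[(gi - 1L) * cfg$snps_per_gene +
                                       seq_len(cfg$snps_per_gene)], 1)
    beta[gi] <- stats::rnorm(1, 0, cfg$effect_size_sd)
    pattern[gi] <- sample(names(cfg$sharing_pattern_probs), 1,
                          prob = cfg$sharing_pattern_probs)
    affected[gi, ] <- switch(pattern[gi],
      global = rep(TRUE, C),
      lineage = lineage == sample(unique(lineage), 1),
      unique = seq_len(C) == sample.int(C, 1))
  }
  beta_int[int_genes] <- stats::rnorm(length(int_genes), 0,
                                      cfg$interaction_effect_sd)
  n_de <- round(cfg$de_fraction * G)
  delta <- numeric(G)
  de_genes <- if (n_de > 0) sample.int(G, n_de) else integer(0)
  delta[de_genes] <- stats::rnorm(n_de, 0, cfg$de_effect_sd)

  base_gene <- stats::rnorm(G, 3, 1)
  base_ct <- matrix(stats::rnorm(G * C, 0, 0.5), G, C)

  pseudobulk <- vector("list", C); names(pseudobulk) <- celltypes
  latent <- vector("list", C); names(latent) <- celltypes
  for (ci in seq_len(C)) {
    M <- matrix(0, n, G, dimnames = list(donors$donor_id, genes$gene))
    for (gi in seq_len(G)) {
      mu <- base_gene[gi] + base_ct[gi, ci] + delta[gi] * d_ind
      if (affected[gi, ci]) {
        gd <- g$dosage[, esnp[gi]]
        mu <- mu + beta[gi] * gd + beta_int[gi] * gd * d_ind
      }
      M[, gi] <- mu
    }
    latent[[ci]] <- M
    eps <- matrix(stats::rnorm(n * G), n, G) *
      (cfg$noise_sd * sqrt(1 + 1 / ncells[, ci]))
    pseudobulk[[ci]] <- M + eps
  }

  truth <- do.call(rbind, lapply(eqtl_genes, function(gi) {
    cts <- which(affected[gi, ])
    data.frame(gene = genes$gene[gi], snp = esnp[gi],
               cell_type = celltypes[cts], true_beta = beta[gi],
               is_interaction = gi %in% int_genes,
               true_beta_interaction = beta_int[gi],
               pattern_label = pattern[gi], stringsAsFactors = FALSE)
  }))
  if (is.null(truth))
    truth <- data.frame(gene = character(0), snp = character(0),
                        cell_type = character(0), true_beta = numeric(0),
                        is_interaction = logical(0),
                        true_beta_interaction = numeric(0),
                        pattern_label = character(0))

  out <- list(genotypes = g, genes = genes, donors = donors,
              celltypes = celltypes, lineage = lineage, ncells = ncells,
              pseudobulk = pseudobulk, latent = latent, truth = truth,
              de_truth = data.frame(gene = genes$gene, delta = delta,
                                    stringsAsFactors = FALSE),
              config = cfg)
  if (make_cells) out <- c(out, draw_cells(cfg, out))
  class(out) <- "SimCohort"
  out
}

# Cell-level Poisson counts around exp-scale latent means with per-cell
# library factors; mean aggregation of normalized log2 counts approximates
# the latent pseudobulk (Jensen bias documented in the vignette).
draw_cells <- function(cfg, cohort) {
  n <- cfg$n_donors; C <- cfg$n_celltypes; G <- cfg$n_genes
  total_cells <- sum(cohort$ncells)
  cell_donor <- integer(total_cells); cell_ct <- integer(total_cells)
  at <- 0L
  for (ci in seq_len(C)) for (di in seq_len(n)) {
    k <- cohort$ncells[di, ci]
    cell_donor[at + seq_len(k)] <- di
    cell_ct[at + seq_len(k)] <- ci
    at <- at + k
  }
  libfac <- exp(stats::rnorm(total_cells, 0, 0.3))
  counts <- Matrix::Matrix(0, nrow = G, ncol = total_cells, sparse = TRUE)
  blocks <- split(seq_len(total_cells), cell_ct)
  for (ci in names(blocks)) {
    cells <- blocks[[ci]]
    lam0 <- pmax(2^cohort$latent[[as.integer(ci)]] - 1, 0)  # donor x gene
    lam <- t(lam0[cell_donor[cells], , drop = FALSE]) *
      rep(libfac[cells], each = G)
    counts[, cells] <- Matrix::Matrix(
      stats::rpois(length(lam), as.vector(lam)), nrow = G, sparse = TRUE)
  }
  cell_ids <- sprintf("cell%06d", seq_len(total_cells))
  dimnames(counts) <- list(cohort$genes$gene, cell_ids)
  cells <- data.frame(
    cell_id = cell_ids,
    donor_id = cohort$donors$donor_id[cell_donor],
    cell_type = cohort$celltypes[cell_ct],
    mito_fraction = stats::rbeta(total_cells, 2, 20),
    n_features = Matrix::colSums(counts > 0),
    disease_status = cohort$donors$disease_status[cell_donor],
    stringsAsFactors = FALSE)
  list(counts = counts, cells = cells)
}

#' @export
print.SimCohort <- function(x, ...) {
  cat(sprintf(paste0("SimCohort: %d donors (%d ILD), %d cell types, ",
                     "%d genes x %d SNPs; %d planted eQTL gene(s), ",
                     "%d with interaction effects\n"),
              nrow(x$donors), sum(x$donors$disease_status == "ILD"),
              length(x$celltypes), nrow(x$genes), ncol(x$genotypes$dosage),
              length(unique(x$truth$gene)),
              length(unique(x$truth$gene[x$truth$is_interaction]))))
  invisible(x)
}

#' Export a synthetic cohort as plain-file fixtures
#'
#' Writes the cohort in the pipeline's input formats: a VCF (v4.2, GT
#' field), MatrixMarket counts with features/barcodes files, cell metadata
#' TSV, gene BED (0-based half-open), donor metadata TSV, nCells TSV and
#' the truth table TSV. The files round-trip through the package readers.
#'
#' @param cohort a [simulate_cohort()] result (with `make_cells = TRUE` if
#'   cell-level files are wanted).
#' @param out_dir output directory, created if missing.
#' @return invisibly, the named vector of file paths written.
#' @export
export_fixture <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "SimCohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             bed = file.path(out_dir, "genes.bed"),
             donors = file.path(out_dir, "donors.tsv"),
             ncells = file.path(out_dir, "ncells.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_vcf_dosage(cohort$genotypes, paths[["vcf"]])
  write_bed_genes(cohort$genes, paths[["bed"]])
  utils::write.table(cohort$donors, paths[["donors"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nc <- data.frame(donor_id = rownames(cohort$ncells), cohort$ncells,
                   check.names = FALSE)
  utils::write.table(nc, paths[["ncells"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$counts)) {
    paths <- c(paths, mtx = file.path(out_dir, "counts.mtx"),
               features = file.path(out_dir, "features.tsv"),
               barcodes = file.path(out_dir, "barcodes.tsv"),
               cellmeta = file.path(out_dir, "cell_metadata.tsv"))
    write_counts_mtx(cohort$counts, paths[["mtx"]], paths[["features"]],
                     paths[["barcodes"]])
    utils::write.table(cohort$cells, paths[["cellmeta"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
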