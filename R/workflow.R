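#' Pipeline configuration
#'
#' Builds the resolved configuration of [run_pipeline()] from defaults that
#' equal the analysis' standard thresholds (mitochondrial cutoff 0.20,
#' gene filters 0.10 / 0.1, cell-type inclusion 40 donors / 5 cells,
#' MAF 0.05, HWE 1e-6, LD pruning 250/50/0.9, 20 expression PCs, LFSR
#' tiers 0.05 / 0.1, sharing factor 0.5, global buffer 2, pruning distance
#' 0.2 with k in \[2,5\], interaction group minimum 10, colocalization
#' minimum 100 shared SNPs and PP4 call 0.6, GWAS nominal threshold 1e-6).
#' Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed above (see
#'   `pipeline_defaults()`).
#' @return validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  defaults <- pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  stopifnot(cfg$lfsr_primary <= cfg$lfsr_secondary)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @rdname pipeline_config
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1L,
    sim = NULL,                 # a sim_config(); NULL = load from fixture_dir
    fixture_dir = NULL,
    use_cells = FALSE,          # run the cell-level QC path when cells exist
    mito_max = 0.20, min_frac_cells = 0.10, min_mean_count = 0.1,
    min_donors = 40, min_cells = 5,
    maf_min = 0.05, hwe_alpha = 1e-6,
    ld_window = 250, ld_step = 50, ld_r2 = 0.9,
    cis_window = 1e6,
    n_expr_pcs = 20, quantile_normalize = TRUE,
    strong_lfsr = 0.1, mash_n_pcs = 5, mash_ed_iters = 50,
    mash_fit_subset = 10000, mash_estimate_V = TRUE,
    lfsr_primary = 0.05, lfsr_secondary = 0.1,
    sharing_factor = 0.5, global_buffer = 2,
    prune_distance = 0.2, prune_k_range = c(2, 5),
    run_interaction = TRUE, interaction_min_donors = 10,
    interaction_maf_min = 0.05, case_label = "ILD",
    gwas_path = NULL, coloc_min_shared = 100, coloc_pp4_call = 0.6,
    coloc_W_eqtl = 0.15, coloc_W_gwas = 0.2,
    gwas_p_threshold = 1e-6)
}

write_manifest <- function(run_dir, stage, info) {
  path <- file.path(run_dir, "manifest.json")
  man <- if (file.exists(path)) jsonlite::read_json(path) else list()
  man[[stage]] <- info
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Run the end-to-end pipeline
#'
#' Executes simulate/load, QC + aggregation, variant QC + GRM + cis index,
#' cis-eQTL mapping, multivariate shrinkage, significance/classification,
#' the interaction analysis (with its own shrinkage and classification),
#' and — when GWAS summary statistics are supplied — colocalization.
#' Every stage writes plain TSV/JSON outputs and a manifest entry (row
#' counts, seed) under `run_dir`; a stage failure leaves earlier outputs
#' intact.
#'
#' @param config a [pipeline_config()].
#' @param run_dir output directory.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, run_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, TRUE)],
                   file.path(run_dir, "config_resolved.yaml"))
  res <- list()

  # --- inputs: simulate or load ------------------------------------------
  if (!is.null(config$sim)) {
    cohort <- simulate_cohort(config$sim, make_cells = config$use_cells)
  } else if (!is.null(config$fixture_dir)) {
    fx <- read_fixture(config$fixture_dir)
    if (is.null(fx$counts))
      stop("fixture at ", config$fixture_dir,
           " has no cell-level counts; cannot rebuild pseudobulk")
    cohort <- structure(
      c(fx, list(celltypes = colnames(fx$ncells))), class = "SimCohort")
    config$use_cells <- TRUE
  } else stop("config needs either `sim` or `fixture_dir`")
  res$cohort <- cohort
  write_manifest(run_dir, "input",
                 list(n_donors = nrow(cohort$donors),
                      n_snps = ncol(cohort$genotypes$dosage),
                      seed = config$seed))

  # --- QC + aggregation ---------------------------------------------------
  if (config$use_cells && !is.null(cohort$counts)) {
    pb <- qc_aggregate(cohort$counts, cohort$cells,
                       mito_max = config$mito_max,
                       min_frac_cells = config$min_frac_cells,
                       min_mean_count = config$min_mean_count,
                       min_donors = config$min_donors,
                       min_cells = config$min_cells)
  } else {
    pb <- as_pseudobulk(cohort)
    keep <- select_celltypes(pb$ncells, config$min_donors, config$min_cells)
    pb$expr <- lapply(stats::setNames(names(keep), names(keep)),
                      function(ct) pb$expr[[ct]][keep[[ct]], , drop = FALSE])
    pb$ncells <- pb$ncells[, names(keep), drop = FALSE]
  }
  res$pseudobulk <- pb
  for (ct in names(pb$expr))
    write_tsv(data.frame(donor_id = rownames(pb$expr[[ct]]),
                         pb$expr[[ct]], check.names = FALSE),
              file.path(run_dir, paste0("pseudobulk_", ct, ".tsv.gz")))
  write_manifest(run_dir, "qc", list(celltypes = names(pb$expr)))

  # --- variant QC, GRM, cis index ----------------------------------------
  g <- cohort$genotypes
  mask <- filter_variants(g, config$maf_min, config$hwe_alpha)
  g <- subset_snps(g, mask)
  kept <- ld_prune(g, config$ld_window, config$ld_step, config$ld_r2)
  g <- subset_snps(g, kept)
  K <- make_grm(g)
  cis <- cis_index(cohort$genes, g$snp_meta, config$cis_window)
  res$genotypes <- g; res$K <- K; res$cis <- cis
  write_tsv(data.frame(snp = g$snp_meta$id), file.path(run_dir, "snps_kept.tsv"))
  write_manifest(run_dir, "genotypes",
                 list(snps_after_filter = sum(mask),
                      snps_after_prune = length(kept)))

  # --- cis mapping + shrinkage + classification --------------------------
  spec <- assoc_spec(config$n_expr_pcs, config$quantile_normalize,
                     config$min_donors)
  assoc <- map_cis(pb, g, cis, spec, K = K)
  res$assoc <- assoc
  write_tsv(assoc, file.path(run_dir, "assoc_cis.tsv.gz"))
  write_manifest(run_dir, "map", list(n_tests = nrow(assoc)))

  panel <- effect_panel(assoc)
  fit <- mash_fit(panel, strong_lfsr = config$strong_lfsr,
                  n_pcs = config$mash_n_pcs,
                  ed_iters = config$mash_ed_iters,
                  fit_subset_size = config$mash_fit_subset,
                  estimate_V = config$mash_estimate_V, seed = config$seed)
  res$mash <- fit
  write_mash_fit(fit, file.path(run_dir, "mash"))

  sig <- call_significance(fit$lfsr, config$lfsr_primary,
                           config$lfsr_secondary)
  top <- select_top(fit$tests, fit$lfsr, sig, fit$post_mean)
  res$sig <- sig; res$top <- top
  if (nrow(top)) {
    rows <- unique(top$row)
    top$label <- classify_sharing(sig, config$global_buffer)[top$row]
    share <- pairwise_sharing(top, sig, fit$post_mean,
                              config$sharing_factor)
    pruned <- prune_representatives(top, fit$post_mean, sig, fit$lfsr,
                                    config$prune_distance,
                                    config$prune_k_range)
    res$sharing <- share; res$pruned <- pruned
    write_tsv(top[setdiff(names(top), "row")],
              file.path(run_dir, "top_eqtls.tsv"))
    write_tsv(as.data.frame(share), file.path(run_dir, "sharing.tsv"))
    write_tsv(pruned[setdiff(names(pruned), "row")],
              file.path(run_dir, "top_eqtls_pruned.tsv"))
  }
  write_manifest(run_dir, "classify",
                 list(n_top = nrow(top),
                      n_egenes = length(unique(top$gene))))

  # --- interaction analysis ----------------------------------------------
  if (config$run_interaction &&
      length(unique(cohort$donors$disease_status)) > 1) {
    int <- map_interaction(pb, g, cis, spec, cohort$donors, K = K,
                           case_label = config$case_label,
                           min_donors_per_group = config$interaction_min_donors,
                           min_cells = config$min_cells,
                           maf_per_group_min = config$interaction_maf_min)
    res$interaction <- int
    write_tsv(int, file.path(run_dir, "assoc_interaction.tsv.gz"))
    if (nrow(int)) {
      ipanel <- effect_panel(int, beta_col = "beta_int", se_col = "se_int")
      ifit <- try(mash_fit(ipanel, strong_lfsr = config$strong_lfsr,
                           n_pcs = config$mash_n_pcs,
                           ed_iters = config$mash_ed_iters,
                           fit_subset_size = config$mash_fit_subset,
                           estimate_V = config$mash_estimate_V,
                           seed = config$seed), silent = TRUE)
      if (!inherits(ifit, "try-error")) {
        isig <- call_significance(ifit$lfsr, config$lfsr_primary,
                                  config$lfsr_secondary)
        res$interaction_mash <- ifit
        res$interaction_sig <- isig
        write_mash_fit(ifit, file.path(run_dir, "mash_interaction"))
      }
    }
    write_manifest(run_dir, "interact",
                   list(n_tests = nrow(int),
                        n_significant = sum(res$interaction_sig %||% 0)))
  }

  # --- differential expression -------------------------------------------
  if (length(unique(cohort$donors$disease_status)) > 1) {
    de <- de_wilcox(pb, cohort$donors, case_label = config$case_label)
    res$de <- de
    write_tsv(de, file.path(run_dir, "de_wilcox.tsv.gz"))
    write_manifest(run_dir, "de",
                   list(n_de = sum(de$p_adj < 0.1)))
  }

  # --- colocalization + enrichment (need external GWAS summary stats) ----
  if (!is.null(config$gwas_path)) {
    gwas <- utils::read.table(config$gwas_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    res$coloc <- run_coloc_stage(res, gwas, config)
    if (!is.null(res$coloc))
      write_tsv(res$coloc, file.path(run_dir, "coloc.tsv"))
    write_manifest(run_dir, "coloc",
                   list(n_gene_celltype = nrow(res$coloc %||% data.frame())))
    res$enrich <- run_enrich_stage(res, gwas, cohort, config)
    if (!is.null(res$enrich))
      write_tsv(res$enrich, file.path(run_dir, "enrichment.tsv"))
  }

  invisible(res)
}

# Fisher enrichment of each top-eQTL class among GWAS risk variants,
# against a TSS-distance-matched null from the non-significant tests
run_enrich_stage <- function(res, gwas, cohort, config) {
  top <- res$top
  if (is.null(top) || !nrow(top) || is.null(top$label)) return(NULL)
  fit <- res$mash
  snp_pos <- res$genotypes$snp_meta$pos[
    match(fit$tests$snp, res$genotypes$snp_meta$id)]
  tss <- cohort$genes$start[match(fit$tests$gene, cohort$genes$gene)]
  dist <- abs(snp_pos - tss)
  risk <- gwas$snp[!is.na(gwas$p) & gwas$p < config$gwas_p_threshold]
  sig_any <- rowSums(res$sig) > 0
  pool <- which(!sig_any)
  out <- list()
  for (lab in unique(top$label)) {
    rows <- unique(top$row[top$label == lab])
    if (length(rows) < 3 || length(pool) <= length(rows)) next
    e <- try(enrich_gwas(fit$tests$snp[rows], dist[rows],
                         fit$tests$snp[pool], dist[pool], risk,
                         seed = config$seed), silent = TRUE)
    if (inherits(e, "try-error")) next
    out[[lab]] <- data.frame(class = lab, odds_ratio = e$odds_ratio,
                             p = e$p, null_size = e$null_size,
                             stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# colocalize every significant eGene x cell type against one GWAS
run_coloc_stage <- function(res, gwas, config) {
  fit <- res$mash; sig <- res$sig; g <- res$genotypes
  if (is.null(res$top) || !nrow(res$top)) return(NULL)
  out <- list()
  for (i in seq_len(nrow(res$top))) {
    gene <- res$top$gene[i]; ct <- res$top$cell_type[i]
    rows <- which(fit$tests$gene == gene)
    if (length(rows) < 2) next
    r <- match(ct, fit$celltypes)
    eq <- lfsr_significance_input(fit$post_mean[rows, r],
                                  fit$post_sd[rows, r],
                                  fit$lfsr[rows, r])
    snp_i <- match(fit$tests$snp[rows], g$snp_meta$id)
    eq <- cbind(eq, snp = fit$tests$snp[rows],
                chrom = g$snp_meta$chrom[snp_i], pos = g$snp_meta$pos[snp_i],
                effect_allele = g$snp_meta$alt[snp_i],
                other_allele = g$snp_meta$ref[snp_i],
                maf = g$maf[snp_i])
    cr <- colocalize_gene(eq, gwas, W1 = config$coloc_W_eqtl,
                          W2 = config$coloc_W_gwas,
                          min_shared = config$coloc_min_shared,
                          call_threshold = config$coloc_pp4_call)
    if (is.null(cr)) next
    out[[length(out) + 1L]] <- data.frame(
      gene = gene, cell_type = ct, t(cr$pp), n_shared_snps = cr$n_snps,
      colocalized = cr$colocalized, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
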