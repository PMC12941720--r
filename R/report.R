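#' Run the full family burden + methylation pipeline
#'
#' Executes the end-to-end analysis: load inputs, restrict the pedigree
#' to blood relatives, extract panel SNPs from the candidate-gene regions
#' (+/- `flank_bp_variants`), apply the variant QC filters, compute the
#' genetic burden table, call APOE epsilon diplotypes from
#' rs429358/rs7412, summarize gene-level methylation (+/-
#' `flank_bp_probes`) and assemble the within-family statistics
#' (family/generation summaries, carrier comparison, sibling discordance,
#' contribution percentages, ICC by generation, generational trend,
#' genotype-methylation correlations, clustering).
#'
#' @param ped_path PED/FAM pedigree file.
#' @param vcf_path VCF of genotypes (alternatively `genotypes_tsv` for a
#'   sample x SNP TSV).
#' @param panel_path variant panel TSV.
#' @param regions_path gene-region TSV (default: the built-in GRCh37
#'   candidate regions).
#' @param genotypes_tsv optional TSV genotype source (instead of VCF).
#' @param apoe_tsv optional side TSV of direct rs429358/rs7412 genotypes
#'   (columns `sample_id, rs429358_gt, rs7412_gt`), for arrays that do
#'   not type these SNPs. When the VCF also contains them the two sources
#'   must agree or an error is raised.
#' @param beta_path,manifest_path,detp_path optional methylation inputs.
#' @param probands ids whose blood relatives define the analysis set
#'   (default: all pedigree members, i.e. marry-ins already excluded).
#' @param flank_bp_variants flank for SNP extraction (default 50000).
#' @param flank_bp_probes flank for probe assignment (default 10000).
#' @param detp_threshold detection p-value cutoff (default 0.01).
#' @return object of class `family_report` (see [report_json()] for
#'   serialization). Burden-dependent blocks are absent (with a warning)
#'   when no SNP survives QC.
#' @export
run_pipeline <- function(ped_path, vcf_path = NULL, panel_path,
                         regions_path = NULL, genotypes_tsv = NULL,
                         apoe_tsv = NULL,
                         beta_path = NULL, manifest_path = NULL,
                         detp_path = NULL, probands = NULL,
                         flank_bp_variants = 50000,
                         flank_bp_probes = 10000,
                         detp_threshold = 0.01) {
  log_stage <- function(...) message("[famgbs] ", sprintf(...))
  ped <- read_pedigree(ped_path)
  log_stage("pedigree: %d individuals", nrow(ped))
  if (is.null(probands)) probands <- ped$id
  ped <- blood_relatives(ped, probands)
  log_stage("blood relatives: %d individuals", nrow(ped))
  gm <- if (!is.null(genotypes_tsv)) read_genotype_tsv(genotypes_tsv)
        else read_genotype_vcf(vcf_path)
  gm_samples <- intersect(ped$id, gm$samples)
  panel <- read_variant_panel(panel_path)
  regions <- if (is.null(regions_path)) gene_regions_ad()
             else read_gene_regions(regions_path)
  panel <- extract_region_variants(panel, regions, flank_bp_variants)
  log_stage("panel after region extraction: %d SNPs", nrow(panel))
  # rs429358/rs7412 side-channel, with agreement check against the VCF
  apoe_direct <- NULL
  if (!is.null(apoe_tsv)) {
    ap <- utils::read.delim(apoe_tsv, stringsAsFactors = FALSE)
    apoe_direct <- list(
      g429358 = stats::setNames(ap$rs429358_gt, ap$sample_id),
      g7412 = stats::setNames(ap$rs7412_gt, ap$sample_id))
    for (rs in c("rs429358", "rs7412")) {
      if (!(rs %in% gm$rsids)) next
      vec <- if (rs == "rs429358") apoe_direct$g429358 else apoe_direct$g7412
      for (s in intersect(names(vec), gm_samples)) {
        vcf_call <- parse_call(gm$calls[rs, s])
        tsv_call <- parse_call(vec[[s]])
        if (!is.null(vcf_call) && !is.null(tsv_call) &&
            canon_call(vcf_call) != canon_call(tsv_call))
          stop("conflicting ", rs, " genotype for ", s,
               " between VCF and direct-typing TSV")
      }
    }
  }
  mendel <- check_mendelian(ped, genotype_matrix(
    gm$calls[, gm_samples, drop = FALSE], gm$rsids, gm_samples,
    gm$multiallelic))
  log_stage("Mendelian violations: %d", nrow(mendel))
  qc <- apply_qc_filters(panel, gm, samples = gm_samples)
  log_stage("panel after QC: %d SNPs", nrow(qc$panel))

  report <- list(ped = ped, qc_report = qc$report, mendelian = mendel,
                 params = list(flank_bp_variants = flank_bp_variants,
                               flank_bp_probes = flank_bp_probes,
                               detp_threshold = detp_threshold))

  if (nrow(qc$panel) == 0) {
    warning("no SNP survived QC: burden block absent")
  } else {
    bt <- compute_gbs(gm, qc$panel, samples = gm_samples)
    report$burden <- bt
    report$family_summary <- group_summary(bt$total, "family")
    report$generation_summaries <- generation_summary(bt, ped)
    gen <- generations(ped)[bt$id]
    if (length(unique(gen)) >= 2) {
      report$icc <- icc_oneway(bt$total, gen)
      report$trend <- generation_trend(bt$total, as.integer(gen))
    }
    gmeans <- vapply(.bt_genes(bt), function(g) mean(bt[[g]]), numeric(1))
    report$gene_means <- gmeans
    report$contribution <- contribution_percentages(gmeans, mean(bt$total))
    # sibling discordance: most discordant full-sib pair
    sib_key <- paste(ped$father_id, ped$mother_id)
    sib_groups <- split(ped$id, sib_key)
    sib_groups <- sib_groups[!grepl("NA", names(sib_groups)) &
                               lengths(sib_groups) >= 2]
    best <- NULL
    for (sg in sib_groups) {
      sg <- intersect(sg, bt$id)
      if (length(sg) < 2) next
      for (i in seq_along(sg)) for (j in seq_along(sg)) if (i < j) {
        d <- relative_discordance(bt$total[match(sg[i], bt$id)],
                                  bt$total[match(sg[j], bt$id)])
        if (is.null(best) || d$delta > best$delta)
          best <- c(list(id_a = sg[i], id_b = sg[j]), d,
                    list(gene_deltas = gene_deltas(bt, sg[i], sg[j])))
      }
    }
    report$sibling_discordance <- best
  }

  # APOE diplotypes: direct TSV wins, else the VCF calls
  g429358 <- g7412 <- NULL
  if (!is.null(apoe_direct)) {
    g429358 <- apoe_direct$g429358[gm_samples]
    g7412 <- apoe_direct$g7412[gm_samples]
  } else if (all(c("rs429358", "rs7412") %in% gm$rsids)) {
    g429358 <- gm$calls["rs429358", gm_samples]
    g7412 <- gm$calls["rs7412", gm_samples]
  }
  if (!is.null(g429358) && !any(is.na(g429358)) && !any(is.na(g7412))) {
    names(g429358) <- names(g7412) <- gm_samples
    report$apoe <- apoe_table(g429358, g7412)
    if (!is.null(report$burden)) {
      flags <- stats::setNames(report$apoe$e4_carrier, report$apoe$sample_id)
      if (any(flags) && !all(flags))
        report$carrier_comparison <- carrier_comparison(report$burden, flags)
    }
  }

  if (!is.null(beta_path) && !is.null(manifest_path)) {
    betas <- read_beta_matrix(beta_path)
    manifest <- read_probe_manifest(manifest_path)
    detp <- if (!is.null(detp_path)) read_beta_matrix(detp_path) else NULL
    fp <- filter_probes(manifest, betas, detp, detp_threshold)
    log_stage("probes kept: %d of %d", length(fp$kept), nrow(manifest))
    report$probe_report <- fp$report
    kept_b <- betas[fp$kept, , drop = FALSE]
    kept_m <- manifest[match(fp$kept, manifest$probe_id), ]
    gms <- gene_methylation(kept_b, kept_m, regions, flank_bp_probes)
    report$gene_methylation <- gms
    if (!is.null(report$burden) && !is.null(gms$means))
      report$genotype_methylation <- genotype_methylation_cor(report$burden, gms)
    if (ncol(kept_b) >= 2 && nrow(kept_b) >= 1)
      report$methylation_cluster <- methylation_cluster(t(kept_b))
  }
  structure(report, class = "family_report")
}

#' @export
print.family_report <- function(x, ...) {
  cat("Family analysis report\n")
  cat(sprintf("  individuals: %d\n", nrow(x$ped)))
  if (!is.null(x$family_summary))
    cat("  GBS ", format(x$family_summary), "\n", sep = "")
  for (gs in x$generation_summaries)
    cat("  ", gs$label, ": ", format(gs), "\n", sep = "")
  if (!is.null(x$sibling_discordance)) {
    sd_ <- x$sibling_discordance
    cat(sprintf("  sibling discordance %s vs %s: delta %d (%.1f%%)\n",
                sd_$id_a, sd_$id_b, sd_$delta,
                round_half_up(sd_$relative_percent, 1)))
  }
  if (!is.null(x$carrier_comparison)) {
    cc <- x$carrier_comparison
    cat("  ", format(cc$carriers), " vs ", format(cc$noncarriers),
        sprintf("; diff %.1f\n", round_half_up(cc$mean_difference, 1)),
        sep = "")
  }
  if (!is.null(x$icc))
    cat(sprintf("  ICC(1) by generation: %.3f\n", x$icc$icc))
  if (!is.null(x$genotype_methylation)) {
    gmc <- x$genotype_methylation
    cat("  genotype-methylation r: ",
        paste(sprintf("%s %.3f", gmc$gene, gmc$r), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Serialize a family report to JSON
#'
#' All displayed numbers derive from the stored full-precision values;
#' the JSON stores full precision. Deterministic for identical inputs
#' (no timestamps).
#'
#' @param report a `family_report`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  strip <- function(x) {
    if (inherits(x, "group_summary")) return(unclass(x))
    if (inherits(x, "hclust")) return(NULL)
    if (is.list(x) && !is.data.frame(x)) {
      x <- lapply(x, strip)
      return(x[!vapply(x, is.null, logical(1))])
    }
    x
  }
  payload <- strip(unclass(report))
  payload$ped <- as.data.frame(payload$ped)
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' The published core-family worked example
#'
#' The seven-member, three-generation family with the printed
#' per-individual burden totals, generation indices, epsilon4-carrier and
#' affected flags, family-level per-gene mean risk-allele counts, the
#' sibling pair used for the discordance analysis, and the three printed
#' individual APOE methylation beta values. `J-011`'s total (41) is not
#' printed as a literal but is forced by the Generation II summary
#' (range 41-45, n = 2) with `J-025` = 45.
#'
#' @return list with elements `ids`, `gbs` (named totals), `generation`
#'   (named), `e4_carrier` (named logical), `affected` (named logical),
#'   `gene_means` (named), `sibling_pair`, `sibling_abs_deltas` (named),
#'   `apoe_beta` (named, three printed values).
#' @export
fixture_core_family <- function() {
  ids <- c("J-003", "J-005", "J-006", "J-011", "J-025", "J-012", "J-017")
  list(
    ids = ids,
    gbs = stats::setNames(c(39, 51, 54, 41, 45, 37, 61), ids),
    generation = stats::setNames(c(1L, 1L, 1L, 2L, 2L, 3L, 3L), ids),
    e4_carrier = stats::setNames(
      ids %in% c("J-003", "J-025", "J-017"), ids),
    affected = stats::setNames(ids == "J-003", ids),
    gene_means = c(CR1 = 18.1, PICALM = 9.4, ABCA7 = 6.1, CLU = 5.3,
                   BIN1 = 5.0, APOE = 2.9),
    sibling_pair = c("J-012", "J-017"),
    sibling_abs_deltas = c(CR1 = 16, PICALM = 16, BIN1 = 10, ABCA7 = 5,
                           CLU = 3, APOE = 1),
    apoe_beta = c("J-003" = 0.495, "J-005" = 0.520, "J-006" = 0.540)
  )
}
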