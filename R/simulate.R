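#' Configuration for the synthetic family generator
#'
#' Defaults encode the stated world the package is tested against: a
#' three-generation, seven-member blood-related core family; a 320-SNP
#' candidate-gene panel with the per-gene composition ABCA7 101, PICALM
#' 89, CR1 84, CLU 29, BIN1 8, APOE 9 (including rs429358/rs7412); LD
#' between adjacent panel SNPs; Mendelian transmission with
#' recombination; beta-valued methylation with optional genotype coupling
#' and an individual-specific (affected) shift.
#'
#' @param seed integer RNG seed; a fixed seed makes every emitted object
#'   and file byte-identical across runs.
#' @param snps_per_gene named integer vector, SNPs simulated per gene.
#' @param risk_freq_range length-2 numeric in `[0,1]`; each SNP's
#'   risk-allele frequency is drawn once, uniformly, from this range.
#'   The default U(0.01, 0.15) puts expected family totals in the tens
#'   (E[GBS] ~ 51 for 320 SNPs), the realistic scale for an unweighted
#'   candidate-gene count.
#' @param rho LD persistence in `[0,1]`: probability that the next SNP on
#'   a haplotype copies the previous SNP's risk/non-risk state instead of
#'   drawing fresh from its frequency. 0 = linkage equilibrium, 1 =
#'   perfectly correlated gene blocks.
#' @param recomb_p per-adjacent-SNP-interval crossover probability during
#'   meiosis (within a gene block; gene blocks assort independently).
#' @param missing_rate per-call missingness probability applied to the
#'   emitted genotypes.
#' @param mendel_errors number of deliberately inconsistent child
#'   genotypes to inject (and log) for checker validation.
#' @param meth list of methylation parameters: `baseline` (named per-gene
#'   beta, defaults around the mid-methylation range), `slope` (named
#'   per-gene logit-scale coupling per risk allele, default 0),
#'   `probes_per_gene`, `decoy_probes` (probes outside every region),
#'   `n_snp_flag`, `n_cross_flag`, `n_sex_probes` (planted mask
#'   failures), `noise_sd` (logit-scale probe noise), `affected_offset`
#'   (logit-scale shift applied to affected individuals, default -0.1,
#'   i.e. mild hypomethylation), `detp_fail_rate` (fraction of kept-type
#'   probes given a failing detection p-value in one sample).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       snps_per_gene = c(ABCA7 = 101L, PICALM = 89L,
                                         CR1 = 84L, CLU = 29L, BIN1 = 8L,
                                         APOE = 9L),
                       risk_freq_range = c(0.01, 0.15),
                       rho = 0.8,
                       recomb_p = 0.01,
                       missing_rate = 0,
                       mendel_errors = 0L,
                       meth = list()) {
  stopifnot(rho >= 0, rho <= 1, recomb_p >= 0, recomb_p <= 1,
            missing_rate >= 0, missing_rate <= 1, mendel_errors >= 0,
            all(risk_freq_range >= 0), all(risk_freq_range <= 1),
            all(snps_per_gene >= 0))
  meth_def <- list(
    baseline = c(APOE = 0.52, PICALM = 0.45, CLU = 0.50, CR1 = 0.55,
                 BIN1 = 0.40, ABCA7 = 0.48),
    slope = c(APOE = 0, PICALM = 0, CLU = 0, CR1 = 0, BIN1 = 0, ABCA7 = 0),
    probes_per_gene = 15L, decoy_probes = 10L,
    n_snp_flag = 0L, n_cross_flag = 0L, n_sex_probes = 0L,
    noise_sd = 0.05, affected_offset = -0.1, detp_fail_rate = 0
  )
  meth <- utils::modifyList(meth_def, meth)
  if (any(meth$baseline <= 0 | meth$baseline >= 1))
    stop("methylation baseline must be inside (0, 1)")
  structure(list(seed = as.integer(seed), snps_per_gene = snps_per_gene,
                 risk_freq_range = risk_freq_range, rho = rho,
                 recomb_p = recomb_p, missing_rate = missing_rate,
                 mendel_errors = as.integer(mendel_errors), meth = meth),
            class = "sim_config")
}

# Synthetic panel laid out inside the real candidate-gene regions so the
# region-extraction path runs unmodified. rs429358/rs7412 keep their real
# GRCh37 positions and alleles; risk allele C for both (the e4-defining
# haplotype states).
build_panel <- function(cfg, regions = gene_regions_ad()) {
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (g in names(cfg$snps_per_gene)) {
    n <- cfg$snps_per_gene[[g]]
    if (n == 0) next
    r <- regions[regions$gene == g, ]
    if (nrow(r) != 1) stop("no region for gene ", g)
    if (g == "APOE" && n >= 2) {
      n_other <- n - 2L
      pos <- if (n_other > 0)
        as.integer(round(seq(r$start, r$end - 200, length.out = n_other))) else integer()
      ref <- sample(bases, n_other, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
      risk_is_alt <- sample(c(TRUE, FALSE), n_other, replace = TRUE)
      rows[[g]] <- data.frame(
        rsid = c(sprintf("sim_%s_%03d", g, seq_len(n_other)),
                 "rs429358", "rs7412"),
        chrom = r$chrom,
        pos = c(pos, 45411941L, 45412079L),
        ref = c(ref, "T", "C"),
        alt = c(alt, "C", "T"),
        risk_allele = c(ifelse(risk_is_alt, alt, ref), "C", "C"),
        gene = g, source = c(rep("simulated", n_other), "lead", "lead"),
        stringsAsFactors = FALSE
      )
    } else {
      pos <- as.integer(round(seq(r$start, r$end, length.out = max(n, 2))))[seq_len(n)]
      ref <- sample(bases, n, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
      risk_is_alt <- sample(c(TRUE, FALSE), n, replace = TRUE)
      rows[[g]] <- data.frame(
        rsid = sprintf("sim_%s_%03d", g, seq_len(n)),
        chrom = r$chrom, pos = pos, ref = ref, alt = alt,
        risk_allele = ifelse(risk_is_alt, alt, ref),
        gene = g, source = "simulated", stringsAsFactors = FALSE
      )
    }
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  panel
}

# One haplotype as a 0/1 risk-state vector. LD comes from a latent-uniform
# copy chain within each gene block: with probability rho the latent
# uniform is copied from the previous SNP, else drawn fresh, and the state
# is 1 iff the latent value falls below the SNP's risk frequency. The
# latent marginal stays exactly U(0,1), so every SNP's state is exactly
# Bernoulli(freq_j) whatever rho, and for equal frequencies the
# adjacent-state correlation equals rho. The chain resets at gene
# boundaries (blocks are in linkage equilibrium with each other).
.draw_haplotype <- function(freq, gene, rho) {
  L <- length(freq)
  u <- numeric(L)
  for (j in seq_len(L)) {
    if (j > 1 && gene[j] == gene[j - 1] && stats::runif(1) < rho)
      u[j] <- u[j - 1]
    else
      u[j] <- stats::runif(1)
  }
  as.integer(u < freq)
}

#' Simulate founder haplotypes with LD
#'
#' Draws per-SNP risk-allele frequencies once (uniform over
#' `cfg$risk_freq_range`), then generates each haplotype left-to-right
#' within gene blocks by a latent-uniform copy chain: with probability
#' `rho` the next SNP reuses the previous SNP's latent uniform, otherwise
#' a fresh one, and carries the risk allele iff the latent value is below
#' the SNP's frequency. Marginals are exactly Bernoulli(freq) at every
#' `rho`; for equal frequencies the adjacent-state correlation is `rho`.
#'
#' @param cfg a [sim_config()]; `cfg$seed` seeds the draw.
#' @param n_founders number of founders (each gets a haplotype pair).
#' @param panel optional pre-built panel (a fresh one is built otherwise).
#' @return list with `panel`, `freq` (per-SNP risk-allele frequency) and
#'   `haplotypes` (list of `n_founders` 2 x L 0/1 matrices).
#' @export
simulate_founder_haplotypes <- function(cfg, n_founders = 3, panel = NULL) {
  set.seed(cfg$seed)
  if (is.null(panel)) panel <- build_panel(cfg)
  freq <- stats::runif(nrow(panel), cfg$risk_freq_range[1],
                       cfg$risk_freq_range[2])
  haps <- lapply(seq_len(n_founders), function(i)
    rbind(.draw_haplotype(freq, panel$gene, cfg$rho),
          .draw_haplotype(freq, panel$gene, cfg$rho)))
  list(panel = panel, freq = freq, haplotypes = haps)
}

#' Meiosis: one gamete from a parental haplotype pair
#'
#' Starts on a uniformly chosen parental haplotype and switches source at
#' each adjacent-SNP interval with probability `recomb_p`; the gamete
#' copies the currently active haplotype at every position. When a
#' `gene` block vector is supplied, the active haplotype is re-drawn
#' uniformly at each block boundary (blocks assort independently, as for
#' genes on different chromosomes).
#'
#' @param hap_pair 2 x L matrix (two parental haplotypes).
#' @param recomb_p per-interval crossover probability.
#' @param gene optional length-L block labels.
#' @return length-L gamete vector.
#' @export
meiosis <- function(hap_pair, recomb_p, gene = NULL) {
  if (!is.matrix(hap_pair) || nrow(hap_pair) != 2)
    stop("hap_pair must be a 2 x L matrix")
  L <- ncol(hap_pair)
  if (!is.null(gene) && length(gene) != L)
    stop("length mismatch between haplotypes and gene blocks")
  active <- sample.int(2L, 1L)
  gamete <- vector(mode = mode(hap_pair[1, ]), length = L)
  for (j in seq_len(L)) {
    if (j > 1) {
      if (!is.null(gene) && gene[j] != gene[j - 1])
        active <- sample.int(2L, 1L)
      else if (stats::runif(1) < recomb_p)
        active <- 3L - active
    }
    gamete[j] <- hap_pair[active, j]
  }
  gamete
}

# risk-state haplotype pair -> "X/Y" call strings against the panel alleles
.states_to_calls <- function(h1, h2, panel) {
  other <- ifelse(panel$risk_allele == panel$ref, panel$alt, panel$ref)
  a1 <- ifelse(h1 == 1, panel$risk_allele, other)
  a2 <- ifelse(h2 == 1, panel$risk_allele, other)
  paste(a1, a2, sep = "/")
}

#' Simulate a complete core family
#'
#' Builds the default seven-member, three-generation blood-related
#' topology: founders `F1` (affected), `F2` x `F3` a founder couple;
#' `P1` their child; `P2` the child of `F1` and an unobserved marry-in
#' (partial parentage); siblings `C1`, `C2` children of `P1` x `P2`.
#' Founder haplotypes are drawn with LD, non-founders by meiosis from
#' both parents. Optional missingness and Mendelian-error injection are
#' applied last and logged in the truth record.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_family`: `ped` ([pedigree]), `gm`
#'   ([genotype_matrix]), `panel`, `regions`, `freq`, and `truth` (per-
#'   individual haplotype state matrices, true per-gene dosages computed
#'   from haplotypes, injected error and missingness logs).
#' @export
simulate_family <- function(cfg) {
  fh <- simulate_founder_haplotypes(cfg, n_founders = 4)  # F1 F2 F3 + marry-in
  panel <- fh$panel
  hp <- list(F1 = fh$haplotypes[[1]], F2 = fh$haplotypes[[2]],
             F3 = fh$haplotypes[[3]], EXT = fh$haplotypes[[4]])
  hp$P1 <- rbind(meiosis(hp$F2, cfg$recomb_p, panel$gene),
                 meiosis(hp$F3, cfg$recomb_p, panel$gene))
  hp$P2 <- rbind(meiosis(hp$F1, cfg$recomb_p, panel$gene),
                 meiosis(hp$EXT, cfg$recomb_p, panel$gene))
  hp$C1 <- rbind(meiosis(hp$P1, cfg$recomb_p, panel$gene),
                 meiosis(hp$P2, cfg$recomb_p, panel$gene))
  hp$C2 <- rbind(meiosis(hp$P1, cfg$recomb_p, panel$gene),
                 meiosis(hp$P2, cfg$recomb_p, panel$gene))
  members <- c("F1", "F2", "F3", "P1", "P2", "C1", "C2")
  ped <- pedigree(
    id = members,
    father_id = c(NA, NA, NA, "F2", NA, "P1", "P1"),
    mother_id = c(NA, NA, NA, "F3", "F1", "P2", "P2"),
    sex = c("female", "male", "female", "male", "female", "male", "male"),
    affected = c(TRUE, rep(FALSE, 6)),
    family_id = "SIMFAM"
  )
  calls <- vapply(members, function(m)
    .states_to_calls(hp[[m]][1, ], hp[[m]][2, ], panel),
    character(nrow(panel)))
  gm <- genotype_matrix(calls, panel$rsid, members)
  # truth dosages from haplotype states (independent of the call strings)
  genes <- unique(panel$gene)
  true_dosage <- t(vapply(members, function(m) {
    d <- hp[[m]][1, ] + hp[[m]][2, ]
    vapply(genes, function(g) sum(d[panel$gene == g]), numeric(1))
  }, numeric(length(genes))))
  truth <- list(haplotypes = hp[members], true_gene_dosage = true_dosage,
                injected_errors = NULL, missing_calls = NULL)
  # Mendelian-error injection: pick child SNPs where an infeasible
  # genotype exists, replace the call, log it
  if (cfg$mendel_errors > 0) {
    inj <- list()
    # leaf children only: corrupting P1 (also a parent) could cascade into
    # violations at C1/C2 and break the exactly-k guarantee
    kids <- c("C1", "C2")
    candidates <- expand.grid(kid = kids, snp = seq_len(nrow(panel)),
                              stringsAsFactors = FALSE)
    candidates <- candidates[sample.int(nrow(candidates)), ]
    for (ci in seq_len(nrow(candidates))) {
      if (length(inj) >= cfg$mendel_errors) break
      kid <- candidates$kid[ci]; j <- candidates$snp[ci]
      fa <- ped$father_id[ped$id == kid]; mo <- ped$mother_id[ped$id == kid]
      fg <- parse_call(gm$calls[j, fa]); mg <- parse_call(gm$calls[j, mo])
      als <- c(panel$ref[j], panel$alt[j])
      gts <- list(c(als[1], als[1]), c(als[1], als[2]), c(als[2], als[2]))
      bad <- Filter(function(g) !mendel_consistent(g, fg, mg), gts)
      if (length(bad) == 0) next  # e.g. het x het: everything feasible
      pick <- bad[[sample.int(length(bad), 1)]]
      gm$calls[j, kid] <- paste(pick, collapse = "/")
      inj[[length(inj) + 1L]] <- data.frame(individual_id = kid,
                                            rsid = panel$rsid[j],
                                            stringsAsFactors = FALSE)
    }
    truth$injected_errors <- if (length(inj)) do.call(rbind, inj) else NULL
  }
  if (cfg$missing_rate > 0) {
    protected <- if (!is.null(truth$injected_errors))
      paste(match(truth$injected_errors$rsid, panel$rsid),
            truth$injected_errors$individual_id) else character()
    drop <- which(matrix(stats::runif(length(gm$calls)) < cfg$missing_rate,
                         nrow = nrow(gm$calls)), arr.ind = TRUE)
    if (nrow(drop)) {
      keep <- !(paste(drop[, 1], gm$samples[drop[, 2]]) %in% protected)
      drop <- drop[keep, , drop = FALSE]
      gm$calls[drop] <- NA_character_
      truth$missing_calls <- data.frame(
        individual_id = gm$samples[drop[, 2]],
        rsid = panel$rsid[drop[, 1]], stringsAsFactors = FALSE)
    }
  }
  structure(list(ped = ped, gm = gm, panel = panel,
                 regions = gene_regions_ad(), freq = fh$freq,
                 truth = truth, config = cfg),
            class = "sim_family")
}

#' @export
print.sim_family <- function(x, ...) {
  cat(sprintf("Simulated family (seed %d): %d members, %d panel SNPs\n",
              x$config$seed, nrow(x$ped), nrow(x$panel)))
  invisible(x)
}

#' Simulate beta-valued methylation coupled to genetic burden
#'
#' For gene *g*, individual *i* and probe *k*:
#' `beta = invlogit(logit(baseline_g) + slope_g * count_ig + offset_i + e)`,
#' `e ~ N(0, noise_sd)` on the logit scale (which keeps beta inside
#' (0,1) by construction). Affected individuals receive
#' `offset_i = affected_offset` (default mild hypomethylation), all
#' others 0. Probes are laid inside each gene region (so the +/-10 kb
#' assignment picks them up); decoy probes outside every region plus
#' probes with planted mask flags / failing detection p-values exercise
#' the filtering rules.
#'
#' @param cfg a [sim_config()] (uses a seed derived from `cfg$seed`, so a
#'   fixed config reproduces the matrices exactly).
#' @param bt `burden_table` of the simulated individuals.
#' @param ped the [pedigree] (source of the affected flags).
#' @param regions gene-region table.
#' @return list: `betas` (probe x sample matrix), `manifest`, `detp`
#'   (probe x sample detection p-values), `truth` (planted flags and
#'   expected filter outcome).
#' @export
simulate_methylation <- function(cfg, bt, ped, regions = gene_regions_ad()) {
  set.seed(cfg$seed + 1000003L)
  mp <- cfg$meth
  samples <- bt$id
  offset <- ifelse(ped$affected[match(samples, ped$id)],
                   mp$affected_offset, 0)
  rows <- list(); beta_rows <- list()
  for (g in .bt_genes(bt)) {
    r <- regions[regions$gene == g, ]
    if (nrow(r) != 1) next
    pos <- as.integer(round(seq(r$start + 50, r$end - 50,
                                length.out = mp$probes_per_gene)))
    ids <- sprintf("cg_%s_%03d", g, seq_len(mp$probes_per_gene))
    rows[[g]] <- data.frame(probe_id = ids, chrom = r$chrom, pos = pos,
                            snp_overlap = FALSE, cross_reactive = FALSE,
                            gene_truth = g, stringsAsFactors = FALSE)
    mu <- logit(mp$baseline[[g]]) + mp$slope[[g]] * bt[[g]] + offset
    beta_rows[[g]] <- t(vapply(seq_len(mp$probes_per_gene), function(k)
      invlogit(stats::rnorm(length(samples), mu, mp$noise_sd)),
      numeric(length(samples))))
  }
  manifest <- do.call(rbind, rows)
  betas <- do.call(rbind, beta_rows)
  # decoys: autosomal probes outside every region, then planted failures
  extra_n <- mp$decoy_probes + mp$n_snp_flag + mp$n_cross_flag + mp$n_sex_probes
  if (extra_n > 0) {
    ex <- data.frame(
      probe_id = sprintf("cg_decoy_%03d", seq_len(extra_n)),
      chrom = c(rep("7", mp$decoy_probes + mp$n_snp_flag + mp$n_cross_flag),
                rep("X", mp$n_sex_probes)),
      pos = as.integer(1e6 + seq_len(extra_n) * 1000),
      snp_overlap = rep(c(FALSE, TRUE, FALSE, FALSE),
                        c(mp$decoy_probes, mp$n_snp_flag, mp$n_cross_flag,
                          mp$n_sex_probes)),
      cross_reactive = rep(c(FALSE, FALSE, TRUE, FALSE),
                           c(mp$decoy_probes, mp$n_snp_flag, mp$n_cross_flag,
                             mp$n_sex_probes)),
      gene_truth = NA_character_, stringsAsFactors = FALSE)
    manifest <- rbind(manifest, ex)
    betas <- rbind(betas, matrix(
      invlogit(stats::rnorm(extra_n * length(samples), 0, mp$noise_sd)),
      nrow = extra_n))
  }
  rownames(betas) <- manifest$probe_id
  colnames(betas) <- samples
  detp <- matrix(stats::runif(length(betas), 0, 0.005), nrow = nrow(betas),
                 dimnames = dimnames(betas))
  det_fail <- character()
  if (mp$detp_fail_rate > 0) {
    fail <- stats::runif(nrow(detp)) < mp$detp_fail_rate
    for (i in which(fail))
      detp[i, sample.int(ncol(detp), 1)] <- stats::runif(1, 0.011, 0.05)
    det_fail <- manifest$probe_id[fail]
  }
  truth <- list(detp_failures = det_fail,
                snp_flagged = manifest$probe_id[manifest$snp_overlap],
                cross_flagged = manifest$probe_id[manifest$cross_reactive],
                sex_probes = manifest$probe_id[norm_chrom(manifest$chrom)
                                               %in% c("X", "Y")])
  manifest$gene_truth <- NULL
  list(betas = betas, manifest = manifest, detp = detp, truth = truth)
}

#' Write a genotype matrix as a minimal VCFv4.2 file
#'
#' Plain-text emitter (CHROM/POS/ID/REF/ALT from the panel, GT-only
#' FORMAT); round-trips through [read_genotype_vcf()].
#'
#' @param gm a [genotype_matrix].
#' @param panel panel rows matching `gm$rsids` (source of coordinates and
#'   alleles).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(gm, panel, path) {
  stopifnot(all(gm$rsids %in% panel$rsid))
  panel <- panel[match(gm$rsids, panel$rsid), ]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=famgbs-simulator",
           sprintf("##contig=<ID=%s>", unique(panel$chrom)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  gt_code <- function(call, ref, alt) {
    al <- parse_call(call)
    if (is.null(al)) return("./.")
    idx <- match(al, c(ref, alt)) - 1L
    if (any(is.na(idx))) stop("call allele not in {ref, alt}: ", call)
    paste(sort(idx), collapse = "/")
  }
  body <- vapply(seq_along(gm$rsids), function(i) {
    gts <- vapply(gm$samples, function(s)
      gt_code(gm$calls[i, s], panel$ref[i], panel$alt[i]), character(1))
    paste(c(panel$chrom[i], panel$pos[i], panel$rsid[i], panel$ref[i],
            panel$alt[i], ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  # VCF convention: records ordered by position within chromosome
  ord <- order(panel$chrom, panel$pos)
  writeLines(c(hdr, body[ord]), path)
  invisible(path)
}

#' Write all files for a simulated family
#'
#' Emits the PED pedigree, VCF genotypes, panel and regions TSVs, and —
#' when a methylation simulation is supplied — beta/manifest/detection-p
#' TSVs plus a truth JSON. Every file round-trips through the package's
#' corresponding loader.
#'
#' @param sim result of [simulate_family()].
#' @param dir output directory (created if needed).
#' @param meth optional result of [simulate_methylation()].
#' @return named character vector of file paths, invisibly.
#' @export
write_family_data <- function(sim, dir, meth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- c(ped = file.path(dir, "family.ped"),
         vcf = file.path(dir, "genotypes.vcf"),
         panel = file.path(dir, "panel.tsv"),
         regions = file.path(dir, "regions.tsv"))
  write_pedigree(sim$ped, p["ped"])
  write_genotype_vcf(sim$gm, sim$panel, p["vcf"])
  utils::write.table(sim$panel, p["panel"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$regions, p["regions"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(meth)) {
    p <- c(p, betas = file.path(dir, "betas.tsv"),
           manifest = file.path(dir, "manifest.tsv"),
           detp = file.path(dir, "detp.tsv"),
           truth = file.path(dir, "truth.json"))
    wmat <- function(m, path) {
      df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                       stringsAsFactors = FALSE)
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    wmat(meth$betas, p["betas"])
    wmat(meth$detp, p["detp"])
    utils::write.table(meth$manifest, p["manifest"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(seed = sim$config$seed,
           true_gene_dosage = as.data.frame(sim$truth$true_gene_dosage),
           injected_errors = sim$truth$injected_errors,
           meth_truth = meth$truth),
      p["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(p)
}
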