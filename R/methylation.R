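#' Beta value from methylated/unmethylated intensities
#'
#' `beta = M / (M + U)`: the methylation fraction at a CpG, 0 = fully
#' unmethylated, 1 = fully methylated. An offset in the denominator
#' (`beta = M / (M + U + offset)`) is supported for numerical
#' stabilization but defaults to 0, the plain intensity ratio.
#'
#' @param meth,unmeth non-negative intensity vectors.
#' @param offset non-negative stabilizing constant (default 0).
#' @return beta values in `[0, 1]`.
#' @export
compute_beta <- function(meth, unmeth, offset = 0) {
  if (any(meth < 0) || any(unmeth < 0)) stop("intensities must be >= 0")
  denom <- meth + unmeth + offset
  if (any(denom == 0)) stop("both intensities zero: beta undefined")
  meth / denom
}

#' Read a probe x sample matrix TSV (beta values or detection p-values)
#'
#' First column `probe_id`, remaining columns one per sample.
#'
#' @param path TSV file.
#' @return numeric matrix with probe rownames.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a CpG probe manifest TSV
#'
#' Columns `probe_id, chrom, pos` and optional logical flag columns
#' `snp_overlap`, `cross_reactive` (absent flags default to `FALSE`).
#'
#' @param path TSV file.
#' @return data.frame manifest; probe ids validated unique.
#' @export
read_probe_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in manifest")
  for (fl in c("snp_overlap", "cross_reactive"))
    if (!fl %in% names(df)) df[[fl]] <- FALSE else df[[fl]] <- as.logical(df[[fl]])
  df
}

#' Filter CpG probes before gene-level summarization
#'
#' Drops probes failing any of, in order (removals attributed to the
#' first matching rule):
#' 1. detection p-value above `detp_threshold` in *any* sample;
#' 2. overlap with a known SNP (manifest flag, optionally augmented by a
#'    user-supplied mask list of probe ids);
#' 3. cross-reactive (flag or mask list);
#' 4. located on a sex chromosome (X/Y).
#'
#' @param manifest probe manifest data.frame (see [read_probe_manifest()]).
#' @param betas beta matrix (probes x samples); rows must match the
#'   manifest's probes.
#' @param detp optional detection p-value matrix aligned with `betas`;
#'   required when the detection rule is to be applied.
#' @param detp_threshold detection p-value cutoff (default 0.01).
#' @param snp_mask,cross_mask optional character vectors of probe ids to
#'   flag in addition to manifest flags.
#' @return list `kept` (character probe ids, manifest order), `report`
#'   (per-rule removal counts plus kept count).
#' @export
filter_probes <- function(manifest, betas, detp = NULL, detp_threshold = 0.01,
                          snp_mask = NULL, cross_mask = NULL) {
  if (!setequal(manifest$probe_id, rownames(betas)) ||
      nrow(manifest) != nrow(betas))
    stop("manifest and beta matrix probes do not match")
  p <- manifest$probe_id
  det_fail <- if (is.null(detp)) rep(FALSE, length(p)) else {
    if (!setequal(rownames(detp), p)) stop("detection-p matrix probes do not match")
    apply(detp[p, , drop = FALSE] > detp_threshold, 1, any)
  }
  snp_fail <- manifest$snp_overlap | p %in% snp_mask
  cross_fail <- manifest$cross_reactive | p %in% cross_mask
  sex_fail <- norm_chrom(manifest$chrom) %in% c("X", "Y", "23", "24")
  rule <- rep(NA_character_, length(p))
  rule[sex_fail] <- "sex_chromosome"
  rule[cross_fail] <- "cross_reactive"
  rule[snp_fail] <- "snp_overlap"
  rule[det_fail] <- "detection_p"   # first rule wins: assigned last
  report <- data.frame(
    rule = c("detection_p", "snp_overlap", "cross_reactive",
             "sex_chromosome", "kept"),
    n = c(sum(rule == "detection_p", na.rm = TRUE),
          sum(rule == "snp_overlap", na.rm = TRUE),
          sum(rule == "cross_reactive", na.rm = TRUE),
          sum(rule == "sex_chromosome", na.rm = TRUE),
          sum(is.na(rule))),
    stringsAsFactors = FALSE
  )
  list(kept = p[is.na(rule)], report = report)
}

#' Gene-level methylation summaries
#'
#' For each gene region extended by `flank_bp` (gene body plus +/-10 kb
#' regulatory flank by default), averages the beta values of the CpG
#' probes falling inside the flanked interval, per individual. Genes with
#' no probe in range are absent from the result rather than reported as 0.
#'
#' @param betas filtered beta matrix (probes x samples).
#' @param manifest probe manifest covering the probes in `betas`.
#' @param regions gene-region table.
#' @param flank_bp non-negative flank (default 10000).
#' @return list: `means` (data.frame gene x sample of mean beta),
#'   `probes_per_gene` (named integer vector).
#' @export
gene_methylation <- function(betas, manifest, regions, flank_bp = 10000) {
  stopifnot(flank_bp >= 0)
  regions <- validate_regions(regions)
  rchrom <- norm_chrom(regions$chrom)
  rstart <- regions$start - flank_bp
  rend <- regions$end + flank_bp
  for (ch in unique(rchrom)) {
    i <- which(rchrom == ch)
    if (length(i) < 2) next
    o <- order(rstart[i]); s <- rstart[i][o]; e <- rend[i][o]
    if (any(s[-1] <= e[-length(e)]))
      stop("overlapping flanked regions on chromosome ", ch,
           ": ambiguous probe assignment")
  }
  manifest <- manifest[match(rownames(betas), manifest$probe_id), ]
  pchrom <- norm_chrom(manifest$chrom)
  means <- list(); np <- integer()
  for (r in seq_len(nrow(regions))) {
    inr <- pchrom == rchrom[r] & manifest$pos >= rstart[r] &
      manifest$pos <= rend[r]
    if (!any(inr)) next
    g <- regions$gene[r]
    means[[g]] <- colMeans(betas[inr, , drop = FALSE])
    np[g] <- sum(inr)
  }
  if (length(means) == 0)
    return(list(means = NULL, probes_per_gene = np))
  list(means = as.data.frame(do.call(rbind, means)), probes_per_gene = np)
}

#' Pearson product-moment correlation with validity checks
#'
#' Thin wrapper over [stats::cor()] enforcing the preconditions under
#' which r is interpretable here: equal lengths, n >= 3, nonzero variance
#' in both vectors.
#'
#' @param x,y numeric vectors.
#' @return r in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Per-gene correlation of risk-allele count with mean methylation
#'
#' For each gene present in both the burden table and the gene-level
#' methylation summary, the Pearson correlation across shared individuals
#' between the gene's risk-allele count and its mean beta. Genes where
#' either vector is constant are flagged undefined (`NA` with
#' `defined = FALSE`) rather than erroring — a gene can legitimately be
#' monomorphic after QC.
#'
#' @param bt a `burden_table`.
#' @param gms result of [gene_methylation()].
#' @return data.frame `gene, r, n, defined`; `r` at full precision
#'   (display convention: 3 decimals).
#' @export
genotype_methylation_cor <- function(bt, gms) {
  if (is.null(gms$means)) stop("no gene-level methylation available")
  shared <- intersect(bt$id, colnames(gms$means))
  if (length(shared) < 3) stop("need >= 3 shared individuals")
  genes <- intersect(.bt_genes(bt), rownames(gms$means))
  rows <- lapply(genes, function(g) {
    cnt <- bt[[g]][match(shared, bt$id)]
    beta <- as.numeric(gms$means[g, shared])
    defined <- stats::sd(cnt) > 0 && stats::sd(beta) > 0
    data.frame(gene = g,
               r = if (defined) stats::cor(cnt, beta) else NA_real_,
               n = length(shared), defined = defined,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hierarchical clustering of methylation profiles
#'
#' Agglomerative clustering with Euclidean distance and complete linkage
#' (via [stats::hclust()]), returned as an explicit merge table for
#' comparison and serialization alongside the `hclust` object.
#'
#' @param profiles numeric matrix, samples x features, no missing values.
#' @return list `merges` (data.frame `cluster_a, cluster_b, height` in
#'   `hclust` merge encoding: negative = singleton sample index) and
#'   `hclust` (the fitted object).
#' @export
methylation_cluster <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need >= 2 samples")
  if (any(!is.finite(profiles))) stop("NaN/NA features not allowed")
  hc <- stats::hclust(stats::dist(profiles, method = "euclidean"),
                      method = "complete")
  list(merges = data.frame(cluster_a = hc$merge[, 1],
                           cluster_b = hc$merge[, 2],
                           height = hc$height),
       hclust = hc)
}
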