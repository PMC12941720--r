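#' Candidate-gene regions (GRCh37)
#'
#' The six late-onset Alzheimer's disease candidate-gene regions used
#' throughout the package, 1-based inclusive GRCh37 coordinates.
#'
#' @return data.frame with columns `gene, chrom, start, end`.
#' @export
gene_regions_ad <- function() {
  data.frame(
    gene  = c("APOE", "PICALM", "CLU", "CR1", "BIN1", "ABCA7"),
    chrom = c("19", "11", "8", "1", "2", "19"),
    start = c(45409011L, 85673738L, 27453434L, 207494290L, 127803005L, 1040673L),
    end   = c(45412650L, 85782667L, 27469869L, 207667439L, 127897976L, 1084340L),
    stringsAsFactors = FALSE
  )
}

#' Read a gene-region table
#'
#' @param path TSV with header columns `gene, chrom, start, end`
#'   (1-based inclusive coordinates).
#' @return validated data.frame of regions.
#' @export
read_gene_regions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  if (nrow(df) == 0)
    return(data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer()))
  validate_regions(df)
}

validate_regions <- function(df) {
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("region table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene)) stop("duplicate gene in region table")
  if (any(df$start > df$end)) stop("region with start > end")
  df$chrom <- as.character(df$chrom)
  df[need]
}

#' Read a variant panel
#'
#' The risk-designated SNP panel: one row per biallelic SNP with its risk
#' allele and gene assignment.
#'
#' @param path TSV with header columns
#'   `rsid, chrom, pos, ref, alt, risk_allele, gene, source`.
#' @return data.frame panel; rsids are validated unique.
#' @export
read_variant_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  need <- c("rsid", "chrom", "pos", "ref", "alt", "risk_allele", "gene")
  if (!all(need %in% names(df)))
    stop("panel must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$rsid)) stop("duplicate rsid in panel")
  if (!"source" %in% names(df)) df$source <- NA_character_
  df
}

#' Construct a genotype matrix
#'
#' Container for unphased diploid calls: a character matrix of `"A/G"`
#' style calls (or `NA` for missing), SNPs in rows, samples in columns.
#'
#' @param calls character matrix, `rsids x samples`.
#' @param rsids,samples row/column identities (defaults to dimnames).
#' @param multiallelic logical vector flagging SNPs that carried more than
#'   one ALT allele on ingestion (dropped later by QC rule 1).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, rsids = rownames(calls),
                            samples = colnames(calls),
                            multiallelic = rep(FALSE, length(rsids))) {
  calls <- as.matrix(calls)
  stopifnot(nrow(calls) == length(rsids), ncol(calls) == length(samples))
  dimnames(calls) <- list(rsids, samples)
  structure(list(calls = calls, rsids = rsids, samples = samples,
                 multiallelic = stats::setNames(multiallelic, rsids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d samples (%d multi-allelic, %d missing calls)\n",
              length(x$rsids), length(x$samples),
              sum(x$multiallelic), sum(is.na(x$calls))))
  invisible(x)
}

#' Read genotypes from a VCF
#'
#' Decodes GT fields to allele-pair calls using each record's REF/ALT.
#' Multi-allelic records are passed through but flagged (the QC filter
#' removes them); missing GT becomes a missing call. Records are indexed
#' by their ID column (rsID).
#'
#' @param path VCF file (plain text or bgzipped).
#' @param samples optional character vector restricting and ordering the
#'   sample columns; an absent sample is an error.
#' @return a [genotype_matrix].
#' @export
read_genotype_vcf <- function(path, samples = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "GRCh37")
  hdr_samples <- colnames(vcf)
  if (is.null(samples)) samples <- hdr_samples
  missing_s <- setdiff(samples, hdr_samples)
  if (length(missing_s))
    stop("requested sample absent from VCF: ", missing_s[1])
  gt <- VariantAnnotation::geno(vcf)$GT[, samples, drop = FALSE]
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT  # DNAStringSetList
  nalt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[nalt >= 1] <- vapply(which(nalt >= 1), function(i)
    as.character(altl[[i]][1]), character(1))
  rsids <- names(rr)
  calls <- matrix(NA_character_, nrow = length(rsids), ncol = length(samples),
                  dimnames = list(rsids, samples))
  for (i in seq_along(rsids)) {
    alleles <- c(ref[i], as.character(altl[[i]]))
    for (j in seq_along(samples)) {
      g <- gt[i, j]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) next
      idx <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
      if (length(idx) != 2 || any(is.na(idx))) next
      calls[i, j] <- paste(alleles[idx + 1L], collapse = "/")
    }
  }
  gm <- genotype_matrix(calls, rsids, samples, multiallelic = nalt > 1)
  attr(gm, "ref") <- stats::setNames(ref, rsids)
  attr(gm, "alt") <- stats::setNames(alt1, rsids)
  gm
}

#' Read genotypes from a simple sample x SNP TSV
#'
#' Alternative plain-text ingestion: first column `rsid`, remaining
#' columns one per sample, cells `"A/G"` style or empty/`NA` for missing.
#'
#' @param path TSV file.
#' @param samples optional restriction/ordering of samples.
#' @return a [genotype_matrix].
#' @export
read_genotype_tsv <- function(path, samples = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  rsids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == ""] <- NA_character_
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(m))
    if (length(missing_s)) stop("requested sample absent: ", missing_s[1])
    m <- m[, samples, drop = FALSE]
  }
  genotype_matrix(m, rsids, colnames(m))
}

#' Restrict a variant panel to candidate-gene regions with flanking
#'
#' Keeps a panel record iff its position falls inside some region extended
#' by `flank_bp` on both sides (1-based inclusive boundaries), and
#' reassigns the record's gene label to the matching region. Flanked
#' regions that overlap on the same chromosome would make assignment
#' ambiguous and raise an error.
#'
#' @param panel variant panel data.frame (see [read_variant_panel()]).
#' @param regions region table (see [read_gene_regions()]).
#' @param flank_bp non-negative flank size in bp (default 50000, i.e.
#'   +/-50 kb around each gene).
#' @return the panel subset, gene labels reassigned, original row order.
#' @export
extract_region_variants <- function(panel, regions, flank_bp = 50000) {
  stopifnot(flank_bp >= 0)
  regions <- validate_regions(regions)
  rchrom <- norm_chrom(regions$chrom)
  rstart <- regions$start - flank_bp
  rend <- regions$end + flank_bp
  # overlap check per chromosome after flanking
  for (ch in unique(rchrom)) {
    i <- which(rchrom == ch)
    if (length(i) < 2) next
    o <- order(rstart[i])
    s <- rstart[i][o]; e <- rend[i][o]
    if (any(s[-1] <= e[-length(e)]))
      stop("overlapping flanked regions on chromosome ", ch,
           ": ambiguous gene assignment")
  }
  pchrom <- norm_chrom(panel$chrom)
  hit <- rep(NA_integer_, nrow(panel))
  for (r in seq_len(nrow(regions))) {
    inr <- pchrom == rchrom[r] & panel$pos >= rstart[r] & panel$pos <= rend[r]
    hit[inr] <- r
  }
  out <- panel[!is.na(hit), , drop = FALSE]
  out$gene <- regions$gene[hit[!is.na(hit)]]
  rownames(out) <- NULL
  out
}

#' Apply the variant QC filters for burden scoring
#'
#' Drops panel SNPs in a fixed rule order, attributing each removal to the
#' first matching rule so the report is reproducible:
#' 1. multi-allelic (flagged at VCF ingestion, or ALT containing a comma);
#' 2. no clear risk-allele designation (`risk_allele` missing or not one
#'    of REF/ALT);
#' 3. monomorphic across the scored samples (a single allele observed);
#' 4. any missing genotype among the scored samples.
#'
#' @param panel variant panel data.frame.
#' @param gm [genotype_matrix] covering the panel SNPs.
#' @param samples samples defining polymorphism/missingness (default: all
#'   samples of `gm`).
#' @return list with `panel` (survivors) and `report` (data.frame of
#'   per-rule removal counts plus survivors).
#' @export
apply_qc_filters <- function(panel, gm, samples = gm$samples) {
  stopifnot(inherits(gm, "genotype_matrix"))
  absent <- setdiff(panel$rsid, gm$rsids)
  if (length(absent))
    stop("panel SNP absent from genotype matrix: ", absent[1])
  calls <- gm$calls[panel$rsid, samples, drop = FALSE]
  multi <- unname(gm$multiallelic[panel$rsid]) | grepl(",", panel$alt)
  risk_bad <- is.na(panel$risk_allele) | panel$risk_allele == "" |
    !(panel$risk_allele == panel$ref | panel$risk_allele == panel$alt)
  mono <- vapply(seq_len(nrow(panel)), function(i) {
    als <- unlist(lapply(calls[i, ], parse_call))
    length(unique(als)) <= 1  # all-missing counts as monomorphic
  }, logical(1))
  missing_any <- vapply(seq_len(nrow(panel)), function(i) {
    any(vapply(calls[i, ], function(g) is.null(parse_call(g)), logical(1)))
  }, logical(1))
  rule <- rep(NA_character_, nrow(panel))
  rule[missing_any] <- "missing_genotype"
  rule[mono] <- "monomorphic"
  rule[risk_bad] <- "no_risk_designation"
  rule[multi] <- "multiallelic"      # highest precedence last
  report <- data.frame(
    rule = c("multiallelic", "no_risk_designation", "monomorphic",
             "missing_genotype", "survivors"),
    n = c(sum(rule == "multiallelic", na.rm = TRUE),
          sum(rule == "no_risk_designation", na.rm = TRUE),
          sum(rule == "monomorphic", na.rm = TRUE),
          sum(rule == "missing_genotype", na.rm = TRUE),
          sum(is.na(rule))),
    stringsAsFactors = FALSE
  )
  list(panel = panel[is.na(rule), , drop = FALSE], report = report)
}

#' Risk-allele dosage of one call
#'
#' Counts how many of the two alleles of an unphased diploid call equal
#' the SNP's designated risk allele — the per-SNP term of the genetic
#' burden score.
#'
#' @param call `"A/G"` style call string (or length-2 allele vector).
#' @param risk_allele the designated risk allele.
#' @return integer dosage in 0..2.
#' @export
risk_dosage <- function(call, risk_allele) {
  al <- if (length(call) == 2) call else parse_call(call)
  if (is.null(al)) stop("missing call has no dosage")
  sum(al == risk_allele)
}
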