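test_that("built-in candidate regions have the expected spans", {
  reg <- gene_regions_ad()
  expect_equal(nrow(reg), 6)
  apoe <- reg[reg$gene == "APOE", ]
  expect_equal(apoe$end - apoe$start + 1, 3640)
  cr1 <- reg[reg$gene == "CR1", ]
  expect_equal(cr1$end - cr1$start + 1, 173150)
  # round-trip through the TSV loader
  f <- tempfile(fileext = ".tsv")
  write.table(reg, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_gene_regions(f), reg)
  # empty file -> empty table
  writeLines("gene\tchrom\tstart\tend", f)
  expect_equal(nrow(read_gene_regions(f)), 0)
  # malformed region
  writeLines(c("gene\tchrom\tstart\tend", "X\t1\t10\t5"), f)
  expect_error(read_gene_regions(f), "start > end")
})

test_that("region extraction keeps exactly the interval-test records", {
  regions <- data.frame(gene = "G1", chrom = "1", start = 1000L, end = 2000L)
  panel <- data.frame(rsid = paste0("rs", 1:4), chrom = "1",
                      pos = c(949L, 950L, 2050L, 2051L),
                      ref = "A", alt = "G", risk_allele = "G",
                      gene = "?", source = "x", stringsAsFactors = FALSE)
  kept <- extract_region_variants(panel, regions, flank_bp = 50)
  expect_equal(kept$rsid, c("rs2", "rs3"))
  expect_equal(unique(kept$gene), "G1")
  # flank 0, pos = start is kept (1-based inclusive)
  kept0 <- extract_region_variants(
    data.frame(rsid = "rs", chrom = "chr1", pos = 1000L, ref = "A",
               alt = "G", risk_allele = "G", gene = "?", source = "x"),
    regions, flank_bp = 0)
  expect_equal(nrow(kept0), 1)

  # random panel vs brute-force per-record membership over the real regions
  set.seed(7)
  reg <- gene_regions_ad()
  rp <- data.frame(
    rsid = paste0("r", 1:100),
    chrom = sample(c("1", "2", "8", "11", "19", "7"), 100, replace = TRUE),
    pos = sample(c(sample.int(300000000L, 60),
                   45309011L + sample.int(203640L, 40))),  # near/inside APOE
    ref = "A", alt = "G", risk_allele = "G", gene = "?", source = "x",
    stringsAsFactors = FALSE)
  kept <- extract_region_variants(rp, reg, flank_bp = 50000)
  oracle <- vapply(seq_len(nrow(rp)), function(i) {
    any(norm_chrom(rp$chrom[i]) == norm_chrom(reg$chrom) &
          rp$pos[i] >= reg$start - 50000 & rp$pos[i] <= reg$end + 50000)
  }, logical(1))
  expect_equal(sort(kept$rsid), sort(rp$rsid[oracle]))

  # monotone in the flank: f1 <= f2 implies subset
  k1 <- extract_region_variants(rp, reg, flank_bp = 10000)
  expect_true(all(k1$rsid %in% kept$rsid))

  # overlapping flanked regions on one chromosome is an error
  reg2 <- data.frame(gene = c("A", "B"), chrom = "1",
                     start = c(1000L, 3000L), end = c(2000L, 4000L))
  expect_error(extract_region_variants(panel, reg2, flank_bp = 600),
               "overlapping")
})

test_that("QC filters drop planted defects with a per-rule report", {
  set.seed(5)
  n <- 50
  samples <- paste0("S", 1:4)
  panel <- data.frame(rsid = sprintf("rs%02d", 1:n), chrom = "1",
                      pos = 1:n * 10L, ref = "A", alt = "G",
                      risk_allele = "G", gene = "G1", source = "x",
                      stringsAsFactors = FALSE)
  calls <- matrix(rep(c("A/A", "A/G", "G/G", "A/G"), each = n),
                  nrow = n, dimnames = list(panel$rsid, samples))
  multi_idx <- 1:3; mono_idx <- 4:5; miss_idx <- 6
  panel$alt[multi_idx] <- "G,T"
  calls[mono_idx, ] <- "A/A"
  calls[miss_idx, 2] <- NA
  gm <- genotype_matrix(calls, panel$rsid, samples,
                        multiallelic = grepl(",", panel$alt))
  qc <- apply_qc_filters(panel, gm)
  expect_equal(qc$report$n,
               c(3, 0, 2, 1, 44))  # multiallelic, risk, monomorphic, missing, survivors
  expect_equal(nrow(qc$panel), 44)
  expect_false(any(qc$panel$rsid %in% panel$rsid[c(multi_idx, mono_idx, miss_idx)]))

  # idempotence: filtering the survivors removes nothing
  qc2 <- apply_qc_filters(qc$panel, gm)
  expect_equal(qc2$panel$rsid, qc$panel$rsid)
  expect_equal(qc2$report$n[qc2$report$rule == "survivors"], 44)

  # first-match attribution: a SNP that is both multi-allelic and missing
  # counts once, under the earlier rule
  panel$alt[miss_idx] <- "G,T"
  gm2 <- genotype_matrix(calls, panel$rsid, samples,
                         multiallelic = grepl(",", panel$alt))
  qc3 <- apply_qc_filters(panel, gm2)
  expect_equal(qc3$report$n, c(4, 0, 2, 0, 44))

  # a bad risk designation fails rule 2
  panel2 <- micro_panel(); panel2$risk_allele[2] <- "T"
  gm3 <- genotype_matrix(matrix(c("A/G", "A/G", "A/G", "A/A", "G/G", "A/A"),
                                nrow = 3,
                                dimnames = list(panel2$rsid, c("a", "b"))))
  qc4 <- apply_qc_filters(panel2, gm3)
  expect_equal(qc4$report$n[qc4$report$rule == "no_risk_designation"], 1)
})

test_that("risk dosage counts the designated allele, whichever strand of ref/alt", {
  expect_equal(risk_dosage("G/G", "G"), 2)
  expect_equal(risk_dosage("A/A", "G"), 0)
  # risk allele equal to the REF allele: a heterozygote still counts 1
  expect_equal(risk_dosage("A/G", "A"), 1)
  expect_error(risk_dosage("./.", "G"), "missing")
  # complement identity: risk + non-risk alleles = 2 always
  set.seed(3)
  for (k in 1:50) {
    al <- sample(c("A", "C", "G", "T"), 2, replace = TRUE)
    risk <- sample(al, 1)
    call <- paste(al, collapse = "/")
    expect_equal(risk_dosage(call, risk) + sum(al != risk), 2)
  }
})

test_that("VCF genotypes round-trip through write and read", {
  sim <- simulate_family(sim_config(seed = 9, missing_rate = 0.01))
  f <- tempfile(fileext = ".vcf")
  write_genotype_vcf(sim$gm, sim$panel, f)
  gm2 <- read_genotype_vcf(f)
  expect_setequal(gm2$rsids, sim$gm$rsids)
  expect_equal(gm2$samples, sim$gm$samples)
  # same calls up to allele order within a genotype
  canon <- function(m) apply(m, c(1, 2), function(g)
    if (is.na(g)) NA_character_ else paste(sort(strsplit(g, "/")[[1]]), collapse = "/"))
  expect_equal(canon(gm2$calls[sim$gm$rsids, ]), canon(sim$gm$calls))
  # sample restriction and missing-sample error
  gm3 <- read_genotype_vcf(f, samples = c("F1", "C2"))
  expect_equal(gm3$samples, c("F1", "C2"))
  expect_error(read_genotype_vcf(f, samples = "nope"), "absent")
})

test_that("TSV genotype ingestion matches the matrix it came from", {
  sim <- simulate_family(sim_config(seed = 10))
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(rsid = sim$gm$rsids, sim$gm$calls, check.names = FALSE)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  gm2 <- read_genotype_tsv(f)
  expect_equal(gm2$calls, sim$gm$calls)
})
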