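test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 14, mendel_errors = 2, missing_rate = 0.005)
  s1 <- simulate_family(cfg)
  s2 <- simulate_family(cfg)
  expect_identical(s1$gm$calls, s2$gm$calls)
  expect_identical(s1$freq, s2$freq)
  expect_identical(s1$truth$injected_errors, s2$truth$injected_errors)
  # byte-identical files across two writes
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  m1 <- simulate_methylation(cfg, compute_gbs_safe(s1), s1$ped)
  m2 <- simulate_methylation(cfg, compute_gbs_safe(s2), s2$ped)
  p1 <- write_family_data(s1, d1, m1)
  p2 <- write_family_data(s2, d2, m2)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     info = nm)
  # a different seed changes the data
  s3 <- simulate_family(sim_config(seed = 15))
  expect_false(identical(s1$gm$calls, s3$gm$calls))
})

test_that("panel composition and layout mirror the candidate-gene design", {
  sim <- simulate_family(sim_config(seed = 3))
  counts <- table(sim$panel$gene)
  expect_equal(counts[["ABCA7"]], 101)
  expect_equal(counts[["PICALM"]], 89)
  expect_equal(counts[["CR1"]], 84)
  expect_equal(counts[["CLU"]], 29)
  expect_equal(counts[["BIN1"]], 8)
  expect_equal(counts[["APOE"]], 9)
  expect_equal(nrow(sim$panel), 320)
  expect_true(all(c("rs429358", "rs7412") %in% sim$panel$rsid))
  # every simulated SNP sits inside its gene region (so +/-50 kb
  # extraction is the identity on the panel)
  ext <- extract_region_variants(sim$panel, sim$regions, 50000)
  expect_equal(ext$rsid, sim$panel$rsid)
  expect_equal(ext$gene, sim$panel$gene)
  expect_true(all(sim$panel$risk_allele == sim$panel$ref |
                    sim$panel$risk_allele == sim$panel$alt))
})

test_that("founder haplotypes honor the LD persistence parameter", {
  # rho = 0: adjacent states essentially uncorrelated
  cfg0 <- sim_config(seed = 8, rho = 0, risk_freq_range = c(0.3, 0.3))
  fh0 <- simulate_founder_haplotypes(cfg0, 400)
  st0 <- do.call(rbind, fh0$haplotypes)
  gene <- fh0$panel$gene
  r0 <- adjacent_state_cor(st0, gene)
  expect_lt(abs(r0), 0.05)
  # rho = 1 with constant per-gene frequency: constant gene blocks
  cfg1 <- sim_config(seed = 8, rho = 1, risk_freq_range = c(0.3, 0.3))
  fh1 <- simulate_founder_haplotypes(cfg1, 20)
  for (h in fh1$haplotypes) for (g in unique(gene)) {
    expect_equal(length(unique(h[1, gene == g])), 1)
    expect_equal(length(unique(h[2, gene == g])), 1)
  }
  # rho = 0.8: adjacent-state correlation near the copy probability
  cfg8 <- sim_config(seed = 8, rho = 0.8, risk_freq_range = c(0.3, 0.3))
  st8 <- do.call(rbind, simulate_founder_haplotypes(cfg8, 1000)$haplotypes)
  r8 <- adjacent_state_cor(st8, gene)
  expect_lt(abs(r8 - 0.8), 0.05)
})

test_that("per-SNP marginals are exactly the configured frequencies (4 SE)", {
  cfg <- sim_config(seed = 42)
  fh <- simulate_founder_haplotypes(cfg, 500)
  st <- do.call(rbind, fh$haplotypes)   # 1000 haplotypes
  emp <- colMeans(st)
  se <- sqrt(fh$freq * (1 - fh$freq) / nrow(st))
  expect_true(all(abs(emp - fh$freq) <= 4 * se))
  expect_lt(mean(abs(emp - fh$freq)), 0.01)
})

test_that("meiosis transmits parental haplotypes with recombination", {
  set.seed(31)
  hp <- rbind(rep(0L, 50), rep(1L, 50))
  # recomb 0: gamete equals one parental haplotype exactly
  g0 <- meiosis(hp, recomb_p = 0)
  expect_true(all(g0 == 0) || all(g0 == 1))
  # recomb 1: source alternates at every interval
  g1 <- meiosis(hp, recomb_p = 1)
  expect_true(all(abs(diff(g1)) == 1))
  # Mendelian expectation at a heterozygous site: 0.5 +/- 0.03
  hp_het <- rbind(0L, 1L)
  draws <- replicate(10000, meiosis(hp_het, recomb_p = 0.01))
  expect_lt(abs(mean(draws) - 0.5), 0.03)
  expect_error(meiosis(matrix(0, 3, 2), 0.1), "2 x L")
})

test_that("clean families are Mendelian-consistent; injected errors are found exactly", {
  sim <- simulate_family(sim_config(seed = 26))
  expect_equal(nrow(check_mendelian(sim$ped, sim$gm)), 0)

  simk <- simulate_family(sim_config(seed = 26, mendel_errors = 3))
  v <- check_mendelian(simk$ped, simk$gm)
  inj <- simk$truth$injected_errors
  expect_equal(nrow(inj), 3)
  expect_setequal(paste(v$individual_id, v$rsid),
                  paste(inj$individual_id, inj$rsid))
})

test_that("burden from emitted genotypes equals burden from truth haplotypes", {
  sim <- simulate_family(sim_config(seed = 5))
  bt <- compute_gbs(sim$gm, sim$panel)
  genes <- colnames(sim$truth$true_gene_dosage)
  expect_equal(as.matrix(bt[, genes]),
               sim$truth$true_gene_dosage[bt$id, ],
               ignore_attr = TRUE)
})

test_that("sibling discordance grows with LD persistence", {
  # positive LD inflates the variance of transmitted haplotype sums, so
  # sib pairs diverge more when rho is high
  mean_abs_delta <- function(rho, n_pairs = 334, seed0) {
    d <- numeric(n_pairs)
    for (k in seq_len(n_pairs)) {
      s <- simulate_family(sim_config(seed = seed0 + k, rho = rho))
      tg <- s$truth$true_gene_dosage
      d[k] <- abs(sum(tg["C1", ]) - sum(tg["C2", ]))
    }
    mean(d)
  }
  d_lo <- mean_abs_delta(0.1, seed0 = 20000)
  d_mid <- mean_abs_delta(0.5, seed0 = 30000)
  d_hi <- mean_abs_delta(0.9, seed0 = 40000)
  expect_lt(d_lo, d_mid)
  expect_lt(d_mid, d_hi)
})

test_that("synthetic methylation couples to burden as configured", {
  cfg <- sim_config(seed = 51)
  sim <- simulate_family(cfg)
  bt <- compute_gbs(sim$gm, sim$panel)
  # slope 0, zero noise, no affected offset: every probe beta = baseline
  cfg0 <- sim_config(seed = 51, meth = list(noise_sd = 1e-9,
                                            affected_offset = 0))
  m0 <- simulate_methylation(cfg0, bt, sim$ped)
  for (g in c("APOE", "CLU")) {
    probes <- grep(paste0("^cg_", g, "_"), rownames(m0$betas))
    expect_equal(unname(m0$betas[probes, ]),
                 matrix(cfg0$meth$baseline[[g]], length(probes), 7),
                 tolerance = 1e-6)
  }
  # a negative individual offset makes that individual the minimum for
  # every gene (inverse-logit is monotone)
  mneg <- simulate_methylation(
    sim_config(seed = 51, meth = list(noise_sd = 1e-9,
                                      affected_offset = -0.1)),
    bt, sim$ped)
  aff <- sim$ped$id[sim$ped$affected]
  fp <- filter_probes(mneg$manifest, mneg$betas, mneg$detp)
  gms <- gene_methylation(mneg$betas[fp$kept, ],
                          mneg$manifest[match(fp$kept, mneg$manifest$probe_id), ],
                          sim$regions)
  for (g in rownames(gms$means))
    expect_equal(names(which.min(gms$means[g, ])), aff)
  # planted manifest flags and detection failures round to the plan
  cfgf <- sim_config(seed = 51, meth = list(n_snp_flag = 3, n_cross_flag = 2,
                                            n_sex_probes = 4,
                                            detp_fail_rate = 0.05))
  mf <- simulate_methylation(cfgf, bt, sim$ped)
  fpf <- filter_probes(mf$manifest, mf$betas, mf$detp)
  rep_ <- setNames(fpf$report$n, fpf$report$rule)
  expect_equal(rep_[["snp_overlap"]],
               sum(!(mf$truth$snp_flagged %in% mf$truth$detp_failures)))
  expect_equal(rep_[["cross_reactive"]],
               sum(!(mf$truth$cross_flagged %in%
                       c(mf$truth$detp_failures, mf$truth$snp_flagged))))
  expect_equal(rep_[["detection_p"]], length(mf$truth$detp_failures))
  expect_equal(rep_[["sex_chromosome"]],
               sum(!(mf$truth$sex_probes %in% c(mf$truth$detp_failures))))
})

test_that("every emitted file round-trips through its loader", {
  cfg <- sim_config(seed = 61)
  sim <- simulate_family(cfg)
  bt <- compute_gbs(sim$gm, sim$panel)
  meth <- simulate_methylation(cfg, bt, sim$ped)
  dir <- file.path(tempdir(), "roundtrip")
  p <- write_family_data(sim, dir, meth)
  ped2 <- read_pedigree(p[["ped"]])
  expect_equal(generations(ped2)[sim$ped$id], generations(sim$ped))
  expect_equal(ped2$affected[match(sim$ped$id, ped2$id)], sim$ped$affected)
  panel2 <- read_variant_panel(p[["panel"]])
  expect_equal(panel2, sim$panel)
  reg2 <- read_gene_regions(p[["regions"]])
  expect_equal(reg2, sim$regions)
  b2 <- read_beta_matrix(p[["betas"]])
  expect_equal(b2, meth$betas, tolerance = 1e-12)
  man2 <- read_probe_manifest(p[["manifest"]])
  expect_equal(man2$probe_id, meth$manifest$probe_id)
  d2 <- read_beta_matrix(p[["detp"]])
  expect_equal(d2, meth$detp, tolerance = 1e-12)
})
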