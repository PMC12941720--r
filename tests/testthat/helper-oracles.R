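# Independent oracles, deliberately naive: each recomputes a quantity by
# brute force along a different route than the package implementation.

# All unphased child genotypes producible from two parental genotypes,
# by exhaustive gamete-pair enumeration.
feasible_child_genotypes <- function(father, mother) {
  out <- character()
  for (a in father) for (b in mother)
    out <- c(out, paste(sort(c(a, b)), collapse = "/"))
  unique(out)
}

# O(n^3) complete-linkage agglomeration from the raw distance matrix:
# at each step merge the pair of clusters with the smallest maximum
# inter-point distance. Returns merge heights and the member set created
# by each merge.
naive_complete_linkage <- function(x) {
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  formed <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (is.null(best) || h < best$h) best <- list(i = i, j = j, h = h)
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    heights <- c(heights, best$h)
    formed <- c(formed, list(merged))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  list(heights = heights, formed = formed)
}

# cluster member sets created along an hclust merge sequence
hclust_formed_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    members <- integer()
    for (v in hc$merge[k, ])
      members <- c(members, if (v < 0) -v else sets[[v]])
    sets[[k]] <- sort(members)
  }
  sets
}

# write the 7-member blood core as a PED file; optionally add two
# marry-in spouses with no blood path
write_core_ped <- function(path, with_spouses = FALSE) {
  rows <- c(
    "FAM1 J-003 0 0 2 2",
    "FAM1 J-005 0 0 1 1",
    "FAM1 J-006 0 0 2 1",
    "FAM1 J-011 J-005 J-006 1 1",
    "FAM1 J-025 0 J-003 2 1",
    "FAM1 J-012 J-011 J-025 1 1",
    "FAM1 J-017 J-011 J-025 1 1"
  )
  if (with_spouses)
    rows <- c(rows, "FAM1 SP-1 0 0 2 1", "FAM1 SP-2 0 0 1 1")
  writeLines(rows, path)
  path
}

# tiny genotype fixture: explicit calls for a 2-sample micro panel
micro_panel <- function() {
  data.frame(
    rsid = c("rsA1", "rsA2", "rsA3"),
    chrom = "1", pos = c(100L, 200L, 300L),
    ref = c("A", "A", "A"), alt = c("G", "G", "G"),
    risk_allele = c("G", "G", "G"), gene = "geneA",
    source = "fixture", stringsAsFactors = FALSE
  )
}

# mean correlation of adjacent within-gene SNP states across haplotypes
adjacent_state_cor <- function(states, gene) {
  cors <- c()
  for (j in 2:ncol(states))
    if (gene[j] == gene[j - 1]) {
      r <- suppressWarnings(stats::cor(states[, j - 1], states[, j]))
      if (is.finite(r)) cors <- c(cors, r)
    }
  mean(cors)
}

# GBS restricted to panel SNPs with complete calls (for simulations that
# carry injected missingness)
compute_gbs_safe <- function(sim) {
  ok <- apply(sim$gm$calls, 1, function(r) !any(is.na(r)))
  compute_gbs(sim$gm, sim$panel[sim$panel$rsid %in% sim$gm$rsids[ok], ])
}
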