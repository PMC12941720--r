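#' Compute the genetic burden score (GBS)
#'
#' The GBS of individual *i* is the unweighted sum of risk-allele dosages
#' over the panel SNPs, `GBS_i = sum_j G_ij`, where `G_ij` in \{0,1,2\} is
#' the count of the designated risk allele in the unphased genotype of
#' individual *i* at SNP *j*. The table also carries the per-gene
#' decomposition (the sum over that gene's SNPs), whose row sums equal the
#' totals exactly. The score is a *within-family comparative* quantity:
#' it is not a calibrated disease probability and has no meaning against
#' population polygenic-score percentiles.
#'
#' @param gm a [genotype_matrix] with no missing calls for the scored
#'   samples at panel SNPs (run [apply_qc_filters()] first; a missing call
#'   is an error, not a silent 0).
#' @param panel QC-passed variant panel data.frame.
#' @param samples samples to score (default: all in `gm`).
#' @return object of class `burden_table`: data.frame with one row per
#'   individual, one column per gene plus `total`; attribute
#'   `snps_per_gene`.
#' @export
compute_gbs <- function(gm, panel, samples = gm$samples) {
  stopifnot(inherits(gm, "genotype_matrix"))
  absent <- setdiff(panel$rsid, gm$rsids)
  if (length(absent)) stop("panel SNP absent from genotypes: ", absent[1])
  genes <- unique(panel$gene)
  out <- matrix(0L, nrow = length(samples), ncol = length(genes),
                dimnames = list(samples, genes))
  for (j in seq_len(nrow(panel))) {
    g <- panel$gene[j]
    for (s in samples) {
      al <- parse_call(gm$calls[panel$rsid[j], s])
      if (is.null(al))
        stop("missing call for ", s, " at ", panel$rsid[j],
             ": QC contract broken")
      out[s, g] <- out[s, g] + sum(al == panel$risk_allele[j])
    }
  }
  df <- as.data.frame(out)
  df$total <- as.integer(rowSums(out))
  df <- cbind(id = samples, df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df,
            snps_per_gene = vapply(genes, function(g)
              sum(panel$gene == g), integer(1)),
            class = c("burden_table", "data.frame"))
}

#' Assemble a burden table from known per-gene counts
#'
#' Constructor used for worked examples and fixtures where per-gene
#' counts (not genotypes) are the available data.
#'
#' @param counts numeric matrix or data.frame, individuals x genes.
#' @param ids individual ids (default rownames).
#' @return a `burden_table`.
#' @export
burden_table <- function(counts, ids = rownames(counts)) {
  m <- as.matrix(counts)
  df <- as.data.frame(m)
  df$total <- as.integer(rowSums(m))
  df <- cbind(id = ids, df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("burden_table", "data.frame"))
}

.bt_genes <- function(bt) setdiff(names(bt), c("id", "total"))

#' @export
print.burden_table <- function(x, ...) {
  cat(sprintf("Genetic burden table: %d individuals, %d genes\n",
              nrow(x), length(.bt_genes(x))))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
summary.burden_table <- function(object, ...) {
  gs <- group_summary(object$total, "family")
  cat("family GBS: ", format(gs), "\n", sep = "")
  gm <- vapply(.bt_genes(object), function(g) mean(object[[g]]), numeric(1))
  cp <- contribution_percentages(gm, mean(object$total))
  for (g in names(sort(-gm)))
    cat(sprintf("  %-8s mean %s (%s%%)\n", g,
                round_half_up(gm[g], 1), round_half_up(cp[g], 1)))
  invisible(list(family = gs, gene_means = gm, contribution = cp))
}

#' Descriptive summary of a numeric group
#'
#' Mean, sample standard deviation (n-1 denominator), minimum and maximum.
#' Values are stored at full precision; rounding (half away from zero, 1
#' decimal) happens only in `format()`/`print()`.
#'
#' @param values numeric vector, length >= 1.
#' @param label group label.
#' @return object of class `group_summary`: list with `label, n, mean, sd,
#'   min, max` (`sd` is `NA` for n = 1).
#' @export
group_summary <- function(values, label = "group") {
  if (length(values) == 0) stop("empty input: nothing to summarize")
  structure(list(label = label, n = length(values),
                 mean = mean(values),
                 sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
                 min = min(values), max = max(values)),
            class = "group_summary")
}

#' @export
format.group_summary <- function(x, digits = 1, ...) {
  sprintf("%s +/- %s (range: %s-%s, n=%d)",
          round_half_up(x$mean, digits),
          if (is.na(x$sd)) "NA" else round_half_up(x$sd, digits),
          x$min, x$max, x$n)
}

#' @export
print.group_summary <- function(x, ...) {
  cat(x$label, ": ", format(x), "\n", sep = "")
  invisible(x)
}

#' Relative discordance between two burden totals
#'
#' Absolute difference and relative percent difference, with the *smaller*
#' total as denominator (the convention under which a 37 vs 61 sibling
#' pair is a 64.9% relative difference).
#'
#' @param a,b positive totals.
#' @return list `delta` (absolute difference) and `relative_percent`
#'   (full precision; display at 1 decimal).
#' @export
relative_discordance <- function(a, b) {
  if (a <= 0 || b <= 0) stop("totals must be positive")
  delta <- abs(a - b)
  list(delta = delta, relative_percent = delta / min(a, b) * 100)
}

#' Per-gene signed differences between two individuals
#'
#' Signed (`b - a`) and absolute per-gene differences; the signed
#' differences sum exactly to the difference in totals.
#'
#' @param bt a `burden_table`.
#' @param id_a,id_b scored individual ids.
#' @return data.frame `gene, signed_delta, abs_delta`.
#' @export
gene_deltas <- function(bt, id_a, id_b) {
  ia <- match(id_a, bt$id); ib <- match(id_b, bt$id)
  if (is.na(ia) || is.na(ib))
    stop("unknown id: ", if (is.na(ia)) id_a else id_b)
  genes <- .bt_genes(bt)
  sd_ <- vapply(genes, function(g) bt[[g]][ib] - bt[[g]][ia], numeric(1))
  data.frame(gene = genes, signed_delta = sd_, abs_delta = abs(sd_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene contribution to the family-average burden
#'
#' @param gene_means named numeric vector of per-gene family means.
#' @param total_mean positive family mean total.
#' @return named numeric vector of full-precision percentages; display
#'   convention is 1 decimal, half away from zero ([round_half_up()]).
#' @export
contribution_percentages <- function(gene_means, total_mean) {
  if (total_mean <= 0) stop("total mean must be positive")
  gene_means / total_mean * 100
}

#' Compare burden between epsilon4 carriers and non-carriers
#'
#' @param bt a `burden_table`.
#' @param carrier_flags named logical vector (ids -> carrier status)
#'   covering all scored individuals.
#' @return list with `carriers`, `noncarriers` ([group_summary]s on
#'   unrounded totals) and `mean_difference` (carrier mean - non-carrier
#'   mean, full precision).
#' @export
carrier_comparison <- function(bt, carrier_flags) {
  flags <- carrier_flags[bt$id]
  if (any(is.na(flags))) stop("carrier flag missing for some individuals")
  if (!any(flags) || all(flags)) stop("both carrier groups must be non-empty")
  carr <- group_summary(bt$total[flags], "e4 carriers")
  nonc <- group_summary(bt$total[!flags], "non-carriers")
  list(carriers = carr, noncarriers = nonc,
       mean_difference = carr$mean - nonc$mean)
}

#' Per-generation burden summaries
#'
#' @param bt a `burden_table`.
#' @param ped a [pedigree] containing every scored individual.
#' @return named list of [group_summary], one per generation in ascending
#'   order, labels `"generation 1"`, ...
#' @export
generation_summary <- function(bt, ped) {
  gen <- generations(ped)[bt$id]
  if (any(is.na(gen))) stop("scored individual missing from pedigree")
  lv <- sort(unique(gen))
  out <- lapply(lv, function(g)
    group_summary(bt$total[gen == g], paste("generation", g)))
  names(out) <- paste0("generation_", lv)
  out
}

#' One-way random-effects intraclass correlation, ICC(1)
#'
#' Familial-clustering ICC from a one-way ANOVA decomposition:
#' `ICC(1) = (MSB - MSW) / (MSB + (k0 - 1) MSW)`, with `k0` the average
#' group size adjusted for unbalanced groups,
#' `k0 = (N - sum(n_i^2)/N) / (a - 1)`.
#'
#' @param values numeric observations.
#' @param groups grouping factor (>= 2 groups; every group non-empty).
#' @return list `icc, msb, msw, k0, n_groups, n`.
#' @export
icc_oneway <- function(values, groups) {
  groups <- factor(groups)
  n_i <- table(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(n_i == 0)) stop("group with zero observations")
  N <- length(values); a <- nlevels(groups)
  grand <- mean(values)
  gmeans <- tapply(values, groups, mean)
  ssb <- sum(n_i * (gmeans - grand)^2)
  ssw <- sum((values - gmeans[groups])^2)
  msb <- ssb / (a - 1)
  msw <- ssw / (N - a)
  k0 <- (N - sum(n_i^2) / N) / (a - 1)
  icc <- if (msw == 0) 1 else (msb - msw) / (msb + (k0 - 1) * msw)
  list(icc = icc, msb = msb, msw = msw, k0 = k0, n_groups = a, n = N)
}

#' Linear trend of burden across generations
#'
#' Ordinary least squares of the value on the ordinal generation code
#' (generation I = 1, II = 2, III = 3, ...).
#'
#' @param values numeric outcomes.
#' @param generation_codes integer generation per observation (>= 2
#'   distinct values).
#' @return list `slope, intercept, r` (Pearson correlation of value with
#'   generation).
#' @export
generation_trend <- function(values, generation_codes) {
  if (length(unique(generation_codes)) < 2)
    stop("all generations identical: trend undefined")
  fit <- stats::lm(values ~ generation_codes)
  r <- if (stats::sd(values) == 0) 0
       else stats::cor(values, generation_codes)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r)
}
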