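# The epsilon haplotype table for the two canonical APOE-defining SNPs
# (alleles given as rs429358, rs7412). Standard domain knowledge:
#   e2 = (T,T); e3 = (T,C); e4 = (C,C); e1 = (C,T) (vanishingly rare).
APOE_HAPLOTYPES <- list(
  e2 = c("T", "T"),
  e3 = c("T", "C"),
  e4 = c("C", "C"),
  e1 = c("C", "T")
)

# canonical display order e2 < e3 < e4 < e1
APOE_ORDER <- c(e2 = 1L, e3 = 2L, e4 = 3L, e1 = 4L)

.eps_label <- function(x) chartr("e", "ε", x)

#' Call the APOE epsilon diplotype from rs429358 and rs7412
#'
#' Enumerates the pairs of epsilon haplotypes consistent with the two
#' unphased genotypes. All nine biallelic genotype combinations resolve
#' uniquely except the double heterozygote (rs429358 C/T with rs7412 C/T),
#' which is consistent with both \eqn{\epsilon2/\epsilon4} and
#' \eqn{\epsilon1/\epsilon3}; it is reported as \eqn{\epsilon2/\epsilon4}
#' (\eqn{\epsilon1} is vanishingly rare) with `ambiguous = TRUE`.
#'
#' @param g429358 unphased rs429358 call over alleles \{T,C\}, e.g. `"T/C"`.
#' @param g7412 unphased rs7412 call over alleles \{C,T\}.
#' @return object of class `apoe_diplotype`: list with `allele1`,
#'   `allele2` (canonical order \eqn{\epsilon2<\epsilon3<\epsilon4<\epsilon1}),
#'   `ambiguous`, `alternative` (the unreported consistent diplotype, or
#'   `NULL`) and `source_genotypes`.
#' @examples
#' call_apoe("T/T", "C/C")   # epsilon3/epsilon3
#' call_apoe("C/T", "C/C")   # epsilon3/epsilon4
#' call_apoe("C/T", "C/T")   # ambiguous double heterozygote
#' @export
call_apoe <- function(g429358, g7412) {
  a1 <- parse_call(if (length(g429358) == 2) paste(g429358, collapse = "/") else g429358)
  a2 <- parse_call(if (length(g7412) == 2) paste(g7412, collapse = "/") else g7412)
  if (is.null(a1) || is.null(a2))
    stop("missing call: both rs429358 and rs7412 genotypes are required")
  if (!all(a1 %in% c("T", "C"))) stop("illegal rs429358 allele: ",
                                      paste(a1, collapse = "/"))
  if (!all(a2 %in% c("C", "T"))) stop("illegal rs7412 allele: ",
                                      paste(a2, collapse = "/"))
  haps <- names(APOE_HAPLOTYPES)
  consistent <- list()
  for (i in seq_along(haps)) for (j in i:length(haps)) {
    h1 <- APOE_HAPLOTYPES[[i]]; h2 <- APOE_HAPLOTYPES[[j]]
    if (canon_call(c(h1[1], h2[1])) == canon_call(a1) &&
        canon_call(c(h1[2], h2[2])) == canon_call(a2))
      consistent[[length(consistent) + 1L]] <- c(haps[i], haps[j])
  }
  if (length(consistent) == 0)  # unreachable over legal alleles
    stop("no epsilon haplotype pair consistent with genotypes")
  ambiguous <- length(consistent) > 1
  pick <- consistent[[1]]
  if (ambiguous) {
    has_e2e4 <- vapply(consistent, function(p) setequal(p, c("e2", "e4")),
                       logical(1))
    pick <- consistent[[which(has_e2e4)[1]]]
  }
  pick <- pick[order(APOE_ORDER[pick])]
  structure(list(
    allele1 = pick[1], allele2 = pick[2],
    ambiguous = ambiguous,
    alternative = if (ambiguous)
      consistent[[which(!vapply(consistent, function(p)
        setequal(p, pick), logical(1)))[1]]] else NULL,
    source_genotypes = c(rs429358 = canon_call(a1), rs7412 = canon_call(a2))
  ), class = "apoe_diplotype")
}

#' @export
print.apoe_diplotype <- function(x, ...) {
  cat(sprintf("APOE %s/%s%s  [rs429358 %s, rs7412 %s]\n",
              .eps_label(x$allele1), .eps_label(x$allele2),
              if (x$ambiguous) sprintf(" (ambiguous; alt %s/%s)",
                                       .eps_label(x$alternative[1]),
                                       .eps_label(x$alternative[2])) else "",
              x$source_genotypes["rs429358"], x$source_genotypes["rs7412"]))
  invisible(x)
}

#' @export
format.apoe_diplotype <- function(x, ...) {
  paste0(.eps_label(x$allele1), "/", .eps_label(x$allele2))
}

#' Is a diplotype an epsilon4 carrier?
#'
#' Carrier status is possession of at least one \eqn{\epsilon4} allele
#' (\eqn{\epsilon3/\epsilon4} or \eqn{\epsilon4/\epsilon4} and the rarer
#' \eqn{\epsilon2/\epsilon4}).
#'
#' @param d an `apoe_diplotype`.
#' @return logical.
#' @export
is_e4_carrier <- function(d) {
  stopifnot(inherits(d, "apoe_diplotype"))
  "e4" %in% c(d$allele1, d$allele2)
}

#' Tabulate APOE diplotypes for a set of samples
#'
#' @param g429358,g7412 named character vectors of calls per sample id
#'   (names must agree).
#' @return data.frame: `sample_id, rs429358_gt, rs7412_gt, diplotype,
#'   e4_carrier, ambiguous`.
#' @export
apoe_table <- function(g429358, g7412) {
  ids <- names(g429358)
  stopifnot(!is.null(ids), setequal(ids, names(g7412)))
  rows <- lapply(ids, function(s) {
    d <- call_apoe(g429358[[s]], g7412[[s]])
    data.frame(sample_id = s,
               rs429358_gt = d$source_genotypes[["rs429358"]],
               rs7412_gt = d$source_genotypes[["rs7412"]],
               diplotype = format(d),
               e4_carrier = is_e4_carrier(d),
               ambiguous = d$ambiguous,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
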