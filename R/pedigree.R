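#' Read a PLINK-dialect pedigree file
#'
#' Parses a whitespace-delimited PED/FAM file, one row per individual:
#' family id, individual id, father id, mother id, sex code, phenotype code.
#' `0` marks a missing parent. Sex codes follow the PLINK convention
#' (1 = male, 2 = female, 0 = unknown), phenotype codes 2 = affected,
#' 1 = unaffected, 0 or -9 = unknown.
#'
#' @param path path to a PED/FAM file.
#' @param external character vector of parent ids that are allowed to be
#'   referenced without appearing as rows (marry-ins genotyped elsewhere).
#'   A referenced parent that is neither a row nor listed here is an error.
#' @return a [pedigree] object.
#' @seealso [pedigree()], [generations()], [blood_relatives()]
#' @export
read_pedigree <- function(path, external = character()) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 6)
    stop("pedigree file must have >= 6 whitespace-delimited columns")
  pedigree(
    id        = raw[[2]],
    father_id = ifelse(raw[[3]] == "0", NA_character_, raw[[3]]),
    mother_id = ifelse(raw[[4]] == "0", NA_character_, raw[[4]]),
    sex       = c("unknown", "male", "female")[match(raw[[5]], c("0", "1", "2"))],
    affected  = raw[[6]] == "2",
    family_id = raw[[1]][1],
    external  = external
  )
}

#' Construct a pedigree
#'
#' Core data model for a family: individuals with parent links. Validates
#' id uniqueness, parent resolution and acyclicity, then assigns
#' generations (founders = 1; a child is one generation below its deepest
#' in-pedigree parent).
#'
#' @param id character vector of unique individual ids.
#' @param father_id,mother_id character vectors of parent ids; `NA` where
#'   the parent is unknown/absent. An individual may have one in-pedigree
#'   parent and one absent parent (partial parentage).
#' @param sex character, one of `"male"`, `"female"`, `"unknown"`.
#' @param affected logical vector of affection status.
#' @param family_id single family label.
#' @param external ids permitted as parent references without being members.
#' @return an object of class `pedigree` (a data.frame with columns
#'   `id, father_id, mother_id, sex, affected, generation` and attribute
#'   `family_id`).
#' @export
pedigree <- function(id, father_id = NA, mother_id = NA,
                     sex = "unknown", affected = FALSE,
                     family_id = "FAM1", external = character()) {
  n <- length(id)
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate individual id: ", id[duplicated(id)][1])
  ped <- data.frame(
    id = id,
    father_id = rep_len(as.character(father_id), n),
    mother_id = rep_len(as.character(mother_id), n),
    sex = rep_len(sex, n),
    affected = rep_len(affected, n),
    stringsAsFactors = FALSE
  )
  bad_sex <- setdiff(unique(ped$sex), c("male", "female", "unknown"))
  if (length(bad_sex)) stop("invalid sex value: ", bad_sex[1])
  for (col in c("father_id", "mother_id")) {
    ref <- ped[[col]]
    unresolved <- !is.na(ref) & !(ref %in% ped$id) & !(ref %in% external)
    if (any(unresolved))
      stop("parent id referenced but neither present nor declared external: ",
           ref[unresolved][1])
    # external parents are treated as absent for generation/descent purposes
    ped[[col]][!is.na(ref) & ref %in% setdiff(external, ped$id)] <- NA
  }
  if (any(!is.na(ped$father_id) & ped$father_id == ped$id) ||
      any(!is.na(ped$mother_id) & ped$mother_id == ped$id))
    stop("cycle detected: individual listed as its own parent")
  ped$generation <- .assign_generations(ped)  # also detects cycles
  structure(ped, family_id = family_id,
            class = c("pedigree", "data.frame"))
}

# iterative longest-ancestor-path generation assignment; errors on cycles
# or on a pedigree with no founder.
.assign_generations <- function(ped) {
  gen <- rep(NA_integer_, nrow(ped))
  names(gen) <- ped$id
  repeat {
    progress <- FALSE
    for (i in seq_len(nrow(ped))) {
      if (!is.na(gen[i])) next
      parents <- c(ped$father_id[i], ped$mother_id[i])
      parents <- parents[!is.na(parents)]
      if (length(parents) == 0) {
        gen[i] <- 1L
        progress <- TRUE
      } else if (all(!is.na(gen[parents]))) {
        gen[i] <- max(gen[parents]) + 1L
        progress <- TRUE
      }
    }
    if (all(!is.na(gen))) return(unname(gen))
    if (!progress)
      stop("cycle detected or no founder: generations unresolvable for ",
           paste(ped$id[is.na(gen)], collapse = ", "))
  }
}

#' Generation index of each pedigree member
#'
#' Founders (no in-pedigree parents) are generation 1; every child is
#' `max(generation(parents)) + 1` over its in-pedigree parents. The
#' assignment is deterministic and independent of row order.
#'
#' @param ped a [pedigree].
#' @return named integer vector, id -> generation.
#' @export
generations <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  stats::setNames(ped$generation, ped$id)
}

# ancestor id set (including self) via parent links
.ancestors <- function(ped, id) {
  seen <- character()
  frontier <- id
  while (length(frontier)) {
    seen <- union(seen, frontier)
    i <- match(frontier, ped$id)
    nxt <- c(ped$father_id[i], ped$mother_id[i])
    frontier <- setdiff(nxt[!is.na(nxt) & nxt %in% ped$id], seen)
  }
  seen
}

#' Blood relatives of a set of probands
#'
#' Restricts a pedigree to individuals genetically related to at least one
#' proband: those sharing a common in-pedigree ancestor with a proband
#' (including ancestors and descendants themselves). Marry-ins with no
#' such path are excluded — the subset used for genetic analyses when
#' spouses do not share the familial genetic background. A spouse who is
#' also a blood relative (e.g. a cousin marriage) is retained.
#'
#' @param ped a [pedigree].
#' @param probands non-empty character vector of member ids.
#' @return a [pedigree] restricted to blood relatives (generations
#'   recomputed on the subset).
#' @export
blood_relatives <- function(ped, probands) {
  stopifnot(inherits(ped, "pedigree"))
  if (length(probands) == 0) stop("proband set must be non-empty")
  unknown <- setdiff(probands, ped$id)
  if (length(unknown)) stop("unknown proband id: ", unknown[1])
  anc <- lapply(ped$id, function(i) .ancestors(ped, i))
  names(anc) <- ped$id
  proband_anc <- Reduce(union, anc[probands])
  keep <- vapply(anc, function(a) length(intersect(a, proband_anc)) > 0,
                 logical(1))
  sub <- ped[keep, , drop = FALSE]
  # sever parent links pointing outside the subset, then rebuild
  pedigree(
    id = sub$id,
    father_id = ifelse(sub$father_id %in% sub$id, sub$father_id, NA),
    mother_id = ifelse(sub$mother_id %in% sub$id, sub$mother_id, NA),
    sex = sub$sex, affected = sub$affected,
    family_id = attr(ped, "family_id")
  )
}

#' Check genotypes for Mendelian consistency
#'
#' For every non-founder and every SNP, tests whether the child's unphased
#' genotype can be produced by transmitting one allele from each parent's
#' genotype (enumeration over parental gamete pairs). With a single
#' in-pedigree genotyped parent the weaker requirement is that the child
#' shares at least one allele with that parent. Missing genotypes (child
#' or parent) are never flagged. SNPs are treated independently (the panel
#' is autosomal; no phasing).
#'
#' @param ped a [pedigree].
#' @param gm a [genotype_matrix]; every sample in `gm` must be a pedigree
#'   member.
#' @return data.frame with columns `individual_id, rsid, child_gt,
#'   father_gt, mother_gt, reason` — zero rows when fully consistent.
#' @export
check_mendelian <- function(ped, gm) {
  stopifnot(inherits(ped, "pedigree"), inherits(gm, "genotype_matrix"))
  extra <- setdiff(gm$samples, ped$id)
  if (length(extra)) stop("sample absent from pedigree: ", extra[1])
  out <- list()
  for (ci in seq_len(nrow(ped))) {
    child <- ped$id[ci]
    if (!(child %in% gm$samples)) next
    fa <- ped$father_id[ci]; mo <- ped$mother_id[ci]
    fa <- if (!is.na(fa) && fa %in% gm$samples) fa else NA
    mo <- if (!is.na(mo) && mo %in% gm$samples) mo else NA
    if (is.na(fa) && is.na(mo)) next
    for (ri in seq_along(gm$rsids)) {
      cg <- parse_call(gm$calls[ri, child])
      if (is.null(cg)) next
      fg <- if (!is.na(fa)) parse_call(gm$calls[ri, fa]) else NULL
      mg <- if (!is.na(mo)) parse_call(gm$calls[ri, mo]) else NULL
      ok <- mendel_consistent(cg, fg, mg)
      if (!ok) {
        out[[length(out) + 1L]] <- data.frame(
          individual_id = child, rsid = gm$rsids[ri],
          child_gt = canon_call(cg),
          father_gt = if (is.null(fg)) NA_character_ else canon_call(fg),
          mother_gt = if (is.null(mg)) NA_character_ else canon_call(mg),
          reason = if (is.null(fg) || is.null(mg))
            "no allele shared with genotyped parent"
          else "no parental gamete pair yields child genotype",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(individual_id = character(), rsid = character(),
               child_gt = character(), father_gt = character(),
               mother_gt = character(), reason = character(),
               stringsAsFactors = FALSE)
}

#' Mendelian consistency of one child call against parental calls
#'
#' @param child length-2 allele vector (child's unphased genotype).
#' @param father,mother length-2 allele vectors or `NULL` when missing.
#' @return `TRUE` when the trio (or duo) is consistent. Both parents
#'   missing is vacuously consistent.
#' @export
mendel_consistent <- function(child, father = NULL, mother = NULL) {
  if (is.null(father) && is.null(mother)) return(TRUE)
  if (!is.null(father) && !is.null(mother)) {
    target <- canon_call(child)
    for (a in father) for (b in mother)
      if (canon_call(c(a, b)) == target) return(TRUE)
    return(FALSE)
  }
  parent <- if (is.null(father)) mother else father
  any(child %in% parent)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree '%s': %d individuals, generations %s\n",
              attr(x, "family_id"), nrow(x),
              paste(sort(unique(x$generation)), collapse = ",")))
  founders <- sum(is.na(x$father_id) & is.na(x$mother_id))
  cat(sprintf("  founders: %d; affected: %d\n", founders, sum(x$affected)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a pedigree as a PLINK-dialect PED file
#'
#' @param ped a [pedigree].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  df <- data.frame(
    fid = attr(ped, "family_id"),
    id = ped$id,
    father = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mother = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = match(ped$sex, c("male", "female")) ,
    phen = ifelse(ped$affected, 2L, 1L)
  )
  df$sex[is.na(df$sex)] <- 0L
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
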