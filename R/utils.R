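#' Round half away from zero
#'
#' Base [round()] uses round-half-to-even ("banker's rounding"), which does
#' not reproduce conventionally reported summary statistics (e.g. a mean of
#' 45.75 displayed as 45.8). All reporting in this package rounds halves
#' away from zero at display time; computation is always full precision.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 1).
#' @return numeric vector rounded half-away-from-zero.
#' @examples
#' round_half_up(45.75, 1)  # 45.8
#' round_half_up(-2.5, 0)   # -3
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

logit <- function(p) log(p / (1 - p))
invlogit <- function(x) 1 / (1 + exp(-x))

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix so "chr19" and "19" compare equal.
#' @param chrom character vector of chromosome labels.
#' @return character vector without "chr" prefix.
#' @export
norm_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

# Parse an unphased diploid call "A/G" (or "A|G") into a length-2 allele
# vector; NA / "./." / "" -> NULL (missing).
parse_call <- function(call) {
  if (length(call) != 1 || is.na(call) || call %in% c("", "./.", ".|.", "."))
    return(NULL)
  al <- strsplit(call, "[/|]")[[1]]
  if (length(al) != 2 || any(al == "."))
    return(NULL)
  al
}

# sorted "A/B" string for comparisons insensitive to allele order
canon_call <- function(alleles) paste(sort(alleles), collapse = "/")

`%||%` <- function(a, b) if (is.null(a)) b else a
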