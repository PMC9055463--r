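# IUPAC nucleotide codes as 4-bit masks: A=1, C=2, G=4, T=8.
# A gap ('-') carries mask 0 and is never a valid primer character.

IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

# code character for each mask value 1..15
BITS_TO_CODE <- character(15L)
BITS_TO_CODE[IUPAC_BITS] <- names(IUPAC_BITS)

BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

POPCOUNT4 <- vapply(1:15, function(b) {
  sum(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L)
}, integer(1))

#' Convert an IUPAC DNA string to a vector of 4-bit base masks
#'
#' @param x a single character string over the IUPAC DNA alphabet
#'   (gaps are rejected; use `allow_gap = TRUE` to map '-' to 0).
#' @param allow_gap logical; accept '-' as mask 0.
#' @return integer vector of masks, one per character.
#' @keywords internal
iupac_bits <- function(x, allow_gap = FALSE) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  bits <- unname(IUPAC_BITS[chars])
  if (allow_gap) bits[chars == "-"] <- 0L
  bad <- which(is.na(bits))
  if (length(bad)) {
    stop("invalid IUPAC character '", chars[bad[1]], "' at position ", bad[1],
         " in sequence '", x, "'")
  }
  bits
}

bits_to_string <- function(bits) {
  out <- character(length(bits))
  out[bits == 0L] <- "-"
  out[bits > 0L] <- BITS_TO_CODE[bits[bits > 0L]]
  paste(out, collapse = "")
}

# complement of a 4-bit mask: A<->T, C<->G
comp_bits <- function(bits) {
  bitwOr(bitwOr(bitwShiftL(bitwAnd(bits, 1L), 3L),
                bitwShiftL(bitwAnd(bits, 2L), 1L)),
         bitwOr(bitwShiftR(bitwAnd(bits, 4L), 1L),
                bitwShiftR(bitwAnd(bits, 8L), 3L)))
}

#' Reverse complement of an IUPAC DNA string
#'
#' Ambiguity codes are complemented set-wise (R <-> Y, M <-> K, ...).
#'
#' @param x IUPAC DNA string.
#' @return the reverse complement string.
#' @export
#' @examples
#' reverse_complement("ACGT")   # "ACGT"
#' reverse_complement("RAC")    # "GTY"
reverse_complement <- function(x) {
  bits_to_string(rev(comp_bits(iupac_bits(x))))
}

#' Degeneracy of an IUPAC DNA string
#'
#' Product over positions of the number of concrete bases each code allows.
#'
#' @param x IUPAC DNA string.
#' @return integer degeneracy (1 for a concrete sequence).
#' @export
degeneracy <- function(x) {
  bits <- iupac_bits(x)
  prod(POPCOUNT4[bits])
}

#' Expand a degenerate IUPAC primer into its concrete sequences
#'
#' @param x IUPAC DNA string (no gaps, no 'N' restriction here; callers that
#'   forbid N must check degeneracy).
#' @return character vector of all ACGT expansions, lexicographically sorted;
#'   length equals `degeneracy(x)`.
#' @export
#' @examples
#' expand_degenerate("ARC")  # "AAC" "AGC"
expand_degenerate <- function(x) {
  bits <- iupac_bits(x)
  per_pos <- lapply(bits, function(b) names(BASE_BITS)[bitwAnd(b, BASE_BITS) > 0L])
  n <- prod(lengths(per_pos))
  if (n > 65536L) stop("degeneracy ", n, " too large to expand")
  grid <- expand.grid(rev(per_pos), stringsAsFactors = FALSE)
  out <- do.call(paste0, rev(grid))
  sort(out)
}

# TRUE where the template mask at each position is compatible with the primer
# mask. Under the strict policy a template base must be concrete (A/C/G/T)
# and contained in the primer's code set; under the permissive policy any
# non-empty intersection of the two sets matches.
bits_compatible <- function(template_bits, primer_bits, allow_degenerate_template = FALSE) {
  inter <- bitwAnd(template_bits, primer_bits) > 0L
  if (allow_degenerate_template) {
    inter
  } else {
    inter & template_bits %in% c(1L, 2L, 4L, 8L)
  }
}
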