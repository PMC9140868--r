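# IUPAC nucleotide alphabet tables shared by all modules.
#
# Primer bases are encoded as 4-bit masks (A=1, C=2, G=4, T=8); a degenerate
# code is the OR of its expansion. Target N carries mask 0 so it never
# matches any primer base (conservative policy for assembly gaps).

.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # G/C
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

.TARGET_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 0L)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

.iupac_letters <- names(.IUPAC_MASK)

#' Expand an IUPAC nucleotide code
#'
#' @param base single IUPAC letter.
#' @return character vector of the concrete bases (`A`, `C`, `G`, `T`) the
#'   code stands for.
#' @examples
#' iupac_expand("R")
#' @export
iupac_expand <- function(base) {
  base <- toupper(base)
  if (length(base) != 1L || is.na(.IUPAC_MASK[base]))
    stop("not an IUPAC nucleotide code: ", base)
  m <- .IUPAC_MASK[[base]]
  c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
}

#' Does a degenerate primer base match a target base?
#'
#' Vectorised over both arguments. A target `N` never matches (unsequenced
#' positions are not treated as binding sites).
#'
#' @param primer_base IUPAC letter(s) from a primer.
#' @param target_base letter(s) from a genome sequence (`A`,`C`,`G`,`T`,`N`).
#' @return logical vector.
#' @examples
#' iupac_match("R", "A")  # TRUE
#' iupac_match("R", "C")  # FALSE
#' iupac_match("W", "N")  # FALSE
#' @export
iupac_match <- function(primer_base, target_base) {
  pm <- .IUPAC_MASK[toupper(primer_base)]
  tm <- .TARGET_MASK[toupper(target_base)]
  if (anyNA(pm)) stop("illegal primer base: ",
                      paste(unique(primer_base[is.na(pm)]), collapse = ","))
  if (anyNA(tm)) stop("illegal target base: ",
                      paste(unique(target_base[is.na(tm)]), collapse = ","))
  unname(bitwAnd(pm, tm) > 0L)
}

#' Reverse complement of an IUPAC DNA string
#'
#' Honours the full 15-letter degenerate alphabet (R<->Y, M<->K, S<->S, ...).
#' An involution: `revcomp(revcomp(s)) == s`.
#'
#' @param seq character vector of IUPAC DNA strings.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("GAGRAAYTG")  # "CARTTYCTC"
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
    comp <- .IUPAC_COMPLEMENT[ch]
    if (anyNA(comp))
      stop("illegal character in sequence: ",
           paste(unique(ch[is.na(comp)]), collapse = ","))
    paste(rev(comp), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Internal: check a string is over the given alphabet; `what` names the
# offending record in the error.
.check_alphabet <- function(seq, letters, what = "sequence") {
  ch <- unique(strsplit(seq, "", fixed = TRUE)[[1L]])
  bad <- setdiff(ch, letters)
  if (length(bad))
    stop("illegal character(s) ", paste(bad, collapse = ","), " in ", what)
  invisible(TRUE)
}
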