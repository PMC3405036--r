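# IUPAC nucleotide alphabet utilities.
#
# Base sets are encoded as 4-bit masks (A = 1, C = 2, G = 4, T = 8) so that
# "could these two characters pair with a common base" is a single bitwAnd().
# Inosine (I) is special-cased throughout: it is a single synthesized base
# (multiplicity 1 for degeneracy) that anneals opposite any template base
# (full base set {A,C,G,T} for matching).

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"),
  I = c("A", "C", "G", "T")  # universal base for matching purposes
)

.BASE_BIT <- c(A = 1L, C = 2L, G = 4L, T = 8L)

.IUPAC_MASK <- vapply(.IUPAC_SETS, function(b) sum(.BASE_BIT[b]), integer(1))

# per-character degeneracy multiplicity: I counts as 1 (one synthesized oligo)
.IUPAC_MULT <- vapply(.IUPAC_SETS, length, integer(1))
.IUPAC_MULT["I"] <- 1L

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N", I = "I"
)

.GAP_CHARS <- c("-", ".")

# 256-slot lookup tables indexed by utf8 code point (fast path for scanning)
.mask_lut <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt(paste(names(.IUPAC_MASK), collapse = ""))] <- unname(.IUPAC_MASK)
  lut[utf8ToInt("-")] <- 0L
  lut[utf8ToInt(".")] <- 0L
  lut
})

iupac_alphabet <- function() names(.IUPAC_SETS)

#' Base set of an IUPAC nucleotide code
#'
#' @param x character vector of single IUPAC codes (inosine `I` allowed).
#' @return a list of character vectors, the standard bases each code stands
#'   for. `I` returns all four bases: as a universal base it can anneal
#'   opposite any template nucleotide.
#' @examples
#' iupac_base_set(c("R", "N", "I"))
#' @export
iupac_base_set <- function(x) {
  x <- toupper(x)
  bad <- !(x %in% names(.IUPAC_SETS))
  if (any(bad)) {
    stop("not an IUPAC nucleotide code: ", paste(unique(x[bad]), collapse = ", "))
  }
  .IUPAC_SETS[x]
}

# Encode a sequence string as an integer mask vector. Gaps map to 0L,
# unknown characters raise an error naming the first offending position.
seq_to_masks <- function(seq, what = "sequence") {
  codes <- utf8ToInt(toupper(seq))
  m <- .mask_lut[codes]
  if (anyNA(m)) {
    pos <- which(is.na(m))[1L]
    stop(sprintf("illegal character '%s' at position %d in %s",
                 substr(toupper(seq), pos, pos), pos, what))
  }
  m
}

# popcount for 4-bit masks
.mask_size <- function(m) {
  (m %% 2L) + (m %/% 2L %% 2L) + (m %/% 4L %% 2L) + (m %/% 8L %% 2L)
}

#' Reverse complement of an IUPAC-degenerate sequence
#'
#' Complements every character over the full IUPAC alphabet (R to Y, S to S,
#' B to V, inosine to inosine, ...) and reverses the string. Applying the
#' function twice returns the input.
#'
#' @param seq character vector of IUPAC nucleotide strings.
#' @return character vector of reverse-complemented strings.
#' @examples
#' revcomp_iupac("ATRTTRTTNGCNGCRTA")
#' @export
revcomp_iupac <- function(seq) {
  vapply(seq, function(s) {
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
    comp <- .IUPAC_COMPLEMENT[ch]
    if (anyNA(comp)) {
      stop("cannot complement non-IUPAC character in: ", s)
    }
    paste(rev(comp), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Degeneracy of a raw IUPAC string (product of per-position multiplicities,
# inosine contributing 1). Internal; user-facing wrapper in primer.R.
iupac_degeneracy <- function(seq) {
  vapply(seq, function(s) {
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
    mult <- .IUPAC_MULT[ch]
    if (anyNA(mult)) stop("non-IUPAC character in: ", s)
    prod(mult)
  }, numeric(1), USE.NAMES = FALSE)
}

# Expand a degenerate IUPAC string into its concrete oligos over {A,C,G,T,I}.
# Inosine positions are retained as I. Refuses above `cap` (combinatorial
# safety); the cap is on the expansion count, i.e. the degeneracy.
iupac_expand <- function(seq, cap = 65536L) {
  seq <- toupper(seq)
  d <- iupac_degeneracy(seq)
  if (d > cap) {
    stop(sprintf("degeneracy %d exceeds expansion cap %d for %s", d, cap, seq))
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  per_pos <- lapply(ch, function(c0) {
    if (c0 == "I") "I" else .IUPAC_SETS[[c0]]
  })
  oligos <- ""
  for (p in per_pos) {
    oligos <- as.vector(outer(oligos, p, paste0))
  }
  oligos
}
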