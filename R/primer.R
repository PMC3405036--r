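# The Primer domain type: a named degenerate oligonucleotide with
# orientation, reference binding window, target group, and provenance.

#' Construct and validate a degenerate primer
#'
#' A primer is a 5'-to-3' IUPAC-degenerate oligonucleotide (inosine `I`
#' allowed) with an orientation relative to the sense strand of the marker
#' gene, an optional binding window in reference coordinates (1-based,
#' inclusive), and a target-group code (`"universal"` for primers intended to
#' amplify all diazotrophs).
#'
#' @param name short identifier.
#' @param sequence IUPAC nucleotide string, 5' to 3'. Uppercased on input.
#' @param orientation `"forward"` or `"reverse"`. Reverse primers are written
#'   as the reverse complement of the sense strand, as synthesized.
#' @param window integer vector of length 2, reference binding window
#'   (start, end), or `NULL` when the site is not representable in reference
#'   coordinates. A window printed 3'-to-5' is normalized to start <= end.
#' @param target_group target-group code, e.g. `"universal"`, `"Fr"`, `"Cy"`.
#' @param citation free-text provenance.
#' @param flagged logical; `TRUE` for primers suspected to carry publication
#'   errors. They are kept verbatim in the registry, never silently corrected.
#' @return an object of class `nifh_primer`.
#' @examples
#' p <- nifh_primer("Nh21F", "GCIWTYTAYGGNAARGG", "forward", c(19, 35))
#' primer_degeneracy(p)
#' @export
nifh_primer <- function(name, sequence, orientation = c("forward", "reverse"),
                        window = NULL, target_group = "universal",
                        citation = NA_character_, flagged = FALSE) {
  orientation <- match.arg(orientation)
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("primer sequence must be a single character string")
  }
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("primer sequence is empty")
  m <- seq_to_masks(sequence, what = paste0("primer ", name))
  if (any(m == 0L)) {
    stop(sprintf("illegal character '%s' at position %d in primer %s",
                 substr(sequence, which(m == 0L)[1L], which(m == 0L)[1L]),
                 which(m == 0L)[1L], name))
  }
  if (!is.null(window)) {
    window <- as.integer(window)
    stopifnot(length(window) == 2L, !anyNA(window))
    if (window[1L] > window[2L]) window <- rev(window)  # e.g. printed 494-478
  }
  structure(
    list(name = as.character(name), sequence = sequence,
         orientation = orientation, window = window,
         target_group = as.character(target_group),
         citation = as.character(citation), flagged = isTRUE(flagged)),
    class = "nifh_primer"
  )
}

#' @export
print.nifh_primer <- function(x, ...) {
  win <- if (is.null(x$window)) "unmapped" else paste(x$window, collapse = "-")
  cat(sprintf("<nifh_primer> %s  %s  (%s, %s, pos %s, degeneracy %d)\n",
              x$name, x$sequence, x$orientation, x$target_group, win,
              primer_degeneracy(x)))
  invisible(x)
}

.primer_seq <- function(p) {
  if (inherits(p, "nifh_primer")) p$sequence else toupper(as.character(p))
}

#' Degeneracy of a primer
#'
#' The number of distinct oligonucleotides the degenerate primer comprises:
#' the product over positions of the IUPAC multiplicity (1 for A/C/G/T, 2 for
#' R/Y/S/W/K/M, 3 for B/D/H/V, 4 for N). Inosine contributes 1 because a
#' single inosine-bearing oligo is synthesized, even though it anneals
#' opposite any base.
#'
#' @param p a `nifh_primer` or an IUPAC sequence string (vectorized).
#' @return numeric vector of degeneracies (always >= 1).
#' @examples
#' primer_degeneracy("GGHAARGGHGGHATHGGNAARTC")  # 1296
#' @export
primer_degeneracy <- function(p) {
  if (inherits(p, "nifh_primer")) return(iupac_degeneracy(p$sequence))
  iupac_degeneracy(toupper(as.character(p)))
}

#' Expand a degenerate primer into its concrete oligonucleotides
#'
#' Every returned oligo is over the alphabet A/C/G/T/I; inosine positions are
#' retained as `I`. The size of the returned set equals
#' [primer_degeneracy()].
#'
#' @param p a `nifh_primer` or IUPAC sequence string.
#' @param cap refuse expansion when degeneracy exceeds this (combinatorial
#'   safety valve).
#' @return character vector of concrete oligos.
#' @examples
#' expand_primer("AY")  # "AC" "AT"
#' @export
expand_primer <- function(p, cap = 65536L) {
  iupac_expand(.primer_seq(p), cap = cap)
}

#' Reverse complement of a primer
#'
#' Complement per IUPAC character (inosine maps to inosine) then reverse.
#' For a `nifh_primer` the returned object keeps name, window and metadata but
#' flips the orientation; applying twice returns the original primer.
#'
#' @param p a `nifh_primer` or IUPAC sequence string.
#' @return same type as the input.
#' @export
reverse_complement <- function(p) {
  if (inherits(p, "nifh_primer")) {
    out <- p
    out$sequence <- revcomp_iupac(p$sequence)
    out$orientation <- if (p$orientation == "forward") "reverse" else "forward"
    return(out)
  }
  revcomp_iupac(.primer_seq(p))
}
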