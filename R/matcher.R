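# Mismatch-tolerant degenerate pattern scanning (the fuzznuc-equivalent
# stage). Matching is Hamming-style against the ungapped record sequence:
# alignment gaps are skipped, no indels are allowed within a hit.

#' Do two IUPAC characters match?
#'
#' Set-intersection semantics: a pattern character matches a target character
#' when their base sets share at least one base. Inosine has the full base
#' set for matching (universal base) even though it contributes 1 to
#' degeneracy. A gap on the target side never matches.
#'
#' @param pattern_char,target_char single IUPAC characters (target may also
#'   be `-` or `.`).
#' @param ambiguity `"intersect"` (default, an ambiguous database base could
#'   be the primer's base) or `"strict"` (an ambiguous target base counts as
#'   a mismatch).
#' @return logical.
#' @examples
#' char_match("R", "A")  # TRUE
#' char_match("Y", "G")  # FALSE
#' @export
char_match <- function(pattern_char, target_char,
                       ambiguity = c("intersect", "strict")) {
  ambiguity <- match.arg(ambiguity)
  pm <- seq_to_masks(pattern_char, "pattern")
  tm <- seq_to_masks(target_char, "target")
  if (ambiguity == "strict") tm[.mask_size(tm) > 1L] <- 0L
  bitwAnd(pm, tm) != 0L
}

# Per-record ungapped representation: integer masks plus the alignment
# column of each ungapped character.
.ungap_record <- function(db, i, ambiguity = "intersect") {
  m <- db$masks[[i]]
  keep <- which(m > 0L)
  masks <- m[keep]
  if (ambiguity == "strict") masks[.mask_size(masks) > 1L] <- 0L
  list(masks = masks, cols = keep)
}

# mismatch counts for every start position of pattern `p` (mask vector)
# along target masks `t`; returns integer vector of length L - m + 1
.mismatch_profile <- function(t, p) {
  L <- length(t); m <- length(p)
  n <- L - m + 1L
  if (n < 1L) return(integer(0))
  mm <- integer(n)
  for (j in seq_len(m)) {
    mm <- mm + (bitwAnd(t[j:(j + n - 1L)], p[j]) == 0L)
  }
  mm
}

#' Scan a database with a degenerate primer
#'
#' A hit places the primer against consecutive non-gap characters of a record
#' (gaps are skipped; matching is against the ungapped sequence) with at most
#' `k` positions failing [char_match()]. Reverse-orientation primers are
#' scanned as their reverse complement against the sense strand. When
#' `window` is the primer's binding window (the default), a hit must start at
#' the alignment column of the window start (within `tol` columns); with
#' `window = NULL` the whole alignment is scanned and off-target sites count.
#'
#' @param db an [aligned_db()].
#' @param primer a [nifh_primer()] (or IUPAC string, treated as a forward
#'   primer scanned over the whole alignment).
#' @param k mismatch budget (0, 1, 2, ...).
#' @param window `"binding"` to confine hits to the primer's own window,
#'   `NULL`/`"none"` for whole-alignment scanning, or an explicit
#'   reference-coordinate window.
#' @param tol start-column tolerance for window confinement (default 0).
#' @param ambiguity target-side ambiguity policy, see [char_match()].
#' @return a list of class `nifh_match`: `primer`, `k`, `hit_events` (count
#'   of (record, start) occurrences), `hit_sequences` (distinct records with
#'   at least one occurrence), `hits` (data frame: id, ref_start, ref_end,
#'   strand, mismatches) and the scanned window.
#' @export
scan_primer <- function(db, primer, k = 0L, window = "binding", tol = 0L,
                        ambiguity = c("intersect", "strict")) {
  ambiguity <- match.arg(ambiguity)
  if (!inherits(primer, "nifh_primer")) {
    primer <- nifh_primer("pattern", primer, "forward")
  }
  pat <- if (primer$orientation == "reverse") revcomp_iupac(primer$sequence)
         else primer$sequence
  p <- seq_to_masks(pat, "primer pattern")
  m <- length(p)

  win <- NULL
  if (!is.null(window) && !identical(window, "none")) {
    win <- if (identical(window, "binding")) primer$window else as.integer(window)
    if (is.null(win)) {
      stop("primer ", primer$name, " has no binding window; scan with window = NULL")
    }
  }
  win_col <- if (is.null(win)) NULL else map_window(db, win)[1L]

  hits <- list()
  n_events <- 0L
  n_seqs <- 0L
  too_short <- TRUE
  for (i in seq_along(db$ids)) {
    ug <- .ungap_record(db, i, ambiguity)
    t <- ug$masks
    if (length(t) >= m) too_short <- FALSE
    if (is.null(win_col)) {
      mm <- .mismatch_profile(t, p)
      starts <- which(mm <= k)
    } else {
      cand <- which(abs(ug$cols - win_col) <= tol)
      cand <- cand[cand + m - 1L <= length(t)]
      starts <- cand[vapply(cand, function(s) {
        sum(bitwAnd(t[s:(s + m - 1L)], p) == 0L) <= k
      }, logical(1))]
      mm <- rep(NA_integer_, length(t))
      for (s in starts) mm[s] <- sum(bitwAnd(t[s:(s + m - 1L)], p) == 0L)
    }
    if (length(starts)) {
      n_events <- n_events + length(starts)
      n_seqs <- n_seqs + 1L
      hits[[length(hits) + 1L]] <- data.frame(
        id = db$ids[i],
        ref_start = .col_to_refpos(db, ug$cols[starts]),
        ref_end = .col_to_refpos(db, ug$cols[starts + m - 1L]),
        strand = if (primer$orientation == "reverse") "-" else "+",
        mismatches = mm[starts],
        stringsAsFactors = FALSE)
    }
  }
  if (too_short && length(db$ids)) {
    warning("primer ", primer$name, " is longer than every record; zero hits")
  }
  structure(
    list(primer = primer$name, k = as.integer(k),
         hit_events = n_events, hit_sequences = n_seqs,
         window = win, ambiguity = ambiguity,
         hits = if (length(hits)) do.call(rbind, hits) else
           data.frame(id = character(), ref_start = integer(),
                      ref_end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)),
    class = "nifh_match")
}

#' @export
print.nifh_match <- function(x, ...) {
  cat(sprintf("<nifh_match> %s k=%d: %d events in %d sequences\n",
              x$primer, x$k, x$hit_events, x$hit_sequences))
  invisible(x)
}

#' Brute-force scanning oracle
#'
#' Independent reference implementation used in tests: fully expands the
#' degenerate primer and compares every expansion against every start
#' position of every ungapped record base by base, taking the minimum
#' Hamming distance over expansions. Same contract as [scan_primer()].
#'
#' @inheritParams scan_primer
#' @param cap refuse primers with degeneracy above this.
#' @return a `nifh_match` list (without a per-hit table).
#' @export
scan_oracle <- function(db, primer, k = 0L, window = "binding", tol = 0L,
                        ambiguity = c("intersect", "strict"), cap = 65536L) {
  ambiguity <- match.arg(ambiguity)
  if (!inherits(primer, "nifh_primer")) {
    primer <- nifh_primer("pattern", primer, "forward")
  }
  pat <- if (primer$orientation == "reverse") revcomp_iupac(primer$sequence)
         else primer$sequence
  expansions <- iupac_expand(pat, cap = cap)
  pmat <- lapply(expansions, seq_to_masks)
  m <- nchar(pat)

  win <- NULL
  if (!is.null(window) && !identical(window, "none")) {
    win <- if (identical(window, "binding")) primer$window else as.integer(window)
    if (is.null(win)) stop("primer has no binding window")
  }
  win_col <- if (is.null(win)) NULL else map_window(db, win)[1L]

  n_events <- 0L; n_seqs <- 0L
  for (i in seq_along(db$ids)) {
    ug <- .ungap_record(db, i, ambiguity)
    t <- ug$masks
    if (length(t) < m) next
    starts <- if (is.null(win_col)) seq_len(length(t) - m + 1L) else {
      cand <- which(abs(ug$cols - win_col) <= tol)
      cand[cand + m - 1L <= length(t)]
    }
    if (!length(starts)) next
    best <- rep(m + 1L, length(starts))
    for (e in pmat) {
      d <- integer(length(starts))
      for (j in seq_len(m)) {
        d <- d + (bitwAnd(t[starts + j - 1L], e[j]) == 0L)
      }
      best <- pmin(best, d)
    }
    nh <- sum(best <= k)
    if (nh > 0L) { n_events <- n_events + nh; n_seqs <- n_seqs + 1L }
  }
  structure(list(primer = primer$name, k = as.integer(k),
                 hit_events = n_events, hit_sequences = n_seqs,
                 window = win, ambiguity = ambiguity, hits = NULL),
            class = "nifh_match")
}
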