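# In-silico PCR for primer pairs (the primersearch-equivalent stage): both
# primers are scanned on the sense strand (the reverse primer as its reverse
# complement) and correctly oriented hit combinations become predicted
# amplicons.

#' Expected amplicon length of a primer pair
#'
#' The inclusive reference-coordinate span from the forward primer's binding
#' start to the reverse primer's binding end.
#'
#' @param pair a list with a `window` element (as from [registry_pair()]),
#'   or a numeric (start, end) window.
#' @return integer base count, or `NA` when either endpoint is not
#'   representable in reference coordinates.
#' @examples
#' expected_length(c(115, 476))  # 362
#' @export
expected_length <- function(pair) {
  w <- if (is.list(pair)) pair$window else pair
  w <- as.numeric(w)
  stopifnot(length(w) == 2L)
  if (anyNA(w)) return(NA_integer_)
  if (w[1L] > w[2L]) stop("amplicon window out of order: ", w[1L], " > ", w[2L])
  as.integer(w[2L] - w[1L] + 1L)
}

#' Predict amplicons for a primer pair
#'
#' Scans the forward primer as-is and the reverse primer as its reverse
#' complement along the (ungapped) sense strand of each record, then pairs
#' every forward hit with every reverse hit downstream of it. Product length
#' is reported both template-relative (ungapped base count between the
#' primers' outer ends, the physical PCR product length) and in reference
#' coordinates (matching the published length convention). Identical results
#' are obtained whether the template is stored gapped or ungapped.
#'
#' @param db an [aligned_db()] (or a single-record database).
#' @param pair list with `forward` and `reverse` [nifh_primer()] elements
#'   and optionally `window`/`length_printed` (see [registry_pair()]).
#' @param k mismatch budget applied to each primer separately.
#' @param max_len maximum template-relative product length; defaults to
#'   twice the pair's expected length (or unbounded when no expected length
#'   is known).
#' @return data frame with one row per predicted amplicon: `id`,
#'   `fwd_ref_start`, `rev_ref_end`, `length_ref`, `length_template`,
#'   `fwd_mm`, `rev_mm`.
#' @export
find_amplicons <- function(db, pair, k = 0L, max_len = NULL) {
  fwd <- pair$forward; rev_ <- pair$reverse
  stopifnot(inherits(fwd, "nifh_primer"), inherits(rev_, "nifh_primer"))
  if (is.null(max_len)) {
    el <- tryCatch(expected_length(pair), error = function(e) NA_integer_)
    max_len <- if (is.na(el)) Inf else 2L * el
  }
  fp <- seq_to_masks(fwd$sequence)
  rp <- seq_to_masks(revcomp_iupac(rev_$sequence))
  mf <- length(fp); mr <- length(rp)

  out <- list()
  for (i in seq_along(db$ids)) {
    ug <- .ungap_record(db, i)
    t <- ug$masks
    fmm <- .mismatch_profile(t, fp)
    fstarts <- which(fmm <= k)
    if (!length(fstarts)) next
    rmm <- .mismatch_profile(t, rp)
    rstarts <- which(rmm <= k)
    if (!length(rstarts)) next
    for (fs in fstarts) {
      for (rs in rstarts) {
        rend <- rs + mr - 1L                 # ungapped index of reverse 5' end
        len_t <- rend - fs + 1L              # template-relative product length
        if (rs <= fs + mf - 1L) next         # overlapping / wrong order
        if (len_t > max_len) next
        out[[length(out) + 1L]] <- data.frame(
          id = db$ids[i],
          fwd_ref_start = .col_to_refpos(db, ug$cols[fs]),
          rev_ref_end = .col_to_refpos(db, ug$cols[rend]),
          fwd_mm = fmm[fs], rev_mm = rmm[rs],
          length_template = len_t,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(id = character(), fwd_ref_start = integer(),
               rev_ref_end = integer(), fwd_mm = integer(),
               rev_mm = integer(), length_template = integer(),
               stringsAsFactors = FALSE)
  res$length_ref <- ifelse(is.na(res$fwd_ref_start) | is.na(res$rev_ref_end),
                           NA_integer_,
                           res$rev_ref_end - res$fwd_ref_start + 1L)
  res[, c("id", "fwd_ref_start", "rev_ref_end", "length_ref",
          "length_template", "fwd_mm", "rev_mm")]
}

#' Coverage of a primer pair in one stratum
#'
#' numerator: records yielding at least one predicted amplicon (record-level
#' counting: a pair either amplifies a template or it does not); denominator:
#' stratum records with nucleotide representation spanning *both* primer
#' binding windows. Either window unmappable gives an `NA` cell.
#'
#' @param db an [aligned_db()].
#' @param pair as for [find_amplicons()].
#' @param k mismatch budget per primer (published pair tables use 0).
#' @param stratum `"all"`, a group code, or an environment code.
#' @param rule denominator spanning rule, see [window_denominator()].
#' @param max_len passed to [find_amplicons()].
#' @return one-row `coverage_cell` data frame (see [primer_coverage()]), with
#'   a `pair` column instead of `primer`.
#' @export
pair_coverage <- function(db, pair, k = 0L, stratum = "all",
                          rule = c("endpoints", "all"), max_len = NULL) {
  rule <- match.arg(rule)
  idx <- .stratum_records(db, stratum)
  wf <- pair$forward$window; wr <- pair$reverse$window
  label <- if (!is.null(pair$label)) pair$label else
    paste0(pair$forward$name, "/", pair$reverse$name)
  if (is.null(wf) || is.null(wr)) {
    num <- NA_integer_; den <- NA_integer_
  } else {
    sub <- .subset_db(db, idx)
    sp <- window_spanning(sub, wf, rule = rule) &
          window_spanning(sub, wr, rule = rule)
    den <- sum(sp)
    amps <- find_amplicons(sub, pair, k = k, max_len = max_len)
    num <- length(intersect(unique(amps$id), sub$ids[sp]))
  }
  pct <- if (is.na(den) || den == 0L) NA_real_ else
    round_half_up(100 * num / den)
  out <- data.frame(pair = label, stratum = stratum, k = as.integer(k),
                    numerator = num, denominator = den, percent = pct,
                    stringsAsFactors = FALSE)
  class(out) <- c("coverage_cell", "data.frame")
  out
}

#' Evaluate a pair registry against a database
#'
#' One row per pair: amplicon window, expected length, database-wide
#' coverage at `k = 0` mismatches, and per-group / per-environment coverage.
#' Pairs whose windows cannot be mapped (or whose primers carry non-IUPAC
#' codes) get `NA` cells.
#'
#' @param db an [aligned_db()].
#' @param pairs a `nifh_pair_registry` ([nifh_pairs()]).
#' @param registry primer registry for name resolution.
#' @param k mismatch budget per primer.
#' @param groups,envs stratum labels.
#' @param ... passed to [pair_coverage()].
#' @return data frame of class `coverage_table`.
#' @export
evaluate_pairs <- function(db, pairs, registry = nifh_primers("all"),
                           k = 0L, groups = .GROUP_CODES, envs = .ENV_CODES,
                           ...) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- pairs[i, ]
    base <- data.frame(pair = r$pair_label, pos_start = r$pos_start,
                       pos_end = r$pos_end,
                       length = expected_length(c(r$pos_start, r$pos_end)),
                       stringsAsFactors = FALSE)
    covs <- stats::setNames(rep(NA_real_, 1L + length(groups) + length(envs)),
                            c("cov", groups, envs))
    pr <- tryCatch(registry_pair(pairs, r$pair_label, registry = registry),
                   error = function(e) NULL)
    ok <- !is.null(pr) && !is.null(pr$forward$window) &&
      !is.null(pr$reverse$window) &&
      tryCatch({ map_window(db, pr$forward$window)
                 map_window(db, pr$reverse$window); TRUE },
               error = function(e) FALSE)
    if (ok) {
      covs["cov"] <- pair_coverage(db, pr, k = k, stratum = "all", ...)$percent
      for (g in groups) {
        covs[g] <- pair_coverage(db, pr, k = k, stratum = g, ...)$percent
      }
      for (e in envs) {
        covs[e] <- pair_coverage(db, pr, k = k, stratum = e, ...)$percent
      }
    }
    cbind(base, as.data.frame(as.list(covs), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("coverage_table", "data.frame")
  out
}
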