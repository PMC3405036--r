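# Coverage statistics: match counts normalised by the number of sequences
# with nucleotide representation in the primer-binding region, stratified by
# phylogenetic group and environment.

# Tables print integer percents; half-up rounding, logged in report metadata.
round_half_up <- function(x) floor(x + 0.5)

#' Coverage of one primer in one stratum
#'
#' numerator: hit events from [scan_primer()] restricted to stratum records;
#' denominator: stratum records with nucleotide representation spanning the
#' primer's binding window ([window_denominator()]). Both use the same
#' window. Coverage can exceed 100 when a highly degenerate primer hits a
#' record at several positions (only possible with whole-alignment scanning
#' or `tol > 0`).
#'
#' @param db an [aligned_db()].
#' @param primer a [nifh_primer()] with a binding window.
#' @param k mismatch budget.
#' @param stratum `"all"`, a group code, or an environment code.
#' @param counting `"events"` (default; matches the published convention for
#'   single primers) or `"sequences"`.
#' @param rule denominator spanning rule, see [window_denominator()].
#' @param ... further arguments to [scan_primer()].
#' @return a one-row data frame (class `coverage_cell`): primer, stratum, k,
#'   numerator, denominator, percent. A zero denominator gives `NA` percent
#'   (no data available in the target region); a zero numerator with a
#'   positive denominator gives 0.
#' @export
primer_coverage <- function(db, primer, k = 0L, stratum = "all",
                            counting = c("events", "sequences"),
                            rule = c("endpoints", "all"), ...) {
  counting <- match.arg(counting)
  rule <- match.arg(rule)
  idx <- .stratum_records(db, stratum)
  if (is.null(primer$window)) {
    num <- NA_integer_; den <- NA_integer_
  } else {
    sub <- .subset_db(db, idx)
    res <- scan_primer(sub, primer, k = k, ...)
    num <- if (counting == "events") res$hit_events else res$hit_sequences
    den <- window_denominator(sub, primer$window, rule = rule)
  }
  pct <- if (is.na(den) || den == 0L) NA_real_ else
    round_half_up(100 * num / den)
  out <- data.frame(primer = primer$name, stratum = stratum, k = as.integer(k),
                    numerator = num, denominator = den, percent = pct,
                    stringsAsFactors = FALSE)
  class(out) <- c("coverage_cell", "data.frame")
  out
}

# restrict a database to a record subset (reference may drop out for group
# strata; keep the reference map from the full db by retaining ref_cols)
.subset_db <- function(db, idx) {
  out <- db
  out$ids <- db$ids[idx]
  out$seqs <- db$seqs[idx]
  out$masks <- db$masks[idx]
  out$group <- db$group[idx]
  out$envs <- db$envs[idx]
  out$ref_index <- match(db$reference_id, out$ids)  # may be NA; unused downstream
  out
}

#' Evaluate a primer registry against a database
#'
#' One row per registry primer: degeneracy, melting-temperature range,
#' database-wide coverage at each mismatch budget, and per-group /
#' per-environment coverage at `k_strata` mismatches (0 by default, the
#' published convention). Primers without a mappable binding window, or
#' written with non-IUPAC base codes, get `NA` cells. Row order follows the
#' registry.
#'
#' @param db an [aligned_db()].
#' @param registry a `nifh_registry` data frame ([nifh_primers()]).
#' @param k mismatch budgets for the database-wide columns.
#' @param groups,envs stratum labels for the stratified columns.
#' @param k_strata mismatch budget used for the stratified columns.
#' @param tm_conditions reaction conditions for the Tm columns, or `NULL` to
#'   skip Tm computation.
#' @param ... further arguments to [primer_coverage()].
#' @return data frame of class `coverage_table`.
#' @export
evaluate_registry <- function(db, registry, k = c(0L, 1L, 2L),
                              groups = .GROUP_CODES, envs = .ENV_CODES,
                              k_strata = 0L, tm_conditions = nifHeval::tm_conditions(),
                              ...) {
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    r <- registry[i, ]
    base <- data.frame(name = r$name,
                       pos_start = r$pos_start, pos_end = r$pos_end,
                       degeneracy = NA_real_, tm_min = NA_real_,
                       tm_max = NA_real_, stringsAsFactors = FALSE)
    covs <- stats::setNames(rep(NA_real_, length(k) + length(groups) + length(envs)),
                            c(paste0("cov", k), groups, envs))
    if (!r$nonstandard) {
      base$degeneracy <- primer_degeneracy(r$sequence)
      if (!is.null(tm_conditions)) {
        tr <- tryCatch(tm_range(registry_primer(registry, r$name),
                                cond = tm_conditions),
                       error = function(e) NULL)
        if (!is.null(tr)) { base$tm_min <- tr$tm_min; base$tm_max <- tr$tm_max }
      }
      if (!is.na(r$pos_start) && !is.na(r$pos_end)) {
        p <- registry_primer(registry, r$name)
        ok <- tryCatch({ map_window(db, p$window); TRUE },
                       error = function(e) FALSE)
        if (ok) {
          for (kk in k) {
            covs[paste0("cov", kk)] <-
              primer_coverage(db, p, k = kk, stratum = "all", ...)$percent
          }
          for (g in groups) {
            covs[g] <- primer_coverage(db, p, k = k_strata, stratum = g, ...)$percent
          }
          for (e in envs) {
            covs[e] <- primer_coverage(db, p, k = k_strata, stratum = e, ...)$percent
          }
        }
      }
    }
    cbind(base, as.data.frame(as.list(covs), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("coverage_table", "data.frame")
  out
}

#' Count primers falling into coverage bins
#'
#' Summarises a coverage table the way a primer survey is summarised in
#' prose: how many primers cover at least 90% of sequences, fewer than 50%,
#' at most 10%.
#'
#' @param table a `coverage_table` (or any data frame with a `cov0` column,
#'   or the column name given by `column`).
#' @param thresholds list with elements `ge`, `lt`, `le` (numeric).
#' @param column name of the percent column to bin.
#' @return named integer vector of bin counts, e.g. `ge90`, `lt50`, `le10`.
#' @export
summarize_thresholds <- function(table,
                                 thresholds = list(ge = 90, lt = 50, le = 10),
                                 column = "cov0") {
  x <- table[[column]]
  x <- x[!is.na(x)]
  out <- c(sum(x >= thresholds$ge), sum(x < thresholds$lt),
           sum(x <= thresholds$le))
  names(out) <- c(paste0("ge", thresholds$ge), paste0("lt", thresholds$lt),
                  paste0("le", thresholds$le))
  out
}
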