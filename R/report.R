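# Full-pipeline evaluation runs and report writing: the scripted layer that
# turns a database plus the primer registry into the standard set of
# machine-parsable coverage tables.

#' Run configuration for a full evaluation
#'
#' Every policy choice defaults to the documented table-reproducing
#' behavior: mismatch budgets 0/1/2 for single primers and 0 for pairs,
#' event counting for single primers and record counting for pairs,
#' intersection semantics for ambiguous database bases, half-up integer
#' rounding, endpoints spanning rule.
#'
#' @param db_fasta,metadata,reference_id input database; all `NULL` to use
#'   the packaged [fig1_fixture()].
#' @param out_dir output directory for the report bundle.
#' @param k mismatch budgets for single-primer tables.
#' @param k_pairs mismatch budget for pair tables.
#' @param ambiguity target-side ambiguity policy ([char_match()]).
#' @param rule denominator spanning rule ([window_denominator()]).
#' @param seed seed recorded in report headers (and used for the packaged
#'   fixture when no database is supplied).
#' @param tm_conditions a [tm_conditions()], or `NULL` to skip Tm columns.
#' @return list of class `run_config`.
#' @export
run_config <- function(db_fasta = NULL, metadata = NULL, reference_id = NULL,
                       out_dir = tempfile("nifheval_run_"),
                       k = c(0L, 1L, 2L), k_pairs = 0L,
                       ambiguity = c("intersect", "strict"),
                       rule = c("endpoints", "all"), seed = 2012L,
                       tm_conditions = nifHeval::tm_conditions()) {
  structure(list(db_fasta = db_fasta, metadata = metadata,
                 reference_id = reference_id, out_dir = out_dir,
                 k = as.integer(k), k_pairs = as.integer(k_pairs),
                 ambiguity = match.arg(ambiguity), rule = match.arg(rule),
                 seed = as.integer(seed), tm_conditions = tm_conditions),
            class = "run_config")
}

.config_meta <- function(cfg) {
  c(package = paste0("nifHeval ", as.character(utils::packageVersion("nifHeval"))),
    seed = cfg$seed,
    mismatch_budgets = paste(cfg$k, collapse = ","),
    pair_mismatch_budget = cfg$k_pairs,
    ambiguity_policy = cfg$ambiguity,
    spanning_rule = cfg$rule,
    counting = "events for single primers, records for pairs",
    rounding = "half-up to integer percent")
}

#' Run the full primer evaluation workflow
#'
#' Evaluates the complete packaged registry (or a user registry) against a
#' database and writes the report bundle: universal and group-specific
#' coverage tables, universal and group-specific pair tables, the positional
#' depth profile, and the primer map. All outputs are TSV with `#`-prefixed
#' metadata headers recording every policy choice, the seed, and a config
#' hash, so identical configurations yield byte-identical reports. On any
#' stage error the partial outputs are removed.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage log lines.
#' @return invisibly, a list with the tables, the depth profile, the primer
#'   map and the output directory.
#' @export
run_full_evaluation <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_line <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  t0 <- Sys.time()
  if (is.null(config$db_fasta)) {
    log_line("input", "no database supplied; generating packaged fixture (seed %d)",
             config$seed)
    db <- fig1_fixture(seed = config$seed)$db
  } else {
    log_line("input", "reading %s", config$db_fasta)
    db <- read_aligned_fasta(config$db_fasta, config$metadata,
                             config$reference_id)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  meta <- .config_meta(config)
  meta["config_hash"] <- .config_hash(config)
  emit <- function(name, df) {
    path <- file.path(config$out_dir, name)
    .write_tsv_with_meta(df, path, meta)
    written <<- c(written, path)
    path
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  out <- list(out_dir = config$out_dir)
  out$universal <- run_stage("evaluate-universal", {
    log_line("evaluate", "universal primers")
    evaluate_registry(db, nifh_primers("universal"), k = config$k,
                      tm_conditions = config$tm_conditions,
                      ambiguity = config$ambiguity, rule = config$rule)
  })
  emit("universal_coverage.tsv", out$universal)
  out$group_specific <- run_stage("evaluate-group-specific", {
    log_line("evaluate", "group-specific primers")
    evaluate_registry(db, nifh_primers("group_specific"), k = config$k,
                      tm_conditions = config$tm_conditions,
                      ambiguity = config$ambiguity, rule = config$rule)
  })
  emit("group_specific_coverage.tsv", out$group_specific)
  out$pairs_universal <- run_stage("pairs-universal", {
    log_line("pairs", "universal pairs")
    evaluate_pairs(db, nifh_pairs("universal"), k = config$k_pairs,
                   rule = config$rule)
  })
  emit("universal_pairs.tsv", out$pairs_universal)
  out$pairs_group_specific <- run_stage("pairs-group-specific", {
    log_line("pairs", "group-specific pairs")
    evaluate_pairs(db, nifh_pairs("group_specific"), k = config$k_pairs,
                   rule = config$rule)
  })
  emit("group_specific_pairs.tsv", out$pairs_group_specific)
  out$depth <- run_stage("depth", depth_profile(db))
  emit("depth_profile.tsv", as.data.frame(out$depth))
  out$primer_map <- run_stage("map", primer_map(nifh_primers("all")))
  emit("primer_map.tsv", out$primer_map)
  writeLines(c(sprintf("# %s: %s", names(meta), unname(meta)),
               sprintf("# elapsed_s: %.1f",
                       as.numeric(difftime(Sys.time(), t0, units = "secs")))),
             file.path(config$out_dir, "run_log.txt"))
  ok <- TRUE
  log_line("done", "report bundle in %s", config$out_dir)
  invisible(out)
}

.config_hash <- function(cfg) {
  keys <- cfg[c("db_fasta", "metadata", "reference_id", "k", "k_pairs",
                "ambiguity", "rule", "seed")]
  paste0("cfg-", substr(.simple_digest(paste(deparse(keys), collapse = "")), 1, 12))
}

# dependency-free stable string hash (djb2 over a split into 4 lanes)
.simple_digest <- function(s) {
  v <- utf8ToInt(s)
  h <- c(5381, 52711, 11113, 3313)
  for (i in seq_along(v)) {
    lane <- (i - 1L) %% 4L + 1L
    h[lane] <- (h[lane] * 33 + v[i]) %% 2147483647
  }
  paste(sprintf("%08x", as.integer(h)), collapse = "")
}

#' Primer map: binding windows in reference coordinates
#'
#' One row per mappable registry primer (name, ref_start, ref_end,
#' orientation), sorted by start position then name; the tabular analogue of
#' drawing every primer as a horizontal bar under the depth profile. Rows
#' without a representable window are skipped with a warning.
#'
#' @param registry a `nifh_registry`.
#' @return data frame.
#' @export
primer_map <- function(registry) {
  keep <- !is.na(registry$pos_start) & !is.na(registry$pos_end)
  if (any(!keep)) {
    warning("skipping primers without a representable binding window: ",
            paste(registry$name[!keep], collapse = ", "))
  }
  df <- data.frame(name = registry$name[keep],
                   ref_start = registry$pos_start[keep],
                   ref_end = registry$pos_end[keep],
                   orientation = registry$orientation[keep],
                   stringsAsFactors = FALSE)
  df <- df[order(df$ref_start, df$name), ]
  rownames(df) <- NULL
  df
}

#' @rdname primer_map
#' @param path output TSV path.
#' @param meta optional metadata header lines.
#' @export
write_primer_map <- function(registry, path, meta = NULL) {
  .write_tsv_with_meta(primer_map(registry), path, meta)
}
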