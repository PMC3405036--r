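# Aligned marker-gene databases: aligned FASTA plus per-record metadata,
# with one designated reference record defining the ungapped coordinate
# system that all primer binding windows are expressed in.

.GROUP_CODES <- c("Pr", "Cy", "III", "IA", "Fr", "Pb", "Ep", "IV")
.ENV_CODES <- c("Soil", "Mat", "Sea")

#' Construct an aligned database
#'
#' All sequences must share one column space (equal aligned lengths). Both
#' `-` and `.` are accepted as gap characters; sequences are uppercased. Each
#' record carries a single phylogenetic group label and a (possibly empty)
#' set of environment labels. A reference record defines the mapping between
#' alignment columns and ungapped reference positions (1-based); columns
#' where the reference has a gap are insertions relative to the reference and
#' are invisible in reference coordinates.
#'
#' @param ids character vector of record identifiers (unique).
#' @param seqs character vector of aligned sequences, same length as `ids`.
#' @param reference_id id of the reference record.
#' @param group character vector of group labels (recycled `"other"` when
#'   missing).
#' @param envs list of character vectors of environment labels per record.
#' @return an object of class `aligned_db`.
#' @export
aligned_db <- function(ids, seqs, reference_id, group = NULL, envs = NULL) {
  stopifnot(length(ids) == length(seqs), !anyDuplicated(ids))
  seqs <- toupper(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: aligned sequences have differing lengths (",
         paste(sort(unique(widths)), collapse = ", "), ")")
  }
  ri <- match(reference_id, ids)
  if (is.na(ri)) stop("reference sequence not present in database: ", reference_id)
  if (is.null(group)) group <- rep("other", length(ids))
  group[is.na(group) | !nzchar(group)] <- "other"
  if (is.null(envs)) envs <- rep(list(character()), length(ids))
  # encode every record once; scanning and denominators reuse these masks
  masks <- lapply(seq_along(ids), function(i) {
    m <- seq_to_masks(seqs[i], what = paste0("record ", ids[i]))
    if (all(m == 0L)) stop("record ", ids[i], " contains no nucleotides")
    m
  })
  ref_cols <- which(masks[[ri]] > 0L)
  db <- structure(
    list(ids = as.character(ids), seqs = seqs, masks = masks,
         group = as.character(group), envs = envs,
         reference_id = reference_id, ref_index = ri,
         ref_cols = ref_cols,        # alignment column of reference position i
         ncol = widths[1L]),
    class = "aligned_db"
  )
  db
}

#' @export
print.aligned_db <- function(x, ...) {
  cat(sprintf("<aligned_db> %d records x %d columns, reference %s (%d nt)\n",
              length(x$ids), x$ncol, x$reference_id, length(x$ref_cols)))
  cat(" groups:", paste(sprintf("%s=%d", names(table(x$group)),
                                table(x$group)), collapse = " "), "\n")
  invisible(x)
}

#' Number of records in an aligned database
#' @param db an `aligned_db`.
#' @export
db_size <- function(db) length(db$ids)

#' Length of the (ungapped) reference sequence
#' @param db an `aligned_db`.
#' @export
reference_length <- function(db) length(db$ref_cols)

#' Read an aligned FASTA database with metadata
#'
#' The FASTA must be a true alignment (uniform row widths, gap characters
#' `-` or `.`). Metadata is a tab-separated table with columns `id`, `group`
#' and `envs` (semicolon-separated environment labels); records absent from
#' the metadata get group `"other"` and no environment labels.
#'
#' @param fasta_path path to aligned FASTA.
#' @param metadata_path path to the metadata TSV, or `NULL` for none.
#' @param reference_id id of the record defining reference coordinates.
#' @return an [aligned_db()].
#' @export
read_aligned_fasta <- function(fasta_path, metadata_path = NULL, reference_id) {
  xs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(xs))
  seqs <- unname(as.character(xs))
  group <- NULL; envs <- NULL
  if (!is.null(metadata_path)) {
    md <- utils::read.delim(metadata_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "#")
    mi <- match(ids, md$id)
    group <- ifelse(is.na(mi), "other", md$group[mi])
    envs <- lapply(mi, function(i) {
      if (is.na(i) || is.na(md$envs[i]) || !nzchar(md$envs[i])) character()
      else strsplit(md$envs[i], ";", fixed = TRUE)[[1L]]
    })
  }
  aligned_db(ids, seqs, reference_id, group = group, envs = envs)
}

#' Write an aligned database to FASTA (+ metadata TSV)
#'
#' @param db an [aligned_db()].
#' @param fasta_path output FASTA path.
#' @param metadata_path output metadata TSV path, or `NULL` to skip.
#' @export
write_aligned_fasta <- function(db, fasta_path, metadata_path = NULL) {
  xs <- Biostrings::BStringSet(db$seqs)
  names(xs) <- db$ids
  Biostrings::writeXStringSet(xs, fasta_path, width = 80L)
  if (!is.null(metadata_path)) {
    md <- data.frame(id = db$ids, group = db$group,
                     envs = vapply(db$envs, paste, character(1), collapse = ";"),
                     stringsAsFactors = FALSE)
    utils::write.table(md, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Map a reference-coordinate window to alignment columns
#'
#' @param db an [aligned_db()].
#' @param window integer (start, end), 1-based inclusive reference positions.
#' @return integer (first column, last column) of the window endpoints.
#'   Errors when an endpoint lies beyond the reference (e.g. a binding site
#'   beyond the reference 3' end cannot be represented in this coordinate
#'   system).
#' @export
map_window <- function(db, window) {
  window <- as.integer(window)
  stopifnot(length(window) == 2L)
  if (anyNA(window)) stop("window contains NA reference positions")
  if (window[1L] > window[2L]) window <- rev(window)
  L <- reference_length(db)
  if (window[1L] < 1L || window[2L] > L) {
    stop(sprintf("window %d-%d outside reference coordinates 1-%d %s",
                 window[1L], window[2L], L,
                 "(binding sites beyond the reference cannot be represented)"))
  }
  db$ref_cols[window]
}

# Inverse of the reference map on a column: reference position or NA for
# insertion columns.
.col_to_refpos <- function(db, cols) {
  match(cols, db$ref_cols)
}

#' Positional sequence-depth profile
#'
#' For each reference position, the number of records whose aligned character
#' at that column is a nucleotide (gaps do not count). Columns that are
#' insertions relative to the reference are excluded, matching an export of
#' the alignment filtered through the reference sequence.
#'
#' @param db an [aligned_db()].
#' @return data frame of class `depth_profile` with columns `ref_position`
#'   and `depth` (0 <= depth <= number of records everywhere).
#' @export
depth_profile <- function(db) {
  depth <- integer(reference_length(db))
  for (m in db$masks) {
    depth <- depth + (m[db$ref_cols] > 0L)
  }
  out <- data.frame(ref_position = seq_len(reference_length(db)), depth = depth)
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' Records with nucleotide representation spanning a window
#'
#' The coverage denominator: a record counts when it has sequence data in the
#' primer-binding region. Under the default `"endpoints"` rule a record
#' counts when it carries a nucleotide at both the first and the last
#' reference position of the window (internal alignment gaps are deletions
#' and still count as representation); under `"all"` every window position
#' must be a nucleotide.
#'
#' @param db an [aligned_db()].
#' @param window reference-coordinate window (start, end).
#' @param rule `"endpoints"` (default) or `"all"`.
#' @param records optional integer/logical index restricting to a stratum.
#' @return the count of qualifying records. Use [window_spanning()] for the
#'   logical vector itself.
#' @export
window_denominator <- function(db, window, rule = c("endpoints", "all"),
                               records = NULL) {
  sp <- window_spanning(db, window, rule = rule)
  if (!is.null(records)) sp <- sp[records]
  sum(sp)
}

#' @rdname window_denominator
#' @export
window_spanning <- function(db, window, rule = c("endpoints", "all")) {
  rule <- match.arg(rule)
  cols <- map_window(db, window)
  check_cols <- if (rule == "endpoints") cols else
    db$ref_cols[window[1L]:window[2L]]
  vapply(db$masks, function(m) all(m[check_cols] > 0L), logical(1))
}

# indices of records in a stratum; stratum is "all", a group code, or an
# environment code
.stratum_records <- function(db, stratum) {
  if (identical(stratum, "all")) return(seq_along(db$ids))
  if (stratum %in% unique(db$group) || stratum %in% .GROUP_CODES) {
    return(which(db$group == stratum))
  }
  all_envs <- unique(unlist(db$envs))
  if (stratum %in% .ENV_CODES || stratum %in% all_envs) {
    return(which(vapply(db$envs, function(e) stratum %in% e, logical(1))))
  }
  stop("unknown stratum '", stratum, "'; known strata: all, groups {",
       paste(union(.GROUP_CODES, unique(db$group)), collapse = ", "),
       "}, environments {",
       paste(union(.ENV_CODES, all_envs), collapse = ", "), "}")
}

#' Write a depth profile as a two-column TSV
#'
#' @param profile a [depth_profile()].
#' @param path output path.
#' @param meta optional named character vector written as `#`-prefixed
#'   header lines.
#' @export
write_depth_profile <- function(profile, path, meta = NULL) {
  .write_tsv_with_meta(as.data.frame(profile), path, meta)
}

.write_tsv_with_meta <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
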