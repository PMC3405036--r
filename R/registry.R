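# The packaged nifH primer registry: 51 universal and 35 group-specific
# primers, and the 42 universal / 19 group-specific pairs built from them,
# transcribed from the published tables. Primers suspected to carry
# publication errors are kept verbatim and flagged, never corrected.

.registry_file <- function(which) {
  f <- switch(which,
    universal      = "primers_universal.tsv",
    group_specific = "primers_group_specific.tsv",
    pairs_universal      = "pairs_universal.tsv",
    pairs_group_specific = "pairs_group_specific.tsv",
    stop("unknown registry table: ", which)
  )
  system.file("extdata", f, package = "nifHeval", mustWork = TRUE)
}

.read_registry_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, na.strings = "NA",
                    check.names = FALSE, quote = "", encoding = "UTF-8")
}

#' Load the packaged nifH primer registry
#'
#' @param which `"universal"` (51 primers), `"group_specific"` (35 primers)
#'   or `"all"` (86).
#' @return a data frame of class `nifh_registry` with columns `name`,
#'   `sequence`, `orientation`, `pos_start`, `pos_end`, `target_group`,
#'   `citation`, `deg_printed` (the degeneracy as originally published, which
#'   for a few primers follows a different inosine convention or appears to be
#'   a misprint; see `note`), `tm_printed`, `flagged`, `nonstandard` (TRUE for
#'   primers written with non-IUPAC base codes, which are stored verbatim but
#'   excluded from matching and melting-temperature analysis), and `note`.
#' @examples
#' reg <- nifh_primers()
#' nrow(reg)  # 51
#' @export
nifh_primers <- function(which = c("universal", "group_specific", "all")) {
  which <- match.arg(which)
  if (which == "all") {
    out <- rbind(nifh_primers("universal"), nifh_primers("group_specific"))
    rownames(out) <- NULL
    return(out)
  }
  df <- .read_registry_tsv(.registry_file(which))
  df$flagged <- df$flagged == 1L
  df$nonstandard <- df$nonstandard == 1L
  df$registry <- which
  # validate every standard row on load
  for (i in which(!df$nonstandard)) {
    seq_to_masks(df$sequence[i], what = paste0("registry primer ", df$name[i]))
  }
  class(df) <- c("nifh_registry", "data.frame")
  df
}

#' Load the packaged nifH primer-pair registry
#'
#' Pairs reference primers in [nifh_primers()] by canonical name; the
#' amplicon window (`pos_start`, `pos_end`) and expected amplicon length
#' (`length_printed`) are stored as published. For every pair with a complete
#' window, `pos_start` equals the forward primer's binding start and
#' `pos_end` the reverse primer's binding end.
#'
#' @param which `"universal"` (42 pairs), `"group_specific"` (19) or `"all"`.
#' @return a data frame of class `nifh_pair_registry`.
#' @export
nifh_pairs <- function(which = c("universal", "group_specific", "all")) {
  which <- match.arg(which)
  if (which == "all") {
    out <- rbind(nifh_pairs("universal"), nifh_pairs("group_specific"))
    rownames(out) <- NULL
    return(out)
  }
  df <- .read_registry_tsv(.registry_file(paste0("pairs_", which)))
  df$registry <- which
  class(df) <- c("nifh_pair_registry", "data.frame")
  df
}

#' Turn a registry row into a nifh_primer object
#'
#' @param registry a `nifh_registry` data frame.
#' @param name primer name present in the registry.
#' @return a [nifh_primer()]. Errors for rows carrying non-IUPAC base codes
#'   (these cannot take part in matching or thermodynamics).
#' @export
registry_primer <- function(registry, name) {
  i <- match(name, registry$name)
  if (is.na(i)) stop("primer not in registry: ", name)
  r <- registry[i, ]
  if (isTRUE(r$nonstandard)) {
    stop("primer ", name, " is written with non-IUPAC base codes and is ",
         "excluded from matching and thermodynamic analysis")
  }
  window <- if (is.na(r$pos_start) || is.na(r$pos_end)) NULL else
    c(r$pos_start, r$pos_end)
  nifh_primer(r$name, r$sequence, r$orientation, window = window,
              target_group = r$target_group, citation = r$citation,
              flagged = r$flagged)
}

#' Resolve a pair-registry row into its forward and reverse primers
#'
#' @param pairs a `nifh_pair_registry` data frame.
#' @param label pair label (`pair_label` column).
#' @param registry primer registry to resolve names against; defaults to the
#'   full packaged registry.
#' @return list with elements `label`, `forward`, `reverse` (both
#'   [nifh_primer()]), `window` (amplicon window, may contain `NA`) and
#'   `length_printed`.
#' @export
registry_pair <- function(pairs, label, registry = nifh_primers("all")) {
  i <- match(label, pairs$pair_label)
  if (is.na(i)) stop("pair not in registry: ", label)
  r <- pairs[i, ]
  list(label = r$pair_label,
       forward = registry_primer(registry, r$forward),
       reverse = registry_primer(registry, r$reverse),
       window = c(r$pos_start, r$pos_end),
       length_printed = r$length_printed)
}
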