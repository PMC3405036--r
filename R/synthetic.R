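# Synthetic aligned-database generator. Real marker-gene databases are
# dominated by PCR-derived fragments of varying span, so positional depth is
# humped: high across the commonly amplified core, low at the gene termini.
# The generator emulates that structure with exact, manifest-recorded ground
# truth: fragment spans, group/environment labels, per-primer planted
# mismatch counts, alignment-insertion columns, and depth dips caused by
# reference-only positions. Every downstream statistic can therefore be
# recomputed independently from the manifest.

#' Configuration for the synthetic database generator
#'
#' @param n number of records (including the reference, always record 1).
#' @param ref_length ungapped reference length in bases.
#' @param seed integer seed; the same configuration and seed yield a
#'   byte-identical database and manifest.
#' @param primers character vector of registry primer names whose binding
#'   sites are planted exactly (0 mismatches) in the reference, or a list of
#'   [nifh_primer()] objects. Overlapping windows are resolved by base-set
#'   intersection; contradictory constraints are an error, never a silent
#'   compromise.
#' @param mm_fractions named list, one element per planted primer: numeric
#'   vector `c("1" = f1, "2" = f2, ...)` giving the fraction of
#'   window-spanning records that receive exactly that many planted
#'   mismatches in the primer's window. Counts are rounded half-up; the
#'   reference record is never mutated.
#' @param group_props named numeric, proportions of phylogenetic group
#'   labels apportioned exactly by largest remainder.
#' @param env_props named numeric, per-label fraction of records carrying
#'   each (multi-valued) environment label, apportioned the same way.
#' @param span fragment-span distribution: `"amplicon"` (most fragments
#'   cover the core region: humped depth profile), `"full"` (every record
#'   full length) or `"uniform"` (random subfragments).
#' @param core reference window most fragments cover under `"amplicon"`.
#' @param dip_positions reference positions present in the reference but
#'   deleted from every other record; they produce sharp dips in the depth
#'   profile, the signature of reference-only insertions.
#' @param insert_cols data frame with columns `after_pos`, `width`:
#'   alignment columns inserted after the given reference position in which
#'   the reference has gaps and a random half of the records carry random
#'   bases. Invisible in reference coordinates.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n = 200L, ref_length = 882L, seed = 1L,
                         primers = character(), mm_fractions = list(),
                         group_props = c(Pr = 0.35, Cy = 0.15, III = 0.15,
                                         IA = 0.1, Fr = 0.05, Pb = 0.05,
                                         Ep = 0.05, IV = 0.1),
                         env_props = c(Soil = 0.4, Mat = 0.1, Sea = 0.25),
                         span = c("amplicon", "full", "uniform"),
                         core = c(115L, 476L), dip_positions = integer(),
                         insert_cols = NULL) {
  span <- match.arg(span)
  stopifnot(n >= 1L, ref_length >= 50L,
            all(unlist(mm_fractions) >= 0), all(unlist(mm_fractions) <= 1),
            all(group_props >= 0), abs(sum(group_props) - 1) < 1e-8)
  if (length(mm_fractions) &&
      !all(names(mm_fractions) %in% .planted_names(primers))) {
    stop("mm_fractions names must be a subset of planted primers")
  }
  structure(list(n = as.integer(n), ref_length = as.integer(ref_length),
                 seed = as.integer(seed), primers = primers,
                 mm_fractions = mm_fractions, group_props = group_props,
                 env_props = env_props, span = span,
                 core = as.integer(core),
                 dip_positions = as.integer(dip_positions),
                 insert_cols = insert_cols),
            class = "synth_config")
}

.planted_names <- function(primers) {
  if (is.character(primers)) primers
  else vapply(primers, function(p) p$name, character(1))
}

.resolve_primers <- function(primers) {
  if (is.character(primers)) {
    reg <- nifh_primers("all")
    lapply(primers, function(nm) registry_primer(reg, nm))
  } else {
    primers
  }
}

# exact apportionment of n among proportions by largest remainder
largest_remainder <- function(props, n) {
  q <- props * n
  base <- floor(q + 1e-9)  # guard against upward float noise in q
  rem <- as.integer(round(n - sum(base)))
  if (rem > 0L) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Generate a synthetic aligned database with known ground truth
#'
#' Builds a random reference carrying an exact binding site for every
#' planted primer, then derives each record as a fragment of the reference
#' with the configured number of mismatches planted in each primer window.
#' Mismatch positions are chosen to be unambiguous: only at window positions
#' where the primer constrains the base (never under an N or inosine) and
#' never inside another planted primer's window, so a planted mismatch can
#' never silently create or destroy a different primer's site. Infeasible
#' requests error rather than compromise.
#'
#' @param config a [synth_config()].
#' @return list of class `nifh_synth` with elements `db` (an
#'   [aligned_db()]) and `manifest` (the complete ground truth: seed,
#'   reference, spans, labels, planted mismatch table, insertion columns).
#' @export
generate_synthetic_db <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, .generate_impl(config))
}

.generate_impl <- function(cfg) {
  L <- cfg$ref_length
  primers <- .resolve_primers(cfg$primers)
  for (p in primers) {
    if (is.null(p$window)) stop("planted primer has no binding window: ", p$name)
    if (p$window[2L] > L) stop("planted primer window beyond reference: ", p$name)
  }

  # per-position base-set constraints from all planted primers (sense strand)
  constraint <- rep(15L, L)
  cover <- rep(0L, L)  # how many planted windows cover each position
  for (p in primers) {
    pat <- if (p$orientation == "reverse") revcomp_iupac(p$sequence) else p$sequence
    masks <- seq_to_masks(pat)
    pos <- p$window[1L]:p$window[2L]
    if (length(pos) != length(masks)) {
      stop("primer ", p$name, " window span does not equal primer length")
    }
    newc <- bitwAnd(constraint[pos], masks)
    if (any(newc == 0L)) {
      stop("contradictory planting constraints at reference position(s) ",
           paste(pos[newc == 0L], collapse = ","), " involving primer ", p$name)
    }
    constraint[pos] <- newc
    cover[pos] <- cover[pos] + 1L
  }
  bases <- c("A", "C", "G", "T")
  ref <- vapply(constraint, function(m) {
    allowed <- bases[bitwAnd(m, .BASE_BIT) != 0L]
    if (length(allowed) == 1L) allowed else sample(allowed, 1L)
  }, character(1))

  # fragment spans; record 1 is the full-length reference
  n <- cfg$n
  spans <- matrix(NA_integer_, n, 2L)
  spans[1L, ] <- c(1L, L)
  if (n > 1L) {
    for (i in 2:n) {
      spans[i, ] <- switch(cfg$span,
        full = c(1L, L),
        amplicon = {
          u <- stats::runif(1)
          if (u < 0.70) {
            c(max(1L, cfg$core[1L] + sample(0:8, 1L)),
              min(L, cfg$core[2L] - sample(0:8, 1L)))
          } else if (u < 0.85) {
            c(1L, L)  # genome-derived full-length sequence
          } else {
            s <- sample.int(max(L - 150L, 1L), 1L)
            c(s, min(L, s + sample(150:500, 1L)))
          }
        },
        uniform = {
          s <- sample.int(max(L - 100L, 1L), 1L)
          c(s, min(L, s + sample(100:L, 1L)))
        })
    }
  }

  # labels: exact largest-remainder apportionment, then shuffled
  counts <- largest_remainder(cfg$group_props, n)
  group <- sample(rep(names(counts), counts))
  envs <- rep(list(character()), n)
  for (e in names(cfg$env_props)) {
    ne <- as.integer(round_half_up(cfg$env_props[[e]] * n))  # labels are independent
    idx <- sample.int(n, ne)
    for (i in idx) envs[[i]] <- c(envs[[i]], e)
  }

  # mismatch planting
  seqs_chars <- lapply(seq_len(n), function(i) ref)
  planted <- data.frame(record = integer(), primer = character(),
                        n_mm = integer(), stringsAsFactors = FALSE)
  for (p in primers) {
    fr <- cfg$mm_fractions[[p$name]]
    if (is.null(fr) || !length(fr)) next
    win <- p$window[1L]:p$window[2L]
    # only positions covered by no other planted window, where the primer
    # actually constrains the base (never under N or inosine)
    eligible_pos <- win[cover[win] == 1L & constraint[win] != 15L &
                          !(win %in% cfg$dip_positions)]
    spanning <- which(spans[, 1L] <= p$window[1L] & spans[, 2L] >= p$window[2L])
    spanning <- setdiff(spanning, 1L)  # never mutate the reference
    spanning <- sample(spanning)       # random assignment order
    counts_k <- round_half_up(as.numeric(fr) * length(spanning))
    if (sum(counts_k) > length(spanning)) {
      stop("mismatch fractions for ", p$name, " exceed the spanning records")
    }
    taken <- 0L
    for (j in seq_along(fr)) {
      n_mm <- as.integer(names(fr)[j])
      cnt <- counts_k[j]
      if (cnt == 0L) next
      if (n_mm > length(eligible_pos)) {
        stop("cannot plant ", n_mm, " unambiguous mismatches for ", p$name,
             ": only ", length(eligible_pos), " eligible window positions")
      }
      recs <- spanning[(taken + 1L):(taken + cnt)]
      taken <- taken + cnt
      for (r in recs) {
        pos_mm <- if (length(eligible_pos) == 1L) eligible_pos else
          sample(eligible_pos, n_mm)
        for (q in pos_mm) {
          allowed <- bitwAnd(constraint[q], .BASE_BIT) != 0L
          forbidden <- bases[!allowed]
          seqs_chars[[r]][q] <- if (length(forbidden) == 1L) forbidden else
            sample(forbidden, 1L)
        }
        planted <- rbind(planted, data.frame(record = r, primer = p$name,
                                             n_mm = n_mm,
                                             stringsAsFactors = FALSE))
      }
    }
  }

  # fragment trimming and reference-only dip positions
  for (i in seq_len(n)) {
    s <- seqs_chars[[i]]
    if (spans[i, 1L] > 1L) s[1:(spans[i, 1L] - 1L)] <- "-"
    if (spans[i, 2L] < L) s[(spans[i, 2L] + 1L):L] <- "-"
    if (i > 1L && length(cfg$dip_positions)) s[cfg$dip_positions] <- "-"
    seqs_chars[[i]] <- s
  }

  # optional insertion columns (reference gapped, half the records filled)
  if (!is.null(cfg$insert_cols) && nrow(cfg$insert_cols)) {
    ins <- cfg$insert_cols[order(cfg$insert_cols$after_pos, decreasing = TRUE), ,
                           drop = FALSE]
    for (r in seq_len(nrow(ins))) {
      ap <- ins$after_pos[r]; w <- ins$width[r]
      carriers <- sort(sample(2:n, max(0L, floor((n - 1L) / 2L))))
      for (i in seq_len(n)) {
        block <- if (i %in% carriers && spans[i, 1L] <= ap && spans[i, 2L] > ap) {
          sample(bases, w, replace = TRUE)
        } else rep("-", w)
        s <- seqs_chars[[i]]
        seqs_chars[[i]] <- append(s, block, after = ap)
      }
    }
  }

  ids <- c("SYNTH_REF", sprintf("SYN%04d", seq_len(n - 1L)))
  db <- aligned_db(ids, vapply(seqs_chars, paste, character(1), collapse = ""),
                   reference_id = "SYNTH_REF", group = group, envs = envs)
  manifest <- list(
    seed = cfg$seed, n = n, ref_length = L,
    reference_id = "SYNTH_REF", reference = paste(ref, collapse = ""),
    planted_primers = .planted_names(cfg$primers),
    spans = data.frame(id = ids, span_start = spans[, 1L],
                       span_end = spans[, 2L], group = group,
                       envs = vapply(envs, paste, character(1), collapse = ";"),
                       stringsAsFactors = FALSE),
    planted = if (nrow(planted)) {
      data.frame(id = ids[planted$record], primer = planted$primer,
                 n_mm = planted$n_mm, stringsAsFactors = FALSE)
    } else {
      data.frame(id = character(), primer = character(), n_mm = integer(),
                 stringsAsFactors = FALSE)
    },
    dip_positions = cfg$dip_positions,
    insert_cols = cfg$insert_cols,
    span_mode = cfg$span, core = cfg$core)
  structure(list(db = db, manifest = manifest), class = "nifh_synth")
}

#' Expected coverage of a planted primer, computed from the manifest alone
#'
#' Independent ground-truth recomputation by interval stabbing: the
#' denominator is the manifest records whose span contains the primer's
#' window (within the stratum), the numerator those among them whose planted
#' mismatch count is at most `k`.
#'
#' @param synth a `nifh_synth` (or its manifest).
#' @param primer_name planted primer name.
#' @param k mismatch budget.
#' @param stratum `"all"`, a group code, or an environment label.
#' @param registry registry used to look up the primer window.
#' @return list with `numerator`, `denominator`, `percent`.
#' @export
manifest_coverage <- function(synth, primer_name, k = 0L, stratum = "all",
                              registry = nifh_primers("all")) {
  man <- if (inherits(synth, "nifh_synth")) synth$manifest else synth
  p <- registry_primer(registry, primer_name)
  sp <- man$spans
  in_stratum <- if (identical(stratum, "all")) rep(TRUE, nrow(sp)) else {
    sp$group == stratum |
      vapply(strsplit(sp$envs, ";", fixed = TRUE),
             function(e) stratum %in% e, logical(1))
  }
  spanning <- sp$span_start <= p$window[1L] & sp$span_end >= p$window[2L]
  den_ids <- sp$id[in_stratum & spanning]
  mm <- stats::setNames(rep(0L, length(den_ids)), den_ids)
  pl <- man$planted[man$planted$primer == primer_name &
                      man$planted$id %in% den_ids, ]
  mm[pl$id] <- pl$n_mm
  num <- sum(mm <= k)
  list(numerator = num, denominator = length(den_ids),
       percent = if (length(den_ids) == 0L) NA_real_ else
         round_half_up(100 * num / length(den_ids)))
}

#' Packaged depth-profile demonstration database
#'
#' A ~300-record synthetic database whose depth profile reproduces the
#' canonical shape of a PCR-amplicon-dominated marker-gene database: maximal
#' inside the commonly amplified core (positions 115-476), lower at both
#' gene termini, with two sharp dips at reference-only positions (the
#' signature of insertions in the reference relative to the other genes).
#' A maximal mutually compatible subset of the packaged registry primers is
#' planted in the reference so the full evaluation workflow has sites to
#' find.
#'
#' @param seed integer seed.
#' @param n number of records.
#' @param dip_positions reference positions carrying the engineered dips.
#' @return a `nifh_synth` list (`db`, `manifest`); the manifest additionally
#'   records the planted primer subset.
#' @export
fig1_fixture <- function(seed = 2012L, n = 300L, dip_positions = c(199L, 350L)) {
  reg <- nifh_primers("all")
  reg <- reg[!reg$nonstandard & !is.na(reg$pos_start) & reg$pos_end <= 882L, ]
  # greedy mutually compatible planting set, registry order
  constraint <- rep(15L, 882L)
  planted <- character()
  for (i in seq_len(nrow(reg))) {
    p <- registry_primer(reg, reg$name[i])
    pat <- if (p$orientation == "reverse") revcomp_iupac(p$sequence) else p$sequence
    masks <- seq_to_masks(pat)
    pos <- p$window[1L]:p$window[2L]
    if (any(pos %in% dip_positions)) next
    newc <- bitwAnd(constraint[pos], masks)
    if (any(newc == 0L)) next
    constraint[pos] <- newc
    planted <- c(planted, p$name)
  }
  cfg <- synth_config(n = n, ref_length = 882L, seed = seed,
                      primers = planted, span = "amplicon",
                      dip_positions = dip_positions)
  generate_synthetic_db(cfg)
}

#' Write a synthetic database to disk
#'
#' Aligned FASTA, metadata TSV, and the manifest as structured JSON text.
#'
#' @param synth a `nifh_synth`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_aligned_fasta(synth$db, file.path(dir, "synthetic.fasta"),
                      file.path(dir, "metadata.tsv"))
  man <- synth$manifest
  man$insert_cols <- if (is.null(man$insert_cols)) NULL else
    as.data.frame(man$insert_cols)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
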