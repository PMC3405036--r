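# Nearest-neighbor melting temperatures. Duplex stability is summed over
# dinucleotide stacks (unified duplex parameter set) with terminal
# initiation terms; the two-state Tm at 1 M Na+ is then corrected to the
# reaction's ionic conditions. The parameter tables are plain-text data
# files so they can be swapped without touching code.

#' Reaction conditions for melting-temperature calculation
#'
#' Defaults reproduce a standard primer-analysis setting: 0.25 uM total
#' oligonucleotide, 50 mM Na+, 1.5 mM Mg2+, 0 mM dNTPs.
#'
#' @param oligo_uM total oligonucleotide concentration in micromolar.
#' @param na_mM monovalent cation concentration (mM).
#' @param mg_mM divalent magnesium concentration (mM).
#' @param dntp_mM dNTP concentration (mM); dNTPs chelate Mg2+ and are
#'   subtracted from it.
#' @param salt_method `"naeq"` (default): SantaLucia entropy correction at a
#'   monovalent-equivalent concentration, treating Mg2+ through the
#'   120*sqrt(mM) sodium-equivalent rule; `"owczarzy2008"`: the
#'   magnesium-aware inverse-Tm correction.
#' @param nn_file,inosine_file override the packaged nearest-neighbor
#'   parameter tables (TSV: stack, dh, ds).
#' @return list of class `tm_conditions`.
#' @export
tm_conditions <- function(oligo_uM = 0.25, na_mM = 50, mg_mM = 1.5,
                          dntp_mM = 0, salt_method = c("naeq", "owczarzy2008"),
                          nn_file = NULL, inosine_file = NULL) {
  stopifnot(oligo_uM > 0, na_mM >= 0, mg_mM >= 0, dntp_mM >= 0)
  structure(list(oligo_uM = oligo_uM, na_mM = na_mM, mg_mM = mg_mM,
                 dntp_mM = dntp_mM, salt_method = match.arg(salt_method),
                 nn_file = nn_file, inosine_file = inosine_file),
            class = "tm_conditions")
}

.nn_cache <- new.env(parent = emptyenv())

.nn_params <- function(cond) {
  key <- paste(cond$nn_file %||% "", cond$inosine_file %||% "")
  if (!is.null(.nn_cache[[key]])) return(.nn_cache[[key]])
  nn_file <- cond$nn_file %||%
    system.file("extdata", "nn_unified.tsv", package = "nifHeval", mustWork = TRUE)
  ino_file <- cond$inosine_file %||%
    system.file("extdata", "nn_inosine.tsv", package = "nifHeval", mustWork = TRUE)
  tab <- rbind(
    utils::read.delim(nn_file, comment.char = "#", stringsAsFactors = FALSE),
    utils::read.delim(ino_file, comment.char = "#", stringsAsFactors = FALSE))
  p <- list(dh = stats::setNames(tab$dh, tab$stack),
            ds = stats::setNames(tab$ds, tab$stack))
  .nn_cache[[key]] <- p
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.init_key <- function(base) {
  switch(base, A = "init_AT", T = "init_AT", G = "init_GC", C = "init_GC",
         I = "init_I", stop("unparameterized terminal base: ", base))
}

#' Nearest-neighbor melting temperature of a concrete oligonucleotide
#'
#' Sums stack enthalpies/entropies over consecutive dinucleotides, adds the
#' terminal initiation terms, computes the two-state Tm at 1 M Na+ with the
#' oligonucleotide concentration term (CT/4 for a non-self-complementary
#' duplex formed from equimolar strands) and applies the configured salt
#' correction. Deterministic; errors on oligos shorter than 8 nt (the
#' two-state model is not meaningful there) and on unparameterized stacks.
#'
#' @param oligo a string over A/C/G/T/I (inosine allowed; it is treated as
#'   paired opposite C with approximate averaged stack parameters).
#' @param cond a [tm_conditions()].
#' @return melting temperature in degrees Celsius.
#' @examples
#' nn_tm("TCTACGGAAAGGGCGGTATCGG")
#' @export
nn_tm <- function(oligo, cond = tm_conditions()) {
  oligo <- toupper(oligo)
  n <- nchar(oligo)
  if (n < 8L) stop("oligo shorter than 8 nt: nearest-neighbor Tm not computed")
  ch <- strsplit(oligo, "", fixed = TRUE)[[1L]]
  if (!all(ch %in% c("A", "C", "G", "T", "I"))) {
    bad <- setdiff(unique(ch), c("A", "C", "G", "T", "I"))
    stop("nn_tm requires a concrete A/C/G/T/I oligo; found: ",
         paste(bad, collapse = ", "), " (expand degenerate primers first)")
  }
  p <- .nn_params(cond)
  stacks <- paste0(ch[-n], ch[-1L])
  dh <- p$dh[stacks]; ds <- p$ds[stacks]
  if (anyNA(dh)) {
    stop("unparameterized dinucleotide stack: ",
         paste(unique(stacks[is.na(dh)]), collapse = ", "))
  }
  dh <- sum(dh) + p$dh[.init_key(ch[1L])] + p$dh[.init_key(ch[n])]
  ds <- sum(ds) + p$ds[.init_key(ch[1L])] + p$ds[.init_key(ch[n])]

  R <- 1.9872          # cal / (mol K)
  ct <- cond$oligo_uM * 1e-6
  tm1m <- 1000 * dh / (ds + R * log(ct / 4)) # Kelvin, at 1 M Na+
  fgc <- mean(ch %in% c("G", "C"))           # inosine counts as neither

  mg <- max(cond$mg_mM - cond$dntp_mM, 0) / 1000   # M free Mg2+
  mon <- cond$na_mM / 1000                         # M monovalent
  tmK <- switch(cond$salt_method,
    naeq = {
      naeq <- mon + 120 * sqrt(mg * 1000) / 1000   # sodium equivalent, M
      if (naeq <= 0) stop("no cations: salt correction undefined")
      ds_corr <- ds + 0.368 * (n - 1) * log(naeq)
      1000 * dh / (ds_corr + R * log(ct / 4))
    },
    owczarzy2008 = .owczarzy2008(tm1m, fgc, n, mon, mg)
  )
  unname(tmK - 273.15)
}

# Magnesium-aware inverse-Tm salt correction (Owczarzy et al. 2008).
.owczarzy2008 <- function(tm1m, fgc, n, mon, mg) {
  a <- 3.92e-5; b <- -9.11e-6; c <- 6.26e-5; d <- 1.42e-5
  e <- -4.82e-4; f <- 5.25e-4; g <- 8.31e-5
  use_mg <- TRUE
  if (mon > 0) {
    r <- sqrt(mg) / mon
    if (r < 0.22) use_mg <- FALSE
    else if (r < 6) {
      lm <- log(mon)
      a <- 3.92e-5 * (0.843 - 0.352 * sqrt(mon) * lm)
      d <- 1.42e-5 * (1.279 - 4.03e-3 * lm - 8.03e-3 * lm^2)
      g <- 8.31e-5 * (0.486 - 0.258 * lm + 5.25e-3 * lm^3)
    }
  }
  inv <- if (use_mg) {
    lmg <- log(mg)
    1 / tm1m + a + b * lmg + fgc * (c + d * lmg) +
      (e + f * lmg + g * lmg^2) / (2 * (n - 1))
  } else {
    lm <- log(mon)
    1 / tm1m + (4.29 * fgc - 3.95) * 1e-5 * lm + 9.40e-6 * lm^2
  }
  1 / inv
}

#' Melting-temperature range of a degenerate primer
#'
#' Minimum and maximum Tm over the primer's concrete expansions. Up to `cap`
#' expansions the range is computed exhaustively; above the cap a coordinate-
#' descent search (iteratively re-optimising each ambiguous position with the
#' others held fixed, which exploits the position-local structure of the
#' nearest-neighbor model) locates the extremes.
#'
#' @param p a [nifh_primer()] or IUPAC sequence string.
#' @param cond a [tm_conditions()].
#' @param cap maximum degeneracy for exhaustive enumeration.
#' @param method `"auto"` (enumerate up to `cap`), `"enumerate"`, or
#'   `"heuristic"` (force coordinate descent).
#' @return list of class `tm_range`: `primer`, `tm_min`, `tm_max`,
#'   `n_evaluated`.
#' @export
tm_range <- function(p, cond = tm_conditions(), cap = 65536L,
                     method = c("auto", "enumerate", "heuristic")) {
  method <- match.arg(method)
  seq <- .primer_seq(p)
  name <- if (inherits(p, "nifh_primer")) p$name else seq
  d <- iupac_degeneracy(seq)
  if (method == "auto") {
    method <- if (d <= cap) "enumerate" else "heuristic"
  }
  if (method == "enumerate") {
    if (d > cap) stop("degeneracy ", d, " exceeds enumeration cap ", cap)
    tms <- vapply(iupac_expand(seq, cap = cap), nn_tm, numeric(1),
                  cond = cond, USE.NAMES = FALSE)
    out <- list(primer = name, tm_min = min(tms), tm_max = max(tms),
                n_evaluated = length(tms))
  } else {
    out <- list(primer = name,
                tm_min = .tm_descend(seq, cond, minimize = TRUE),
                tm_max = .tm_descend(seq, cond, minimize = FALSE),
                n_evaluated = NA_integer_)
  }
  structure(out, class = "tm_range")
}

#' @export
print.tm_range <- function(x, ...) {
  cat(sprintf("<tm_range> %s: %.1f-%.1f degC\n", x$primer, x$tm_min, x$tm_max))
  invisible(x)
}

# coordinate descent over ambiguous positions; multi-start from the AT-most
# and GC-most assignments to dodge shallow local optima
.tm_descend <- function(seq, cond, minimize) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  opts <- lapply(ch, function(c0) if (c0 == "I") "I" else .IUPAC_SETS[[c0]])
  amb <- which(lengths(opts) > 1L)
  pick <- function(prefer) vapply(opts, function(o) {
    hit <- intersect(prefer, o)
    if (length(hit)) hit[1L] else o[1L]
  }, character(1))
  starts <- list(pick(c("A", "T", "C", "G")), pick(c("G", "C", "A", "T")))
  best <- NULL
  for (cur in starts) {
    repeat {
      changed <- FALSE
      for (i in amb) {
        vals <- vapply(opts[[i]], function(b) {
          cur2 <- cur; cur2[i] <- b
          nn_tm(paste(cur2, collapse = ""), cond)
        }, numeric(1))
        b <- opts[[i]][if (minimize) which.min(vals) else which.max(vals)]
        if (!identical(b, cur[i])) { cur[i] <- b; changed <- TRUE }
      }
      if (!changed) break
    }
    v <- nn_tm(paste(cur, collapse = ""), cond)
    if (is.null(best) || (minimize && v < best) || (!minimize && v > best)) {
      best <- v
    }
  }
  best
}
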