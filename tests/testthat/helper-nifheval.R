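# Shared test helpers: random-instance generators and independent oracles.

BASES <- c("A", "C", "G", "T")
IUPAC_ALL <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "I")

random_dna <- function(n, alphabet = BASES) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random degenerate primer: mostly concrete with a few ambiguity codes
random_degenerate_primer <- function(len = sample(15:22, 1), n_amb = sample(1:4, 1)) {
  ch <- sample(BASES, len, replace = TRUE)
  amb_pos <- sample(len, min(n_amb, len))
  ch[amb_pos] <- sample(c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N", "I"),
                        length(amb_pos), replace = TRUE)
  paste(ch, collapse = "")
}

# small random aligned database: ungapped random records of varying length,
# optionally with ambiguity codes sprinkled into the targets
random_db <- function(n_records = 20, len = 120, amb_frac = 0.02) {
  seqs <- vapply(seq_len(n_records), function(i) {
    ch <- sample(BASES, len, replace = TRUE)
    n_amb <- rbinom(1, len, amb_frac)
    if (n_amb > 0) {
      pos <- sample(len, n_amb)
      ch[pos] <- sample(c("R", "Y", "N", "S", "W"), n_amb, replace = TRUE)
    }
    paste(ch, collapse = "")
  }, character(1))
  aligned_db(ids = sprintf("r%03d", seq_len(n_records)), seqs = seqs,
             reference_id = "r001")
}

# ---------------------------------------------------------------------------
# Independent nearest-neighbor Tm oracle: a from-scratch summation over the
# published unified parameters, written without reference to the package's
# table files or code path. A/C/G/T only.
oracle_nn_tm <- function(seq, oligo_uM = 0.25, na_mM = 50, mg_mM = 1.5,
                         dntp_mM = 0) {
  DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
          GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0, TT = -7.9, TG = -8.5,
          AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
  DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
          CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
          TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
          CC = -19.9)
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  dh <- 0; ds <- 0
  for (i in seq_len(n - 1)) {
    st <- paste0(ch[i], ch[i + 1])
    dh <- dh + DH[[st]]; ds <- ds + DS[[st]]
  }
  for (term in ch[c(1, n)]) {
    if (term %in% c("A", "T")) { dh <- dh + 2.3; ds <- ds + 4.1 }
    else { dh <- dh + 0.1; ds <- ds - 2.8 }
  }
  # sodium equivalent: Na(mM) + 120 * sqrt(Mg(mM) - dNTP(mM))
  naeq_M <- (na_mM + 120 * sqrt(max(mg_mM - dntp_mM, 0))) / 1000
  ds <- ds + 0.368 * (n - 1) * log(naeq_M)
  1000 * dh / (ds + 1.9872 * log(oligo_uM * 1e-6 / 4)) - 273.15
}

# degeneracy-1 primers with a published Tm, transcribed with the registry
printed_tm1 <- function() {
  reg <- nifh_primers("all")
  reg <- reg[!reg$nonstandard & !is.na(reg$tm_printed), ]
  reg <- reg[!grepl("-", reg$tm_printed, fixed = TRUE), ]
  reg[primer_degeneracy(reg$sequence) == 1, c("name", "sequence", "tm_printed")]
}
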