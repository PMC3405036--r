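# Primer model, degeneracy, expansion, reverse complement, and the packaged
# registry fixtures.

test_that("validate rejects malformed sequences and accepts valid primers", {
  p <- nifh_primer("Nh21F", "GCIWTYTAYGGNAARGG", "forward", c(19, 35))
  expect_s3_class(p, "nifh_primer")
  expect_equal(nchar(p$sequence), 17)
  expect_equal(p$window, c(19L, 35L))

  expect_error(nifh_primer("x", ""), "empty")
  expect_error(nifh_primer("x", "ACGU"), "position 4")
  expect_error(nifh_primer("x", "AC-GT"), "position 3")
  # lowercase is uppercased, printed 3'-5' windows are normalized
  p2 <- nifh_primer("nifH3", "atrttrttngcngcrta", "reverse", c(494, 478))
  expect_equal(p2$sequence, "ATRTTRTTNGCNGCRTA")
  expect_equal(p2$window, c(478L, 494L))
})

test_that("degeneracy follows the per-position multiplicity product, I -> 1", {
  expect_equal(primer_degeneracy("GCIWTYTAYGGNAARGG"), 64)       # Nh21F
  expect_equal(primer_degeneracy("GGHAARGGHGGHATHGGNAARTC"), 1296) # MehtaF
  expect_equal(primer_degeneracy("ACGT"), 1)
  expect_equal(primer_degeneracy("NN"), 16)
  expect_equal(primer_degeneracy("IIII"), 1)
  # multiplicative in concatenation
  for (i in 1:20) {
    a <- random_degenerate_primer(8); b <- random_degenerate_primer(8)
    expect_equal(primer_degeneracy(paste0(a, b)),
                 primer_degeneracy(a) * primer_degeneracy(b))
  }
})

test_that("expansion size equals degeneracy and retains inosine", {
  expect_setequal(expand_primer("AY"), c("AC", "AT"))
  ex <- expand_primer("TGYGAYCCIAAIGCIGA")  # F2
  expect_length(ex, 4)
  expect_true(all(substr(ex, 9, 9) == "I" & substr(ex, 12, 12) == "I" &
                    substr(ex, 15, 15) == "I"))
  expect_error(expand_primer("NNNNNNNNN", cap = 1000), "cap")
  withr::with_seed(11, {
    for (i in 1:25) {
      s <- random_degenerate_primer()
      expect_length(expand_primer(s), primer_degeneracy(s))
    }
  })
})

test_that("expand agrees with degeneracy for every packaged primer", {
  reg <- nifh_primers("all")
  std <- reg[!reg$nonstandard, ]
  for (i in seq_len(nrow(std))) {
    expect_length(expand_primer(std$sequence[i]),
                  primer_degeneracy(std$sequence[i]))
  }
})

test_that("reverse complement is an involution and preserves degeneracy", {
  expect_equal(revcomp_iupac("A"), "T")
  expect_equal(revcomp_iupac("ATRTTRTTNGCNGCRTA"), "TAYGCNGCNAAYAAYAT")
  # set-level check: expansions of the revcomp equal revcomps of expansions
  # (inosine-free primer so plain complementation applies)
  s <- "ATRTTRTTNGCNGCRTA"
  rc_of_exp <- vapply(expand_primer(s), function(e) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(e, "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  expect_setequal(expand_primer(revcomp_iupac(s)), rc_of_exp)
  withr::with_seed(12, {
    for (i in 1:25) {
      s <- random_degenerate_primer()
      expect_equal(revcomp_iupac(revcomp_iupac(s)), s)
      expect_equal(primer_degeneracy(revcomp_iupac(s)), primer_degeneracy(s))
    }
  })
  p <- nifh_primer("R6", "TCIGGIGARATGATGGC", "reverse", c(457, 473))
  expect_equal(reverse_complement(reverse_complement(p)), p)
})

test_that("packaged registry fixtures are complete and well-formed", {
  u <- nifh_primers("universal")
  g <- nifh_primers("group_specific")
  expect_equal(nrow(u), 51)
  expect_equal(nrow(g), 35)
  expect_false(anyDuplicated(c(u$name, g$name)) > 0)
  expect_true(all(u$target_group == "universal"))
  expect_true(all(g$target_group %in%
    c("BR", "Fr", "AP", "R", "RA", "AM", "Cy", "AB", "GP", "AN", "MS", "Cs", "TB")))
  # every standard primer's window span equals its length
  all_p <- rbind(u, g)
  std <- all_p[!all_p$nonstandard & !is.na(all_p$pos_start), ]
  expect_equal(std$pos_end - std$pos_start + 1, nchar(std$sequence))
  # flagged suspect primers are present, verbatim
  expect_setequal(all_p$name[all_p$flagged],
                  c("roeschF-1b", "nifHRb", "YAA-poly", "AMR-R"))
  pu <- nifh_pairs("universal")
  pg <- nifh_pairs("group_specific")
  expect_equal(nrow(pu), 42)
  expect_equal(nrow(pg), 19)
  # every pair resolves to registry primers
  expect_true(all(c(pu$forward, pg$forward, pu$reverse, pg$reverse) %in% all_p$name))
})

test_that("computed degeneracy matches the published values, with documented exceptions", {
  reg <- nifh_primers("all")
  std <- reg[!reg$nonstandard & !is.na(reg$deg_printed), ]
  computed <- primer_degeneracy(std$sequence)
  mismatch <- std$name[computed != std$deg_printed]
  # F1, ChenBR1 and ChenBR2 were published with inosine counted as 4;
  # KAD3 and nifH-c1-rev printed values are inconsistent with any convention
  # (registry notes record this). Everything else agrees exactly.
  expect_setequal(mismatch, c("F1", "KAD3", "ChenBR1", "nifH-c1-rev", "ChenBR2"))
  # the inosine-as-4 trio matches under that convention
  i4 <- function(s) {
    primer_degeneracy(s) * 4^lengths(regmatches(s, gregexpr("I", s)))
  }
  sub <- std[std$name %in% c("F1", "ChenBR1", "ChenBR2"), ]
  expect_equal(i4(sub$sequence), as.numeric(sub$deg_printed))
})

test_that("nonstandard primers are stored verbatim but refused for analysis", {
  reg <- nifh_primers("universal")
  expect_true(all(c("PicenoF44", "PicenoR436") %in% reg$name[reg$nonstandard]))
  expect_match(reg$sequence[reg$name == "PicenoF44"], "(P/K)", fixed = TRUE)
  expect_error(registry_primer(reg, "PicenoF44"), "non-IUPAC")
})
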