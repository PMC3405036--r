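# In-silico PCR for primer pairs.

test_that("expected_length follows the inclusive reference-span convention", {
  expect_equal(expected_length(c(115, 476)), 362)
  expect_equal(expected_length(c(31, 494)), 464)
  expect_equal(expected_length(c(7, 7)), 1)
  expect_error(expected_length(c(476, 115)), "out of order")
  expect_true(is.na(expected_length(c(759, NA))))
})

test_that("every packaged pair's printed length matches its window span", {
  pairs <- nifh_pairs("all")
  expect_equal(nrow(pairs), 61)
  has_win <- !is.na(pairs$pos_start) & !is.na(pairs$pos_end)
  expect_equal(sum(!has_win), 1)  # only the pair beyond the reference 3' end
  lens <- vapply(which(has_win), function(i)
    expected_length(c(pairs$pos_start[i], pairs$pos_end[i])), integer(1))
  expect_equal(lens, pairs$length_printed[has_win])
  # pair windows agree with the constituent primers' windows
  reg <- nifh_primers("all")
  for (i in which(has_win)) {
    f <- reg[reg$name == pairs$forward[i], ]
    r <- reg[reg$name == pairs$reverse[i], ]
    expect_equal(f$pos_start, pairs$pos_start[i], info = pairs$pair_label[i])
    expect_equal(r$pos_end, pairs$pos_end[i], info = pairs$pair_label[i])
  }
})

test_that("find_amplicons predicts correctly oriented products", {
  sy <- generate_synthetic_db(synth_config(n = 2, seed = 71,
                                           primers = c("F2", "R6"),
                                           span = "full"))
  pr <- registry_pair(nifh_pairs("universal"), "F2/R6")
  amps <- find_amplicons(sy$db, pr, k = 0)
  expect_gte(nrow(amps), 2)
  one <- amps[amps$id == "SYNTH_REF", ][1, ]
  expect_equal(one$fwd_ref_start, 115)
  expect_equal(one$rev_ref_end, 473)
  expect_equal(one$length_ref, 359)
  expect_equal(one$length_template, 359)  # ungapped template

  # template lacking the reverse site -> empty
  trunc <- aligned_db("t", paste0(substr(sy$manifest$reference, 1, 300),
                                  strrep("-", 582)), "t")
  expect_equal(nrow(find_amplicons(trunc, pr, k = 0)), 0)
})

test_that("multiple forward sites produce one prediction per combination", {
  fsite <- "TGCGATCCTAAAGCTGA"                      # matches F2 exactly
  rsite <- revcomp_iupac("TCAGGAGAAATGATGGC")       # sense-strand R6 site
  tmpl <- paste0("GG", fsite, strrep("A", 10), fsite, strrep("A", 10), rsite, "GG")
  db <- aligned_db("t", tmpl, "t")
  pr <- list(forward = nifh_primer("F2", "TGYGAYCCIAAIGCIGA", "forward"),
             reverse = nifh_primer("R6", "TCIGGIGARATGATGGC", "reverse"))
  amps <- find_amplicons(db, pr, k = 0, max_len = 1000)
  expect_equal(nrow(amps), 2)
  # brute-force enumeration over planted site positions
  fpos <- c(3, 3 + nchar(fsite) + 10)
  rend <- 2 + 2 * nchar(fsite) + 20 + nchar(rsite)
  expect_setequal(amps$fwd_ref_start, fpos)
  expect_true(all(amps$rev_ref_end == rend))
  expect_setequal(amps$length_template, rend - fpos + 1)
})

test_that("amplicon predictions are identical for gapped and ungapped templates", {
  sy <- generate_synthetic_db(synth_config(n = 1, seed = 72,
                                           primers = c("F2", "R6"),
                                           span = "full"))
  pr <- registry_pair(nifh_pairs("universal"), "F2/R6")
  ref <- sy$manifest$reference
  ch <- strsplit(ref, "")[[1]]
  withr::with_seed(73, {
    gapped <- paste(unlist(lapply(ch, function(c0)
      if (runif(1) < 0.2) c(c0, "-") else c0)), collapse = "")
  })
  a0 <- find_amplicons(aligned_db("t", ref, "t"), pr, k = 0)
  a1 <- find_amplicons(aligned_db("t", gapped, "t"), pr, k = 0)
  expect_equal(a1$length_template, a0$length_template)
  expect_equal(a1$fwd_mm, a0$fwd_mm)
  expect_equal(nrow(a1), nrow(a0))
})

test_that("pair coverage recovers planted fractions and respects bounds", {
  cfg <- synth_config(n = 100, seed = 74, primers = c("F2", "R6"),
                      mm_fractions = list(F2 = c(`1` = 0.4)), span = "full")
  sy <- generate_synthetic_db(cfg)
  pr <- registry_pair(nifh_pairs("universal"), "F2/R6")
  pc <- pair_coverage(sy$db, pr, k = 0)
  # exactly the records without a planted F2 mismatch amplify
  want <- manifest_coverage(sy, "F2", k = 0)
  expect_equal(pc$numerator, want$numerator)
  expect_equal(pc$denominator, 100)
  expect_equal(pc$percent, 60)
  # conjunction bound: pair coverage <= each primer's coverage on the
  # both-windows denominator set
  for (nm in c("F2", "R6")) {
    expect_lte(pc$percent,
               primer_coverage(sy$db, registry_pair(nifh_pairs("universal"),
                                                    "F2/R6")[[
                 if (nm == "F2") "forward" else "reverse"]], k = 0)$percent)
  }
  # non-decreasing in k
  expect_lte(pc$percent, pair_coverage(sy$db, pr, k = 1)$percent)
})

test_that("evaluate_pairs yields full tables with NA for unmappable pairs", {
  sy <- generate_synthetic_db(synth_config(n = 30, seed = 75, span = "full",
                                           primers = c("F2", "R6")))
  pu <- evaluate_pairs(sy$db, nifh_pairs("universal"))
  pg <- evaluate_pairs(sy$db, nifh_pairs("group_specific"))
  expect_equal(nrow(pu), 42)
  expect_equal(nrow(pg), 19)
  expect_equal(pu$cov[pu$pair == "F2/R6"], 100)
  expect_true(is.na(pu$cov[pu$pair == "PicenoF44/PicenoR436"]))
  expect_true(is.na(pg$cov[pg$pair == "FGPH750/FGPD913"]))
})
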