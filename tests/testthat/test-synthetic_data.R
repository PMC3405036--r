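# The synthetic-database generator and its manifest contract.

test_that("generation is byte-identical for a fixed seed", {
  cfg <- synth_config(n = 60, seed = 91, primers = c("F2", "R6"),
                      mm_fractions = list(F2 = c(`1` = 0.2)))
  a <- generate_synthetic_db(cfg)
  b <- generate_synthetic_db(cfg)
  expect_identical(a$db$seqs, b$db$seqs)
  expect_identical(a$manifest, b$manifest)
  # written artefacts are byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic(a, d1); write_synthetic(b, d2)
  for (f in c("synthetic.fasta", "metadata.tsv", "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the database
  c2 <- generate_synthetic_db(synth_config(n = 60, seed = 92,
                                           primers = c("F2", "R6"),
                                           mm_fractions = list(F2 = c(`1` = 0.2))))
  expect_false(identical(a$db$seqs, c2$db$seqs))
})

test_that("group proportions are apportioned exactly by largest remainder", {
  cfg <- synth_config(n = 10, seed = 93, group_props = c(Pr = 0.5, Cy = 0.5))
  sy <- generate_synthetic_db(cfg)
  expect_equal(sort(as.vector(table(sy$db$group))), c(5L, 5L))
  cfg2 <- synth_config(n = 7, seed = 94,
                       group_props = c(Pr = 0.5, Cy = 0.3, III = 0.2))
  tab <- table(generate_synthetic_db(cfg2)$db$group)
  expect_equal(sum(tab), 7)
  expect_equal(unname(tab[c("Pr", "Cy", "III")]), c(4L, 2L, 1L),
               ignore_attr = TRUE)
})

test_that("planted fractions convert to coverage by construction", {
  cfg <- synth_config(n = 100, seed = 95, primers = c("F2", "R6"),
                      mm_fractions = list(F2 = c(`1` = 0.3)), span = "full")
  sy <- generate_synthetic_db(cfg)
  p <- registry_primer(nifh_primers("all"), "F2")
  expect_equal(primer_coverage(sy$db, p, k = 0)$percent, 70)
  expect_equal(primer_coverage(sy$db, p, k = 1)$percent, 100)
  # cross-checked by the expansion oracle
  expect_equal(scan_oracle(sy$db, p, 0)$hit_sequences, 70)
})

test_that("manifest and FASTA are mutually consistent", {
  cfg <- synth_config(n = 50, seed = 96, primers = c("F2", "R6"),
                      mm_fractions = list(F2 = c(`1` = 0.2, `2` = 0.1)),
                      span = "amplicon")
  sy <- generate_synthetic_db(cfg)
  ref <- strsplit(sy$manifest$reference, "")[[1]]
  sp <- sy$manifest$spans
  for (i in seq_len(db_size(sy$db))) {
    ch <- strsplit(sy$db$seqs[i], "")[[1]]
    nt <- which(ch != "-")
    # re-derive the span from the FASTA
    expect_equal(range(nt), c(sp$span_start[i], sp$span_end[i]),
                 ignore_attr = TRUE)
  }
  # re-derive planted mismatch counts in the F2 window by alignment to the
  # known reference
  win <- 115:131
  pl <- sy$manifest$planted
  for (i in which(sp$span_start <= 115 & sp$span_end >= 131)) {
    ch <- strsplit(sy$db$seqs[i], "")[[1]]
    diffs <- sum(ch[win] != ref[win])
    want <- pl$n_mm[pl$id == sp$id[i] & pl$primer == "F2"]
    expect_equal(diffs, if (length(want)) want else 0L)
  }
})

test_that("contradictory or infeasible planting requests error out", {
  # fully overlapping windows demanding different concrete bases
  expect_error(generate_synthetic_db(
    synth_config(n = 10, seed = 97,
                 primers = c("nifH-a2-forB", "nifH-g1-forB"))),
    "contradictory")
  # overlapping identical windows leave no unambiguous positions to mutate
  expect_error(generate_synthetic_db(
    synth_config(n = 10, seed = 97, primers = c("F2", "nifH2"),
                 mm_fractions = list(F2 = c(`1` = 0.5)))),
    "eligible")
  expect_error(synth_config(n = 10, mm_fractions = list(F2 = c(`1` = 0.5))),
               "subset of planted")
})

test_that("fig1 fixture has the canonical humped profile with engineered dips", {
  fx <- fig1_fixture(seed = 98, n = 120)
  dp <- depth_profile(fx$db)
  n <- db_size(fx$db)
  expect_true(all(dp$depth <= n))
  core <- dp$depth[115:476]
  # maximal in the core, under-represented termini
  expect_true(which.max(dp$depth) %in% 115:476)
  expect_lt(dp$depth[1], max(core))
  expect_lt(dp$depth[nrow(dp)], max(core))
  # dips exactly at the manifest positions: only the reference remains
  dips <- fx$manifest$dip_positions
  expect_equal(dp$depth[dips], c(1L, 1L))
  expect_gt(dp$depth[dips[1] - 1], 1)
  expect_gt(dp$depth[dips[2] + 1], 1)
  # depth away from dips dominates terminal depth
  expect_gt(stats::median(core), dp$depth[1])
})

test_that("round trip: evaluation of a generated database matches its manifest", {
  cfg <- synth_config(
    n = 150, seed = 99,
    primers = c("Nh21F", "KAD3", "R6", "nifHI"),
    mm_fractions = list(Nh21F = c(`1` = 0.15), KAD3 = c(`1` = 0.3, `2` = 0.05),
                        R6 = c(`1` = 0.1), nifHI = c(`2` = 0.25)),
    span = "amplicon")
  sy <- generate_synthetic_db(cfg)
  reg <- nifh_primers("all")
  for (nm in cfg$primers) {
    for (k in 0:2) {
      for (st in c("all", "Pr", "IV", "Mat")) {
        got <- primer_coverage(sy$db, registry_primer(reg, nm), k, st)
        want <- manifest_coverage(sy, nm, k, st)
        expect_equal(got$percent, want$percent,
                     info = sprintf("%s k=%d %s", nm, k, st))
      }
    }
  }
})
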