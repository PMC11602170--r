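test_that("part validation enforces ORF and synTCE invariants", {
  expect_error(part("x", "orf", "GCUAUGUAA"), "begin with AUG")
  expect_error(part("x", "orf", "AUGGCUA"), "multiple of 3")
  expect_error(part("x", "orf", "AUGGCUGCA"), "end with a stop")
  expect_error(part("x", "orf", "AUGUAAGCUUAA"), "internal in-frame stop")
  expect_s3_class(part("x", "orf", "AUGGCUUAA"), "part")
  expect_error(part("t", "syntce", "GCUA"), "stem_len")
  expect_error(part("x", "bogus", "AUG"))
})

test_that("operons assemble with URAUG junctions and shifted frames", {
  reg <- fixture_registry()
  tce1 <- fixture_syntce("GCAGCC", "tce1")
  tce2 <- fixture_syntce("CCAGGC", "tce2")
  op <- assemble_operon(list(reg$gfp, tce1, reg$mcherry, tce2, reg$tagbfp))
  expect_equal(length(op$junctions), 2)
  cds <- op$annotations[op$annotations$role == "CDS", ]
  expect_equal(nrow(cds), 3)
  s <- unclass(op$transcript)
  # re-translation oracle: each CDS starts AUG, is stop-free, ends at a stop
  for (k in seq_len(nrow(cds))) {
    sub <- substr(s, cds$start[k] + 1, cds$end[k])
    expect_equal(substr(sub, 1, 3), "AUG")
    expect_equal(scan_stop_codons(sub, 0), nchar(sub) - 3L)
  }
  # successive CDS frames follow the junction arithmetic
  expect_equal(cds$frame[2], junction_frame(cds$frame[1]))
  expect_equal(cds$frame[3], junction_frame(cds$frame[2]))
  # each junction URAUG is found where annotated
  for (j in op$junctions) {
    expect_true(j$stop_start %in% find_overlap_motif(s))
  }
  # illegal layouts
  expect_error(assemble_operon(list(reg$gfp, reg$mcherry)), "illegal part order")
  expect_error(assemble_operon(list(tce1, reg$gfp)), "illegal part order")
})

test_that("synTCE chaining is associative", {
  reg <- fixture_registry()
  tce1 <- fixture_syntce("GCAGCC", "tce1")
  tce2 <- fixture_syntce("CCAGGC", "tce2")
  full <- assemble_operon(list(reg$gfp, tce1, reg$mcherry, tce2, reg$tagbfp))
  head2 <- assemble_operon(list(reg$gfp, tce1, reg$mcherry))
  # appending (tce2, tagbfp) to the two-output transcript reproduces the
  # three-output transcript residue-for-residue
  manual <- paste0(substr(unclass(head2$transcript), 1,
                          nchar(unclass(head2$transcript)) - 3),
                   unclass(tce2$sequence), unclass(reg$tagbfp$sequence))
  expect_equal(unclass(full$transcript), manual)
})

test_that("junction validation computes distance, class and warnings", {
  reg <- fixture_registry()
  tce <- fixture_syntce()
  op <- assemble_operon(list(reg$gfp, tce, reg$mcherry))
  rep1 <- validate_junction(op, 1, MODEL, CONFIG)
  expect_equal(rep1$intergenic_distance, -1L)
  expect_equal(rep1$distance_class, "optimal")
  expect_true(rep1$structure_check$pass)
  expect_length(rep1$warnings, 0)
  # long upstream run: build an oversized upstream ORF (~3.5 kb); SD-like
  # scrubbing is off here (irrelevant to the warning and costly at this size)
  fs <- fixture_spec(exclude_sd_like = FALSE, seed = 5)
  big <- make_fixture_orf(fs, "big", length = 3498, seed = 5)
  op2 <- assemble_operon(list(big, tce, reg$mcherry))
  rep2 <- validate_junction(op2, 1, MODEL, CONFIG)
  expect_match(rep2$warnings[1], "converged")
  mid <- make_fixture_orf(fs, "mid", length = 1200, seed = 6)
  op3 <- assemble_operon(list(mid, tce, reg$mcherry))
  rep3 <- validate_junction(op3, 1, MODEL, CONFIG)
  expect_match(rep3$warnings[1], "decay")
})

test_that("distance_class is a pure function of intergenic distance", {
  d <- -1:30
  cls <- distance_class(d)
  expect_equal(cls[d >= -1 & d <= 5], rep("optimal", 7))
  expect_equal(cls[d >= 6 & d <= 14], rep("degrading", 9))
  expect_equal(cls[d >= 15], rep("poor", 16))
  expect_error(distance_class(-2), "below")
})

test_that("gate layouts validate counts, frames and truth tables", {
  reg <- fixture_registry()
  sw <- function(nm, n = 20) part(nm, "switch",
                                  paste(rep("ACG", n), collapse = ""))
  g_or <- gate_layout("OR", list(sw("A"), sw("B")), list(reg$gfp))
  expect_equal(sum(g_or$annotations$role == "switch"), 2)
  expect_equal(g_or$truth_table$expected,
               c("OFF", "ON", "ON", "ON"))
  g_or6 <- gate_layout("OR", lapply(LETTERS[1:6], sw), list(reg$gfp))
  expect_equal(sum(g_or6$annotations$role == "switch"), 6)
  expect_error(gate_layout("OR", lapply(LETTERS[1:7], sw), list(reg$gfp)),
               "unsupported")
  expect_error(gate_layout("OR", list(sw("A"),
                                      part("B", "switch", "ACGA")),
                           list(reg$gfp)), "multiple")
  and_sw <- part("split", "switch", paste(rep("CAG", 15), collapse = ""),
                 metadata = list(inputs = c("A", "B")))
  g_and <- gate_layout("AND", list(and_sw), list(reg$gfp))
  expect_equal(g_and$truth_table$expected, c("OFF", "OFF", "OFF", "ON"))
  g_nand <- gate_layout("NAND", list(sw("A"), sw("B")), list(reg$gfp))
  expect_equal(g_nand$truth_table$expected, c("ON", "ON", "ON", "OFF"))
  g_nimply <- gate_layout("NIMPLY", list(and_sw), list(reg$gfp))
  expect_equal(g_nimply$truth_table$expected, c("OFF", "ON", "OFF", "OFF"))
  # multi-output gate
  g_mo <- gate_layout("OR", list(sw("A"), sw("B")),
                      list(reg$gfp, reg$mcherry),
                      list(fixture_syntce()))
  expect_equal(length(g_mo$junctions), 1)
})

test_that("internal RBS scanning finds planted sites and is threshold-monotone", {
  planted <- paste0("CCGCCGCAC", "AGAGGAGA", "CAUCC", "AUGGCACAC")
  hits <- scan_internal_rbs(planted, MODEL, CONFIG, threshold = -2)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$position, 22)
  # negative control: SD-free fixture linker
  fs <- fixture_spec(seed = 8)
  lnk <- make_fixture_linker(fs, "lnk", length = 120, seed = 8)
  clean_hits <- scan_internal_rbs(unclass(lnk$sequence), MODEL, CONFIG,
                                  threshold = -2)
  expect_equal(nrow(clean_hits), 0)
  # relaxing the threshold can only add hits
  n_prev <- 0
  for (th in c(-8, -6, -4, -2, 0, 5, 30)) {
    n <- nrow(scan_internal_rbs(planted, MODEL, CONFIG, threshold = th))
    expect_gte(n, n_prev)
    n_prev <- n
  }
})
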