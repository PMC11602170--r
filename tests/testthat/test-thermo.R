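test_that("energy model loads a complete, sane parameter table", {
  expect_s3_class(MODEL, "energy_model")
  expect_length(MODEL$stacks, 36)
  expect_true(all(as.character(3:30) %in% names(MODEL$hairpin)))
  expect_true(all(MODEL$hairpin >= 0))
  # non-decreasing beyond loop size 9 (logarithmic regime)
  sizes <- 9:30
  vals <- MODEL$hairpin[as.character(sizes)]
  expect_true(all(diff(vals) >= 0))
  expect_gt(hairpin_loop_penalty(40, MODEL), hairpin_loop_penalty(30, MODEL))
})

test_that("stem_dG equals the manual table summation", {
  expect_equal(stem_dG("", MODEL), 0)
  expect_equal(stem_dG("A", MODEL), 0)
  # hand-summed from the shipped table: GC/CG and CG/GC stacks alternate
  expect_equal(stem_dG("GCGCGC", MODEL), -15.0)
  expect_equal(stem_dG("AUAUAU", MODEL), -4.9)
  stems <- c("GC", "AU", "GU", "GGG", "CCC", "AAAA", "ACGU", "GCAGCC",
             "CCAGGC", "UUGGCC", "GAUCGA", "AGCUAGCU", "GGGGCCCC",
             "AUGCAUGC", "CGCGCGCG", "UAUAUAUA", "GCGUACGC", "CAGUCAGU",
             "GGAUCCGG", "AAGGCCUU")
  for (s in stems) {
    expect_equal(stem_dG(s, MODEL), oracle_stem_dG(s), info = s)
  }
  expect_lt(stem_dG("GCGCGC", MODEL), stem_dG("AUAUAU", MODEL))
})

test_that("stem_dG is additive and strengthens under AU -> GC substitution", {
  set.seed(21)
  for (i in 1:15) {
    n <- sample(3:10, 1)
    s <- random_rna(n)
    # additivity: appending one base adds exactly one stack (+ terminal delta)
    b <- sample(c("A", "C", "G", "U"), 1)
    ext <- paste0(s, b)
    top <- strsplit(ext, "", fixed = TRUE)[[1]]
    bot <- chartr("ACGU", "UGCA", top)
    new_stack <- oracle_stacks[[paste0(top[n], top[n + 1], "/",
                                       bot[n], bot[n + 1])]]
    term <- function(x) if (paste0(x, chartr("ACGU", "UGCA", x)) %in%
                              c("AU", "UA", "GU", "UG")) oracle_terminal_au else 0
    expect_equal(stem_dG(ext, MODEL),
                 stem_dG(s, MODEL) + new_stack - term(substr(s, n, n)) +
                   term(b),
                 info = ext)
    # replacing any A or U with G or C (respectively) never weakens the stem
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (k in which(ch %in% c("A", "U"))) {
      ch2 <- ch
      ch2[k] <- if (ch[k] == "A") "G" else "C"
      expect_lte(stem_dG(paste(ch2, collapse = ""), MODEL),
                 stem_dG(s, MODEL))
    }
  }
})

test_that("asd_duplex_dG equals brute-force alignment enumeration", {
  anti_sd <- "ACCUCCUUA"
  # perfect complement of the anti-SD gives the full-duplex energy
  perfect <- unclass(revcomp(anti_sd))
  res <- asd_duplex_dG(perfect, region(0, nchar(perfect)), anti_sd, MODEL)
  expect_equal(res$dG, oracle_stem_dG(perfect))
  expect_equal(res$aligned$start, 0L)
  expect_equal(res$aligned$end, nchar(perfect))
  # A-run: only weak 2-pair runs form, which score positive -> no duplex
  res0 <- asd_duplex_dG("AAAAAAAA", region(0, 8), anti_sd, MODEL)
  expect_equal(res0$dG, 0)
  expect_null(res0$aligned)
  # random windows up to 30 nt against the brute-force oracle
  set.seed(31)
  for (i in 1:100) {
    w <- random_rna(sample(6:30, 1))
    got <- asd_duplex_dG(w, region(0, nchar(w)), anti_sd, MODEL)
    expect_equal(got$dG, oracle_duplex_dG(w, anti_sd), info = w)
  }
})

test_that("asd_duplex_dG is invariant to padding that keeps the site inside", {
  anti_sd <- "ACCUCCUUA"
  core <- paste0("CCC", "AGAGGAGA", "CCC")
  padded <- paste0("CACACACACA", core, "CACACACACA")
  a <- asd_duplex_dG(core, region(0, nchar(core)), anti_sd, MODEL)
  b <- asd_duplex_dG(padded, region(0, nchar(padded)), anti_sd, MODEL)
  expect_equal(a$dG, b$dG)
  expect_error(asd_duplex_dG("ACGU", region(0, 10), anti_sd, MODEL), "bounds")
})

test_that("spacing_penalty matches its closed form and is monotone", {
  cfg <- rbs_config()
  expect_equal(spacing_penalty(5, cfg), 0)
  closed <- function(s) {
    d <- s - 5
    pmin(ifelse(d < 0, 0.30 * d^2, 0.15 * d^2), 25)
  }
  expect_equal(spacing_penalty(0:15, cfg), closed(0:15))
  expect_gt(spacing_penalty(2, cfg), spacing_penalty(4, cfg))
  expect_gt(spacing_penalty(9, cfg), spacing_penalty(6, cfg))
  expect_error(spacing_penalty(-1, cfg), "non-negative")
})

test_that("rbs_strength decomposes exactly and responds to spacing", {
  mk <- function(spacer) paste0("CCC", "AGAGGAGA", strrep("C", spacer),
                                "AUGGCU")
  start5 <- 11L + 5L
  r5 <- rbs_strength(mk(5), start5, MODEL, CONFIG)
  expect_equal(r5$total, r5$dG_rRNA_mRNA + r5$dG_spacing)
  expect_lt(r5$dG_rRNA_mRNA, 0)
  # spacer C's cannot pair the anti-SD, so the duplex is spacer-invariant
  r12 <- rbs_strength(mk(12), 11L + 12L, MODEL, CONFIG)
  expect_equal(r12$dG_rRNA_mRNA, r5$dG_rRNA_mRNA)
  expect_gt(r12$total, r5$total)
  # locality: far-upstream context cannot change the score
  far <- paste0(strrep("CAU", 17), mk(5))
  rfar <- rbs_strength(far, 51L + start5, MODEL, CONFIG)
  expect_equal(rfar$total, r5$total)
  expect_error(rbs_strength("AAACCC", 0, MODEL, CONFIG), "start codon")
  # no duplex at all: zero hybridization, maximal spacing penalty
  rnone <- rbs_strength(paste0(strrep("CAC", 8), "AUGGCU"), 24L, MODEL, CONFIG)
  expect_equal(rnone$dG_rRNA_mRNA, 0)
  expect_equal(rnone$total, CONFIG$max_spacing_penalty)
})

test_that("hairpin_structure_check validates designed hairpins", {
  # loop ends (A..., ...C) cannot pair, so the designed registration is maximal
  loop14 <- "AGAGGAGACAACAC"
  win <- paste0("GCGGCC", loop14, unclass(revcomp("GCGGCC")))
  chk <- hairpin_structure_check(win, 6, 14, MODEL)
  expect_true(chk$pass)
  expect_equal(chk$designed_dG,
               oracle_stem_dG("GCGGCC") + MODEL$hairpin[["14"]])
  expect_true(chk$designed_dG <= chk$best_alt_dG)
  # no stem at all (first-generation architecture): always fails
  chk0 <- hairpin_structure_check(loop14, 0, 14, MODEL)
  expect_false(chk0$pass)
  expect_equal(chk0$designed_dG, MODEL$hairpin[["14"]])
  # scrambled 3' half: designed structure not formable
  bad <- paste0("GCGGCC", loop14, "ACAUAC")
  chkb <- hairpin_structure_check(bad, 6, 14, MODEL)
  expect_false(chkb$pass)
  expect_false(chkb$formable)
  expect_true(is.na(chkb$designed_dG))
  expect_error(hairpin_structure_check(win, 5, 14, MODEL), "length")
})
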