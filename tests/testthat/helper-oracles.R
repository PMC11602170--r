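# Independent oracles used across the suite. They read the packaged
# parameter table directly and re-derive every quantity by brute force,
# sharing no code path with the implementation under test.

oracle_tab <- utils::read.delim(system.file("extdata", "nn_params.tsv",
                                            package = "syntce"),
                                stringsAsFactors = FALSE)
oracle_stacks <- with(oracle_tab[oracle_tab$type == "stack", ],
                      stats::setNames(dg, key))
oracle_hairpin <- with(oracle_tab[oracle_tab$type == "hairpin", ],
                       stats::setNames(dg, key))
oracle_terminal_au <- oracle_tab$dg[oracle_tab$key == "terminal_au"]

oracle_pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
oracle_weak <- c("AU", "UA", "GU", "UG")

oracle_complement <- function(ch) chartr("ACGU", "UGCA", ch)

# manual table summation for a perfect stem duplex
oracle_stem_dG <- function(stem5) {
  top <- strsplit(stem5, "", fixed = TRUE)[[1]]
  n <- length(top)
  if (n < 2) return(0)
  bottom <- oracle_complement(top)
  e <- 0
  for (i in 1:(n - 1)) {
    e <- e + oracle_stacks[[paste0(top[i], top[i + 1], "/",
                                   bottom[i], bottom[i + 1])]]
  }
  for (i in c(1, n)) {
    if (paste0(top[i], bottom[i]) %in% oracle_weak) e <- e + oracle_terminal_au
  }
  e
}

# exhaustive enumeration of ungapped antiparallel alignments: minimum energy
# over every contiguous run of >= 2 complementary (WC/GU) pairs; 0 when no
# stabilizing run exists
oracle_duplex_dG <- function(window_seq, anti_sd) {
  top <- strsplit(window_seq, "", fixed = TRUE)[[1]]
  asd <- rev(strsplit(anti_sd, "", fixed = TRUE)[[1]])
  n <- length(top); L <- length(asd)
  best <- 0
  for (off in (-(L - 1)):(n - 1)) {
    run <- integer(0)
    for (i in 1:(n + 1)) {  # i = n+1 flushes the last run
      j <- i - off
      ok <- i <= n && j >= 1 && j <= L &&
        paste0(top[i], asd[j]) %in% oracle_pairs
      if (ok) {
        run <- c(run, i)
      } else if (length(run) >= 2) {
        e <- 0
        for (k in run[-length(run)]) {
          e <- e + oracle_stacks[[paste0(top[k], top[k + 1], "/",
                                         asd[k - off], asd[k + 1 - off])]]
        }
        for (k in c(run[1], run[length(run)])) {
          if (paste0(top[k], asd[k - off]) %in% oracle_weak) {
            e <- e + oracle_terminal_au
          }
        }
        best <- min(best, e)
        run <- integer(0)
      } else {
        run <- integer(0)
      }
    }
  }
  best
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# shared model/config instances (loading the table once keeps tests fast)
MODEL <- energy_model()
CONFIG <- rbs_config()

# a small deterministic three-ORF fixture registry
fixture_registry <- function(seed = 11) {
  fs <- fixture_spec(seed = seed)
  list(gfp = make_fixture_orf(fs, "gfp", length = 120, seed = seed + 1),
       mcherry = make_fixture_orf(fs, "mcherry", length = 90, seed = seed + 2),
       tagbfp = make_fixture_orf(fs, "tagbfp", length = 99, seed = seed + 3))
}

# two reusable scored synTCE parts
fixture_syntce <- function(stem5 = "GCAGCC", name = "tce1") {
  as_syntce_part(filter_candidate(assemble_syntce(syntce_spec(), stem5),
                                  MODEL, CONFIG), name)
}
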