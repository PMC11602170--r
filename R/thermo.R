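# Nearest-neighbor free-energy layer: stem duplex energies, anti-SD:mRNA
# hybridization, start-codon spacing penalty, combined RBS strength, and the
# designed-hairpin structure check. All energies are dG37 in kcal/mol.

# admissible base pairs (Watson-Crick + GU wobble), written top:bottom
ADMISSIBLE_PAIRS <- c("AU", "UA", "CG", "GC", "GU", "UG")
WEAK_CLOSING <- c("AU", "UA", "GU", "UG")  # pairs taking the terminal penalty

#' Load the nearest-neighbor energy model
#'
#' Reads the packaged (or a user-supplied) tab-separated parameter table of
#' Turner-2004-style RNA dG37 increments: the 36 ordered stacks of the six
#' admissible pairs (AU, UA, CG, GC, GU, UG), hairpin-loop initiation
#' penalties for loop sizes 3-30 (log-extrapolated beyond 30), and the
#' terminal AU/GU helix-end penalty. Temperature is fixed at 37 C; no salt
#' correction is applied.
#'
#' @param file Path to a parameter TSV with columns `type` (stack | hairpin |
#'   misc), `key` (stack as `XY/WZ` for 5'XY3' over 3'WZ5'; hairpin as loop
#'   size; misc as parameter name) and `dg` (kcal/mol). Defaults to the
#'   packaged table.
#' @return An `energy_model` object.
#' @export
energy_model <- function(file = system.file("extdata", "nn_params.tsv",
                                            package = "syntce")) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("type", "key", "dg") %in% names(tab)))
  st <- tab[tab$type == "stack", ]
  stacks <- stats::setNames(st$dg, st$key)
  expected <- as.vector(outer(ADMISSIBLE_PAIRS, ADMISSIBLE_PAIRS,
    function(p1, p2) sprintf("%s%s/%s%s", substr(p1, 1, 1), substr(p2, 1, 1),
                             substr(p1, 2, 2), substr(p2, 2, 2))))
  missing <- setdiff(expected, names(stacks))
  if (length(missing)) {
    stop("energy model is missing stack entries: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  hp <- tab[tab$type == "hairpin", ]
  hairpin <- stats::setNames(hp$dg, hp$key)
  if (!all(as.character(3:30) %in% names(hairpin))) {
    stop("energy model must define hairpin penalties for loop sizes 3..30",
         call. = FALSE)
  }
  if (any(hairpin < 0)) stop("hairpin penalties must be non-negative", call. = FALSE)
  misc <- tab[tab$type == "misc", ]
  mv <- stats::setNames(misc$dg, misc$key)
  structure(list(stacks = stacks, hairpin = hairpin,
                 terminal_au = unname(mv[["terminal_au"]]),
                 lxc = if ("lxc" %in% names(mv)) unname(mv[["lxc"]]) else 1.07856,
                 temperature = 37),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(paste0("<energy_model> %d stacks, hairpin sizes %s-%s, ",
                     "terminal AU/GU penalty %+0.2f kcal/mol, 37 C\n"),
              length(x$stacks), min(as.integer(names(x$hairpin))),
              max(as.integer(names(x$hairpin))), x$terminal_au))
  invisible(x)
}

# internal: stack increment for 5'XY3' paired with 3'WZ5'
stack_energy <- function(model, x, y, w, z) {
  unname(model$stacks[[paste0(x, y, "/", w, z)]])
}

is_paired <- function(top, bottom) paste0(top, bottom) %in% ADMISSIBLE_PAIRS

#' Hairpin-loop initiation penalty
#'
#' Tabulated for loop sizes 3-30; larger loops use the standard logarithmic
#' extrapolation `dG(n) = dG(30) + lxc * ln(n/30)`. Loops of fewer than 3 nt
#' cannot form and are rejected.
#'
#' @param loop_len Loop size in nt (>= 3).
#' @param model An [energy_model()].
#' @return Penalty in kcal/mol (non-negative).
#' @export
hairpin_loop_penalty <- function(loop_len, model = energy_model()) {
  loop_len <- as.integer(loop_len)
  if (is.na(loop_len) || loop_len < 3L) {
    stop("hairpin loops must be at least 3 nt", call. = FALSE)
  }
  if (loop_len <= 30L) return(unname(model$hairpin[[as.character(loop_len)]]))
  unname(model$hairpin[["30"]]) + model$lxc * log(loop_len / 30)
}

#' Free energy of a perfect stem duplex
#'
#' Energy of the helix formed by `stem5` paired against its reverse
#' complement: the sum of the `n - 1` nearest-neighbor stack increments plus
#' the terminal penalty for each AU/UA/GU/UG closing pair. Empty and 1-nt
#' stems have no stacks and return 0.
#'
#' @param stem5 The 5' half of the stem (the 3' half is its reverse
#'   complement by construction). May be the empty string.
#' @param model An [energy_model()].
#' @return dG37 in kcal/mol.
#' @examples
#' m <- energy_model()
#' stem_dG("GCGCGC", m) < stem_dG("AUAUAU", m)  # strong beats weak pairs
#' @export
stem_dG <- function(stem5, model = energy_model()) {
  s <- if (is.character(stem5) && length(stem5) == 1L && !nzchar(gsub("\\s", "", stem5))) {
    ""
  } else unclass(to_rna(stem5))
  n <- nchar(s)
  if (n < 2L) return(0)
  top <- strsplit(s, "", fixed = TRUE)[[1]]
  bottom <- complement_chars(top)  # bottom strand aligned 3'->5' under top
  e <- 0
  for (i in seq_len(n - 1L)) {
    e <- e + stack_energy(model, top[i], top[i + 1L], bottom[i], bottom[i + 1L])
  }
  for (end in c(1L, n)) {
    if (paste0(top[end], bottom[end]) %in% WEAK_CLOSING) e <- e + model$terminal_au
  }
  e
}

# internal: best single contiguous duplex run of anti_sd against the mRNA
# window, over all ungapped antiparallel alignments. Returns list(dG, start,
# end) in window-local 0-based half-open coordinates, or dG = 0 with NULL
# region when no run of >= min_run pairs exists. Ties prefer the run ending
# closest to the 3' side of the window (nearest a downstream start codon),
# then the smallest start.
best_duplex_run <- function(sub, anti_sd, model, min_run = 2L) {
  n <- nchar(sub); L <- nchar(anti_sd)
  top <- strsplit(sub, "", fixed = TRUE)[[1]]
  asd <- strsplit(anti_sd, "", fixed = TRUE)[[1]]
  rev_asd <- rev(asd)  # anti_sd read 3'->5', laid antiparallel under the mRNA
  runs <- list()
  for (off in seq.int(-(L - 1L), n - 1L)) {
    # mRNA index (1-based) i pairs rev_asd index i - off
    j <- seq_len(n) - off
    valid <- j >= 1L & j <= L
    partner <- ifelse(valid, rev_asd[pmax(pmin(j, L), 1L)], "-")
    paired <- valid & is_paired(top, partner)
    r <- rle(paired)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      a <- starts[k]; b <- ends[k]
      e <- 0
      for (i in a:(b - 1L)) {
        e <- e + stack_energy(model, top[i], top[i + 1L],
                              rev_asd[i - off], rev_asd[i + 1L - off])
      }
      for (i in c(a, b)) {
        if (paste0(top[i], rev_asd[i - off]) %in% WEAK_CLOSING) {
          e <- e + model$terminal_au
        }
      }
      runs[[length(runs) + 1L]] <- c(dG = e, start = a - 1, end = b)
    }
  }
  if (!length(runs)) return(list(dG = 0, start = NA_integer_, end = NA_integer_))
  tab <- do.call(rbind, runs)
  # minimal energy; ties resolved toward the 3'-most end, then smallest start
  ord <- order(tab[, "dG"], -tab[, "end"], tab[, "start"])
  b <- tab[ord[1L], ]
  list(dG = unname(b[["dG"]]), start = as.integer(b[["start"]]),
       end = as.integer(b[["end"]]))
}

#' Best anti-SD:mRNA duplex energy within a window
#'
#' Minimizes the hybridization free energy over every ungapped antiparallel
#' alignment of the anti-Shine-Dalgarno sequence (3' tail of 16S rRNA)
#' against a window of the mRNA. Only contiguous runs of two or more
#' complementary (Watson-Crick or GU) pairs are scored, with
#' nearest-neighbor stacks plus terminal AU/GU penalties. When no such run
#' exists the energy is 0 and the aligned region is empty.
#'
#' @param mrna The mRNA sequence.
#' @param window A [region()] of `mrna` to search.
#' @param anti_sd Anti-SD sequence, 5'->3' (default the E. coli 16S rRNA 3'
#'   tail ACCUCCUUA), length >= 4.
#' @param model An [energy_model()].
#' @return List with `dG` (kcal/mol, <= 0) and `aligned` (a [region()] of
#'   `mrna`, or NULL when no duplex forms).
#' @export
asd_duplex_dG <- function(mrna, window, anti_sd = "ACCUCCUUA",
                          model = energy_model()) {
  m <- unclass(to_rna(mrna))
  if (!inherits(window, "region")) stop("window must be a region", call. = FALSE)
  if (window$end > nchar(m)) stop("window outside mrna bounds", call. = FALSE)
  a <- unclass(to_rna(anti_sd))
  if (nchar(a) < 4L) stop("anti_sd must be at least 4 nt", call. = FALSE)
  if (region_width(window) == 0L) return(list(dG = 0, aligned = NULL))
  sub <- substr(m, window$start + 1L, window$end)
  run <- best_duplex_run(sub, a, model)
  # a duplex only counts when it is stabilizing (dG <= 0): short GU-rich
  # runs can score positive under the stack table and are treated as unpaired
  if (is.na(run$start) || run$dG > 0) return(list(dG = 0, aligned = NULL))
  list(dG = run$dG,
       aligned = region(window$start + run$start, window$start + run$end,
                        label = "asd_duplex"))
}

#' Default RBS-strength configuration
#'
#' Parameters of the spacing penalty and the anti-SD search used by
#' [rbs_strength()]: a piecewise-quadratic penalty that is zero at the
#' optimal spacing and rises with separate stiffness constants on the
#' compressed and stretched sides, capped at `max_spacing_penalty` (also the
#' penalty charged when no SD duplex is found at all).
#'
#' @param spacing_opt Optimal nt between the last paired base and the start
#'   codon (default 5).
#' @param k_compressed Stiffness (kcal/mol/nt^2) for spacing below optimum
#'   (default 0.30; compression is penalized more steeply than stretch).
#' @param k_stretched Stiffness for spacing above optimum (default 0.15).
#' @param max_spacing_penalty Cap, and the no-duplex penalty (default 25).
#' @param search_window nt upstream of the start codon searched for the
#'   anti-SD duplex (default 20).
#' @param anti_sd Anti-SD sequence, 5'->3'.
#' @return An `rbs_config` list.
#' @export
rbs_config <- function(spacing_opt = 5L, k_compressed = 0.30,
                       k_stretched = 0.15, max_spacing_penalty = 25,
                       search_window = 20L, anti_sd = "ACCUCCUUA") {
  stopifnot(spacing_opt >= 0, k_compressed > 0, k_stretched > 0,
            max_spacing_penalty > 0, search_window >= 4)
  structure(list(spacing_opt = as.integer(spacing_opt),
                 k_compressed = k_compressed, k_stretched = k_stretched,
                 max_spacing_penalty = max_spacing_penalty,
                 search_window = as.integer(search_window),
                 anti_sd = unclass(to_rna(anti_sd))),
            class = "rbs_config")
}

#' Start-codon spacing penalty
#'
#' Zero at the configured optimal SD-to-start spacing and strictly
#' increasing as the spacing departs it in either direction:
#' `k_compressed * d^2` below the optimum and `k_stretched * d^2` above it
#' (d = |spacing - optimum|), capped at `max_spacing_penalty`.
#'
#' @param spacing Non-negative integer nt between the last SD-paired mRNA
#'   base and the first base of the start codon.
#' @param config An [rbs_config()].
#' @return Penalty in kcal/mol (>= 0).
#' @export
spacing_penalty <- function(spacing, config = rbs_config()) {
  if (any(is.na(spacing)) || any(spacing < 0) || any(spacing != floor(spacing))) {
    stop("spacing must be a non-negative integer", call. = FALSE)
  }
  d <- spacing - config$spacing_opt
  pen <- ifelse(d < 0, config$k_compressed * d^2, config$k_stretched * d^2)
  pmin(pen, config$max_spacing_penalty)
}

#' Decomposed RBS strength at a start codon
#'
#' The two-term translation-initiation score: the best anti-SD:mRNA duplex
#' energy found in a window upstream of the start codon (`dG_rRNA_mRNA`,
#' <= 0 when any duplex forms) plus the spacing penalty for the distance
#' between that duplex and the start codon (`dG_spacing`, >= 0). More
#' negative totals mean stronger predicted initiation. When no duplex of
#' two or more pairs exists, `dG_rRNA_mRNA` is 0 and the maximal configured
#' spacing penalty is charged.
#'
#' @param mrna The transcript.
#' @param start_pos 0-based position of the start codon (must read AUG, or
#'   GUG when `allow_gug`).
#' @param model An [energy_model()].
#' @param config An [rbs_config()].
#' @param allow_gug Also accept GUG start codons (used by internal-RBS
#'   scanning).
#' @return An `rbs_score` list: `dG_rRNA_mRNA`, `dG_spacing`, `total`
#'   (their exact sum), `aligned` region and `spacing` (nt, NA when no
#'   duplex).
#' @export
rbs_strength <- function(mrna, start_pos, model = energy_model(),
                         config = rbs_config(), allow_gug = FALSE) {
  m <- unclass(to_rna(mrna))
  start_pos <- as.integer(start_pos)
  codon <- substr(m, start_pos + 1L, start_pos + 3L)
  ok <- codon == "AUG" || (allow_gug && codon == "GUG")
  if (!ok) {
    stop(sprintf("position %d does not hold a start codon (found '%s')",
                 start_pos, codon), call. = FALSE)
  }
  win <- region(max(0L, start_pos - config$search_window), start_pos,
                label = "rbs_search")
  dup <- asd_duplex_dG(m, win, config$anti_sd, model)
  if (is.null(dup$aligned)) {
    res <- list(dG_rRNA_mRNA = 0, dG_spacing = config$max_spacing_penalty,
                total = config$max_spacing_penalty, aligned = NULL,
                spacing = NA_integer_)
  } else {
    spacing <- start_pos - dup$aligned$end
    pen <- spacing_penalty(spacing, config)
    res <- list(dG_rRNA_mRNA = dup$dG, dG_spacing = pen,
                total = dup$dG + pen, aligned = dup$aligned,
                spacing = as.integer(spacing))
  }
  structure(res, class = "rbs_score")
}

#' @export
print.rbs_score <- function(x, ...) {
  cat(sprintf("<rbs_score> total %+0.2f = dG(rRNA:mRNA) %+0.2f + dG(spacing) %+0.2f; spacing %s nt\n",
              x$total, x$dG_rRNA_mRNA, x$dG_spacing,
              ifelse(is.na(x$spacing), "NA", x$spacing)))
  invisible(x)
}

# internal: enumerate every single-hairpin registration inside a window.
# A registration is (i, j, L): an L-bp stem pairing positions i+k with j-k
# (0-based, k = 0..L-1, admissible pairs) closing a loop of j-i+1-2L >= 3 nt.
# Returns a data.frame with i, j, L and dG (stacks + loop penalty + terminal
# penalties at both helix ends).
enumerate_hairpins <- function(seq, model, min_stem = 3L) {
  s <- unclass(to_rna(seq))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  out <- list()
  for (i in 0:(n - 1L)) {
    for (j in i:(n - 1L)) {
      max_L <- (j - i + 1L - 3L) %/% 2L
      if (max_L < min_stem) next
      # pairs must hold for all k = 0..L-1; find the maximal consecutive run
      L <- 0L
      while (L < max_L && is_paired(ch[i + L + 1L], ch[j - L + 1L])) L <- L + 1L
      if (L < min_stem) next
      for (Luse in min_stem:L) {
        e <- 0
        for (k in 0:(Luse - 2L)) {
          e <- e + stack_energy(model, ch[i + k + 1L], ch[i + k + 2L],
                                ch[j - k + 1L], ch[j - k])
        }
        for (k in c(0L, Luse - 1L)) {
          if (paste0(ch[i + k + 1L], ch[j - k + 1L]) %in% WEAK_CLOSING) {
            e <- e + model$terminal_au
          }
        }
        loop <- j - i + 1L - 2L * Luse
        e <- e + hairpin_loop_penalty(loop, model)
        out[[length(out) + 1L]] <- c(i = i, j = j, L = Luse, dG = e)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(0), j = integer(0), L = integer(0),
                      dG = numeric(0)))
  }
  as.data.frame(do.call(rbind, out))
}

#' Check that the designed hairpin is the dominant structure
#'
#' The designed structure of a synTCE window is the full-length stem
#' (`stem_len` bp) closing the loop (`loop_len` nt); its energy is
#' `stem_dG(stem5) + hairpin_loop_penalty(loop_len)`. The check
#' exhaustively enumerates every alternative single-hairpin registration
#' (all contiguous complementary stems of >= 3 bp) within the window and
#' passes iff the designed structure is formable, is the minimum-energy
#' hairpin, and its energy is at or below the stability threshold.
#'
#' @param candidate_seq The hairpin window, length `2*stem_len + loop_len`.
#' @param stem_len Designed stem length in bp (0 allowed: no hairpin, the
#'   first-generation architecture, which always fails the threshold).
#' @param loop_len Designed loop length in nt.
#' @param model An [energy_model()].
#' @param threshold Maximum designed dG to pass (default -6 kcal/mol).
#' @return List: `pass`, `designed_dG` (NA when the designed stem cannot
#'   form), `best_alt_dG` (minimum over alternative registrations, Inf when
#'   none), `formable`.
#' @export
hairpin_structure_check <- function(candidate_seq, stem_len, loop_len,
                                    model = energy_model(), threshold = -6) {
  s <- unclass(to_rna(candidate_seq))
  stem_len <- as.integer(stem_len); loop_len <- as.integer(loop_len)
  if (nchar(s) != 2L * stem_len + loop_len) {
    stop(sprintf("candidate length %d != 2*stem_len + loop_len = %d",
                 nchar(s), 2L * stem_len + loop_len), call. = FALSE)
  }
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  formable <- stem_len == 0L ||
    all(vapply(seq_len(stem_len),
               function(k) is_paired(ch[k], ch[n - k + 1L]), logical(1)))
  designed_dG <- if (!formable) NA_real_ else {
    stem_part <- if (stem_len > 0L) stem_dG(substr(s, 1L, stem_len), model) else 0
    stem_part + hairpin_loop_penalty(loop_len, model)
  }
  hp <- enumerate_hairpins(s, model)
  is_designed <- stem_len >= 3L & hp$i == 0L & hp$j == n - 1L & hp$L == stem_len
  alt <- hp[!is_designed, , drop = FALSE]
  best_alt_dG <- if (nrow(alt)) min(alt$dG) else Inf
  pass <- formable && !is.na(designed_dG) && designed_dG <= threshold &&
    designed_dG <= best_alt_dG
  list(pass = pass, designed_dG = designed_dG, best_alt_dG = best_alt_dG,
       formable = formable)
}
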