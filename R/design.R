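# synTCE candidate generation: randomized stems around a fixed RBS-bearing
# loop, a URAUG overlapping stop-start junction, pattern-constraint and
# in-frame-stop filtering, thermodynamic scoring and deterministic ranking.

#' The default pattern-constraint set
#'
#' Ten IUPAC patterns forbidding runs of identical or chemically similar
#' nucleotides in designed (randomized) domains: homopolymers of 4 and runs
#' of 6 over each two-letter class (K = G/U, M = A/C, R = A/G purines,
#' S = C/G strong, W = A/U weak, Y = C/U pyrimidines).
#'
#' @return Character vector of IUPAC patterns.
#' @export
default_patterns <- function() {
  c("AAAA", "CCCC", "GGGG", "UUUU",
    "KKKKKK", "MMMMMM", "RRRRRR", "SSSSSS", "WWWWWW", "YYYYYY")
}

#' Specify a synTCE design request
#'
#' A synTCE cassette is `upstream context (stop stripped) + stem5 + loop +
#' revcomp(stem5) + overlapping stop-start junction`. The loop carries the
#' ribosome binding site; the junction reads URAUG (stop UAA or UGA sharing
#' its last base with the downstream AUG). Only the stem is randomized; the
#' loop, RBS and junction are fixed domains.
#'
#' @param stem_len Stem length in bp, 0-12 (default 6).
#' @param loop_seq Loop sequence containing the RBS, 8-20 nt (default the
#'   15-nt `AGAGGAGACAACAUC`; 15 nt keeps `2*stem_len + loop` a multiple of
#'   3 at the default stem so the junction stop lies in the upstream frame).
#' @param overlap_codon The junction stop codon, `"UAA"` or `"UGA"`.
#' @param upstream_context In-frame tail of the upstream ORF, ending with
#'   its own stop codon (stripped and replaced by the junction stop on
#'   assembly).
#' @param rbs The RBS that must occur in `loop_seq` (default `AGAGGAGA`).
#' @param pattern_constraints IUPAC patterns forbidden in randomized
#'   domains (default [default_patterns()]).
#' @param seed Integer seed for stem randomization.
#' @param n_candidates Number of distinct passing stems to draw.
#' @param max_attempts Sampling budget before declaring the constraints
#'   unsatisfiable.
#' @return A `syntce_spec` object.
#' @export
syntce_spec <- function(stem_len = 6L,
                        loop_seq = "AGAGGAGACAACAUC",
                        overlap_codon = c("UAA", "UGA"),
                        upstream_context = "GGCGGCAGCGGCUAA",
                        rbs = "AGAGGAGA",
                        pattern_constraints = default_patterns(),
                        seed = 1L,
                        n_candidates = 10L,
                        max_attempts = 20000L) {
  stem_len <- as.integer(stem_len)
  if (is.na(stem_len) || stem_len < 0L || stem_len > 12L) {
    stop("stem_len must be between 0 and 12", call. = FALSE)
  }
  loop <- to_rna(loop_seq)
  if (seq_len_nt(loop) < 8L || seq_len_nt(loop) > 20L) {
    stop("loop_seq must be 8-20 nt", call. = FALSE)
  }
  rbs <- to_rna(rbs)
  if (!grepl(unclass(rbs), unclass(loop), fixed = TRUE)) {
    stop("loop_seq must contain the RBS sequence", call. = FALSE)
  }
  overlap_codon <- match.arg(overlap_codon)
  ctx <- to_rna(upstream_context)
  lapply(pattern_constraints, check_iupac_pattern)
  structure(list(stem_len = stem_len, loop_seq = loop,
                 overlap_codon = overlap_codon, upstream_context = ctx,
                 rbs = rbs, pattern_constraints = pattern_constraints,
                 seed = as.integer(seed),
                 n_candidates = as.integer(n_candidates),
                 max_attempts = as.integer(max_attempts)),
            class = "syntce_spec")
}

#' @export
print.syntce_spec <- function(x, ...) {
  cat(sprintf("<syntce_spec> %d-bp stem, %d-nt loop ('%s'), junction %s|AUG, %d candidates, seed %d\n",
              x$stem_len, seq_len_nt(x$loop_seq), unclass(x$loop_seq),
              x$overlap_codon, x$n_candidates, x$seed))
  invisible(x)
}

# internal: splice rule for the upstream ORF tail: its own trailing stop
# codon is removed (the junction's overlapping stop takes its place), so
# the upstream protein is preserved.
strip_trailing_stop <- function(ctx) {
  s <- unclass(to_rna(ctx))
  n <- nchar(s)
  if (n >= 3L && substr(s, n - 2L, n) %in% STOP_CODONS) {
    s <- substr(s, 1L, n - 3L)
  }
  s
}

# internal: pattern violations are matches of any forbidden pattern lying
# entirely within a variable (randomized) domain; matches spanning into the
# fixed loop/RBS/junction domains are not counted (the fixed RBS is itself
# a purine run and is exempt by design). `variable` is a list of regions;
# returns TRUE when clean.
patterns_clean <- function(cassette, variable, patterns) {
  s <- unclass(to_rna(cassette))
  for (v in variable) {
    if (v$end - v$start == 0L) next
    dom <- substr(s, v$start + 1L, v$end)
    for (p in patterns) {
      if (length(match_iupac_naive(dom, p))) return(FALSE)
    }
  }
  TRUE
}

#' Assemble a synTCE candidate around a given stem
#'
#' Builds the full cassette `spliced upstream context + stem5 + loop +
#' revcomp(stem5) + junction`, where the junction is the first two bases of
#' the overlap stop codon followed by AUG (so the cassette ends in the 5-nt
#' URAUG motif with the stop in the upstream reading frame). All
#' sub-domains are annotated as [region()]s.
#'
#' @param spec A [syntce_spec()].
#' @param stem5 The 5' stem half (length `spec$stem_len`; empty string when
#'   `stem_len` is 0).
#' @return A `syntce_candidate` (unscored; see [filter_candidate()]).
#' @export
assemble_syntce <- function(spec, stem5 = "") {
  stopifnot(inherits(spec, "syntce_spec"))
  s5 <- if (spec$stem_len == 0L) "" else unclass(to_rna(stem5))
  if (nchar(s5) != spec$stem_len) {
    stop(sprintf("stem5 has %d nt but spec$stem_len is %d",
                 nchar(s5), spec$stem_len), call. = FALSE)
  }
  ctx <- strip_trailing_stop(spec$upstream_context)
  if (nchar(ctx) %% 3L != 0L) {
    stop("upstream_context length not a multiple of 3 after stop splice",
         call. = FALSE)
  }
  loop <- unclass(spec$loop_seq)
  hairpin_len <- 2L * spec$stem_len + nchar(loop)
  if (hairpin_len %% 3L != 0L) {
    stop(sprintf(paste0("2*stem_len + loop length = %d is not a multiple of 3: ",
                        "the junction stop codon would leave the upstream ",
                        "reading frame"), hairpin_len), call. = FALSE)
  }
  s3 <- if (spec$stem_len == 0L) "" else unclass(revcomp(s5))
  junction <- paste0(substr(spec$overlap_codon, 1L, 2L), "AUG")
  cassette <- paste0(ctx, s5, loop, s3, junction)
  nctx <- nchar(ctx)
  off <- function(a, b, label, frame = NA) region(a, b, label, frame)
  rbs_at <- regexpr(unclass(spec$rbs), loop, fixed = TRUE)[1] - 1L
  regions <- list(
    context = off(0L, nctx, "context", 0L),
    stem5 = off(nctx, nctx + spec$stem_len, "stem5"),
    loop = off(nctx + spec$stem_len, nctx + spec$stem_len + nchar(loop), "loop"),
    rbs = off(nctx + spec$stem_len + rbs_at,
              nctx + spec$stem_len + rbs_at + nchar(unclass(spec$rbs)), "rbs"),
    stem3 = off(nctx + spec$stem_len + nchar(loop),
                nctx + hairpin_len, "stem3"),
    stop = off(nctx + hairpin_len, nctx + hairpin_len + 3L, "stop", 0L),
    start = off(nctx + hairpin_len + 2L, nctx + hairpin_len + 5L, "start",
                junction_frame(0L))
  )
  structure(list(cassette = to_rna(cassette), regions = regions,
                 spec = spec, stem5 = s5, scores = NULL, flags = NULL,
                 provenance = list(seed = spec$seed, draw = NA_integer_)),
            class = "syntce_candidate")
}

#' @export
print.syntce_candidate <- function(x, ...) {
  cat(sprintf("<syntce_candidate> stem5 '%s', cassette %d nt", x$stem5,
              seq_len_nt(x$cassette)))
  if (!is.null(x$flags)) {
    cat(sprintf(" [%s]", if (candidate_passes(x)) "PASS" else
      paste("fail:", paste(names(which(!unlist(x$flags))), collapse = ","))))
  }
  cat("\n")
  invisible(x)
}

# variable (randomized) domains of a candidate
variable_regions <- function(cand) {
  if (cand$spec$stem_len == 0L) return(list())
  list(cand$regions$stem5, cand$regions$stem3)
}

#' Generate pattern-clean random stems
#'
#' Rejection-samples uniform random stems of the specified length, keeping
#' those whose insertion into the assembled cassette produces no
#' forbidden-pattern match overlapping a randomized domain. Deterministic
#' given `spec$seed`; distinct survivors are returned in draw order.
#' With `enumerate = TRUE` the full 4^stem_len space is screened
#' exhaustively instead (stem_len <= 8), giving the complete passing set in
#' lexicographic order.
#'
#' @param spec A [syntce_spec()].
#' @param enumerate Exhaustively enumerate instead of sampling.
#' @return Character vector of stem5 sequences (a single empty string when
#'   `stem_len` is 0).
#' @export
generate_stems <- function(spec, enumerate = FALSE) {
  stopifnot(inherits(spec, "syntce_spec"))
  if (spec$stem_len == 0L) return("")
  # the constraint scope is containment in a randomized domain, so a stem is
  # judged on stem5 and its reverse complement (stem3) alone; identical to
  # filtering the assembled cassette (property-tested)
  ok_stem <- function(s5) {
    s3 <- unclass(revcomp(s5))
    for (p in spec$pattern_constraints) {
      if (length(match_iupac_naive(s5, p)) ||
          length(match_iupac_naive(s3, p))) return(FALSE)
    }
    TRUE
  }
  if (enumerate) {
    if (spec$stem_len > 8L) {
      stop("exhaustive enumeration supported for stem_len <= 8", call. = FALSE)
    }
    grid <- do.call(expand.grid, rep(list(RNA_BASES), spec$stem_len))
    all_stems <- sort(apply(grid, 1L, paste, collapse = ""))
    return(all_stems[vapply(all_stems, ok_stem, logical(1))])
  }
  with_seed(spec$seed, {
    survivors <- character(0)
    for (attempt in seq_len(spec$max_attempts)) {
      s5 <- paste(sample(RNA_BASES, spec$stem_len, replace = TRUE),
                  collapse = "")
      if (!s5 %in% survivors && ok_stem(s5)) {
        survivors <- c(survivors, s5)
        if (length(survivors) >= spec$n_candidates) break
      }
    }
    if (!length(survivors)) {
      stop(sprintf(paste0("unsatisfiable constraints: no stem of length %d ",
                          "passed the pattern constraints (%s) within %d ",
                          "attempts"), spec$stem_len,
                   paste(spec$pattern_constraints, collapse = ", "),
                   spec$max_attempts), call. = FALSE)
    }
    survivors
  })
}

#' Apply the synTCE filters and score a candidate
#'
#' Sets three pass/fail flags: (a) `no_upstream_stop` - no stop codon in
#' the upstream reading frame anywhere in the cassette before the junction
#' stop; (b) `patterns_clean` - no forbidden-pattern match overlapping a
#' randomized domain; (c) `structure_ok` - the designed hairpin passes
#' [hairpin_structure_check()]. A candidate passes overall iff all flags
#' pass. Also attaches scores: stem dG, the RBS strength at the coupled
#' AUG, and the structure-check result.
#'
#' @param candidate A `syntce_candidate` from [assemble_syntce()].
#' @param model An [energy_model()].
#' @param config An [rbs_config()].
#' @param structure_threshold Designed-hairpin stability threshold
#'   (kcal/mol, default -6).
#' @return The candidate with `$flags` and `$scores` populated.
#' @export
filter_candidate <- function(candidate, model = energy_model(),
                             config = rbs_config(),
                             structure_threshold = -6) {
  stopifnot(inherits(candidate, "syntce_candidate"))
  spec <- candidate$spec
  cass <- unclass(candidate$cassette)
  stop_pos <- candidate$regions$stop$start
  hits <- scan_stop_codons(cass, 0L)
  no_upstream_stop <- !any(hits < stop_pos) && stop_pos %in% hits
  pat_ok <- patterns_clean(cass, variable_regions(candidate),
                           spec$pattern_constraints)
  hp_window <- substr(cass, candidate$regions$stem5$start + 1L,
                      candidate$regions$stem3$end)
  sc <- hairpin_structure_check(hp_window, spec$stem_len,
                                seq_len_nt(spec$loop_seq), model,
                                threshold = structure_threshold)
  rbs <- rbs_strength(cass, candidate$regions$start$start, model, config)
  candidate$scores <- list(
    stem_dG = if (spec$stem_len > 0L) stem_dG(candidate$stem5, model) else 0,
    rbs = rbs, structure = sc)
  candidate$flags <- list(no_upstream_stop = no_upstream_stop,
                          patterns_clean = pat_ok,
                          structure_ok = sc$pass)
  candidate
}

#' Does a scored candidate pass all filters?
#' @param candidate A scored `syntce_candidate`.
#' @return Logical.
#' @export
candidate_passes <- function(candidate) {
  !is.null(candidate$flags) && all(unlist(candidate$flags))
}

#' Rank scored candidates deterministically
#'
#' Passing candidates come first, ordered by ascending designed hairpin dG
#' (most stable structure first), then by ascending RBS-strength total
#' (more negative = stronger initiation first), then lexicographically by
#' cassette as the tie-break. Failing candidates follow, in the same key
#' order.
#'
#' @param candidates List of scored `syntce_candidate`s.
#' @return The reordered list.
#' @export
rank_candidates <- function(candidates) {
  if (!length(candidates)) return(candidates)
  stopifnot(all(vapply(candidates, function(x) !is.null(x$flags), logical(1))))
  pass <- vapply(candidates, candidate_passes, logical(1))
  key_dg <- vapply(candidates, function(x) {
    d <- x$scores$structure$designed_dG
    if (is.na(d)) Inf else d
  }, numeric(1))
  key_rbs <- vapply(candidates, function(x) x$scores$rbs$total, numeric(1))
  key_seq <- vapply(candidates, function(x) unclass(x$cassette), character(1))
  candidates[order(!pass, key_dg, key_rbs, key_seq)]
}

#' Generate, filter, score and rank synTCE candidates
#'
#' The full design pipeline: draw pattern-clean stems ([generate_stems()]),
#' assemble each cassette ([assemble_syntce()]), apply the filters and
#' thermodynamic scores ([filter_candidate()]) and rank deterministically
#' ([rank_candidates()]).
#'
#' @inheritParams filter_candidate
#' @param spec A [syntce_spec()].
#' @param enumerate Screen the whole stem space instead of sampling (see
#'   [generate_stems()]).
#' @return A ranked list of scored `syntce_candidate`s.
#' @export
design_syntce <- function(spec, model = energy_model(), config = rbs_config(),
                          structure_threshold = -6, enumerate = FALSE) {
  stems <- generate_stems(spec, enumerate = enumerate)
  cands <- lapply(seq_along(stems), function(i) {
    cand <- assemble_syntce(spec, stems[[i]])
    cand$provenance$draw <- i
    filter_candidate(cand, model, config, structure_threshold)
  })
  rank_candidates(cands)
}

#' Tabulate scores and flags of a candidate list
#'
#' @param candidates Scored `syntce_candidate`s.
#' @return A data.frame, one row per candidate: stem5, cassette, scores,
#'   flags and overall pass.
#' @export
candidate_table <- function(candidates) {
  rows <- lapply(candidates, function(x) {
    data.frame(stem5 = x$stem5,
               cassette = unclass(x$cassette),
               stem_dG = x$scores$stem_dG,
               designed_dG = x$scores$structure$designed_dG,
               best_alt_dG = x$scores$structure$best_alt_dG,
               rbs_total = x$scores$rbs$total,
               dG_rRNA_mRNA = x$scores$rbs$dG_rRNA_mRNA,
               dG_spacing = x$scores$rbs$dG_spacing,
               no_upstream_stop = x$flags$no_upstream_stop,
               patterns_clean = x$flags$patterns_clean,
               structure_ok = x$flags$structure_ok,
               passes = candidate_passes(x),
               seed = x$provenance$seed,
               draw = x$provenance$draw)
  })
  do.call(rbind, rows)
}
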