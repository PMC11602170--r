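# Compilation of parts (switches, ORFs, linkers, synTCEs) into annotated
# multi-output operon transcripts and ribocomputing gate layouts, with
# per-junction validation.

PART_ROLES <- c("switch", "orf", "linker", "syntce", "output_tag")

#' Construct a part
#'
#' @param name Identifier.
#' @param role One of switch, orf, linker, syntce, output_tag. Switches are
#'   opaque riboregulator modules; orfs must satisfy ORF invariants (see
#'   [validate_part()]); syntce parts carry `stem_len` and `loop_len`
#'   metadata.
#' @param sequence The part sequence (DNA accepted, normalized to RNA).
#' @param metadata Free-form named list (e.g. cognate trigger for a switch).
#' @return A `part` object.
#' @export
part <- function(name, role, sequence, metadata = list()) {
  role <- match.arg(role, PART_ROLES)
  p <- structure(list(name = as.character(name), role = role,
                      sequence = to_rna(sequence), metadata = metadata),
                 class = "part")
  validate_part(p)
}

#' @export
print.part <- function(x, ...) {
  cat(sprintf("<part> %s [%s], %d nt\n", x$name, x$role,
              seq_len_nt(x$sequence)))
  invisible(x)
}

#' Validate part invariants
#'
#' ORF parts must begin with AUG, have length divisible by 3, contain no
#' internal in-frame stop codon and end with a stop codon. synTCE parts must
#' carry `stem_len`/`loop_len` metadata consistent with their length
#' (`2*stem_len + loop_len + 2`: hairpin plus the first two bases of the
#' overlap stop codon).
#'
#' @param p A `part`.
#' @return The part, invisibly-validated (errors on violation).
#' @export
validate_part <- function(p) {
  stopifnot(inherits(p, "part"))
  s <- unclass(p$sequence)
  if (p$role == "orf") {
    n <- nchar(s)
    if (substr(s, 1, 3) != "AUG") {
      stop(sprintf("orf part '%s' must begin with AUG", p$name), call. = FALSE)
    }
    if (n %% 3L != 0L) {
      stop(sprintf("orf part '%s' length %d is not a multiple of 3",
                   p$name, n), call. = FALSE)
    }
    stops <- scan_stop_codons(s, 0L)
    if (!(n - 3L) %in% stops) {
      stop(sprintf("orf part '%s' must end with a stop codon", p$name),
           call. = FALSE)
    }
    if (any(stops < n - 3L)) {
      stop(sprintf("orf part '%s' contains an internal in-frame stop at %d",
                   p$name, min(stops[stops < n - 3L])), call. = FALSE)
    }
  }
  if (p$role == "syntce") {
    sl <- p$metadata$stem_len; ll <- p$metadata$loop_len
    if (is.null(sl) || is.null(ll)) {
      stop(sprintf("syntce part '%s' needs stem_len and loop_len metadata",
                   p$name), call. = FALSE)
    }
    if (nchar(s) != 2L * sl + ll + 2L) {
      stop(sprintf("syntce part '%s': length %d != 2*%d + %d + 2",
                   p$name, nchar(s), sl, ll), call. = FALSE)
    }
    tail2 <- substr(s, nchar(s) - 1L, nchar(s))
    if (!tail2 %in% c("UA", "UG")) {
      stop(sprintf("syntce part '%s' must end with the UA/UG overlap bases",
                   p$name), call. = FALSE)
    }
  }
  if (p$role == "linker" && nchar(s) %% 3L != 0L) {
    stop(sprintf("linker part '%s' length must be a multiple of 3 (it is translated through)",
                 p$name), call. = FALSE)
  }
  p
}

#' Convert a designed candidate into a reusable synTCE part
#'
#' Drops the candidate's upstream context and the junction AUG (the
#' downstream ORF supplies its own start codon), leaving
#' `stem5 + loop + stem3 + UA/UG`: the insert placed between two ORFs.
#'
#' @param candidate A `syntce_candidate`.
#' @param name Part name.
#' @return A `part` with role `syntce`.
#' @export
as_syntce_part <- function(candidate, name = "syntce") {
  stopifnot(inherits(candidate, "syntce_candidate"))
  r <- candidate$regions
  s <- substr(unclass(candidate$cassette), r$stem5$start + 1L, r$stop$end - 1L)
  part(name, "syntce", s,
       metadata = list(stem_len = candidate$spec$stem_len,
                       loop_len = region_width(r$loop),
                       overlap_codon = candidate$spec$overlap_codon,
                       rbs_offset = r$rbs$start - r$loop$start,
                       rbs = unclass(candidate$spec$rbs)))
}

#' Compile an ordered part list into an annotated operon transcript
#'
#' Parts must alternate legally: zero or more switches, then an ORF,
#' optionally followed by repeated `[linker] -> syntce -> orf` blocks, with
#' an optional trailing output_tag. At each synTCE the upstream ORF's own
#' stop codon is stripped; the synTCE's overlapping stop-start junction
#' replaces it, so the downstream ORF begins inside the URAUG motif in
#' frame `junction_frame(upstream frame)`. Every ORF annotation is
#' re-validated against the assembled transcript.
#'
#' @param parts Ordered list of [part()] objects.
#' @return An `operon_design`: `transcript`, `annotations` (data.frame with
#'   name, role, start, end, frame; 0-based half-open), `junctions` (one
#'   record per synTCE).
#' @export
assemble_operon <- function(parts) {
  stopifnot(length(parts) >= 1L, all(vapply(parts, inherits, logical(1), "part")))
  roles <- vapply(parts, function(p) p$role, character(1))
  rle_sig <- paste(roles, collapse = " ")
  legal <- grepl("^(switch )*orf( (linker )?syntce orf)*( output_tag)?$",
                 paste0(rle_sig, ""))
  if (!legal) {
    stop(sprintf("illegal part order: %s (expected switch* orf ([linker] syntce orf)* [output_tag])",
                 rle_sig), call. = FALSE)
  }
  lapply(parts, validate_part)
  transcript <- ""
  ann <- list()
  junctions <- list()
  pos <- 0L
  i <- 1L
  add_ann <- function(name, role, start, end, frame = NA_integer_) {
    ann[[length(ann) + 1L]] <<- data.frame(name = name, role = role,
                                           start = start, end = end,
                                           frame = as.integer(frame))
  }
  # leading switches
  while (i <= length(parts) && roles[i] == "switch") {
    w <- seq_len_nt(parts[[i]]$sequence)
    add_ann(parts[[i]]$name, "switch", pos, pos + w, pos %% 3L)
    transcript <- paste0(transcript, unclass(parts[[i]]$sequence))
    pos <- pos + w
    i <- i + 1L
  }
  prev_orf <- NULL  # list(name, start, frame); coding end patched at junctions
  while (i <= length(parts)) {
    p <- parts[[i]]
    if (p$role == "orf") {
      orf_seq <- unclass(p$sequence)
      n <- nchar(orf_seq)
      # is this ORF followed (possibly via a linker) by a synTCE?
      followed <- (i < length(parts) && roles[i + 1L] == "syntce") ||
        (i + 1L < length(parts) && roles[i + 1L] == "linker" &&
           roles[i + 2L] == "syntce")
      body <- if (followed) substr(orf_seq, 1L, n - 3L) else orf_seq
      start_here <- pos
      frame_here <- pos %% 3L
      if (!is.null(prev_orf)) {
        expected <- junction_frame(prev_orf$frame)
        if (frame_here != expected) {
          stop(sprintf("frame inconsistency at junction before orf '%s': frame %d, expected %d",
                       p$name, frame_here, expected), call. = FALSE)
        }
      }
      add_ann(p$name, "CDS", start_here, start_here + nchar(body), frame_here)
      transcript <- paste0(transcript, body)
      pos <- pos + nchar(body)
      prev_orf <- list(name = p$name, start = start_here, frame = frame_here,
                       ann_index = length(ann))
    } else if (p$role == "linker") {
      w <- seq_len_nt(p$sequence)
      if (length(scan_stop_codons(unclass(p$sequence), 0L))) {
        stop(sprintf("linker '%s' contains a stop codon in the translated frame",
                     p$name), call. = FALSE)
      }
      add_ann(p$name, "linker", pos, pos + w, pos %% 3L)
      transcript <- paste0(transcript, unclass(p$sequence))
      pos <- pos + w
    } else if (p$role == "syntce") {
      sl <- p$metadata$stem_len; ll <- p$metadata$loop_len
      s <- unclass(p$sequence)
      t_start <- pos
      add_ann(p$name, "syntce", pos, pos + nchar(s))
      if (sl > 0L) {
        add_ann(paste0(p$name, ":stem5"), "stem5", pos, pos + sl)
      }
      add_ann(paste0(p$name, ":loop"), "loop", pos + sl, pos + sl + ll)
      rbs_off <- if (!is.null(p$metadata$rbs_offset)) p$metadata$rbs_offset else 0L
      rbs_len <- if (!is.null(p$metadata$rbs)) nchar(p$metadata$rbs) else 8L
      add_ann(paste0(p$name, ":rbs"), "rbs", pos + sl + rbs_off,
              pos + sl + rbs_off + rbs_len)
      if (sl > 0L) {
        add_ann(paste0(p$name, ":stem3"), "stem3", pos + sl + ll,
                pos + 2L * sl + ll)
      }
      transcript <- paste0(transcript, s)
      pos <- pos + nchar(s)
      # junction: overlap bases are the last 2 nt; the downstream orf's AUG
      # completes both the stop codon and the URAUG motif
      stop_start <- pos - 2L
      if ((stop_start - prev_orf$start) %% 3L != 0L) {
        stop(sprintf("frame error at junction '%s': stop codon not in upstream frame",
                     p$name), call. = FALSE)
      }
      junctions[[length(junctions) + 1L]] <- list(
        name = p$name, stop_start = stop_start, start_start = pos,
        hairpin_start = t_start, stem_len = sl, loop_len = ll,
        upstream_orf = prev_orf$name, upstream_start = prev_orf$start,
        upstream_frame = prev_orf$frame, upstream_ann = prev_orf$ann_index)
      # upstream coding annotation runs through to the junction stop
      ann[[prev_orf$ann_index]]$end <- stop_start + 3L
    } else if (p$role == "output_tag") {
      w <- seq_len_nt(p$sequence)
      add_ann(p$name, "output_tag", pos, pos + w)
      transcript <- paste0(transcript, unclass(p$sequence))
      pos <- pos + w
    }
    i <- i + 1L
  }
  ann_df <- do.call(rbind, ann)
  design <- structure(list(transcript = to_rna(transcript),
                           annotations = ann_df, junctions = junctions,
                           truth_table = NULL, gate = NULL),
                      class = "operon_design")
  reparse_operon(design)
  design
}

# internal: integrity re-check of an assembled design -- every CDS decodes
# stop-free in its annotated frame and ends at a stop; every junction URAUG
# is found at the annotated position.
reparse_operon <- function(design) {
  s <- unclass(design$transcript)
  cds <- design$annotations[design$annotations$role == "CDS", , drop = FALSE]
  for (k in seq_len(nrow(cds))) {
    sub <- substr(s, cds$start[k] + 1L, cds$end[k])
    if (substr(sub, 1, 3) != "AUG") {
      stop(sprintf("CDS '%s' does not begin with AUG on reparse", cds$name[k]),
           call. = FALSE)
    }
    stops <- scan_stop_codons(sub, 0L)
    if (!identical(stops, nchar(sub) - 3L)) {
      stop(sprintf("CDS '%s' does not decode stop-free to its annotated stop",
                   cds$name[k]), call. = FALSE)
    }
  }
  for (j in design$junctions) {
    if (!(j$stop_start %in% find_overlap_motif(s))) {
      stop(sprintf("junction '%s': URAUG not found at annotated position %d",
                   j$name, j$stop_start), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.operon_design <- function(x, ...) {
  cat(sprintf("<operon_design> %d nt, %d annotations, %d junction(s)%s\n",
              seq_len_nt(x$transcript), nrow(x$annotations),
              length(x$junctions),
              if (!is.null(x$gate)) paste0(", gate ", x$gate) else ""))
  invisible(x)
}

#' Classify an intergenic distance
#'
#' Coupling efficiency bands: "optimal" for -1..5 nt (the URAUG overlap is
#' -1), "degrading" for 6..14 (gradual loss of dynamic range), "poor" for
#' 15 and beyond.
#'
#' @param d Integer intergenic distance(s), >= -1.
#' @return Character vector of classes.
#' @export
distance_class <- function(d) {
  if (any(d < -1L)) stop("intergenic distance cannot be below -1", call. = FALSE)
  ifelse(d <= 5L, "optimal", ifelse(d <= 14L, "degrading", "poor"))
}

#' Validate one coupling junction of an assembled operon
#'
#' Computes the intergenic distance (start codon first base minus stop
#' codon last base minus 1; -1 for the URAUG overlap), the RBS strength at
#' the coupled start codon, the hairpin structure check over the synTCE
#' window, the distance class, and warnings for long upstream translated
#' runs (> 1 kb: coupling decay; > 3 kb: ON/OFF states converge).
#'
#' @param design An `operon_design`.
#' @param junction_index 1-based junction index.
#' @param model An [energy_model()].
#' @param config An [rbs_config()].
#' @param structure_threshold Hairpin stability threshold (kcal/mol).
#' @return A `junction_report` list.
#' @export
validate_junction <- function(design, junction_index, model = energy_model(),
                              config = rbs_config(),
                              structure_threshold = -6) {
  stopifnot(inherits(design, "operon_design"),
            junction_index >= 1L, junction_index <= length(design$junctions))
  j <- design$junctions[[junction_index]]
  s <- unclass(design$transcript)
  d <- j$start_start - (j$stop_start + 2L) - 1L
  rbs <- rbs_strength(s, j$start_start, model, config)
  hp_len <- 2L * j$stem_len + j$loop_len
  sc <- if (hp_len > 0L && j$stem_len > 0L) {
    hairpin_structure_check(substr(s, j$hairpin_start + 1L,
                                   j$hairpin_start + hp_len),
                            j$stem_len, j$loop_len, model,
                            threshold = structure_threshold)
  } else list(pass = FALSE, designed_dG = NA_real_, best_alt_dG = Inf,
              formable = FALSE)
  warnings <- character(0)
  run_len <- j$stop_start - j$upstream_start
  if (run_len > 3000L) {
    warnings <- c(warnings, sprintf(
      "upstream translated run of %d nt exceeds 3 kb: ON/OFF states converged, coupling is lost",
      run_len))
  } else if (run_len > 1000L) {
    warnings <- c(warnings, sprintf(
      "upstream translated run of %d nt exceeds 1 kb: expect gradual coupling decay",
      run_len))
  }
  structure(list(junction = j$name, intergenic_distance = d,
                 distance_class = distance_class(d), rbs_score = rbs,
                 structure_check = sc, upstream_run = run_len,
                 warnings = warnings),
            class = "junction_report")
}

#' @export
print.junction_report <- function(x, ...) {
  cat(sprintf("<junction_report> %s: distance %d (%s), RBS total %+0.2f, structure %s\n",
              x$junction, x$intergenic_distance, x$distance_class,
              x$rbs_score$total,
              if (isTRUE(x$structure_check$pass)) "ok" else "FAIL"))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Tabulate junction reports for a design
#'
#' @inheritParams validate_junction
#' @return data.frame with one row per junction.
#' @export
junction_table <- function(design, model = energy_model(),
                           config = rbs_config(), structure_threshold = -6) {
  reps <- lapply(seq_along(design$junctions), validate_junction,
                 design = design, model = model, config = config,
                 structure_threshold = structure_threshold)
  do.call(rbind, lapply(reps, function(r) {
    data.frame(junction = r$junction,
               intergenic_distance = r$intergenic_distance,
               distance_class = r$distance_class,
               rbs_total = r$rbs_score$total,
               dG_rRNA_mRNA = r$rbs_score$dG_rRNA_mRNA,
               dG_spacing = r$rbs_score$dG_spacing,
               designed_dG = r$structure_check$designed_dG,
               structure_pass = r$structure_check$pass,
               upstream_run = r$upstream_run,
               n_warnings = length(r$warnings))
  }))
}

#' Lay out a ribocomputing logic gate
#'
#' Builds the concatenated gate transcript: sensor (switch) modules in one
#' reading frame upstream of the output ORF(s), with synTCEs chaining
#' additional outputs. OR and NAND gates take 2-6 switch modules (each a
#' multiple of 3 nt so the concatenated modules share a frame); AND and
#' NIMPLY take a single switch whose metadata names the two split-trigger
#' inputs (`inputs = c("A", "B")`). A truth-table stub recording the
#' expected qualitative output per input combination is attached.
#'
#' @param gate One of "OR", "AND", "NAND", "NIMPLY".
#' @param switch_parts List of switch [part()]s.
#' @param output_parts List of orf [part()]s (>= 1; extra outputs need
#'   matching `syntce_parts`).
#' @param syntce_parts List of syntce [part()]s, length
#'   `length(output_parts) - 1`.
#' @return An `operon_design` with `$gate` and `$truth_table` set.
#' @export
gate_layout <- function(gate = c("OR", "AND", "NAND", "NIMPLY"),
                        switch_parts, output_parts, syntce_parts = list()) {
  gate <- match.arg(gate)
  stopifnot(length(output_parts) >= 1L,
            length(syntce_parts) == length(output_parts) - 1L)
  if (gate %in% c("OR", "NAND")) {
    ns <- length(switch_parts)
    if (ns < 2L) stop(gate, " gate needs at least 2 switch modules", call. = FALSE)
    if (ns > 6L) {
      stop(gate, " gate with more than 6 switch modules is unsupported",
           call. = FALSE)
    }
    bad <- vapply(switch_parts,
                  function(p) seq_len_nt(p$sequence) %% 3L != 0L, logical(1))
    if (any(bad)) {
      stop("switch modules must be multiples of 3 nt to share a reading frame",
           call. = FALSE)
    }
    inputs <- vapply(switch_parts, function(p) p$name, character(1))
  } else {
    if (length(switch_parts) != 1L) {
      stop(gate, " gate takes exactly one switch module", call. = FALSE)
    }
    inputs <- switch_parts[[1L]]$metadata$inputs
    if (is.null(inputs) || length(inputs) != 2L) {
      stop(gate, " gate switch needs metadata$inputs naming the two split-trigger inputs",
           call. = FALSE)
    }
  }
  parts <- switch_parts
  parts[[length(parts) + 1L]] <- output_parts[[1L]]
  if (length(output_parts) > 1L) {
    for (k in seq_along(syntce_parts)) {
      parts[[length(parts) + 1L]] <- syntce_parts[[k]]
      parts[[length(parts) + 1L]] <- output_parts[[k + 1L]]
    }
  }
  design <- assemble_operon(parts)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(inputs)))
  names(combos) <- inputs
  on <- switch(gate,
    OR = apply(combos, 1L, any),
    AND = apply(combos, 1L, all),
    NAND = !apply(combos, 1L, all),
    NIMPLY = combos[[1L]] & !combos[[2L]])
  combos$expected <- ifelse(on, "ON", "OFF")
  design$gate <- gate
  design$truth_table <- combos
  design
}

#' Scan a sequence for putative internal ribosome binding sites
#'
#' Reports every AUG or GUG start codon whose two-term RBS strength
#' ([rbs_strength()]) is at or below a threshold - the spurious initiation
#' sites that accumulate in long linkers and degrade coupling.
#'
#' @param seq Sequence to scan.
#' @param model An [energy_model()].
#' @param config An [rbs_config()] (carries the anti-SD).
#' @param threshold Report sites with total <= threshold kcal/mol
#'   (default -4.5; relaxing it upward can only add hits).
#' @return data.frame: 0-based `position`, `codon`, `total`,
#'   `dG_rRNA_mRNA`, `dG_spacing`; ascending position.
#' @export
scan_internal_rbs <- function(seq, model = energy_model(),
                              config = rbs_config(), threshold = -4.5) {
  s <- unclass(to_rna(seq))
  pos <- sort(c(match_iupac(s, "AUG"), match_iupac(s, "GUG")))
  rows <- lapply(pos, function(p) {
    r <- rbs_strength(s, p, model, config, allow_gug = TRUE)
    data.frame(position = p, codon = substr(s, p + 1L, p + 3L),
               total = r$total, dG_rRNA_mRNA = r$dG_rRNA_mRNA,
               dG_spacing = r$dG_spacing)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(position = integer(0), codon = character(0),
               total = numeric(0), dG_rRNA_mRNA = numeric(0),
               dG_spacing = numeric(0))
  }
  out[out$total <= threshold, , drop = FALSE]
}
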