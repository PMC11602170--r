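# Readers/writers for the standard exchange formats (FASTA parts registry
# with a sidecar metadata table, GenBank construct records), the seeded
# fixture generator, the YAML configuration, and the command-line entry
# point. Internal coordinates are 0-based half-open; GenBank output is
# 1-based inclusive, converted at this boundary.

#' Specify the synthetic-part fixture generator
#'
#' Describes the synthetic ORFs and linkers generated for tests and demos:
#' lengths (multiples of 3 for ORFs and linkers, both are translated), a GC
#' content band, and optionally the exclusion of Shine-Dalgarno-like
#' windows (no window hybridizing to the anti-SD with 4 or more contiguous
#' pairs) so that coupling measurements are not confounded by spurious
#' internal initiation.
#'
#' @param n_orfs Number of ORFs to generate.
#' @param orf_length_range Min/max ORF length in nt (multiples of 3,
#'   including start and stop codons).
#' @param linker_length_range Min/max linker length in nt (multiples of 3).
#' @param gc_range GC fraction band, within (0, 1).
#' @param exclude_sd_like Scrub SD-like windows (default TRUE).
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_orfs = 3L, orf_length_range = c(90L, 300L),
                         linker_length_range = c(30L, 90L),
                         gc_range = c(0.35, 0.65), exclude_sd_like = TRUE,
                         seed = 1L) {
  stopifnot(n_orfs >= 1L, length(orf_length_range) == 2L,
            length(gc_range) == 2L, gc_range[1] > 0, gc_range[2] < 1,
            gc_range[1] <= gc_range[2],
            orf_length_range[1] >= 9L,
            all(orf_length_range %% 3L == 0L),
            all(linker_length_range %% 3L == 0L))
  structure(list(n_orfs = as.integer(n_orfs),
                 orf_length_range = as.integer(orf_length_range),
                 linker_length_range = as.integer(linker_length_range),
                 gc_range = gc_range,
                 exclude_sd_like = isTRUE(exclude_sd_like),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

gc_fraction <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  mean(ch %in% c("G", "C"))
}

# internal: first window (0-based start) hybridizing to anti_sd with a run
# of >= min_pairs contiguous WC/GU pairs, or NA when none
first_sd_like <- function(s, anti_sd, min_pairs = 4L) {
  n <- nchar(s); L <- nchar(anti_sd)
  top <- strsplit(s, "", fixed = TRUE)[[1]]
  rev_asd <- rev(strsplit(anti_sd, "", fixed = TRUE)[[1]])
  for (off in seq.int(-(L - 1L), n - 1L)) {
    j <- seq_len(n) - off
    valid <- j >= 1L & j <= L
    partner <- ifelse(valid, rev_asd[pmax(pmin(j, L), 1L)], "-")
    paired <- valid & is_paired(top, partner)
    r <- rle(paired)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_pairs)
    if (length(hit)) return(starts[hit[1L]] - 1L)
  }
  NA_integer_
}

# internal: random in-frame codon string of n_codons with no stop codons
sample_codons <- function(n_codons) {
  paste(sample(NON_STOP_CODONS, n_codons, replace = TRUE), collapse = "")
}

# internal: draw a stop-free codon body of given nt length within the GC
# band, scrubbing SD-like windows by local codon resampling when asked
make_codon_body <- function(len_nt, gc_range, exclude_sd_like, anti_sd,
                            max_rounds = 2000L) {
  n_codons <- len_nt %/% 3L
  for (restart in 1:25) {
    body <- sample_codons(n_codons)
    if (exclude_sd_like) {
      ok <- FALSE
      for (round in seq_len(max_rounds)) {
        hit <- first_sd_like(body, anti_sd)
        if (is.na(hit)) { ok <- TRUE; break }
        # resample the codons covering the offending window
        c0 <- hit %/% 3L + 1L
        c1 <- min(n_codons, (hit + nchar(anti_sd)) %/% 3L + 1L)
        repl <- sample_codons(c1 - c0 + 1L)
        body <- paste0(substr(body, 1L, (c0 - 1L) * 3L), repl,
                       substr(body, c1 * 3L + 1L, len_nt))
      }
      if (!ok) next
    }
    gc <- gc_fraction(body)
    if (gc >= gc_range[1] && gc <= gc_range[2]) return(body)
  }
  stop(sprintf("could not generate a %d-nt body satisfying the fixture spec",
               len_nt), call. = FALSE)
}

#' Generate a synthetic ORF part
#'
#' Deterministic given the seed: AUG start, stop-free random codon body
#' within the GC band (SD-like windows scrubbed when the spec asks), and a
#' terminal UAA stop.
#'
#' @param spec A [fixture_spec()].
#' @param name Part name.
#' @param length ORF length in nt (multiple of 3); drawn from the spec's
#'   range when NULL.
#' @param seed Seed override (defaults to `spec$seed`).
#' @param anti_sd Anti-SD used for the SD-like exclusion.
#' @return An orf [part()].
#' @export
make_fixture_orf <- function(spec = fixture_spec(), name = "orf",
                             length = NULL, seed = spec$seed,
                             anti_sd = "ACCUCCUUA") {
  with_seed(seed, {
    len <- if (is.null(length)) {
      3L * sample(seq(spec$orf_length_range[1L] %/% 3L,
                      spec$orf_length_range[2L] %/% 3L), 1L)
    } else as.integer(length)
    if (len %% 3L != 0L || len < 9L) {
      stop("ORF length must be a multiple of 3 and at least 9 nt", call. = FALSE)
    }
    body <- make_codon_body(len - 6L, spec$gc_range, spec$exclude_sd_like,
                            unclass(to_rna(anti_sd)))
    part(name, "orf", paste0("AUG", body, "UAA"))
  })
}

#' Generate a synthetic linker part
#'
#' A stop-free translated spacer (multiple of 3 nt), SD-like windows
#' scrubbed under the same rule as [make_fixture_orf()].
#'
#' @inheritParams make_fixture_orf
#' @param length Linker length in nt (multiple of 3); drawn from the
#'   spec's range when NULL.
#' @return A linker [part()].
#' @export
make_fixture_linker <- function(spec = fixture_spec(), name = "linker",
                                length = NULL, seed = spec$seed,
                                anti_sd = "ACCUCCUUA") {
  with_seed(seed, {
    len <- if (is.null(length)) {
      3L * sample(seq(spec$linker_length_range[1L] %/% 3L,
                      spec$linker_length_range[2L] %/% 3L), 1L)
    } else as.integer(length)
    if (len %% 3L != 0L || len < 3L) {
      stop("linker length must be a positive multiple of 3", call. = FALSE)
    }
    body <- make_codon_body(len, spec$gc_range, spec$exclude_sd_like,
                            unclass(to_rna(anti_sd)))
    part(name, "linker", body)
  })
}

#' Generate a full synthetic parts registry
#'
#' `n_orfs` fixture ORFs plus one linker, each drawn under a sub-seed
#' derived from the spec seed so the registry is reproducible as a whole.
#'
#' @param spec A [fixture_spec()].
#' @return Named list of [part()]s.
#' @export
make_fixture_parts <- function(spec = fixture_spec()) {
  parts <- list()
  for (k in seq_len(spec$n_orfs)) {
    nm <- sprintf("orf%d", k)
    parts[[nm]] <- make_fixture_orf(spec, nm, seed = spec$seed * 131L + k)
  }
  parts[["linker1"]] <- make_fixture_linker(spec, "linker1",
                                            seed = spec$seed * 131L + 101L)
  parts
}

#' Read a parts registry from FASTA (plus optional metadata table)
#'
#' Sequences are normalized to RNA on input (T read as U). Roles and
#' additional metadata come from a sidecar tab-separated table with columns
#' `name`, `role` and any extra columns (stored in the part metadata;
#' `stem_len`/`loop_len` are converted to integers for syntce parts).
#' Without a metadata table every record is read as an `orf`.
#'
#' @param path FASTA file.
#' @param metadata Optional path to the sidecar TSV.
#' @return Named list of [part()]s, in file order.
#' @export
read_parts <- function(path, metadata = NULL) {
  set <- Biostrings::readBStringSet(path)
  meta <- if (!is.null(metadata)) {
    utils::read.delim(metadata, stringsAsFactors = FALSE)
  } else NULL
  parts <- list()
  for (k in seq_along(set)) {
    nm <- sub("\\s.*$", "", names(set)[k])
    role <- "orf"
    md <- list()
    if (!is.null(meta) && nm %in% meta$name) {
      row <- meta[meta$name == nm, , drop = FALSE][1L, ]
      role <- row$role
      extra <- setdiff(names(row), c("name", "role"))
      md <- as.list(row[extra])
      for (f in intersect(c("stem_len", "loop_len", "rbs_offset"), names(md))) {
        md[[f]] <- as.integer(md[[f]])
      }
    }
    parts[[nm]] <- part(nm, role, as.character(set[[k]]), md)
  }
  parts
}

#' Write a parts registry as FASTA plus metadata TSV
#'
#' @param parts Named list of [part()]s.
#' @param fasta Output FASTA path.
#' @param metadata Output TSV path (NULL to skip).
#' @return Invisibly, the FASTA path.
#' @export
write_parts <- function(parts, fasta, metadata = NULL) {
  lines <- unlist(lapply(parts, function(p) {
    c(paste0(">", p$name), unclass(p$sequence))
  }))
  writeLines(lines, fasta)
  if (!is.null(metadata)) {
    rows <- lapply(parts, function(p) {
      base <- data.frame(name = p$name, role = p$role)
      for (f in c("stem_len", "loop_len", "rbs_offset", "rbs")) {
        base[[f]] <- if (!is.null(p$metadata[[f]])) p$metadata[[f]] else NA
      }
      base
    })
    utils::write.table(do.call(rbind, rows), metadata, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}

# --- GenBank construct records ------------------------------------------

genbank_role_feature <- function(role) {
  switch(role,
         CDS = "CDS", rbs = "RBS",
         "misc_feature")
}

#' Write an assembled construct as a GenBank or FASTA record
#'
#' GenBank output carries one CDS feature per ORF (with `/codon_start=1`
#' relative to the feature), an `RBS` feature per synTCE RBS and
#' `misc_feature` entries for the remaining annotations, all in 1-based
#' inclusive coordinates converted from the internal 0-based half-open
#' convention. No timestamps are written, so identical designs produce
#' byte-identical files.
#'
#' @param design An `operon_design`.
#' @param path Output file.
#' @param format "genbank" or "fasta".
#' @param name Locus/record name.
#' @return Invisibly, `path`.
#' @export
write_construct <- function(design, path, format = c("genbank", "fasta"),
                            name = "operon") {
  format <- match.arg(format)
  s <- unclass(design$transcript)
  if (format == "fasta") {
    writeLines(c(paste0(">", name), s), path)
    return(invisible(path))
  }
  n <- nchar(s)
  lines <- c(sprintf("LOCUS       %s %d bp    RNA     linear   SYN", name, n),
             sprintf("DEFINITION  %s multi-output operon transcript.", name),
             "FEATURES             Location/Qualifiers")
  fmt_q <- function(k, v) sprintf("                     /%s=%s", k, v)
  for (r in seq_len(nrow(design$annotations))) {
    a <- design$annotations[r, ]
    feat <- genbank_role_feature(a$role)
    lines <- c(lines,
               sprintf("     %-15s %d..%d", feat, a$start + 1L, a$end),
               fmt_q("label", sprintf("\"%s\"", a$name)),
               fmt_q("note", sprintf("\"role:%s\"", a$role)))
    if (a$role == "CDS") {
      lines <- c(lines, fmt_q("codon_start", "1"))
    }
  }
  lines <- c(lines, "ORIGIN")
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(n, p + 59L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(nchar(chunk), seq(10, nchar(chunk) + 9, 10)))
    lines <- c(lines, sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GenBank construct record written by [write_construct()]
#'
#' Minimal parser for the subset of the flat-file format this package
#' writes: LOCUS, simple `a..b` feature locations with `/label` and
#' `/note="role:..."` qualifiers, and the ORIGIN block. Coordinates are
#' converted back to 0-based half-open.
#'
#' @param path GenBank file.
#' @return List with `name`, `sequence` (`nuc_seq`) and `annotations`
#'   (data.frame name/role/start/end).
#' @export
read_genbank_construct <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank record: no LOCUS line", call. = FALSE)
  name <- strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1]][1]
  origin_at <- grep("^ORIGIN", lines)
  if (!length(origin_at)) stop("no ORIGIN block", call. = FALSE)
  seq_lines <- lines[(origin_at + 1L):(length(lines))]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq_txt <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))
  feat_start <- grep("^FEATURES", lines)
  ann <- list()
  cur <- NULL
  for (ln in lines[(feat_start + 1L):(origin_at - 1L)]) {
    if (grepl("^     \\S", ln)) {
      if (!is.null(cur)) ann[[length(ann) + 1L]] <- cur
      bits <- strsplit(trimws(ln), "\\s+")[[1]]
      loc <- strsplit(bits[2L], "\\.\\.")[[1]]
      if (length(loc) != 2L) {
        stop(sprintf("unsupported feature location '%s' (line: %s)", bits[2L], ln),
             call. = FALSE)
      }
      cur <- data.frame(name = NA_character_, role = NA_character_,
                        start = as.integer(loc[1L]) - 1L,
                        end = as.integer(loc[2L]))
    } else if (grepl("/label=", ln)) {
      cur$name <- gsub("\"", "", sub(".*?/label=", "", ln))
    } else if (grepl("/note=\"role:", ln)) {
      cur$role <- gsub("\"", "", sub(".*?/note=\"role:", "", ln))
    }
  }
  if (!is.null(cur)) ann[[length(ann) + 1L]] <- cur
  list(name = name, sequence = to_rna(seq_txt),
       annotations = do.call(rbind, ann))
}

# --- configuration -------------------------------------------------------

#' Read a YAML design configuration
#'
#' Recognized keys (all optional, defaults per the constructors):
#' `stem_len`, `loop_seq`, `overlap_codon`, `upstream_context`, `rbs`,
#' `pattern_constraints`, `n_candidates`, `max_attempts` (design);
#' `anti_sd`, `spacing_opt`, `k_compressed`, `k_stretched`,
#' `max_spacing_penalty`, `search_window` (RBS scoring);
#' `structure_threshold`; `energy_params` (path to an alternative
#' parameter TSV); `fixtures` (sub-map with [fixture_spec()] keys).
#'
#' @param path YAML file.
#' @param seed Seed override (takes precedence over the file).
#' @return List with `spec` ([syntce_spec()]), `config` ([rbs_config()]),
#'   `model` ([energy_model()]), `structure_threshold` and `fixtures`.
#' @export
read_config <- function(path = NULL, seed = NULL) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  pick <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  use_seed <- if (!is.null(seed)) as.integer(seed) else pick("seed", 1L)
  spec <- syntce_spec(
    stem_len = pick("stem_len", 6L),
    loop_seq = pick("loop_seq", "AGAGGAGACAACAUC"),
    overlap_codon = pick("overlap_codon", "UAA"),
    upstream_context = pick("upstream_context", "GGCGGCAGCGGCUAA"),
    rbs = pick("rbs", "AGAGGAGA"),
    pattern_constraints = unlist(pick("pattern_constraints", default_patterns())),
    seed = use_seed,
    n_candidates = pick("n_candidates", 10L),
    max_attempts = pick("max_attempts", 20000L))
  config <- rbs_config(
    spacing_opt = pick("spacing_opt", 5L),
    k_compressed = pick("k_compressed", 0.30),
    k_stretched = pick("k_stretched", 0.15),
    max_spacing_penalty = pick("max_spacing_penalty", 25),
    search_window = pick("search_window", 20L),
    anti_sd = pick("anti_sd", "ACCUCCUUA"))
  model <- if (!is.null(cfg$energy_params)) energy_model(cfg$energy_params) else energy_model()
  fx <- cfg$fixtures
  fixtures <- fixture_spec(
    n_orfs = if (!is.null(fx$n_orfs)) fx$n_orfs else 3L,
    orf_length_range = if (!is.null(fx$orf_length_range)) unlist(fx$orf_length_range) else c(90L, 300L),
    linker_length_range = if (!is.null(fx$linker_length_range)) unlist(fx$linker_length_range) else c(30L, 90L),
    gc_range = if (!is.null(fx$gc_range)) unlist(fx$gc_range) else c(0.35, 0.65),
    exclude_sd_like = if (!is.null(fx$exclude_sd_like)) fx$exclude_sd_like else TRUE,
    seed = use_seed)
  list(spec = spec, config = config, model = model,
       structure_threshold = pick("structure_threshold", -6),
       fixtures = fixtures)
}

# --- command-line interface ---------------------------------------------

cli_log <- function(...) message("[syntce] ", sprintf(...))

cli_parse_flags <- function(args) {
  flags <- list()
  positional <- character(0)
  k <- 1L
  while (k <= length(args)) {
    a <- args[[k]]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (k == length(args) || grepl("^--", args[[k + 1L]])) {
        flags[[key]] <- TRUE
      } else {
        flags[[key]] <- args[[k + 1L]]
        k <- k + 1L
      }
    } else positional <- c(positional, a)
    k <- k + 1L
  }
  list(flags = flags, positional = positional)
}

#' Command-line entry point
#'
#' Subcommands: `design` (ranked candidates FASTA + score table),
#' `fixtures` (synthetic parts FASTA + metadata), `assemble` (parts +
#' layout -> GenBank/FASTA), `validate` (construct -> junction report TSV),
#' `score` (designed candidates -> feature table), `fit` (feature table +
#' measurement CSV -> regression report). Common flags: `--config <yaml>`,
#' `--seed <int>`, `--out <dir>`, `--format genbank|fasta`. Identical
#' config and seed give byte-identical outputs.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments; pass explicitly to run in-process).
#' @return Invisibly, the output directory. Called for its file side
#'   effects.
#' @export
syntce_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: syntce <design|fixtures|assemble|validate|score|fit> [--config F] [--seed N] [--out DIR]\n")
    return(invisible(NULL))
  }
  cmd <- args[[1L]]
  parsed <- cli_parse_flags(args[-1L])
  fl <- parsed$flags
  out_dir <- if (!is.null(fl$out)) fl$out else "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(fl$seed)) as.integer(fl$seed) else NULL
  ctx <- read_config(fl$config, seed = seed)
  w_tab <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (cmd == "design") {
    cands <- design_syntce(ctx$spec, ctx$model, ctx$config,
                           ctx$structure_threshold)
    tab <- candidate_table(cands)
    fasta <- unlist(lapply(seq_along(cands), function(i) {
      c(sprintf(">candidate_%03d stem5=%s pass=%s seed=%d", i,
                cands[[i]]$stem5, candidate_passes(cands[[i]]),
                cands[[i]]$provenance$seed),
        unclass(cands[[i]]$cassette))
    }))
    writeLines(fasta, file.path(out_dir, "candidates.fasta"))
    w_tab(tab, "scores.tsv")
    cli_log("design: %d candidates (%d passing) -> %s",
            nrow(tab), sum(tab$passes), out_dir)
  } else if (cmd == "fixtures") {
    parts <- make_fixture_parts(ctx$fixtures)
    write_parts(parts, file.path(out_dir, "parts.fasta"),
                file.path(out_dir, "parts_meta.tsv"))
    cli_log("fixtures: %d parts -> %s", length(parts), out_dir)
  } else if (cmd == "assemble") {
    if (is.null(fl$parts) || is.null(fl$layout)) {
      stop("assemble needs --parts <fasta> (with --meta <tsv>) and --layout <name,name,...>",
           call. = FALSE)
    }
    parts <- read_parts(fl$parts, fl$meta)
    layout <- strsplit(fl$layout, ",", fixed = TRUE)[[1]]
    missing <- setdiff(layout, names(parts))
    if (length(missing)) {
      stop("layout names not in parts registry: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    design <- assemble_operon(parts[layout])
    format <- if (!is.null(fl$format)) fl$format else "genbank"
    ext <- if (format == "genbank") "gb" else "fasta"
    write_construct(design, file.path(out_dir, paste0("construct.", ext)),
                    format = format)
    w_tab(junction_table(design, ctx$model, ctx$config,
                         ctx$structure_threshold), "junctions.tsv")
    cli_log("assemble: %d nt transcript, %d junction(s) -> %s",
            seq_len_nt(design$transcript), length(design$junctions), out_dir)
  } else if (cmd == "validate") {
    if (is.null(fl$construct)) stop("validate needs --construct <gb>", call. = FALSE)
    rec <- read_genbank_construct(fl$construct)
    hits <- find_overlap_motif(rec$sequence)
    scan <- scan_internal_rbs(rec$sequence, ctx$model, ctx$config)
    w_tab(data.frame(urAUG_position = hits), "junction_motifs.tsv")
    w_tab(scan, "internal_rbs.tsv")
    cli_log("validate: %d URAUG motif(s), %d internal RBS hit(s) -> %s",
            length(hits), nrow(scan), out_dir)
  } else if (cmd == "score") {
    cands <- design_syntce(ctx$spec, ctx$model, ctx$config,
                           ctx$structure_threshold)
    w_tab(feature_table(cands, ctx$model, ctx$config), "features.tsv")
    cli_log("score: %d rows -> %s", length(cands), out_dir)
  } else if (cmd == "fit") {
    if (is.null(fl$features) || is.null(fl$measurements)) {
      stop("fit needs --features <tsv> and --measurements <csv>", call. = FALSE)
    }
    feat_col <- if (!is.null(fl$feature)) fl$feature else "rbs_total"
    feats <- utils::read.delim(fl$features, stringsAsFactors = FALSE)
    samples <- read_measurements(fl$measurements)
    ids <- unique(vapply(samples, function(s) s$construct_id, character(1)))
    rows <- lapply(ids, function(id) {
      on <- samples[[paste0(id, ".ON")]]; off <- samples[[paste0(id, ".OFF")]]
      if (is.null(on) || is.null(off)) return(NULL)
      fc <- fold_change(on, off)
      data.frame(construct_id = id, fold = fc$fold,
                 relative_error = fc$relative_error)
    })
    fc_tab <- do.call(rbind, rows)
    merged <- merge(feats, fc_tab, by.x = "id", by.y = "construct_id")
    fit <- fit_linear(merged[[feat_col]], merged$fold)
    w_tab(data.frame(feature = feat_col, slope = fit$slope,
                     intercept = fit$intercept, r_squared = fit$r_squared,
                     n_points = fit$n_points), "fit.tsv")
    w_tab(merged, "joined.tsv")
    cli_log("fit: %s vs fold change, r^2 = %.3f -> %s", feat_col,
            fit$r_squared, out_dir)
  } else {
    stop("unknown subcommand: ", cmd, call. = FALSE)
  }
  invisible(out_dir)
}
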