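#' @importFrom Biostrings RNAString reverseComplement matchPattern
#' @importFrom BiocGenerics start
#' @importFrom utils head read.delim write.table
#' @importFrom stats lm coef setNames sd runif
NULL

#' Normalize raw input into a validated RNA sequence
#'
#' Accepts DNA or RNA text (any case, surrounding whitespace allowed) and
#' returns the uppercase RNA string used throughout the package. Thymine is
#' transcribed to uracil at this boundary; ambiguity codes are rejected in
#' concrete sequences (they are allowed only in patterns, see
#' [match_iupac()]).
#'
#' @param raw A single character string over A/C/G/T/U, any case.
#' @return A `nuc_seq` object (a validated character scalar, 5'->3').
#' @examples
#' to_rna("atgTTT")   # "AUGUUU"
#' @export
to_rna <- function(raw) {
  if (inherits(raw, "nuc_seq")) return(raw)
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("sequence input must be a single character string", call. = FALSE)
  }
  s <- toupper(gsub("\\s", "", raw))
  if (!nzchar(s)) stop("empty sequence", call. = FALSE)
  s <- chartr("T", "U", s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% RNA_BASES)
  if (length(bad)) {
    stop(sprintf("invalid residue '%s' at position %d (0-based %d)",
                 ch[bad[1]], bad[1], bad[1] - 1L), call. = FALSE)
  }
  structure(s, class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  s <- unclass(x)
  shown <- if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
  cat(sprintf("<nuc_seq> %d nt: %s\n", nchar(s), shown))
  invisible(x)
}

#' @export
as.character.nuc_seq <- function(x, ...) unclass(x)

seq_len_nt <- function(seq) nchar(unclass(to_rna(seq)))

#' Reverse complement of an RNA sequence
#'
#' @param seq A `nuc_seq` or coercible string.
#' @return The reverse complement as a `nuc_seq` (A<->U, C<->G).
#' @examples
#' revcomp("AUGC")  # "GCAU"
#' @export
revcomp <- function(seq) {
  s <- to_rna(seq)
  to_rna(as.character(Biostrings::reverseComplement(Biostrings::RNAString(unclass(s)))))
}

# internal: complement without reversal (bottom strand written 3'->5')
complement_chars <- function(ch) chartr("ACGU", "UGCA", ch)

#' A labeled half-open region on a transcript
#'
#' Coordinates are 0-based, half-open (`start` inclusive, `end` exclusive),
#' 5'->3'. `frame` is the offset of `start` modulo 3 relative to the frame
#' reference (transcript position 0 unless stated otherwise).
#'
#' @param start,end 0-based offsets, `0 <= start <= end`.
#' @param label Free-text label.
#' @param frame Optional reading-frame offset in 0:2 (NA when not meaningful).
#' @return A `region` list.
#' @export
region <- function(start, end, label = "", frame = NA_integer_) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end < start) {
    stop("invalid region: need 0 <= start <= end", call. = FALSE)
  }
  if (!is.na(frame) && !frame %in% 0:2) stop("frame must be 0, 1 or 2", call. = FALSE)
  structure(list(start = start, end = end, label = label,
                 frame = as.integer(frame)), class = "region")
}

region_width <- function(r) r$end - r$start

check_iupac_pattern <- function(pattern) {
  p <- toupper(chartr("T", "U", pattern))
  ch <- strsplit(p, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% names(IUPAC_RNA))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC symbol '%s' at position %d in pattern '%s'",
                 ch[bad[1]], bad[1], pattern), call. = FALSE)
  }
  p
}

#' Find all matches of an IUPAC pattern
#'
#' Reports every 0-based start position where the pattern's residue sets all
#' contain the corresponding sequence residue. Overlapping matches are all
#' reported, in ascending order. A pattern longer than the sequence yields an
#' empty result.
#'
#' @param seq Concrete sequence (`nuc_seq` or string).
#' @param pattern IUPAC pattern string (15-letter alphabet, RNA reading:
#'   K = G/U, M = A/C, R = A/G, S = C/G, W = A/U, Y = C/U, plus B, D, H, V, N).
#' @return Integer vector of 0-based match starts.
#' @examples
#' match_iupac("AGAGGAGA", "RRRRRR")  # 0 1 2
#' @export
match_iupac <- function(seq, pattern) {
  s <- unclass(to_rna(seq))
  p <- check_iupac_pattern(pattern)
  if (nchar(p) > nchar(s)) return(integer(0))
  hits <- Biostrings::matchPattern(Biostrings::RNAString(p),
                                   Biostrings::RNAString(s),
                                   fixed = c(pattern = FALSE, subject = TRUE))
  sort(as.integer(BiocGenerics::start(hits)) - 1L)
}

# internal: naive per-window IUPAC matcher (0-based starts). Same contract
# as match_iupac; used on the generator hot path where short sequences are
# screened millions of times, and as the independent cross-check in tests.
match_iupac_naive <- function(s, pattern) {
  p <- check_iupac_pattern(pattern)
  n <- nchar(s); w <- nchar(p)
  if (w > n) return(integer(0))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  pch <- strsplit(p, "", fixed = TRUE)[[1]]
  sets <- IUPAC_RNA[pch]
  hits <- integer(0)
  for (start in 0:(n - w)) {
    ok <- TRUE
    for (i in seq_len(w)) {
      if (!ch[start + i] %in% sets[[i]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, start)
  }
  hits
}

#' Scan a reading frame for stop codons
#'
#' @param seq Sequence to scan.
#' @param frame Frame offset in 0:2 relative to position 0.
#' @return 0-based positions `p` with `p %% 3 == frame` whose codon is
#'   UAA, UAG or UGA (only codons fully inside the sequence).
#' @examples
#' scan_stop_codons("AUGUAAUGA", 0)  # 3 6
#' @export
scan_stop_codons <- function(seq, frame) {
  s <- unclass(to_rna(seq))
  if (!length(frame) == 1L || !frame %in% 0:2) stop("frame must be 0, 1 or 2", call. = FALSE)
  n <- nchar(s)
  starts <- seq.int(frame, by = 3L, length.out = max(0L, (n - frame) %/% 3L))
  if (!length(starts)) return(integer(0))
  codons <- substring(s, starts + 1L, starts + 3L)
  starts[codons %in% STOP_CODONS]
}

#' Locate overlapping stop-start (URAUG) motifs
#'
#' The 5-nt motif U-R-A-U-G places a stop codon (UAA or UGA) at positions
#' `p..p+2` and the start codon AUG at `p+2..p+4`, sharing one nucleotide:
#' the geometry that gives intergenic distance -1.
#'
#' @param seq Sequence to scan.
#' @return 0-based motif start positions.
#' @examples
#' find_overlap_motif("UAAUG")  # 0
#' @export
find_overlap_motif <- function(seq) match_iupac(seq, "URAUG")

#' Reading frame downstream of a URAUG junction
#'
#' The downstream AUG begins two nucleotides into the upstream-frame stop
#' codon, so the second ORF runs in frame `(upstream_frame + 2) %% 3`.
#'
#' @param upstream_frame Frame offset in 0:2 of the upstream ORF.
#' @return Frame offset of the downstream ORF.
#' @export
junction_frame <- function(upstream_frame) {
  if (!length(upstream_frame) == 1L || !upstream_frame %in% 0:2) {
    stop("frame must be 0, 1 or 2", call. = FALSE)
  }
  (as.integer(upstream_frame) + 2L) %% 3L
}

# internal: run body under a temporary Mersenne-Twister seed, restoring
# the caller's RNG state afterwards (all package randomness funnels here)
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}
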