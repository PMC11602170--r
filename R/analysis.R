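# Quantitative utilities: geometric-mean fold change with quadrature error
# propagation, simple linear regression of design features against
# measurements, CFU computation and the feature-table export that joins the
# thermodynamic scores to measured outputs.

#' Geometric mean
#'
#' @param x Positive numeric values.
#' @return `exp(mean(log(x)))`.
#' @export
geomean <- function(x) {
  if (!length(x) || any(is.na(x)) || any(x <= 0)) {
    stop("geometric mean requires positive values", call. = FALSE)
  }
  exp(mean(log(x)))
}

#' A replicate fluorescence measurement record
#'
#' Holds the replicates of one construct in one induction state together
#' with the derived geometric mean and relative error. The relative error
#' convention is the sample standard deviation of the replicates divided by
#' their geometric mean.
#'
#' @param construct_id Construct identifier.
#' @param state "ON" or "OFF".
#' @param values Replicate fluorescence values (arbitrary units, > 0).
#' @return A `measurement_sample` list with `geometric_mean` and
#'   `relative_error` fields.
#' @export
measurement_sample <- function(construct_id, state = c("ON", "OFF"), values) {
  state <- match.arg(state)
  values <- as.numeric(values)
  if (!length(values) || any(is.na(values)) || any(values <= 0)) {
    stop("replicate values must all be positive", call. = FALSE)
  }
  gm <- geomean(values)
  rel <- if (length(values) > 1L) stats::sd(values) / gm else 0
  structure(list(construct_id = as.character(construct_id), state = state,
                 values = values, geometric_mean = gm, relative_error = rel),
            class = "measurement_sample")
}

#' @export
print.measurement_sample <- function(x, ...) {
  cat(sprintf("<measurement_sample> %s [%s]: n=%d, geomean %.4g, rel err %.4g\n",
              x$construct_id, x$state, length(x$values), x$geometric_mean,
              x$relative_error))
  invisible(x)
}

#' Fold change between ON and OFF states
#'
#' The ratio of the geometric-mean ON-state to OFF-state fluorescence; its
#' relative error combines the two states' relative errors in quadrature:
#' `sqrt(rel_ON^2 + rel_OFF^2)`.
#'
#' @param on,off `measurement_sample` objects (see [measurement_sample()]).
#' @return List with `fold` and `relative_error`.
#' @examples
#' on <- measurement_sample("c1", "ON", c(100, 100, 100))
#' off <- measurement_sample("c1", "OFF", c(10, 10, 10))
#' fold_change(on, off)  # fold 10, relative_error 0
#' @export
fold_change <- function(on, off) {
  stopifnot(inherits(on, "measurement_sample"),
            inherits(off, "measurement_sample"))
  list(fold = on$geometric_mean / off$geometric_mean,
       relative_error = sqrt(on$relative_error^2 + off$relative_error^2))
}

#' Simple linear regression of a feature against a response
#'
#' Ordinary least squares `y ~ x` with `r_squared = 1 - SS_res/SS_tot`
#' (defined as 0 when the response is constant).
#'
#' @param x Numeric predictor (a design feature), not constant, length >= 3.
#' @param y Numeric response (e.g. fluorescence output), same length.
#' @return A `regression_fit`: `slope`, `intercept`, `r_squared`,
#'   `n_points`.
#' @export
fit_linear <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(is.na(x)) || any(is.na(y))) stop("missing values not allowed", call. = FALSE)
  if (isTRUE(all.equal(stats::var(x), 0)) || stats::var(x) == 0) {
    stop("degenerate predictor: x is constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = unname(co[["x"]]), intercept = unname(co[["(Intercept)"]]),
                 r_squared = max(0, min(1, r2)), n_points = length(x)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> y = %.4g x + %.4g, r^2 = %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Colony-forming units per ml
#'
#' `colonies * dilution_factor / 0.005` - the plated volume is 5 ul.
#'
#' @param colonies Non-negative integer colony count.
#' @param dilution_factor Dilution factor (>= 1).
#' @return CFU/ml.
#' @examples
#' cfu_per_ml(50, 1e4)  # 1e8
#' @export
cfu_per_ml <- function(colonies, dilution_factor) {
  if (any(colonies < 0) || any(colonies != floor(colonies))) {
    stop("colonies must be a non-negative integer", call. = FALSE)
  }
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1", call. = FALSE)
  colonies * dilution_factor / 0.005
}

# internal: windowed local-structure score around a coupled start codon --
# the minimum single-hairpin energy found within +/- `flank` nt of the start.
# A labeled stand-in for a full local-folding metric: more negative means
# more structure impeding post-termination scanning.
local_structure_score <- function(seq, start_pos, model, flank = 20L) {
  s <- unclass(to_rna(seq))
  a <- max(0L, start_pos - flank)
  b <- min(nchar(s), start_pos + 3L + flank)
  hp <- enumerate_hairpins(substr(s, a + 1L, b), model)
  if (!nrow(hp)) return(0)
  min(0, min(hp$dG))
}

#' Export the design feature table
#'
#' One row per scored design (or per junction for assembled operons) with
#' the columns used for feature-vs-output regressions: stem dG, RBS
#' strength (total and components), intergenic distance, loop length, a
#' windowed local-structure score around the coupled start codon, and the
#' internal putative-RBS count of the cassette/transcript.
#'
#' @param designs List of scored `syntce_candidate` and/or `operon_design`
#'   objects.
#' @param model An [energy_model()].
#' @param config An [rbs_config()].
#' @param internal_rbs_threshold Threshold for [scan_internal_rbs()].
#' @return A data.frame.
#' @export
feature_table <- function(designs, model = energy_model(),
                          config = rbs_config(),
                          internal_rbs_threshold = -4.5) {
  if (inherits(designs, c("syntce_candidate", "operon_design"))) {
    designs <- list(designs)
  }
  rows <- list()
  for (d in designs) {
    if (inherits(d, "syntce_candidate")) {
      if (is.null(d$scores)) stop("unscored candidate: run filter_candidate first",
                                  call. = FALSE)
      s <- unclass(d$cassette)
      start_pos <- d$regions$start$start
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0("syntce:", d$stem5),
        stem_dG = d$scores$stem_dG,
        rbs_total = d$scores$rbs$total,
        dG_rRNA_mRNA = d$scores$rbs$dG_rRNA_mRNA,
        dG_spacing = d$scores$rbs$dG_spacing,
        intergenic_distance = -1L,
        loop_len = region_width(d$regions$loop),
        local_struct_dG = local_structure_score(s, start_pos, model),
        internal_rbs_count = nrow(scan_internal_rbs(s, model, config,
                                                    internal_rbs_threshold)))
    } else if (inherits(d, "operon_design")) {
      s <- unclass(d$transcript)
      n_int <- nrow(scan_internal_rbs(s, model, config, internal_rbs_threshold))
      for (k in seq_along(d$junctions)) {
        j <- d$junctions[[k]]
        rep <- validate_junction(d, k, model, config)
        stem5 <- if (j$stem_len > 0L) {
          substr(s, j$hairpin_start + 1L, j$hairpin_start + j$stem_len)
        } else ""
        rows[[length(rows) + 1L]] <- data.frame(
          id = paste0(j$name, "@", j$stop_start),
          stem_dG = stem_dG(stem5, model),
          rbs_total = rep$rbs_score$total,
          dG_rRNA_mRNA = rep$rbs_score$dG_rRNA_mRNA,
          dG_spacing = rep$rbs_score$dG_spacing,
          intergenic_distance = rep$intergenic_distance,
          loop_len = j$loop_len,
          local_struct_dG = local_structure_score(s, j$start_start, model),
          internal_rbs_count = n_int)
      }
    } else {
      stop("feature_table accepts syntce_candidate and operon_design objects",
           call. = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Read a measurement CSV into samples
#'
#' Expects columns `construct_id`, `state` (ON/OFF), `replicate`, `value`;
#' replicates of each construct/state are collected into one
#' [measurement_sample()].
#'
#' @param path CSV file path.
#' @return Named list of `measurement_sample`s (names
#'   `construct_id.state`).
#' @export
read_measurements <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("construct_id", "state", "replicate", "value")
  if (!all(need %in% names(tab))) {
    stop("measurement CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  groups <- split(tab, paste(tab$construct_id, tab$state, sep = "."))
  lapply(groups, function(g) {
    measurement_sample(g$construct_id[1L], g$state[1L], g$value)
  })
}
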