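#' Construct a probe set
#'
#' @param probes data.frame: probe_id, chrom, start, end, is_control.
#' @param input,enriched Probe-by-sample log2 intensity matrices.
#' @param samples data.frame with \code{sample} and \code{tissue}.
#' @return An object of class \code{probe_set}.
#' @export
probe_set <- function(probes, input, enriched, samples) {
  stopifnot(nrow(probes) == nrow(input), nrow(probes) == nrow(enriched),
            ncol(input) == nrow(samples), ncol(enriched) == nrow(samples))
  structure(list(probes = probes, input = input, enriched = enriched,
                 samples = samples), class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat("probe_set:", nrow(x$probes), "probes (",
      sum(x$probes$is_control), "controls ),",
      nrow(x$samples), "samples\n")
  invisible(x)
}

#' Normalize two-channel tiling-array intensities
#'
#' Within each sample, a lowess curve of enriched-minus-input versus input
#' intensity is fitted on the non-genomic control probes and subtracted from
#' the enriched channel of every probe (extrapolated flat beyond the control
#' intensity range), removing intensity-dependent enrichment bias. Both
#' channels are then quantile-normalized across samples so their sorted
#' per-sample distributions coincide.
#'
#' @param ps A \code{probe_set}.
#' @param min_controls Minimum control probes required for the lowess step;
#'   below this the step is skipped with a warning.
#' @return The normalized \code{probe_set}.
#' @export
normalize_probes <- function(ps, min_controls = 10) {
  ctrl <- ps$probes$is_control
  if (sum(ctrl) < min_controls) {
    warning("fewer than ", min_controls,
            " control probes; skipping lowess bias correction")
  } else {
    for (j in seq_len(ncol(ps$input))) {
      m <- ps$enriched[, j] - ps$input[, j]
      if (length(unique(ps$input[ctrl, j])) < 2) {
        # degenerate control intensities: flat bias only
        ps$enriched[, j] <- ps$enriched[, j] - mean(m[ctrl])
        next
      }
      fit <- stats::lowess(ps$input[ctrl, j], m[ctrl])
      bias <- stats::approx(fit$x, fit$y, xout = ps$input[, j],
                            rule = 2, ties = mean)$y
      ps$enriched[, j] <- ps$enriched[, j] - bias
    }
  }
  ps$input <- limma::normalizeQuantiles(ps$input)
  ps$enriched <- limma::normalizeQuantiles(ps$enriched)
  ps
}

#' Remove probes with background-level input intensity
#'
#' The background threshold is a low quantile of the control-probe input
#' intensities; genomic probes whose mean input falls below it are dropped,
#' and control probes are removed from downstream testing altogether.
#'
#' @param ps A \code{probe_set}.
#' @param quantile Control-input quantile defining background (default
#'   0.025).
#' @return The filtered \code{probe_set} (genomic probes only), with an
#'   attribute \code{n_removed} giving the number of background probes
#'   dropped.
#' @export
filter_background <- function(ps, quantile = 0.025) {
  ctrl <- ps$probes$is_control
  thr <- stats::quantile(rowMeans(ps$input[ctrl, , drop = FALSE]),
                         quantile, names = FALSE)
  keep <- !ctrl & rowMeans(ps$input) >= thr
  if (!any(keep)) stop("all genomic probes fall below background")
  out <- probe_set(ps$probes[keep, ], ps$input[keep, , drop = FALSE],
                   ps$enriched[keep, , drop = FALSE], ps$samples)
  attr(out, "n_removed") <- sum(!ctrl) - sum(keep)
  out
}

#' Per-probe relative methylation
#'
#' Relative methylation is the log2 ratio of the methylation-enriched signal
#' to the input signal, i.e. enriched minus input on the log2 scale.
#'
#' @param ps A (normalized, filtered) \code{probe_set}.
#' @return A probe-by-sample matrix of relative methylation values.
#' @export
relative_methylation <- function(ps) {
  ps$enriched - ps$input
}

# Per-probe moderated t-test between tissues via limma's empirical-Bayes
# variance shrinkage; pools variance information across all probes, which a
# 3-vs-3 design needs for usable power.
row_moderated_t <- function(m, group) {
  g <- as.logical(group)
  design <- cbind(Intercept = 1, groupA = as.numeric(g))
  fit <- limma::eBayes(limma::lmFit(m, design))
  data.frame(delta = fit$coefficients[, "groupA"],
             statistic = fit$t[, "groupA"],
             df = fit$df.total,
             p_value = fit$p.value[, "groupA"])
}

#' Call tissue-specific differentially methylated regions
#'
#' Tests every probe for a between-tissue difference in relative
#' methylation, then merges maximal runs of at least \code{min_probes}
#' neighbouring significant probes with a consistent direction into T-DMRs.
#' "Neighbouring" means adjacent in array order on the same chromosome with
#' a genomic gap of at most \code{max_gap} bp.
#'
#' Probe-level p-values come from a moderated t-statistic (limma
#' empirical-Bayes variance shrinkage; default) or a plain Welch t-test
#' (\code{method = "welch"}).
#'
#' @param m Probe-by-sample relative methylation matrix.
#' @param probes Probe data.frame aligned with \code{m} (genomic probes).
#' @param samples Sample data.frame with \code{tissue}.
#' @param p_cutoff Per-probe significance cutoff (default 0.005).
#' @param min_probes Minimum probes per region (default 3).
#' @param max_gap Maximum genomic gap between neighbouring probes in bp.
#' @param method "moderated" (default) or "welch".
#' @return A list with \code{tdmrs} (data.frame: tdmr_id, chrom, start, end,
#'   n_probes, direction, mean_delta, min_p, probe_ids) and
#'   \code{probe_stats} (per-probe delta and p-value). Direction is the
#'   tissue with the higher methylation, as \code{"<tissue>-hyper"}.
#' @export
call_tdmrs <- function(m, probes, samples, p_cutoff = 0.005, min_probes = 3,
                       max_gap = 300, method = c("moderated", "welch")) {
  method <- match.arg(method)
  stopifnot(nrow(m) == nrow(probes))
  tissues <- unique(samples$tissue)
  if (length(tissues) != 2) stop("exactly two tissues are required")
  ord <- order(probes$chrom, probes$start)
  if (is.unsorted(ord)) {
    message("probes not sorted by (chrom, start); sorting internally")
    probes <- probes[ord, ]
    m <- m[ord, , drop = FALSE]
  }
  g <- samples$tissue == tissues[1]
  stats_fun <- if (method == "moderated") row_moderated_t else row_welch_t
  st <- stats_fun(m, g)

  pass <- st$p_value < p_cutoff & st$delta != 0
  same_chrom <- c(FALSE, probes$chrom[-1] == probes$chrom[-nrow(probes)])
  small_gap <- c(FALSE, probes$start[-1] - probes$end[-nrow(probes)] <= max_gap)
  same_dir <- c(FALSE, sign(st$delta[-1]) == sign(st$delta[-nrow(probes)]))
  linked <- pass & c(FALSE, pass[-length(pass)]) &
    same_chrom & small_gap & same_dir
  run_id <- cumsum(pass & !linked)
  run_id[!pass] <- NA

  runs <- split(which(pass), run_id[pass])
  keep <- vapply(runs, length, integer(1)) >= min_probes
  runs <- runs[keep]

  tdmrs <- lapply(seq_along(runs), function(i) {
    idx <- runs[[i]]
    delta <- mean(st$delta[idx])
    data.frame(
      tdmr_id = sprintf("TDMR%04d", i),
      chrom = probes$chrom[idx[1]],
      start = probes$start[idx[1]],
      end = probes$end[idx[length(idx)]],
      n_probes = length(idx),
      direction = paste0(if (delta > 0) tissues[1] else tissues[2], "-hyper"),
      mean_delta = delta,
      min_p = min(st$p_value[idx]),
      probe_ids = paste(probes$probe_id[idx], collapse = ","),
      stringsAsFactors = FALSE)
  })
  tdmrs <- if (length(tdmrs)) do.call(rbind, tdmrs) else
    data.frame(tdmr_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), n_probes = integer(0),
               direction = character(0), mean_delta = numeric(0),
               min_p = numeric(0), probe_ids = character(0))
  list(tdmrs = tdmrs,
       probe_stats = cbind(probes["probe_id"], st),
       tissues = tissues, p_cutoff = p_cutoff)
}
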