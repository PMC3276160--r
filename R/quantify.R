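# GC-bin background correction, detection above background (DABG), and
# log-scale probe-set summarization.
#
# The probe-set signal is Y_i = ln( sum_j (X_ij - GC_j) / N_i + 100 ):
# X_ij the raw intensity of probe j in set i, GC_j the background value of
# the probe's GC bin (per sample), N_i the number of probes in the set.

GC_BIN_MIN <- 3L
GC_BIN_MAX <- 24L

#' Construct a GC-bin control set
#'
#' Background (GC band) control probes grouped by their G+C count, with one
#' intensity per control probe per sample. Control probes match no genomic
#' sequence, so their intensities estimate nonspecific hybridization within
#' each GC bin.
#'
#' @param values numeric matrix, control probes x samples.
#' @param bins integer vector of GC counts, one per control probe row.
#' @return object of class `gc_controls`.
#' @export
gc_controls <- function(values, bins) {
  values <- as.matrix(values)
  bins <- as.integer(bins)
  stopifnot(nrow(values) == length(bins), all(!is.na(values)),
            all(values >= 0))
  structure(list(values = values, bins = bins), class = "gc_controls")
}

#' @export
print.gc_controls <- function(x, ...) {
  cat(sprintf("gc_controls: %d control probes in %d GC bins x %d samples\n",
              nrow(x$values), length(unique(x$bins)), ncol(x$values)))
  invisible(x)
}

#' Assign probes to GC bins
#'
#' The bin is the probe's G+C count clamped to the control range
#' \[3, 24\].
#'
#' @param x character vector of probe sequences (GC counted, non-ACGT is an
#'   error) or an integer vector of GC counts.
#' @param lo,hi clamp range (defaults 3 and 24).
#' @return integer vector of GC bins.
#' @export
#' @examples
#' assign_gc_bin(c(2, 12, 25))   # 3 12 24
assign_gc_bin <- function(x, lo = GC_BIN_MIN, hi = GC_BIN_MAX) {
  counts <- if (is.character(x)) gc_count(x) else as.integer(x)
  pmin(pmax(counts, lo), hi)
}

# Per-bin, per-sample summary of control intensities. `stat` is "median"
# (for DABG), "mean" (the background value GC_j of the summarization
# formula) or "percentile" (with probability `p`).
gc_bin_stat <- function(controls, stat = c("mean", "median", "percentile"),
                        p = 0.05, bins_needed = NULL) {
  stopifnot(inherits(controls, "gc_controls"))
  stat <- match.arg(stat)
  bins <- sort(unique(controls$bins))
  if (!is.null(bins_needed)) {
    missing <- setdiff(bins_needed, bins)
    if (length(missing)) {
      stop("no control probes for GC bin(s): ",
           paste(missing, collapse = ", "))
    }
  }
  fun <- switch(stat,
                mean = colMeans,
                median = function(m) apply(m, 2, median),
                percentile = function(m) apply(m, 2, quantile, probs = p,
                                               names = FALSE))
  res <- vapply(bins, function(b) {
    fun(controls$values[controls$bins == b, , drop = FALSE])
  }, numeric(ncol(controls$values)))
  # vapply drops to a plain vector when there is a single sample
  out <- if (is.matrix(res)) t(res) else matrix(res, ncol = 1L)
  rownames(out) <- bins
  colnames(out) <- colnames(controls$values)
  out
}

#' Detection-above-background calls
#'
#' A probe is called detected in a sample when its intensity is strictly
#' higher than the median intensity of the control probes in its GC bin
#' (computed per sample). Detected fractions are reported per sample,
#' overall and per module.
#'
#' @param intensities numeric matrix, probes x samples (row names are
#'   probe ids).
#' @param annot probe annotation data.frame with `probe_id`, `gc`
#'   (GC count or bin) and optionally `module`.
#' @param controls a [gc_controls()] object.
#' @return list with `detected` (logical matrix probes x samples),
#'   `fraction` (named numeric per sample) and `by_module` (data.frame
#'   module x sample fractions; `NULL` without a `module` column).
#' @export
dabg <- function(intensities, annot, controls) {
  intensities <- as.matrix(intensities)
  stop_if_not_df_cols(annot, c("probe_id", "gc"), "annot")
  annot <- annot[match(rownames(intensities), annot$probe_id), ]
  if (any(is.na(annot$probe_id))) {
    stop("intensity rows missing from probe annotation")
  }
  bin <- assign_gc_bin(annot$gc)
  med <- gc_bin_stat(controls, "median", bins_needed = unique(bin))
  thresh <- med[match(bin, as.integer(rownames(med))), , drop = FALSE]
  detected <- intensities > thresh
  fraction <- colMeans(detected)
  by_module <- NULL
  if ("module" %in% names(annot)) {
    by_module <- aggregate(detected, by = list(module = annot$module),
                           FUN = mean)
  }
  list(detected = detected, fraction = fraction, by_module = by_module)
}

#' Background-corrected log summarization of probe sets
#'
#' Computes, per probe group and sample,
#' `Y = ln( mean_j(X_j - GC_j) + offset )` with `offset = 100`, where
#' `GC_j` is the background value of probe j's GC bin in that sample.
#' Grouping is per probe set, or per allele class (PM1/PM2/MM) within each
#' SNP probe set -- the treatment levels of the allelic-imbalance model.
#' The background statistic is the per-bin control mean by default; a
#' percentile variant (e.g. the 5th percentile) is available.
#'
#' @param intensities numeric matrix, probes x samples.
#' @param annot probe annotation with `probe_id`, `probeset_id`, `gc` and,
#'   for allele-class grouping, `role` (PM1/PM2/MM).
#' @param controls a [gc_controls()] object.
#' @param grouping `"probeset"` or `"allele"`.
#' @param background `"mean"` or `"percentile"`; `p` the percentile level.
#' @param offset additive offset inside the log (default 100).
#' @param epsilon floor for nonpositive log arguments; each clamped cell
#'   increments the warning counter.
#' @return object of class `probeset_signal`: list with `Y` (groups x
#'   samples matrix of natural-log signals), `N` (probes per group),
#'   `groups` (data.frame `probeset_id`, `role`), `grouping`, `clamped`
#'   (number of clamped cells).
#' @export
summarize_signal <- function(intensities, annot, controls,
                             grouping = c("probeset", "allele"),
                             background = c("mean", "percentile"),
                             p = 0.05, offset = 100, epsilon = 1e-6) {
  grouping <- match.arg(grouping)
  background <- match.arg(background)
  intensities <- as.matrix(intensities)
  need <- c("probe_id", "probeset_id", "gc",
            if (grouping == "allele") "role")
  stop_if_not_df_cols(annot, need, "annot")
  annot <- annot[match(rownames(intensities), annot$probe_id), ]
  if (any(is.na(annot$probe_id))) {
    stop("intensity rows missing from probe annotation")
  }
  bin <- assign_gc_bin(annot$gc)
  bg <- gc_bin_stat(controls, stat = background, p = p,
                    bins_needed = unique(bin))
  corrected <- intensities - bg[match(bin, as.integer(rownames(bg))), ,
                                drop = FALSE]
  group <- if (grouping == "probeset") annot$probeset_id
           else paste(annot$probeset_id, annot$role, sep = "|")
  n <- as.vector(table(group)[unique(group)])
  means <- rowsum(corrected, group, reorder = FALSE) /
    as.vector(table(group)[unique(group)])
  arg <- means + offset
  clamped <- sum(arg <= 0)
  if (clamped > 0) {
    warning(clamped, " log argument(s) <= 0 clamped to epsilon")
    arg[arg <= 0] <- epsilon
  }
  Y <- log(arg)
  groups <- if (grouping == "probeset") {
    data.frame(probeset_id = rownames(Y), role = NA_character_,
               stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(rownames(Y), "|", fixed = TRUE)
    data.frame(probeset_id = vapply(parts, `[`, character(1), 1),
               role = vapply(parts, `[`, character(1), 2),
               stringsAsFactors = FALSE)
  }
  structure(list(Y = Y, N = setNames(n, rownames(Y)), groups = groups,
                 grouping = grouping, clamped = clamped),
            class = "probeset_signal")
}

#' @export
print.probeset_signal <- function(x, ...) {
  cat(sprintf(
    "probeset_signal (%s grouping): %d groups x %d samples%s\n",
    x$grouping, nrow(x$Y), ncol(x$Y),
    if (x$clamped) sprintf(" (%d clamped)", x$clamped) else ""))
  invisible(x)
}

#' Per-probe background-corrected log signal
#'
#' `ln(X - GC + offset)` for every individual probe (no summarization);
#' the normalized scale on which genotype base ranking averages probes.
#'
#' @inheritParams summarize_signal
#' @return numeric matrix, probes x samples.
#' @export
probe_signal <- function(intensities, annot, controls,
                         background = c("mean", "percentile"),
                         p = 0.05, offset = 100, epsilon = 1e-6) {
  background <- match.arg(background)
  intensities <- as.matrix(intensities)
  stop_if_not_df_cols(annot, c("probe_id", "gc"), "annot")
  annot <- annot[match(rownames(intensities), annot$probe_id), ]
  bin <- assign_gc_bin(annot$gc)
  bg <- gc_bin_stat(controls, stat = background, p = p,
                    bins_needed = unique(bin))
  arg <- intensities - bg[match(bin, as.integer(rownames(bg))), ,
                          drop = FALSE] + offset
  arg[arg <= 0] <- epsilon
  log(arg)
}

#' Numeric per-sample quality summary
#'
#' Quantiles of the raw intensity distribution per sample plus the DABG
#' fraction -- a numeric stand-in for distribution-level QC plots.
#'
#' @inheritParams dabg
#' @param probs quantile probabilities.
#' @return data.frame, one row per sample.
#' @export
qc_summary <- function(intensities, annot, controls,
                       probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  q <- t(apply(as.matrix(intensities), 2, quantile, probs = probs))
  colnames(q) <- paste0("q", probs * 100)
  d <- dabg(intensities, annot, controls)
  data.frame(sample_id = colnames(intensities), q,
             dabg_fraction = d$fraction, row.names = NULL,
             stringsAsFactors = FALSE)
}
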