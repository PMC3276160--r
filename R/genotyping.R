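# Rank-based genotype calling from allele-probe intensities, concordance
# against known alleles, and Fisher linear discriminant separation of
# genotype classes.

#' Rank the four SNP bases by hybridization signal
#'
#' For each SNP probe set and sample group, estimates the signal of each
#' base as the average over the probes representing that base (both
#' strands, all offsets; a reverse-strand probe interrogating base b
#' counts toward complement(b) on the forward strand), ranks the four
#' bases by signal, and records the top and second calls. Ties are broken
#' by the fixed base order A < C < G < T and flagged.
#'
#' @param values numeric matrix of per-probe signals, probes x samples
#'   (normalized log scale from [probe_signal()] by default).
#' @param annot probe annotation with `probe_id`, `probeset_id`,
#'   `snp_base` (base at the SNP site as read on the probe's own strand)
#'   and `strand` (`forward`/`reverse`).
#' @param groups named character vector mapping sample id to a group label
#'   (e.g. genotype x nucleic acid); samples sharing a label are averaged.
#'   Defaults to one group per sample.
#' @param scale `"log"` (average the values as given) or `"raw"` (average
#'   `exp(values)` and report the log of the mean).
#' @return data.frame, one row per probe set x group: `probeset_id`,
#'   `group`, mean signals `A`, `C`, `G`, `T` (forward strand), `rank`
#'   (bases in descending signal order, e.g. `"ACGT"`), `top`, `second`,
#'   `tie` (any tie among the four means).
#' @export
rank_bases <- function(values, annot, groups = NULL,
                       scale = c("log", "raw")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  stop_if_not_df_cols(annot, c("probe_id", "probeset_id", "snp_base",
                               "strand"), "annot")
  annot <- annot[match(rownames(values), annot$probe_id), ]
  if (any(is.na(annot$probe_id))) {
    stop("signal rows missing from probe annotation")
  }
  if (is.null(groups)) {
    groups <- setNames(colnames(values), colnames(values))
  }
  keep <- intersect(colnames(values), names(groups))
  values <- values[, keep, drop = FALSE]
  groups <- groups[keep]
  if (scale == "raw") values <- exp(values)

  fwd_base <- ifelse(annot$strand == "reverse",
                     dna_complement(annot$snp_base), annot$snp_base)
  out <- list()
  for (g in unique(groups)) {
    probe_mean <- rowMeans(values[, groups == g, drop = FALSE])
    by_base <- tapply(probe_mean, list(annot$probeset_id, fwd_base), mean)
    if (!all(BASES %in% colnames(by_base)) ||
        anyNA(by_base[, BASES])) {
      stop("every probe set needs probes for all four bases")
    }
    by_base <- by_base[, BASES, drop = FALSE]
    if (scale == "raw") by_base <- log(by_base)
    for (i in seq_len(nrow(by_base))) {
      m <- by_base[i, ]
      ord <- order(-m, BASES)              # ties: fixed A<C<G<T order
      out[[length(out) + 1L]] <- data.frame(
        probeset_id = rownames(by_base)[i], group = g,
        A = m[["A"]], C = m[["C"]], G = m[["G"]], T = m[["T"]],
        rank = paste(BASES[ord], collapse = ""),
        top = BASES[ord[1]], second = BASES[ord[2]],
        tie = anyDuplicated(m) > 0L,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Concordance of ranked base calls with known alleles
#'
#' For homozygous truth (`mode = "top1"`): the share of probe sets whose
#' top-ranked base equals the known allele, overall and per base. For
#' heterozygous truth (`mode = "top2"`): the share whose two top-ranked
#' bases equal the two known alleles; the per-base rows then condition on
#' probe sets whose allele pair contains that base.
#'
#' @param calls data.frame from [rank_bases()].
#' @param truth data.frame with `probeset_id` and `allele` (top1 mode) or
#'   `allele1`, `allele2` (top2 mode).
#' @param mode `"top1"` or `"top2"`.
#' @return data.frame with rows `Overall`, `A`, `C`, `G`, `T` and one
#'   percentage column per group (plus `n_<group>` counts).
#' @export
concordance_report <- function(calls, truth, mode = c("top1", "top2")) {
  mode <- match.arg(mode)
  need <- if (mode == "top1") "allele" else c("allele1", "allele2")
  stop_if_not_df_cols(truth, c("probeset_id", need), "truth")
  calls <- merge(calls, truth, by = "probeset_id")
  if (!nrow(calls)) stop("no probe sets shared between calls and truth")
  correct <- if (mode == "top1") {
    calls$top == calls$allele
  } else {
    (calls$top == calls$allele1 & calls$second == calls$allele2) |
      (calls$top == calls$allele2 & calls$second == calls$allele1)
  }
  in_row <- function(base) {
    if (mode == "top1") calls$allele == base
    else calls$allele1 == base | calls$allele2 == base
  }
  rows <- c("Overall", BASES)
  out <- data.frame(allele = rows, stringsAsFactors = FALSE)
  for (g in unique(calls$group)) {
    gsel <- calls$group == g
    pct <- vapply(rows, function(r) {
      sel <- gsel & (if (r == "Overall") TRUE else in_row(r))
      if (!any(sel)) return(NA_real_)
      round(100 * mean(correct[sel]), 2)
    }, numeric(1))
    n <- vapply(rows, function(r) {
      sum(gsel & (if (r == "Overall") TRUE else in_row(r)))
    }, numeric(1))
    out[[g]] <- pct
    out[[paste0("n_", g)]] <- n
  }
  out
}

#' Fisher linear discriminant separation of genotype classes
#'
#' Projects labeled observations onto up to `ndim` Fisher discriminant
#' axes (eigenvectors of the within-class-whitened between-class scatter)
#' and reports the resubstitution accuracy of nearest-centroid
#' classification in the projected space. A singular within-class scatter
#' is regularized by a ridge term with a warning.
#'
#' @param x numeric matrix, observations x features.
#' @param labels class labels, one per row of `x` (>= 2 classes, each with
#'   >= 2 observations).
#' @param ndim number of discriminant axes to keep (default 2, capped at
#'   classes - 1).
#' @param ridge ridge added to the within-class scatter diagonal; 0 means
#'   auto-regularize only if singular.
#' @return list with `scaling` (features x axes), `scores` (projected
#'   coordinates), `centroids` (class centroids in projected space),
#'   `predicted`, `accuracy` (resubstitution), `ridge_used`.
#' @export
lda_separation <- function(x, labels, ndim = 2L, ridge = 0) {
  x <- as.matrix(x)
  labels <- factor(labels)
  k <- nlevels(labels)
  if (k < 2L) stop("need at least two classes")
  if (any(table(labels) < 2L)) {
    stop("every class needs at least two observations")
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  p <- ncol(x)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (cl in levels(labels)) {
    xi <- xc[labels == cl, , drop = FALSE]
    mi <- colMeans(xi)
    W <- W + crossprod(sweep(xi, 2, mi))
    B <- B + nrow(xi) * tcrossprod(mi)
  }
  W <- W / (nrow(x) - k)                   # pooled within-class covariance
  Wr <- W + diag(ridge, p)
  ch <- tryCatch(chol(Wr), error = function(e) NULL)
  if (is.null(ch)) {
    auto <- max(ridge, 1e-6 * mean(diag(W)), 1e-8)
    warning("within-class scatter is singular; ridge ", signif(auto, 3),
            " applied")
    Wr <- W + diag(auto, p)
    ch <- chol(Wr)
    ridge <- auto
  }
  Winv_half <- backsolve(ch, diag(p))      # W^{-1/2} (right factor inverse)
  M <- t(Winv_half) %*% B %*% Winv_half
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  ndim <- min(ndim, k - 1L, p)
  scaling <- Winv_half %*% e$vectors[, seq_len(ndim), drop = FALSE]
  scores <- xc %*% scaling
  centroids <- apply(scores, 2, tapply, labels, mean)
  centroids <- matrix(centroids, nrow = k,
                      dimnames = list(levels(labels), NULL))
  d2 <- vapply(seq_len(k), function(i) {
    rowSums(sweep(scores, 2, centroids[i, ])^2)
  }, numeric(nrow(scores)))
  predicted <- levels(labels)[max.col(-d2, ties.method = "first")]
  list(scaling = scaling, scores = scores, centroids = centroids,
       predicted = predicted,
       accuracy = mean(predicted == as.character(labels)),
       ridge_used = ridge)
}
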