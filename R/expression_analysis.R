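# Per-probe-set sex-effect testing, threshold summaries, and agreement
# between the 3' expression and exon modules.

# Accept either a probeset_signal object or a plain groups x samples matrix.
as_signal_matrix <- function(signal) {
  if (inherits(signal, "probeset_signal")) signal$Y else as.matrix(signal)
}

#' Test each probe set for a sex effect on expression
#'
#' Fits the one-way fixed-effects model `Y = mu + sex + error` per probe
#' set over the RNA samples of a single genotype and tests equality of the
#' sexes with an F test; q-values are BH-adjusted over the tested sets.
#'
#' @param signal a [summarize_signal()] result (probe-set grouping) or a
#'   matrix of Y values, probe sets x samples.
#' @param meta sample metadata data.frame with `sample_id`, `sex`
#'   (`"F"`/`"M"`) and optionally `nucleic_acid` (only `"RNA"` samples are
#'   used) and `genotype` (must be single after filtering).
#' @param min_reps minimum replicates per sex (default 2); probe sets with
#'   fewer complete values are skipped with a reason.
#' @return data.frame, one row per probe set: `probeset_id`, `mean_f`,
#'   `mean_m`, `estimate` (male minus female), `direction`
#'   (`"male_higher"` / `"female_higher"` / `"none"`), `F`, `df1`, `df2`,
#'   `p`, `q`, `skipped` (reason, `NA` when tested).
#' @export
test_sex_effect <- function(signal, meta, min_reps = 2L) {
  Y <- as_signal_matrix(signal)
  stop_if_not_df_cols(meta, c("sample_id", "sex"), "meta")
  if ("nucleic_acid" %in% names(meta)) {
    meta <- meta[meta$nucleic_acid == "RNA", , drop = FALSE]
  }
  if ("genotype" %in% names(meta) &&
      length(unique(meta$genotype)) > 1L) {
    stop("sex-effect test expects RNA samples from a single genotype")
  }
  keep <- intersect(colnames(Y), meta$sample_id)
  if (length(keep) < 2L * min_reps) {
    stop("not enough RNA samples with metadata")
  }
  Y <- Y[, keep, drop = FALSE]
  sex <- meta$sex[match(keep, meta$sample_id)]

  res <- lapply(seq_len(nrow(Y)), function(i) {
    y <- Y[i, ]
    ok <- !is.na(y)
    tab <- table(factor(sex[ok], levels = c("F", "M")))
    if (any(tab == 0L)) {
      return(data.frame(mean_f = NA_real_, mean_m = NA_real_,
                        estimate = NA_real_, F = NA_real_, df1 = NA_real_,
                        df2 = NA_real_, p = NA_real_, degenerate = FALSE,
                        skipped = "missing_sex_level"))
    }
    if (any(tab < min_reps)) {
      return(data.frame(mean_f = NA_real_, mean_m = NA_real_,
                        estimate = NA_real_, F = NA_real_, df1 = NA_real_,
                        df2 = NA_real_, p = NA_real_, degenerate = FALSE,
                        skipped = "insufficient_replicates"))
    }
    fit <- fit_oneway(y[ok], sex[ok])
    means <- tapply(y[ok], sex[ok], mean)
    data.frame(mean_f = unname(means["F"]), mean_m = unname(means["M"]),
               estimate = unname(means["M"] - means["F"]),
               F = fit$F, df1 = fit$df1, df2 = fit$df2, p = fit$p,
               degenerate = fit$degenerate, skipped = NA_character_)
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(probeset_id = rownames(Y),
                          stringsAsFactors = FALSE), out)
  out$direction <- ifelse(is.na(out$estimate) | out$estimate == 0, "none",
                          ifelse(out$estimate > 0, "male_higher",
                                 "female_higher"))
  out$q <- NA_real_
  tested <- is.na(out$skipped)
  out$q[tested] <- fdr_bh(out$p[tested])
  rownames(out) <- NULL
  out
}

#' Summarize significance counts at multiple FDR thresholds
#'
#' @param results data.frame with `q` and optionally `direction`
#'   (from [test_sex_effect()] or [test_ai()]).
#' @param thresholds FDR cutoffs (default 0.05, 0.1, 0.2).
#' @return data.frame per threshold: `threshold`, `n_tested`,
#'   `n_significant`, `pct` (share of tested, 2 decimal places), and the
#'   male/female-higher split when directions are available.
#' @export
threshold_summary <- function(results, thresholds = c(0.05, 0.1, 0.2)) {
  q <- results$q[!is.na(results$q)]
  n_tested <- length(q)
  out <- do.call(rbind, lapply(thresholds, function(th) {
    sig <- !is.na(results$q) & results$q < th
    row <- data.frame(threshold = th, n_tested = n_tested,
                      n_significant = sum(sig),
                      pct = round(100 * sum(sig) / n_tested, 2))
    if ("direction" %in% names(results)) {
      row$n_male_higher <- sum(sig & results$direction == "male_higher")
      row$n_female_higher <- sum(sig & results$direction == "female_higher")
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Agreement in sex-bias detection between the 3' and exon modules
#'
#' Compares gene-level significance calls between a 3' expression result
#' table and an exon-module result table. Genes mapping to more than one
#' 3' probe set are excluded. A gene's exon-module call aggregates its
#' constitutive exon probe sets: significant if any (default) or the
#' majority of them pass the threshold.
#'
#' @param results_3prime,results_exon data.frames with `probeset_id`, `q`.
#' @param gene_map data.frame with `gene_id`, `probeset_id`, `module`
#'   (`"3prime"` or `"exon"`); exon rows should carry constitutive probe
#'   sets only.
#' @param threshold FDR threshold for a significant call (default 0.1).
#' @param aggregate `"any"` or `"majority"` rule for gene-level exon calls.
#' @return list with `agreement` (an [agreement()] table, A = exon module,
#'   B = 3' module), `simple_pct` (nearest-integer simple agreement),
#'   `n_genes`, and `excluded` (data.frame of gene, reason).
#' @export
cross_module_agreement <- function(results_3prime, results_exon, gene_map,
                                   threshold = 0.1,
                                   aggregate = c("any", "majority")) {
  aggregate <- match.arg(aggregate)
  stop_if_not_df_cols(gene_map, c("gene_id", "probeset_id", "module"),
                      "gene_map")
  map3 <- gene_map[gene_map$module == "3prime", , drop = FALSE]
  mapx <- gene_map[gene_map$module == "exon", , drop = FALSE]

  n3 <- table(map3$gene_id)
  multi <- names(n3)[n3 > 1L]
  excluded <- data.frame(gene_id = multi,
                         reason = rep("multiple_3prime_probesets",
                                      length(multi)),
                         stringsAsFactors = FALSE)
  genes <- intersect(setdiff(names(n3), multi), unique(mapx$gene_id))
  genes <- genes[order(genes)]

  sig_of <- function(results, ids) {
    q <- results$q[match(ids, results$probeset_id)]
    !is.na(q) & q < threshold
  }
  call3 <- vapply(genes, function(g) {
    sig_of(results_3prime, map3$probeset_id[map3$gene_id == g])
  }, logical(1))
  callx <- vapply(genes, function(g) {
    s <- sig_of(results_exon, mapx$probeset_id[mapx$gene_id == g])
    if (aggregate == "any") any(s) else mean(s) > 0.5
  }, logical(1))

  ag <- agreement(callx, call3)
  list(agreement = ag,
       simple_pct = round(100 * ag$simple_agreement),
       n_genes = length(genes),
       excluded = excluded)
}
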