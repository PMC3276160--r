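# Allelic-imbalance testing: the PM1-PM2 difference in RNA contrasted
# against the same difference in genomic DNA of the same heterozygote.
# The DNA hybridization carries the probe-affinity bias at a known 1:1
# allele ratio, so the contrast cancels that bias.

AI_WEIGHTS <- c("RNA.PM1" = 1, "RNA.PM2" = -1,
                "DNA.PM1" = -1, "DNA.PM2" = 1)

#' Select probe sets testable for allelic imbalance
#'
#' A probe set is testable when the two parental strains carry exactly the
#' two design alleles (PM1 and PM2) and differ -- i.e. the F1 is
#' heterozygous and unambiguous for the design. Optionally restricts to
#' autosomal probe sets.
#'
#' @param design data.frame with `probeset_id`, `pm1`, `pm2` and
#'   optionally `chrom`.
#' @param truth per-strain allele calls: data.frame with `probeset_id`,
#'   `allele1` (strain 1), `allele2` (strain 2).
#' @param autosomal_only drop probe sets on X/Y (requires `chrom`).
#' @return data.frame: design columns plus `allele1`, `allele2`,
#'   `zygosity` (`het`/`hom`), `testable`, `reason`
#'   (`homozygous`/`design_mismatch`/`sex_chromosome`, `NA` if testable).
#' @export
select_testable <- function(design, truth, autosomal_only = FALSE) {
  stop_if_not_df_cols(design, c("probeset_id", "pm1", "pm2"), "design")
  stop_if_not_df_cols(truth, c("probeset_id", "allele1", "allele2"),
                      "truth")
  d <- merge(design, truth, by = "probeset_id")
  match_design <- mapply(function(a1, a2, p1, p2) {
    all(c(a1, a2) %in% c(p1, p2))
  }, d$allele1, d$allele2, d$pm1, d$pm2)
  het <- d$allele1 != d$allele2
  d$zygosity <- ifelse(het, "het", "hom")
  d$reason <- NA_character_
  d$reason[!match_design] <- "design_mismatch"
  d$reason[match_design & !het] <- "homozygous"
  if (autosomal_only) {
    stop_if_not_df_cols(d, "chrom", "design (autosomal filter)")
    sexchr <- d$chrom %in% c("X", "Y")
    d$reason[is.na(d$reason) & sexchr] <- "sex_chromosome"
  }
  d$testable <- is.na(d$reason)
  d
}

# Build the long per-probe-set data for the AI model: one observation per
# (sample, allele class), treatment = nucleic acid x class (6 levels).
ai_long_data <- function(signal, meta, genotype = NULL) {
  stopifnot(inherits(signal, "probeset_signal"))
  if (signal$grouping != "allele") {
    stop("test_ai needs allele-class summarization ",
         "(summarize_signal(..., grouping = 'allele'))")
  }
  stop_if_not_df_cols(meta, c("sample_id", "nucleic_acid", "sex"), "meta")
  if ("genotype" %in% names(meta)) {
    if (!is.null(genotype)) {
      meta <- meta[meta$genotype == genotype, , drop = FALSE]
    }
    if (length(unique(meta$genotype)) > 1L) {
      stop("AI testing uses arrays of the heterozygous genotype only; ",
           "pass `genotype` to select it")
    }
  }
  keep <- intersect(colnames(signal$Y), meta$sample_id)
  if (!any(meta$nucleic_acid[match(keep, meta$sample_id)] == "DNA")) {
    stop("AI testing requires DNA arrays as the baseline")
  }
  list(Y = signal$Y[, keep, drop = FALSE],
       groups = signal$groups,
       meta = meta[match(keep, meta$sample_id), , drop = FALSE])
}

ai_fit_one <- function(Y, groups, meta, ps, sex_term) {
  sel <- groups$probeset_id == ps
  roles <- groups$role[sel]
  sub <- Y[sel, , drop = FALSE]
  y <- as.vector(sub)
  role <- rep(roles, times = ncol(sub))
  nucleic <- rep(meta$nucleic_acid, each = nrow(sub))
  sex <- rep(meta$sex, each = nrow(sub))
  treatment <- paste(nucleic, role, sep = ".")
  fit_contrast(y, treatment, AI_WEIGHTS,
               sex = if (sex_term) sex else NULL)
}

#' Test allelic imbalance per SNP probe set
#'
#' Fits, per probe set, the model `Y = mu + sex + treatment + error` over
#' the F1 arrays, with six treatment levels: nucleic acid (DNA/RNA) x
#' allele class (PM1/PM2/MM). AI is the single-df contrast
#' `(RNA.PM1 - RNA.PM2) - (DNA.PM1 - DNA.PM2)`: the allele difference in
#' expression minus the same difference in genomic DNA, which removes
#' probe-affinity bias. MM cells carry zero contrast weight but contribute
#' residual degrees of freedom. The sex effect is estimated from the RNA
#' rows (DNA arrays are female-only in the reference design).
#'
#' @param signal allele-class [summarize_signal()] result for the F1
#'   arrays (rows are probe set x PM1/PM2/MM).
#' @param meta sample metadata: `sample_id`, `nucleic_acid`, `sex`.
#' @param testable optional [select_testable()] result or character vector
#'   of probe-set ids to restrict to.
#' @param sex_term include the additive sex effect (default TRUE).
#' @param genotype when `meta` carries several genotypes, the label of the
#'   heterozygous F1 whose arrays are tested (e.g. `"F1"`).
#' @return data.frame per probe set: `probeset_id`, `estimate` (log-scale
#'   AI contrast), `se`, `F`, `df1`, `df2`, `p`, `q`, `degenerate`.
#' @export
test_ai <- function(signal, meta, testable = NULL, sex_term = TRUE,
                    genotype = NULL) {
  dat <- ai_long_data(signal, meta, genotype = genotype)
  ps_ids <- unique(dat$groups$probeset_id)
  if (!is.null(testable)) {
    ids <- if (is.data.frame(testable)) {
      testable$probeset_id[testable$testable]
    } else testable
    ps_ids <- intersect(ps_ids, ids)
  }
  rows <- lapply(ps_ids, function(ps) {
    fit <- ai_fit_one(dat$Y, dat$groups, dat$meta, ps, sex_term)
    cbind(data.frame(probeset_id = ps, stringsAsFactors = FALSE), fit)
  })
  out <- do.call(rbind, rows)
  out$q <- fdr_bh(out$p)
  rownames(out) <- NULL
  out
}

#' Sex-stratified allelic-imbalance tests
#'
#' Runs [test_ai()] separately on the female and male data: RNA arrays of
#' one sex plus all DNA arrays (the genomic-DNA baseline is shared), with
#' the sex term dropped.
#'
#' @inheritParams test_ai
#' @return named list of per-sex result data.frames (`F`, `M`).
#' @export
test_ai_by_sex <- function(signal, meta, testable = NULL,
                           genotype = NULL) {
  stop_if_not_df_cols(meta, c("sample_id", "nucleic_acid", "sex"), "meta")
  if ("genotype" %in% names(meta) && !is.null(genotype)) {
    meta <- meta[meta$genotype == genotype, , drop = FALSE]
  }
  sexes <- sort(unique(meta$sex[meta$nucleic_acid == "RNA"]))
  out <- lapply(sexes, function(s) {
    sub <- meta[meta$nucleic_acid == "DNA" |
                  (meta$nucleic_acid == "RNA" & meta$sex == s), ,
                drop = FALSE]
    test_ai(signal, sub, testable = testable, sex_term = FALSE)
  })
  names(out) <- sexes
  out
}

#' Threshold summary table for pooled and per-sex AI results
#'
#' @param results_pooled result of [test_ai()].
#' @param results_by_sex result of [test_ai_by_sex()].
#' @param thresholds FDR cutoffs.
#' @return data.frame with one row per analysis (`both_sexes`, per sex)
#'   and one significance-count column per threshold.
#' @export
ai_threshold_summary <- function(results_pooled, results_by_sex = NULL,
                                 thresholds = c(0.05, 0.1, 0.2)) {
  count_row <- function(label, res) {
    counts <- vapply(thresholds,
                     function(th) sum(!is.na(res$q) & res$q < th),
                     numeric(1))
    df <- data.frame(analysis = label, n_tested = sum(!is.na(res$q)))
    for (i in seq_along(thresholds)) {
      df[[paste0("fdr_", thresholds[i])]] <- counts[i]
    }
    df
  }
  out <- count_row("both_sexes", results_pooled)
  if (!is.null(results_by_sex)) {
    labels <- c("F" = "female", "M" = "male")
    for (s in names(results_by_sex)) {
      lab <- if (s %in% names(labels)) labels[[s]] else s
      out <- rbind(out, count_row(lab, results_by_sex[[s]]))
    }
  }
  rownames(out) <- NULL
  out
}
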