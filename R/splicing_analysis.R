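# Exon classification and the sex-specific isoform-usage test: the
# exon-type x sex interaction with sex-specific residual variances.

#' Classify exon probe sets as constitutive, alternative or ambiguous
#'
#' A probe set is constitutive when its exon appears in every annotated
#' isoform of its (single) gene, alternative when it appears in a proper
#' subset, and ambiguous -- excluded from analysis -- when it maps to more
#' than one gene or to overlapping exon regions. The isoform universe of a
#' gene is the union of isoform memberships over its probe sets.
#'
#' @param annotation data.frame with `probeset_id`, `gene_id`
#'   (comma-separated when a probe set maps to several genes), `isoforms`
#'   (comma-separated isoform ids containing the exon) and optionally
#'   `overlapping` (logical: lies in an ambiguous overlap region).
#' @return data.frame: `probeset_id`, `gene_id`, `exon_class`
#'   (`constitutive` / `alternative` / `ambiguous` / `unmapped`),
#'   `excluded`, `reason`.
#' @export
classify_probesets <- function(annotation) {
  stop_if_not_df_cols(annotation, c("probeset_id", "gene_id", "isoforms"),
                      "annotation")
  genes <- strsplit(ifelse(is.na(annotation$gene_id), "",
                           annotation$gene_id), ",")
  isos <- strsplit(ifelse(is.na(annotation$isoforms), "",
                          annotation$isoforms), ",")
  n_genes <- lengths(genes)
  overlapping <- if ("overlapping" %in% names(annotation)) {
    isTRUE_vec <- annotation$overlapping
    !is.na(isTRUE_vec) & isTRUE_vec
  } else rep(FALSE, nrow(annotation))

  # isoform universe per gene from single-gene probe sets
  single <- n_genes == 1L
  universe <- tapply(isos[single], unlist(genes[single]),
                     function(l) unique(unlist(l)))

  out <- data.frame(probeset_id = annotation$probeset_id,
                    gene_id = vapply(genes, paste, character(1),
                                     collapse = ","),
                    exon_class = NA_character_,
                    excluded = FALSE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(annotation))) {
    if (n_genes[i] == 0L) {
      out$exon_class[i] <- "unmapped"
      out$excluded[i] <- TRUE
      out$reason[i] <- "unmapped"
    } else if (n_genes[i] > 1L) {
      out$exon_class[i] <- "ambiguous"
      out$excluded[i] <- TRUE
      out$reason[i] <- "multiple_genes"
    } else if (overlapping[i]) {
      out$exon_class[i] <- "ambiguous"
      out$excluded[i] <- TRUE
      out$reason[i] <- "overlapping_exons"
    } else {
      u <- universe[[genes[[i]][1]]]
      m <- unique(isos[[i]])
      out$exon_class[i] <- if (setequal(m, u)) "constitutive"
                           else "alternative"
    }
  }
  out
}

# Heteroscedastic exon-type x sex interaction Wald test on cell means.
# Per-sex residual variances come from within-cell replicates; each
# interaction contrast gets a Satterthwaite df, and the denominator df is
# their mean. In the equal-variance limit this reduces exactly to the
# ordinary two-way ANOVA interaction F.
interaction_wald <- function(y, exon_type, sex) {
  exon_type <- droplevels(factor(exon_type))
  sex <- droplevels(factor(sex))
  E <- nlevels(exon_type)
  if (E < 2L || nlevels(sex) < 2L) {
    stop("interaction test needs >= 2 exon types and both sexes")
  }
  lev_e <- levels(exon_type)
  lev_s <- levels(sex)
  # cell bookkeeping without name parsing (exon-type labels are free text)
  cell_e <- rep(lev_e, times = 2L)
  cell_s <- rep(lev_s, each = E)
  cell_idx <- match(paste0(as.integer(exon_type), "/", as.integer(sex)),
                    paste0(match(cell_e, lev_e), "/", match(cell_s, lev_s)))
  n_cell <- tabulate(cell_idx, nbins = length(cell_e))
  if (any(n_cell < 1L)) stop("empty exon-type x sex cell")
  m_cell <- vapply(seq_along(cell_e),
                   function(k) mean(y[cell_idx == k]), numeric(1))

  # per-sex residual variance from within-cell replicates
  s2 <- df_sex <- setNames(numeric(2), lev_s)
  for (s in lev_s) {
    idx <- sex == s
    res <- y[idx] - m_cell[cell_idx[idx]]
    df_sex[s] <- sum(idx) - sum(cell_s == s)
    if (df_sex[s] < 1L) stop("no within-cell replication for sex ", s)
    s2[s] <- sum(res^2) / df_sex[s]
  }

  # interaction contrasts: (e vs e1) x (sex2 vs sex1), e = 2..E
  q <- E - 1L
  C <- matrix(0, nrow = q, ncol = length(cell_e))
  cell_of <- function(e, s) which(cell_e == e & cell_s == s)
  for (k in seq_len(q)) {
    e <- lev_e[k + 1L]
    C[k, cell_of(e, lev_s[1])] <- 1
    C[k, cell_of(lev_e[1], lev_s[1])] <- -1
    C[k, cell_of(e, lev_s[2])] <- -1
    C[k, cell_of(lev_e[1], lev_s[2])] <- 1
  }
  v_cell <- unname(s2[cell_s]) / n_cell
  V <- C %*% diag(v_cell, nrow = length(cell_e)) %*% t(C)
  psi <- drop(C %*% m_cell)
  tol <- .Machine$double.eps * max(1, sum(y^2))
  if (max(v_cell) <= tol) {
    # noiseless fit: exact interaction recovery, flagged degenerate
    if (max(abs(psi)) <= sqrt(tol)) {
      return(list(F = 0, df1 = q, df2 = sum(df_sex), p = 1, s2 = s2,
                  psi = psi, degenerate = TRUE))
    }
    return(list(F = Inf, df1 = q, df2 = sum(df_sex), p = 0, s2 = s2,
                psi = psi, degenerate = TRUE))
  }
  Fstat <- drop(t(psi) %*% solve(V, psi)) / q

  # Satterthwaite df per contrast, averaged
  df_i <- vapply(seq_len(q), function(k) {
    contrib <- C[k, ]^2 * v_cell           # per-cell variance contribution
    per_sex <- tapply(contrib, cell_s, sum)
    sum(per_sex)^2 / sum(per_sex^2 / df_sex[names(per_sex)])
  }, numeric(1))
  df_den <- mean(df_i)
  list(F = Fstat, df1 = q, df2 = df_den,
       p = pf(Fstat, q, df_den, lower.tail = FALSE),
       s2 = s2, psi = psi, degenerate = FALSE)
}

#' Test genes for sex-specific isoform usage
#'
#' Fits, per gene, the two-factor model `Y = mu + exon_type + sex +
#' exon_type:sex + error` over its exon probe sets and RNA samples, and
#' tests the interaction -- the signature of differential isoform usage
#' between the sexes. Probe sets from constitutive exons are pooled as a
#' single exon type; each alternative exon is its own type. The residual
#' variance is estimated separately for each sex; the default test is a
#' weighted (heteroscedastic) Wald F with Satterthwaite denominator
#' degrees of freedom, which reduces to the ordinary two-way ANOVA
#' interaction F when the sex variances are equal. `method = "anova"`
#' forces the ordinary homoscedastic test.
#'
#' @param signal a [summarize_signal()] result (probe-set grouping) or
#'   matrix of Y values, probe sets x samples.
#' @param annotation classified exon annotation from
#'   [classify_probesets()] (ambiguous/unmapped rows are dropped).
#' @param meta sample metadata with `sample_id`, `sex`, optionally
#'   `nucleic_acid` (RNA kept).
#' @param method `"heteroscedastic"` (default) or `"anova"`.
#' @return data.frame per gene: `gene_id`, `n_exon_types`, `estimate`
#'   (the interaction contrast when it has a single df, heteroscedastic
#'   method only), `F`, `df1`, `df2`, `p`, `q`, `skipped` (reason or
#'   `NA`).
#' @export
test_isoform_usage <- function(signal, annotation, meta,
                               method = c("heteroscedastic", "anova")) {
  method <- match.arg(method)
  Y <- as_signal_matrix(signal)
  stop_if_not_df_cols(meta, c("sample_id", "sex"), "meta")
  if ("nucleic_acid" %in% names(meta)) {
    meta <- meta[meta$nucleic_acid == "RNA", , drop = FALSE]
  }
  keep <- intersect(colnames(Y), meta$sample_id)
  Y <- Y[, keep, drop = FALSE]
  sex <- meta$sex[match(keep, meta$sample_id)]

  ann <- annotation[!annotation$excluded, , drop = FALSE]
  ann <- ann[ann$probeset_id %in% rownames(Y), , drop = FALSE]
  genes <- unique(ann$gene_id)

  rows <- lapply(genes, function(g) {
    ps <- ann[ann$gene_id == g, , drop = FALSE]
    exon_type <- ifelse(ps$exon_class == "constitutive", "constitutive",
                        ps$probeset_id)
    if (length(unique(exon_type)) < 2L) {
      return(data.frame(gene_id = g, n_exon_types = length(unique(exon_type)),
                        estimate = NA_real_,
                        F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                        p = NA_real_, skipped = "single_exon_type",
                        stringsAsFactors = FALSE))
    }
    sub <- Y[ps$probeset_id, , drop = FALSE]
    long_y <- as.vector(sub)
    long_type <- rep(exon_type, times = ncol(sub))
    long_sex <- rep(sex, each = nrow(sub))
    if (method == "anova") {
      fit <- lm(long_y ~ factor(long_type) * factor(long_sex))
      a <- anova(fit)
      irow <- grep(":", rownames(a))
      data.frame(gene_id = g, n_exon_types = length(unique(exon_type)),
                 estimate = NA_real_,
                 F = a[irow, "F value"], df1 = a[irow, "Df"],
                 df2 = a["Residuals", "Df"], p = a[irow, "Pr(>F)"],
                 skipped = NA_character_, stringsAsFactors = FALSE)
    } else {
      w <- interaction_wald(long_y, long_type, long_sex)
      data.frame(gene_id = g, n_exon_types = length(unique(exon_type)),
                 estimate = if (w$df1 == 1L) w$psi else NA_real_,
                 F = w$F, df1 = w$df1, df2 = w$df2, p = w$p,
                 skipped = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- is.na(out$skipped)
  out$q[tested] <- fdr_bh(out$p[tested])
  rownames(out) <- NULL
  out
}
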