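# Shared linear-model machinery: one-way ANOVA F tests, single-df
# contrasts in the sex + treatment cell-means model, BH false-discovery
# correction, and kappa/McNemar agreement statistics.

test_result <- function(estimate = NA_real_, F = NA_real_,
                        df1 = NA_real_, df2 = NA_real_,
                        p = NA_real_, degenerate = FALSE) {
  data.frame(estimate = estimate, F = F, df1 = df1, df2 = df2, p = p,
             degenerate = degenerate)
}

#' One-way fixed-effects ANOVA F test
#'
#' Classical one-way ANOVA for the model `Y = mu + group + error`:
#' `F = MSB / MSW` with the usual degrees of freedom. Zero-residual-variance
#' fits are flagged degenerate rather than erroring (noiseless synthetic
#' inputs are legitimate): p = 0 when group means differ, p = 1 when they
#' do not.
#'
#' @param values numeric response vector.
#' @param groups factor (or coercible) of group labels, same length.
#' @return one-row data.frame: `estimate` (difference of group means,
#'   second minus first level, when there are exactly two groups),
#'   `F`, `df1`, `df2`, `p`, `degenerate`.
#' @export
#' @examples
#' fit_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))  # F = 13.5
fit_oneway <- function(values, groups) {
  g <- droplevels(factor(groups))
  if (nlevels(g) < 2L) stop("fit_oneway needs at least two groups")
  means <- tapply(values, g, mean)
  est <- if (nlevels(g) == 2L) unname(means[2] - means[1]) else NA_real_
  fit <- lm(values ~ g)
  a <- suppressWarnings(anova(fit))  # perfect fits are handled explicitly
  msw <- a["Residuals", "Mean Sq"]
  msb <- a["g", "Mean Sq"]
  df1 <- a["g", "Df"]
  df2 <- a["Residuals", "Df"]
  tol <- .Machine$double.eps * max(1, sum(values^2))
  if (df2 < 1L || msw <= tol) {
    if (msb <= tol) {
      return(test_result(est, F = 0, df1 = df1, df2 = df2, p = 1,
                         degenerate = TRUE))
    }
    return(test_result(est, F = Inf, df1 = df1, df2 = df2, p = 0,
                       degenerate = TRUE))
  }
  test_result(est, F = a["g", "F value"], df1 = df1, df2 = df2,
              p = a["g", "Pr(>F)"])
}

#' Single-df contrast F test in a sex + treatment cell-means model
#'
#' Fits `Y = treatment + sex` (cell-means parametrization for the
#' treatment factor, an additive sex effect when `sex` is supplied) by
#' least squares and tests the contrast `L'beta` with weights over the
#' treatment levels: `F = (L'b)^2 / Var(L'b)`, single numerator df, with
#' the residual variance pooled across all treatment cells -- so cells
#' that carry zero contrast weight (e.g. mismatch probes) still
#' contribute error degrees of freedom.
#'
#' @param values numeric response vector.
#' @param treatment factor of treatment cell labels.
#' @param weights named numeric contrast weights over treatment levels;
#'   must sum to zero. Levels not named get weight 0.
#' @param sex optional factor; when present an additive sex effect is
#'   estimated alongside the cells.
#' @return one-row data.frame: `estimate` (= L'b), `se`, `F`, `df1` (= 1),
#'   `df2`, `p`, `degenerate`.
#' @export
fit_contrast <- function(values, treatment, weights, sex = NULL) {
  tr <- droplevels(factor(treatment))
  if (is.null(names(weights))) {
    stop("contrast weights must be named by treatment level")
  }
  unknown <- setdiff(names(weights), levels(tr))
  if (length(unknown)) {
    stop("contrast weights name unknown treatment level(s): ",
         paste(unknown, collapse = ", "))
  }
  w <- setNames(numeric(nlevels(tr)), levels(tr))
  w[names(weights)] <- weights
  if (abs(sum(w)) > 1e-8) stop("contrast weights must sum to zero")

  dat <- data.frame(y = values, tr = tr)
  if (!is.null(sex)) {
    dat$sex <- droplevels(factor(sex))
    fit <- lm(y ~ 0 + tr + sex, data = dat)
  } else {
    fit <- lm(y ~ 0 + tr, data = dat)
  }
  b <- coef(fit)
  if (anyNA(b)) {
    aliased <- names(b)[is.na(b)]
    stop("rank-deficient design; aliased cell(s): ",
         paste(aliased, collapse = ", "))
  }
  L <- setNames(numeric(length(b)), names(b))
  L[paste0("tr", levels(tr))] <- w[levels(tr)]
  est <- sum(L * b)
  df2 <- fit$df.residual
  rss <- sum(fit$residuals^2)
  tol <- .Machine$double.eps * max(1, sum(values^2))
  if (df2 < 1L || rss / max(df2, 1) <= tol) {
    if (abs(est) <= sqrt(tol)) {
      return(cbind(test_result(est, F = 0, df1 = 1, df2 = df2, p = 1,
                               degenerate = TRUE), se = 0))
    }
    return(cbind(test_result(est, F = Inf, df1 = 1, df2 = df2, p = 0,
                             degenerate = TRUE), se = 0))
  }
  v <- drop(t(L) %*% vcov(fit) %*% L)
  Fstat <- if (all(w == 0)) 0 else est^2 / v
  p <- pf(Fstat, 1, df2, lower.tail = FALSE)
  cbind(test_result(est, F = Fstat, df1 = 1, df2 = df2, p = p),
        se = sqrt(v))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment; a thin, validated wrapper around
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order.
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Agreement between two sets of significance calls
#'
#' Cross-tabulates two boolean call vectors, then reports Cohen's kappa
#' and McNemar's test without continuity correction:
#' `chi^2 = (b - c)^2 / (b + c)` on the discordant counts, 1 df.
#'
#' @param calls_a,calls_b logical vectors over the same units.
#' @return object of class `agreement_table`: list with counts `a` (both
#'   significant), `b` (A only), `c` (B only), `d` (neither), `n`,
#'   `simple_agreement` (proportion agreeing), `kappa`,
#'   `mcnemar_stat`, `mcnemar_p` (both `NA` when `b + c = 0`).
#' @export
#' @examples
#' # discordant counts 106 and 265 give the McNemar statistic 68.1429
#' ag <- agreement(c(rep(TRUE, 106), rep(FALSE, 265)),
#'                 c(rep(FALSE, 106), rep(TRUE, 265)))
#' ag$mcnemar_stat
agreement <- function(calls_a, calls_b) {
  stopifnot(length(calls_a) == length(calls_b),
            is.logical(calls_a), is.logical(calls_b))
  a <- sum(calls_a & calls_b)
  b <- sum(calls_a & !calls_b)
  c <- sum(!calls_a & calls_b)
  d <- sum(!calls_a & !calls_b)
  n <- a + b + c + d
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps) {
    if (po >= 1) 1 else 0
  } else {
    (po - pe) / (1 - pe)
  }
  if (b + c == 0L) {
    mcnemar_stat <- NA_real_
    mcnemar_p <- NA_real_
  } else {
    mc <- suppressWarnings(
      mcnemar.test(matrix(c(a, b, c, d), nrow = 2), correct = FALSE))
    mcnemar_stat <- unname(mc$statistic)
    mcnemar_p <- mc$p.value
  }
  structure(list(a = a, b = b, c = c, d = d, n = n,
                 simple_agreement = po, kappa = kappa,
                 mcnemar_stat = mcnemar_stat, mcnemar_p = mcnemar_p),
            class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  cat(sprintf(
    "agreement over %d units: both %d, A-only %d, B-only %d, neither %d\n",
    x$n, x$a, x$b, x$c, x$d))
  cat(sprintf("  simple agreement %.2f%%, kappa %.4f, McNemar %.4f (p %.3g)\n",
              100 * x$simple_agreement, x$kappa, x$mcnemar_stat,
              x$mcnemar_p))
  invisible(x)
}
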