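# Rank-based base calling, concordance reporting and LDA separation.

test_that("rank_bases averages per base and calls the top signal", {
  # two probe sets, one probe per (base x strand), one sample
  annot <- expand.grid(probeset_id = c("ps1", "ps2"),
                       fwd = c("A", "C", "G", "T"),
                       strand = c("forward", "reverse"),
                       stringsAsFactors = FALSE)
  annot$snp_base <- ifelse(annot$strand == "reverse",
                           chartr("ACGT", "TGCA", annot$fwd), annot$fwd)
  annot$probe_id <- sprintf("p%02d", seq_len(nrow(annot)))
  base_level <- c(A = 5, C = 4.5, G = 4, T = 3.5)
  vals <- matrix(base_level[annot$fwd], nrow(annot), 1,
                 dimnames = list(annot$probe_id, "s1"))
  vals[annot$probeset_id == "ps1" & annot$fwd == "A", 1] <- 8
  vals[annot$probeset_id == "ps2" & annot$fwd == "G", 1] <- 9
  calls <- rank_bases(vals, annot)
  c1 <- calls[calls$probeset_id == "ps1", ]
  expect_equal(c1$top, "A")
  expect_equal(c1$A, 8)
  expect_false(c1$tie)
  expect_equal(calls$top[calls$probeset_id == "ps2"], "G")
  expect_true(all(calls$tie == FALSE))
  vals2 <- vals
  vals2[annot$probeset_id == "ps1" & annot$fwd == "C", 1] <- 8
  calls2 <- rank_bases(vals2, annot)
  c2 <- calls2[calls2$probeset_id == "ps1", ]
  expect_true(c2$tie)
  expect_equal(c2$top, "A")      # tie broken by fixed A<C<G<T order
})

test_that("reverse-strand probes are counted on the forward strand", {
  # a single reverse-strand probe with snp_base T interrogates A forward
  annot <- data.frame(probeset_id = "ps1",
                      snp_base = c("A", "C", "G", "T", "T", "G", "C", "A"),
                      strand = rep(c("forward", "reverse"), each = 4),
                      probe_id = paste0("p", 1:8))
  vals <- matrix(c(1, 2, 3, 4, 9, 2, 3, 4), ncol = 1,
                 dimnames = list(annot$probe_id, "s1"))
  calls <- rank_bases(vals, annot)
  # reverse T probe (value 9) counts toward forward A: A mean = (1+9)/2 = 5
  expect_equal(calls$A, 5)
  expect_equal(calls$top, "A")
})

test_that("noiseless homozygous simulations call the true allele always", {
  bank <- random_probe_bank(30, seed = 401)
  ex <- simulate_experiment(bank, params = sim_params(noise_sd = 0,
                                                      control_noise_sd = 0),
                            seed = 402)
  pv <- probe_signal(ex$intensities, ex$annot, ex$controls)
  grp <- setNames(paste(ex$meta$genotype, ex$meta$nucleic_acid, sep = "_"),
                  ex$meta$sample_id)
  calls <- rank_bases(pv, ex$annot, grp)
  p1 <- calls[calls$group == "P1_DNA", ]
  expect_equal(p1$top[match(names(ex$truth$pm1), p1$probeset_id)],
               unname(ex$truth$pm1))
  # heterozygous F1: top-2 are the two true alleles
  f1 <- calls[calls$group == "F1_DNA", ]
  i <- match(names(ex$truth$pm1), f1$probeset_id)
  expect_true(all(
    (f1$top[i] == ex$truth$pm1 & f1$second[i] == ex$truth$pm2) |
      (f1$top[i] == ex$truth$pm2 & f1$second[i] == ex$truth$pm1)))
})

test_that("heterozygous top-2 concordance exceeds 95% at moderate noise", {
  bank <- random_probe_bank(1000, seed = 403)
  # noise sd = 0.25 of the allele-signal gap between carried and
  # cross-hybridizing bases (gap = xhyb - log(0.5) on the log scale)
  gap <- 2 - log(0.5)
  ex <- simulate_experiment(bank,
                            params = sim_params(noise_sd = 0.25 * gap),
                            seed = 404)
  pv <- probe_signal(ex$intensities, ex$annot, ex$controls)
  grp <- setNames(ifelse(ex$meta$genotype == "F1" &
                           ex$meta$nucleic_acid == "DNA", "F1_DNA", "other"),
                  ex$meta$sample_id)
  calls <- rank_bases(pv, ex$annot, grp)
  truth <- data.frame(probeset_id = names(ex$truth$pm1),
                      allele1 = unname(ex$truth$pm1),
                      allele2 = unname(ex$truth$pm2))
  rep <- concordance_report(calls[calls$group == "F1_DNA", ], truth,
                            mode = "top2")
  expect_gte(rep$F1_DNA[rep$allele == "Overall"], 95)
})

test_that("concordance is perfect for correct calls, ~25% for permuted ones", {
  set.seed(405)
  n <- 2000
  bases <- c("A", "C", "G", "T")
  truth <- data.frame(probeset_id = paste0("ps", 1:n),
                      allele = sample(bases, n, replace = TRUE))
  calls <- data.frame(probeset_id = truth$probeset_id, group = "g",
                      top = truth$allele, second = "A")
  rep_ok <- concordance_report(calls, truth, mode = "top1")
  expect_true(all(rep_ok$g[!is.na(rep_ok$g)] == 100))
  # weighted per-base average equals the overall percentage
  w <- rep_ok$n_g[-1]
  expect_equal(sum(rep_ok$g[-1] * w) / sum(w),
               rep_ok$g[rep_ok$allele == "Overall"])

  calls$top <- sample(bases, n, replace = TRUE)   # random assignment
  rep_rand <- concordance_report(calls, truth, mode = "top1")
  expect_lt(abs(rep_rand$g[rep_rand$allele == "Overall"] - 25), 3)
})

test_that("concordance decreases monotonically with noise", {
  bank <- random_probe_bank(150, seed = 406)
  overall <- vapply(c(0.5, 2, 4), function(sd) {
    ex <- simulate_experiment(bank, params = sim_params(noise_sd = sd),
                              seed = 407)
    pv <- probe_signal(ex$intensities, ex$annot, ex$controls)
    grp <- setNames(rep("all", nrow(ex$meta)), ex$meta$sample_id)
    dna <- ex$meta$sample_id[ex$meta$genotype == "F1" &
                               ex$meta$nucleic_acid == "DNA"]
    calls <- rank_bases(pv[, dna], ex$annot, grp[dna])
    truth <- data.frame(probeset_id = names(ex$truth$pm1),
                        allele1 = unname(ex$truth$pm1),
                        allele2 = unname(ex$truth$pm2))
    rep <- concordance_report(calls, truth, mode = "top2")
    rep$all[rep$allele == "Overall"]
  }, numeric(1))
  expect_true(all(diff(overall) <= 0))
})

test_that("rank_bases is invariant to probe order", {
  ex <- make_small_experiment(n_ps = 5, seed = 408)
  pv <- probe_signal(ex$intensities, ex$annot, ex$controls)
  grp <- setNames(rep("g", nrow(ex$meta)), ex$meta$sample_id)
  c1 <- rank_bases(pv, ex$annot, grp)
  perm <- sample(nrow(pv))
  c2 <- rank_bases(pv[perm, ], ex$annot[perm, ], grp)
  c2 <- c2[match(c1$probeset_id, c2$probeset_id), ]
  rownames(c2) <- NULL
  expect_equal(c1, c2)
})

test_that("LDA separates distinct genotype classes and reports chance
           accuracy for identical ones", {
  set.seed(409)
  x <- rbind(matrix(rnorm(40, 0, 0.2), 10),
             matrix(rnorm(40, 3, 0.2), 10),
             matrix(rnorm(40, 6, 0.2), 10))
  lab <- rep(c("AA", "AC", "CC"), each = 10)
  fit <- lda_separation(x, lab)
  expect_equal(fit$accuracy, 1)
  expect_lte(ncol(fit$scores), 2)

  acc <- replicate(30, {
    xr <- matrix(rnorm(120), 30)
    lda_separation(xr, lab)$accuracy
  })
  # resubstitution on pure noise overfits somewhat; stay near chance
  expect_lt(mean(acc), 0.75)
  expect_gt(mean(acc), 1 / 3 - 0.05)
})

test_that("LDA projection is invariant to adding a constant", {
  set.seed(410)
  x <- rbind(matrix(rnorm(30, 0), 10), matrix(rnorm(30, 2), 10))
  lab <- rep(c("a", "b"), each = 10)
  f1 <- lda_separation(x, lab, ndim = 1)
  f2 <- lda_separation(x + 5, lab, ndim = 1)
  r <- f2$scores[, 1] / f1$scores[, 1]
  expect_equal(sd(r), 0, tolerance = 1e-6)   # same up to sign/scale
  expect_equal(f1$accuracy, f2$accuracy)
})

test_that("singular within-class scatter triggers ridge regularization", {
  x <- cbind(rep(c(0, 3), each = 6), rep(c(0, 3), each = 6))  # collinear
  lab <- rep(c("a", "b"), each = 6)
  expect_warning(fit <- lda_separation(x, lab), "ridge")
  expect_gt(fit$ridge_used, 0)
  expect_equal(fit$accuracy, 1)
})

test_that("LDA cross-checks against MASS::lda on a well-posed problem", {
  skip_if_not_installed("MASS")
  set.seed(411)
  x <- rbind(matrix(rnorm(60, 0), 15), matrix(rnorm(60, 1.5), 15))
  lab <- rep(c("a", "b"), each = 15)
  ours <- lda_separation(x, lab, ndim = 1)
  ref <- MASS::lda(x, grouping = lab)
  ref_scores <- as.matrix(scale(x, center = TRUE, scale = FALSE)) %*%
    ref$scaling
  cor_abs <- abs(cor(ours$scores[, 1], ref_scores[, 1]))
  expect_gt(cor_abs, 0.999)
  expect_equal(ours$accuracy,
               mean(predict(ref)$class == lab))
})
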