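# Synthetic alignments and probe-intensity experiments with known truth,
# so that every pipeline stage is testable without array hybridizations.
#
# The intensity model is additive on the natural-log scale -- the scale of
# the summarization formula -- so planted effects are directly
# recoverable: log signal = GC background + probe affinity +
# expression(sex, gene) + allele-fraction term + match term + noise,
# exponentiated to raw intensities. Genomic DNA of a heterozygote carries
# both alleles at 1:1, so its PM1-PM2 difference reflects probe affinity
# only -- the property the DNA control of the AI test relies on.

#' Simulate a multiple sequence alignment with planted SNPs
#'
#' Generates `n_sequences` aligned rows from a random reference with
#' planted biallelic (or multi-allelic) variants at stated positions and
#' allele frequencies. Allele counts are assigned deterministically
#' (first `round(freq * n)` rows carry allele 1, ...) so the planted
#' support is exact.
#'
#' @param n_sequences rows in the alignment (first row is the reference).
#' @param length ungapped reference length.
#' @param snp_spec data.frame with `position` (0-based on the reference),
#'   `alleles` (e.g. `"A/G"`), `freqs` (e.g. `"0.5/0.5"`, must sum to 1).
#' @param seed RNG seed; same seed, same alignment.
#' @param region_id region identifier.
#' @param gap_rate per-cell gap probability in non-reference rows
#'   (never at planted SNP columns).
#' @param assert_clean error if two planted SNPs fall within one design
#'   window (17 bases) of each other.
#' @return list with `alignment` (an [snp_alignment()]) and `truth`
#'   (planted positions, alleles and expected support).
#' @export
simulate_alignment <- function(n_sequences = 6L, length = 200L,
                               snp_spec = NULL, seed = 1L,
                               region_id = "sim_region", gap_rate = 0,
                               assert_clean = FALSE) {
  if (is.null(snp_spec)) {
    snp_spec <- data.frame(position = integer(0), alleles = character(0),
                           freqs = character(0))
  }
  stopifnot(all(snp_spec$position >= 0 & snp_spec$position < length))
  if (assert_clean && nrow(snp_spec) > 1L) {
    pos <- sort(snp_spec$position)
    if (any(diff(pos) <= WINDOW_FLANK)) {
      stop("planted SNPs closer than one design window; ",
           "overlapping windows requested with assert_clean")
    }
  }
  with_seed(seed, {
    ref <- sample(BASES, length, replace = TRUE)
    rows <- matrix(rep(ref, each = n_sequences), nrow = n_sequences)
    snp_cols <- snp_spec$position + 1L
    for (i in seq_len(nrow(snp_spec))) {
      alleles <- strsplit(snp_spec$alleles[i], "/")[[1]]
      freqs <- as.numeric(strsplit(as.character(snp_spec$freqs[i]),
                                   "/")[[1]])
      if (abs(sum(freqs) - 1) > 1e-8) {
        stop("allele frequencies must sum to 1 at position ",
             snp_spec$position[i])
      }
      counts <- round(freqs * n_sequences)
      counts[1] <- n_sequences - sum(counts[-1])
      rows[, snp_cols[i]] <- rep(alleles, times = counts)
    }
    if (gap_rate > 0 && n_sequences > 1L) {
      gappable <- setdiff(seq_len(length), snp_cols)
      for (r in 2:n_sequences) {
        gaps <- gappable[runif(base::length(gappable)) < gap_rate]
        rows[r, gaps] <- "-"
      }
    }
    seqs <- apply(rows, 1, paste, collapse = "")
    names(seqs) <- c("ref", paste0("strain", seq_len(n_sequences - 1L)))
    list(alignment = snp_alignment(region_id, seqs, ref_index = 1L),
         truth = list(seed = seed,
                      positions = snp_spec$position,
                      alleles = snp_spec$alleles,
                      ref_base = ref[snp_cols]))
  })
}

#' Default sample plan mirroring the verification design
#'
#' Three RNA replicates per sex of the F1 heterozygote (6 RNA arrays) and
#' three female genomic-DNA replicates each of the two parental strains
#' and the F1 (9 DNA arrays).
#'
#' @return data.frame with `sample_id`, `genotype` (`P1`, `P2`, `F1`),
#'   `nucleic_acid`, `sex`, `replicate`.
#' @export
default_sample_plan <- function() {
  plan <- rbind(
    expand.grid(genotype = "F1", nucleic_acid = "RNA", sex = c("F", "M"),
                replicate = 1:3, stringsAsFactors = FALSE),
    expand.grid(genotype = c("P1", "P2", "F1"), nucleic_acid = "DNA",
                sex = "F", replicate = 1:3, stringsAsFactors = FALSE))
  plan$sample_id <- sprintf("%s_%s_%s_r%d", plan$genotype,
                            plan$nucleic_acid, plan$sex, plan$replicate)
  plan[, c("sample_id", "genotype", "nucleic_acid", "sex", "replicate")]
}

#' Simulation parameters
#'
#' Defaults are the package's reference study conditions: expression well
#' above background so log summarization recovers planted effects, modest
#' probe-affinity spread shared between RNA and DNA, and a cross-
#' hybridization damping that keeps mismatch probes clearly below
#' perfect-match probes.
#'
#' @param mu mean log expression level of RNA targets (default 8.5).
#' @param gene_sd per-gene spread of expression around `mu` (default 0.5).
#' @param dna_level log signal level of genomic DNA targets (default 8.5;
#'   copy number does not depend on expression).
#' @param sex_effect male-minus-female log expression shift; scalar or one
#'   value per probe set (default 0).
#' @param ai_delta log-scale allelic-imbalance effect, PM1 over PM2 in
#'   RNA of the heterozygote; scalar or per probe set (default 0).
#' @param affinity_sd per-probe affinity SD, shared across samples
#'   (default 0.3) -- the bias the DNA control cancels.
#' @param noise_sd residual log-normal noise SD (default 0.2).
#' @param xhyb log-scale damping of probes whose SNP base the sample does
#'   not carry, including MM probes (default 2).
#' @param bg0,bg_gc intercept and per-GC slope of the log background
#'   curve (defaults 3 and 0.06).
#' @param n_controls_per_bin control probes per GC bin (default 20).
#' @param control_noise_sd noise SD of control probes (default 0.2).
#' @return list of parameters for [simulate_experiment()].
#' @export
sim_params <- function(mu = 8.5, gene_sd = 0.5, dna_level = 8.5,
                       sex_effect = 0, ai_delta = 0, affinity_sd = 0.3,
                       noise_sd = 0.2, xhyb = 2, bg0 = 3, bg_gc = 0.06,
                       n_controls_per_bin = 20L, control_noise_sd = 0.2) {
  as.list(environment())
}

#' Simulate a probe-intensity experiment with known truth
#'
#' Generates raw probe intensities, GC-bin controls and sample metadata
#' for a set of designed SNP probe sets under a stated sample plan.
#' Parental strain P1 is homozygous for the PM1 allele, P2 for PM2 and the
#' F1 heterozygous; DNA of the heterozygote carries the alleles 1:1, RNA
#' allele fractions are shifted by the planted AI effect
#' (`f_PM1 / f_PM2 = exp(ai_delta)`). Probes for a base the sample does
#' not carry (including all MM probes) are damped by the
#' cross-hybridization factor.
#'
#' @param probes per-probe design table (from
#'   [design_probesets()]`$probes` or [build_probe_set()]`$probes` rows
#'   bound with `probeset_id`/`gene_id`/`pm1`/`pm2` columns): needs
#'   `probe_id`, `probeset_id`, `gene_id`, `sequence`, `strand`,
#'   `snp_base`, `role`, `pm1`, `pm2`.
#' @param sample_plan data.frame as [default_sample_plan()].
#' @param params list from [sim_params()].
#' @param seed RNG seed; same seed, byte-identical output.
#' @return list of class `sim_experiment`: `intensities` (probes x
#'   samples, raw scale), `annot` (probe annotation with `gc` and
#'   `module`), `controls` ([gc_controls()]), `meta` (sample plan),
#'   `truth` (per-probe-set effects, per-probe affinities, parameters,
#'   seed).
#' @export
simulate_experiment <- function(probes, sample_plan = default_sample_plan(),
                                params = sim_params(), seed = 1L) {
  stop_if_not_df_cols(probes, c("probe_id", "probeset_id", "gene_id",
                                "sequence", "strand", "snp_base", "role",
                                "pm1", "pm2"), "probes")
  ps_ids <- unique(probes$probeset_id)
  n_ps <- length(ps_ids)
  genes <- unique(probes$gene_id)
  expand <- function(x, n, what) {
    if (length(x) == 1L) rep(x, n)
    else if (length(x) == n) x
    else stop(what, " must be scalar or one per probe set")
  }
  sex_eff <- setNames(expand(params$sex_effect, n_ps, "sex_effect"), ps_ids)
  ai_delta <- setNames(expand(params$ai_delta, n_ps, "ai_delta"), ps_ids)

  fwd_base <- ifelse(probes$strand == "reverse",
                     dna_complement(probes$snp_base), probes$snp_base)
  pm1 <- probes$pm1
  pm2 <- probes$pm2
  gc <- assign_gc_bin(probes$sequence)
  n_probe <- nrow(probes)
  n_samp <- nrow(sample_plan)

  with_seed(seed, {
    gene_mu <- setNames(params$mu + rnorm(length(genes), 0,
                                          params$gene_sd), genes)
    affinity <- rnorm(n_probe, 0, params$affinity_sd)

    # carried-allele log fraction of each probe in each genotype state
    frac_term <- function(genotype, nucleic) {
      delta <- ai_delta[probes$probeset_id]
      f1 <- switch(genotype,
                   P1 = 1, P2 = 0,
                   F1 = if (nucleic == "DNA") 0.5
                        else exp(delta / 2) / (exp(delta / 2) +
                                                 exp(-delta / 2)))
      f_of_probe <- ifelse(fwd_base == pm1, f1,
                           ifelse(fwd_base == pm2, 1 - f1, 0))
      ifelse(f_of_probe > 0, log(f_of_probe), -params$xhyb)
    }
    states <- unique(sample_plan[, c("genotype", "nucleic_acid")])
    state_terms <- lapply(seq_len(nrow(states)), function(i) {
      frac_term(states$genotype[i], states$nucleic_acid[i])
    })
    names(state_terms) <- paste(states$genotype, states$nucleic_acid)

    log_signal <- matrix(NA_real_, n_probe, n_samp,
                         dimnames = list(probes$probe_id,
                                         sample_plan$sample_id))
    for (s in seq_len(n_samp)) {
      smp <- sample_plan[s, ]
      expr <- if (smp$nucleic_acid == "DNA") params$dna_level
              else gene_mu[probes$gene_id] +
                sex_eff[probes$probeset_id] * (smp$sex == "M")
      log_signal[, s] <- params$bg0 + params$bg_gc * gc + affinity +
        expr + state_terms[[paste(smp$genotype, smp$nucleic_acid)]] +
        rnorm(n_probe, 0, params$noise_sd)
    }

    bins <- rep(GC_BIN_MIN:GC_BIN_MAX, each = params$n_controls_per_bin)
    ctrl <- matrix(
      exp(params$bg0 + params$bg_gc * bins +
            rnorm(length(bins) * n_samp, 0, params$control_noise_sd)),
      nrow = length(bins), ncol = n_samp,
      dimnames = list(NULL, sample_plan$sample_id))

    annot <- data.frame(probe_id = probes$probe_id,
                        probeset_id = probes$probeset_id,
                        gene_id = probes$gene_id,
                        module = "SNP",
                        role = probes$role,
                        snp_base = probes$snp_base,
                        strand = probes$strand,
                        gc = gc, stringsAsFactors = FALSE)
    structure(list(
      intensities = exp(log_signal),
      annot = annot,
      controls = gc_controls(ctrl, bins),
      meta = sample_plan,
      truth = list(seed = seed, params = params,
                   sex_effect = sex_eff, ai_delta = ai_delta,
                   gene_mu = gene_mu,
                   affinity = setNames(affinity, probes$probe_id),
                   pm1 = setNames(pm1[!duplicated(probes$probeset_id)],
                                  ps_ids),
                   pm2 = setNames(pm2[!duplicated(probes$probeset_id)],
                                  ps_ids))),
      class = "sim_experiment")
  })
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf(
    "sim_experiment: %d probes x %d samples, %d probe sets (seed %d)\n",
    nrow(x$intensities), ncol(x$intensities),
    length(unique(x$annot$probeset_id)), x$truth$seed))
  invisible(x)
}

# Quick generator of a bank of synthetic SNP probe sets (random windows,
# random biallelic alleles) for simulation studies that do not need a real
# alignment round-trip.
#' Generate a bank of synthetic SNP probe sets
#'
#' Builds `n` probe sets from random 35-base windows with random biallelic
#' SNPs -- design-table input for [simulate_experiment()].
#'
#' @param n number of probe sets.
#' @param probesets_per_gene probe sets per simulated gene (default 1).
#' @param seed RNG seed.
#' @return data.frame of probes with design columns (`probeset_id`,
#'   `gene_id`, `pm1`, `pm2`, `probe_id`, `sequence`, `strand`, `offset`,
#'   `snp_base`, `fwd_base`, `role`, `quality`).
#' @export
random_probe_bank <- function(n, probesets_per_gene = 1L, seed = 1L) {
  with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      alleles <- sample(BASES, 2)
      window <- paste(sample(BASES, 2L * WINDOW_FLANK + 1L,
                             replace = TRUE), collapse = "")
      substr(window, WINDOW_FLANK + 1L, WINDOW_FLANK + 1L) <- alleles[1]
      cand <- list(region_id = sprintf("r%04d", i),
                   ref_position = WINDOW_FLANK,
                   window = window,
                   allele1 = alleles[1], allele2 = alleles[2])
      gene <- sprintf("gene%04d",
                      (i - 1L) %/% probesets_per_gene + 1L)
      ps <- build_probe_set(cand, gene_id = gene,
                            probeset_id = sprintf("ps%04d", i))
      cbind(data.frame(probeset_id = ps$probeset_id, gene_id = ps$gene_id,
                       pm1 = ps$pm1, pm2 = ps$pm2,
                       stringsAsFactors = FALSE),
            ps$probes)
    })
    do.call(rbind, rows)
  })
}

#' Simulate probe-set-level expression signals
#'
#' Signal-level shortcut for testing the expression and splicing
#' statistics without simulating individual probes: Y values for
#' `n_probesets` probe sets over `n_rep` RNA replicates per sex, with a
#' planted male-minus-female effect.
#'
#' @param n_probesets number of probe sets.
#' @param sex_effect male-minus-female shift; scalar or per probe set.
#' @param mu baseline log signal (default 6).
#' @param noise_sd residual SD.
#' @param n_rep replicates per sex.
#' @param seed RNG seed.
#' @return list with `Y` (matrix probe sets x samples) and `meta`.
#' @export
simulate_expression_signal <- function(n_probesets, sex_effect = 0,
                                       mu = 6, noise_sd = 0.2, n_rep = 3L,
                                       seed = 1L) {
  eff <- if (length(sex_effect) == 1L) rep(sex_effect, n_probesets)
         else sex_effect
  stopifnot(length(eff) == n_probesets)
  meta <- expand.grid(sex = c("F", "M"), replicate = seq_len(n_rep),
                      stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("RNA_%s_r%d", meta$sex, meta$replicate)
  meta$nucleic_acid <- "RNA"
  meta$genotype <- "F1"
  with_seed(seed, {
    base <- mu + rnorm(n_probesets, 0, 1)
    Y <- sapply(seq_len(nrow(meta)), function(j) {
      base + eff * (meta$sex[j] == "M") +
        rnorm(n_probesets, 0, noise_sd)
    })
    dimnames(Y) <- list(sprintf("ps%05d", seq_len(n_probesets)),
                        meta$sample_id)
    list(Y = Y, meta = meta[, c("sample_id", "genotype", "nucleic_acid",
                                "sex", "replicate")])
  })
}

#' Simulate allele-class signals for the AI contrast test
#'
#' Signal-level shortcut that generates allele-class Y values directly
#' under the AI model's own error structure: per probe set, each of the
#' six treatment cells (DNA/RNA x PM1/PM2/MM) gets a class-specific
#' probe-affinity shift shared between DNA and RNA -- the bias the
#' genomic-DNA control exists to cancel -- plus the planted AI effect
#' (PM1 + delta/2, PM2 - delta/2, RNA only) and iid Gaussian noise.
#'
#' @param n_probesets number of SNP probe sets.
#' @param ai_delta planted log-scale AI effect; scalar or per probe set.
#' @param affinity_sd SD of the class-specific affinity shifts
#'   (default 0.6).
#' @param noise_sd residual SD (default 0.2).
#' @param n_rep replicates: `n_rep` DNA arrays (female) and `n_rep` RNA
#'   arrays per sex.
#' @param seed RNG seed.
#' @return list with `signal` (a `probeset_signal` with allele grouping)
#'   and `meta`.
#' @export
simulate_ai_signal <- function(n_probesets, ai_delta = 0,
                               affinity_sd = 0.6, noise_sd = 0.2,
                               n_rep = 3L, seed = 1L) {
  delta <- if (length(ai_delta) == 1L) rep(ai_delta, n_probesets)
           else ai_delta
  stopifnot(length(delta) == n_probesets)
  meta <- rbind(
    data.frame(nucleic_acid = "DNA", sex = "F",
               replicate = seq_len(n_rep)),
    expand.grid(nucleic_acid = "RNA", sex = c("F", "M"),
                replicate = seq_len(n_rep),
                stringsAsFactors = FALSE)[, c("nucleic_acid", "sex",
                                              "replicate")])
  meta$sample_id <- sprintf("F1_%s_%s_r%d", meta$nucleic_acid, meta$sex,
                            meta$replicate)
  meta$genotype <- "F1"
  roles <- c("PM1", "PM2", "MM")
  ps_ids <- sprintf("ps%05d", seq_len(n_probesets))
  group_ids <- as.vector(t(outer(ps_ids, roles, paste, sep = "|")))
  with_seed(seed, {
    affinity <- matrix(rnorm(n_probesets * 3, 0, affinity_sd),
                       n_probesets, 3)
    base <- rnorm(n_probesets, 6, 0.5)
    Y <- matrix(NA_real_, length(group_ids), nrow(meta),
                dimnames = list(group_ids, meta$sample_id))
    for (s in seq_len(nrow(meta))) {
      rna <- meta$nucleic_acid[s] == "RNA"
      cell <- base + affinity                       # n_ps x 3
      if (rna) {
        cell[, 1] <- cell[, 1] + delta / 2
        cell[, 2] <- cell[, 2] - delta / 2
      }
      cell[, 3] <- cell[, 3] - 2                    # MM damped
      Y[, s] <- as.vector(t(cell)) + rnorm(length(group_ids), 0, noise_sd)
    }
    groups <- data.frame(probeset_id = rep(ps_ids, each = 3),
                         role = rep(roles, n_probesets),
                         stringsAsFactors = FALSE)
    signal <- structure(list(Y = Y, N = setNames(rep(1L, nrow(Y)),
                                                 rownames(Y)),
                             groups = groups, grouping = "allele",
                             clamped = 0L),
                        class = "probeset_signal")
    list(signal = signal,
         meta = meta[, c("sample_id", "genotype", "nucleic_acid", "sex",
                         "replicate")])
  })
}

#' Simulate exon-level signals for one gene's isoform-usage test
#'
#' Y values for a gene with pooled constitutive exons plus alternative
#' exons, a planted exon-type x sex interaction, and optionally different
#' residual SDs per sex.
#'
#' @param n_constitutive,n_alternative probe sets of each class.
#' @param interaction planted interaction: extra male-minus-female shift
#'   of each alternative exon relative to the constitutive exons.
#' @param sd_f,sd_m residual SD per sex.
#' @param mu baseline; `sex_effect` additive sex shift;
#'   `exon_effect` additive shift of alternative exons.
#' @param n_rep replicates per sex.
#' @param seed RNG seed.
#' @param gene_id gene identifier.
#' @return list with `Y`, `meta`, `annotation` (classified, ready for
#'   [test_isoform_usage()]).
#' @export
simulate_isoform_gene <- function(n_constitutive = 2L, n_alternative = 1L,
                                  interaction = 0, sd_f = 0.2, sd_m = 0.2,
                                  mu = 6, sex_effect = 0, exon_effect = 0,
                                  n_rep = 3L, seed = 1L,
                                  gene_id = "gene1") {
  n_ps <- n_constitutive + n_alternative
  is_alt <- c(rep(FALSE, n_constitutive), rep(TRUE, n_alternative))
  ps_ids <- sprintf("%s_ps%d", gene_id, seq_len(n_ps))
  meta <- expand.grid(sex = c("F", "M"), replicate = seq_len(n_rep),
                      stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("RNA_%s_r%d", meta$sex, meta$replicate)
  meta$nucleic_acid <- "RNA"
  with_seed(seed, {
    Y <- sapply(seq_len(nrow(meta)), function(j) {
      male <- meta$sex[j] == "M"
      mu + exon_effect * is_alt + sex_effect * male +
        interaction * is_alt * male +
        rnorm(n_ps, 0, if (male) sd_m else sd_f)
    })
    dimnames(Y) <- list(ps_ids, meta$sample_id)
    annotation <- data.frame(
      probeset_id = ps_ids,
      gene_id = gene_id,
      exon_class = ifelse(is_alt, "alternative", "constitutive"),
      excluded = FALSE, reason = NA_character_,
      stringsAsFactors = FALSE)
    list(Y = Y, meta = meta[, c("sample_id", "nucleic_acid", "sex",
                                "replicate")],
         annotation = annotation)
  })
}
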