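# SNP discovery and allele-specific probe-set design.
#
# Coordinates are 0-based half-open throughout; the design window of a SNP
# at reference position p spans [p - 17, p + 18) on the reference strand,
# i.e. 17 bases either side of the SNP (35 bases total).

WINDOW_FLANK <- 17L
PROBE_LENGTH <- 25L
PROBE_OFFSETS <- c(-4L, 0L, 4L)

#' Construct a multiple sequence alignment of an exon region
#'
#' A lightweight container for one aligned exon region across strains.
#' All rows must have equal (aligned) length; gaps are `-`.
#'
#' @param region_id exon/region identifier.
#' @param sequences named character vector of aligned rows (may contain `-`).
#' @param ref_index index (or name) of the reference row that carries the
#'   genomic coordinate system.
#' @param ref_start 0-based genomic start of the reference row.
#' @return an object of class `snp_alignment`.
#' @export
#' @examples
#' aln <- snp_alignment("ex1", c(ref = "ACGTACGT", s1 = "ACGAACGT"))
snp_alignment <- function(region_id, sequences, ref_index = 1L,
                          ref_start = 0L) {
  if (length(sequences) < 1L) stop("alignment needs at least one sequence")
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    stop("aligned rows must all have equal length")
  }
  if (is.character(ref_index)) {
    ref_index <- match(ref_index, names(sequences))
    if (is.na(ref_index)) stop("reference row name not found in alignment")
  }
  ref_index <- as.integer(ref_index)
  if (ref_index < 1L || ref_index > length(sequences)) {
    stop("ref_index out of range")
  }
  structure(
    list(region_id = region_id,
         sequences = toupper(sequences),
         ref_index = ref_index,
         ref_start = as.integer(ref_start)),
    class = "snp_alignment")
}

#' @export
print.snp_alignment <- function(x, ...) {
  cat(sprintf("snp_alignment '%s': %d sequences x %d columns (ref: %s)\n",
              x$region_id, length(x$sequences), nchar(x$sequences[[1]]),
              names(x$sequences)[x$ref_index]))
  invisible(x)
}

#' Read aligned FASTA files into alignment objects
#'
#' One file per exon region; the file stem is used as the region id.
#'
#' @param paths character vector of aligned FASTA files, or a directory
#'   (every `.fa`/`.fasta` file inside is read).
#' @param ref name of the reference row; defaults to the first record.
#' @param ref_start 0-based genomic start of the reference row (recycled).
#' @return list of [snp_alignment()] objects.
#' @export
read_alignments <- function(paths, ref = NULL, ref_start = 0L) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  }
  ref_start <- rep_len(ref_start, length(paths))
  out <- lapply(seq_along(paths), function(i) {
    ss <- Biostrings::readDNAStringSet(paths[i])
    seqs <- setNames(as.character(ss), names(ss))
    snp_alignment(region_id = sub("\\.(fa|fasta)$", "", basename(paths[i])),
                  sequences = seqs,
                  ref_index = if (is.null(ref)) 1L else ref,
                  ref_start = ref_start[i])
  })
  names(out) <- vapply(out, `[[`, character(1), "region_id")
  out
}

#' Identify SNP candidates in a multiple sequence alignment
#'
#' Scans every alignment column for two or more distinct non-gap bases and
#' returns one candidate per variant column, with its 35-base design window
#' extracted from the (ungapped) reference row. Candidates failing the
#' support rule or with more than two alleles are flagged, not dropped;
#' [apply_window_filters()] performs the actual partition.
#'
#' @param alignment an [snp_alignment()].
#' @param min_support minimum number of non-gap sequences covering a site
#'   for it to be usable (default 5; sites below are flagged `low_support`).
#' @param flank bases either side of the SNP in the design window
#'   (default 17, a 35-base window).
#' @return data.frame with one row per variant column: `region_id`,
#'   `column` (1-based alignment column), `ref_position` (0-based genomic),
#'   `alleles` (e.g. `"A=3,G=3"`, by descending support), `allele1`,
#'   `allele2`, `n_alleles`, `support`, `window`, `flags`
#'   (comma-separated, `""` if clean).
#' @export
find_snps <- function(alignment, min_support = 5L, flank = WINDOW_FLANK) {
  stopifnot(inherits(alignment, "snp_alignment"))
  mat <- do.call(rbind, strsplit(alignment$sequences, ""))
  ncol_aln <- ncol(mat)
  ref_row <- mat[alignment$ref_index, ]
  is_ref_base <- ref_row %in% BASES
  ref_seq <- paste(ref_row[is_ref_base], collapse = "")
  ref_len <- nchar(ref_seq)
  # 0-based ungapped reference position of each alignment column (NA at gaps)
  ref_pos <- ifelse(is_ref_base, cumsum(is_ref_base) - 1L, NA_integer_)

  rows <- lapply(seq_len(ncol_aln), function(j) {
    col <- mat[, j]
    obs <- col[col %in% BASES]
    tab <- table(factor(obs, levels = BASES))
    tab <- tab[tab > 0L]
    if (length(tab) < 2L) return(NULL)
    # order alleles by count (desc), ties alphabetical
    tab <- tab[order(-as.integer(tab), names(tab))]
    support <- length(obs)
    flags <- character(0)
    if (support < min_support) flags <- c(flags, "low_support")
    if (length(tab) > 2L) flags <- c(flags, "multiallelic")
    pos <- ref_pos[j]
    window <- NA_character_
    if (is.na(pos)) {
      flags <- c(flags, "unresolvable")
    } else {
      lo <- pos - flank
      hi <- pos + flank
      if (lo < 0L || hi > ref_len - 1L) {
        flags <- c(flags, "window_truncated")
        window <- substr(ref_seq, max(lo, 0L) + 1L, min(hi, ref_len - 1L) + 1L)
      } else {
        window <- substr(ref_seq, lo + 1L, hi + 1L)
      }
    }
    data.frame(
      region_id = alignment$region_id,
      column = j,
      ref_position = if (is.na(pos)) NA_integer_
                     else pos + alignment$ref_start,
      alleles = paste(names(tab), as.integer(tab), sep = "=",
                      collapse = ","),
      allele1 = names(tab)[1],
      allele2 = if (length(tab) >= 2L) names(tab)[2] else NA_character_,
      n_alleles = length(tab),
      support = support,
      window = window,
      flags = paste(flags, collapse = ","),
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(region_id = character(0), column = integer(0),
                      ref_position = integer(0), alleles = character(0),
                      allele1 = character(0), allele2 = character(0),
                      n_alleles = integer(0), support = integer(0),
                      window = character(0), flags = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

add_flag <- function(flags, new) {
  ifelse(flags == "", new, paste(flags, new, sep = ","))
}

has_flag <- function(flags, flag) {
  vapply(strsplit(flags, ","), function(f) flag %in% f, logical(1))
}

#' Partition SNP candidates into design-ready and discarded sets
#'
#' Applies the window-level quality rules: a candidate fails if it has
#' fewer than the required supporting sequences (`low_support`), more than
#' two alleles (`multiallelic`; only biallelic SNPs proceed), another
#' candidate within the design window (`multi_snp_window`), or a window
#' that maps to more than one genomic location (`multi_map`, delegated to
#' a caller-supplied uniqueness oracle). The partition is exhaustive and
#' disjoint.
#'
#' @param candidates data.frame from [find_snps()] (one or more regions).
#' @param uniqueness_oracle function mapping a 35-mer window to its genome
#'   hit count; the default assumes every window is unique.
#' @param flank design-window flank (must match [find_snps()]).
#' @return list with data.frames `pass` and `fail`; `fail` rows carry the
#'   discard reason(s) in `flags`.
#' @export
apply_window_filters <- function(candidates,
                                 uniqueness_oracle = function(w) 1L,
                                 flank = WINDOW_FLANK) {
  if (!nrow(candidates)) return(list(pass = candidates, fail = candidates))
  flags <- candidates$flags
  # more than one SNP inside a design window: any other candidate within
  # `flank` bases on the same region (either SNP's window contains the other)
  for (rid in unique(candidates$region_id)) {
    idx <- which(candidates$region_id == rid &
                   !is.na(candidates$ref_position))
    if (length(idx) < 2L) next
    pos <- candidates$ref_position[idx]
    crowded <- vapply(seq_along(idx), function(k) {
      any(abs(pos[-k] - pos[k]) <= flank)
    }, logical(1))
    flags[idx[crowded]] <- add_flag(flags[idx[crowded]], "multi_snp_window")
  }
  ok_window <- !is.na(candidates$window) &
    nchar(candidates$window) == 2L * flank + 1L
  hits <- rep(1L, nrow(candidates))
  hits[ok_window] <- vapply(candidates$window[ok_window],
                            function(w) as.integer(uniqueness_oracle(w)),
                            integer(1), USE.NAMES = FALSE)
  flags[hits > 1L] <- add_flag(flags[hits > 1L], "multi_map")
  candidates$flags <- flags
  fail <- flags != ""
  list(pass = candidates[!fail, , drop = FALSE],
       fail = candidates[fail, , drop = FALSE])
}

# Probe hybridization quality heuristic. The original platform used a
# proprietary scorer (Tm, secondary structure, empirical weights); this
# reproducible stand-in keeps the same discard semantics: a weighted sum of
#   - deviation of Wallace-rule Tm (2(A+T)+4(G+C)) from the probe-set median,
#   - longest self-complementary run (hairpin/self-dimer proxy),
#   - longest homopolymer run,
# each scaled to [0,1] and subtracted from 1, so higher = better.
score_probe_quality <- function(sequences,
                                weights = c(tm = 0.5, selfcomp = 0.25,
                                            homopolymer = 0.25),
                                tm_scale = 16, selfcomp_scale = 12,
                                homopolymer_scale = 6) {
  counts_gc <- gc_count(sequences)
  tm <- 2 * (nchar(sequences) - counts_gc) + 4 * counts_gc
  p_tm <- pmin(1, abs(tm - median(tm)) / tm_scale)
  p_sc <- pmin(1, max_selfcomp(sequences) / selfcomp_scale)
  p_hp <- pmin(1, (max_homopolymer(sequences) - 1) /
                 (homopolymer_scale - 1))
  w <- weights / sum(weights)
  1 - (w[["tm"]] * p_tm + w[["selfcomp"]] * p_sc +
         w[["homopolymer"]] * p_hp)
}

#' Build the 24-probe set for a passing SNP candidate
#'
#' Designs 25-mer probes with the SNP base at offsets -4, 0 and +4 from the
#' probe center, on both strands, with each of A/C/G/T at the SNP site:
#' 4 bases x 3 offsets x 2 strands = 24 probes. Probes whose SNP base
#' (read on the forward strand) equals the first or second design allele
#' are perfect-match probes PM1 / PM2 (6 each); the remaining 12 are
#' mismatch (MM) probes. Reverse-strand probes are reverse complements of
#' their forward counterparts.
#'
#' @param candidate one-row data.frame from [find_snps()] /
#'   [apply_window_filters()]`$pass`.
#' @param gene_id gene the SNP belongs to.
#' @param probeset_id identifier; default `"<region>_<position>"`.
#' @param offsets SNP offsets from the probe center (default -4, 0, +4).
#' @param probe_length probe length (default 25).
#' @param quality_weights,tm_scale passed to the quality heuristic.
#' @return list of class `snp_probe_set` with elements `probeset_id`,
#'   `gene_id`, `pm1`, `pm2` (forward-strand design alleles), `candidate`,
#'   and `probes` (24-row data.frame: `probe_id`, `sequence`, `strand`,
#'   `offset`, `snp_base`, `fwd_base`, `role`, `quality`).
#' @export
build_probe_set <- function(candidate, gene_id,
                            probeset_id = NULL,
                            offsets = PROBE_OFFSETS,
                            probe_length = PROBE_LENGTH,
                            quality_weights = c(tm = 0.5, selfcomp = 0.25,
                                                homopolymer = 0.25),
                            tm_scale = 16) {
  if (is.data.frame(candidate)) {
    stopifnot(nrow(candidate) == 1L)
    candidate <- as.list(candidate)
  }
  window <- candidate$window
  wlen <- nchar(window)
  center <- (wlen + 1L) %/% 2L              # 1-based SNP index in window
  if (is.na(window) || wlen %% 2L == 0L) {
    stop("candidate window is missing or not centered on the SNP")
  }
  half <- (probe_length - 1L) %/% 2L        # 12 for 25-mers
  if (is.null(probeset_id)) {
    probeset_id <- paste0(candidate$region_id, "_", candidate$ref_position)
  }
  pm1 <- candidate$allele1
  pm2 <- candidate$allele2

  grid <- expand.grid(fwd_base = BASES,
                      strand = c("forward", "reverse"),
                      offset = offsets,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  fwd_seq <- character(nrow(grid))
  for (off in offsets) {
    start <- center - (half + off)          # SNP at probe index half+off (0b)
    end <- start + probe_length - 1L
    if (start < 1L || end > wlen) {
      stop(sprintf("design window too short for offset %+d", off))
    }
    base_probe <- substr(window, start, end)
    snp_idx <- half + off + 1L              # 1-based within probe
    sel <- which(grid$offset == off)
    fwd_seq[sel] <- vapply(grid$fwd_base[sel], function(b) {
      s <- base_probe
      substr(s, snp_idx, snp_idx) <- b
      s
    }, character(1), USE.NAMES = FALSE)
  }
  is_fwd <- grid$strand == "forward"
  sequence <- fwd_seq
  sequence[!is_fwd] <- dna_revcomp(fwd_seq[!is_fwd])
  probes <- data.frame(
    sequence = sequence, strand = grid$strand, offset = grid$offset,
    snp_base = ifelse(is_fwd, grid$fwd_base,
                      dna_complement(grid$fwd_base)),
    fwd_base = grid$fwd_base,
    role = ifelse(grid$fwd_base == pm1, "PM1",
                  ifelse(grid$fwd_base == pm2, "PM2", "MM")),
    stringsAsFactors = FALSE)
  probes$quality <- score_probe_quality(probes$sequence,
                                        weights = quality_weights,
                                        tm_scale = tm_scale)
  probes$probe_id <- sprintf("%s_p%02d", probeset_id, seq_len(nrow(probes)))
  probes <- probes[, c("probe_id", "sequence", "strand", "offset",
                       "snp_base", "fwd_base", "role", "quality")]
  structure(list(probeset_id = probeset_id, gene_id = gene_id,
                 pm1 = pm1, pm2 = pm2, candidate = candidate,
                 probes = probes),
            class = "snp_probe_set")
}

#' @export
print.snp_probe_set <- function(x, ...) {
  cat(sprintf("snp_probe_set %s (gene %s): %d probes, alleles %s/%s\n",
              x$probeset_id, x$gene_id, nrow(x$probes), x$pm1, x$pm2))
  print(table(x$probes$role))
  invisible(x)
}

#' Decide whether a designed probe set survives probe-quality filtering
#'
#' A probe set is eliminated when any probe contains a homopolymer run of
#' `homopolymer_len` or more, when any probe cannot be synthesized (carries
#' a non-ACGT character), or when one third or more of its probes
#' (`ceiling(n/3)`, i.e. 8 of 24) have predicted hybridization quality
#' below `poor_threshold`.
#'
#' @param ps an `snp_probe_set` from [build_probe_set()].
#' @param homopolymer_len minimum run length that disqualifies (default 6).
#' @param poor_threshold quality score below which a probe counts as poor
#'   (default 0.5).
#' @return list with `keep` (logical) and `reasons` (character vector,
#'   empty when kept; subset of `homopolymer`, `unsynthesizable`,
#'   `poor_hybridization`).
#' @export
quality_filter_probe_set <- function(ps, homopolymer_len = 6L,
                                     poor_threshold = 0.5) {
  stopifnot(inherits(ps, "snp_probe_set"))
  seqs <- ps$probes$sequence
  reasons <- character(0)
  if (any(max_homopolymer(seqs) >= homopolymer_len)) {
    reasons <- c(reasons, "homopolymer")
  }
  if (any(grepl("[^ACGT]", seqs))) {
    reasons <- c(reasons, "unsynthesizable")
  }
  n_poor <- sum(ps$probes$quality < poor_threshold)
  if (n_poor >= ceiling(nrow(ps$probes) / 3)) {
    reasons <- c(reasons, "poor_hybridization")
  }
  list(keep = length(reasons) == 0L, reasons = reasons)
}

#' Capacity-aware per-gene selection of probe sets
#'
#' Every gene with `per_gene_max` (default 7) or fewer surviving probe sets
#' contributes all of them; genes with more contribute a seeded uniform
#' draw of `per_gene_max`. Any remaining array capacity is filled by a
#' seeded uniform draw from the leftover probe sets. Deterministic given
#' the seed.
#'
#' @param probesets data.frame with columns `probeset_id` and `gene_id`.
#' @param capacity total number of probe sets the array can carry.
#' @param seed integer seed for the random draws.
#' @param per_gene_max per-gene guarantee threshold (default 7).
#' @return character vector of selected `probeset_id`s.
#' @export
select_per_gene <- function(probesets, capacity, seed = 1L,
                            per_gene_max = 7L) {
  stop_if_not_df_cols(probesets, c("probeset_id", "gene_id"), "probesets")
  split_ids <- split(probesets$probeset_id, probesets$gene_id)
  guaranteed_n <- sum(pmin(per_gene_max, lengths(split_ids)))
  if (capacity < guaranteed_n) {
    stop(sprintf(
      "capacity %d below the per-gene guarantee of %d probe sets (short %d)",
      capacity, guaranteed_n, guaranteed_n - capacity))
  }
  with_seed(seed, {
    selected <- unlist(lapply(split_ids, function(ids) {
      if (length(ids) <= per_gene_max) ids
      else sample(ids, per_gene_max)
    }), use.names = FALSE)
    leftover <- setdiff(probesets$probeset_id, selected)
    n_fill <- min(capacity - length(selected), length(leftover))
    if (n_fill > 0L) {
      selected <- c(selected, sample(leftover, n_fill))
    }
    selected
  })
}

#' Run the full probe-design pipeline over a set of alignments
#'
#' find SNPs -> window filters -> build 24-probe sets -> probe-quality
#' filter -> capacity-aware per-gene selection.
#'
#' @param alignments list of [snp_alignment()] objects.
#' @param gene_map named character vector mapping region id to gene id;
#'   defaults to one gene per region.
#' @param capacity array capacity in probe sets (default: no limit).
#' @param seed seed for the selection draw.
#' @param min_support,uniqueness_oracle,homopolymer_len,poor_threshold
#'   passed to the respective steps.
#' @return list with `probes` (per-probe table over all kept probe sets),
#'   `probesets` (per-probe-set table with kept flags and discard reasons),
#'   `candidates` (all candidates with filter flags) and `report`
#'   (filter-stage counts).
#' @export
design_probesets <- function(alignments, gene_map = NULL,
                             capacity = Inf, seed = 1L,
                             min_support = 5L,
                             uniqueness_oracle = function(w) 1L,
                             homopolymer_len = 6L, poor_threshold = 0.5) {
  if (inherits(alignments, "snp_alignment")) alignments <- list(alignments)
  cand <- do.call(rbind, lapply(alignments, find_snps,
                                min_support = min_support))
  part <- apply_window_filters(cand, uniqueness_oracle = uniqueness_oracle)
  gene_of <- function(region) {
    if (is.null(gene_map)) region else unname(gene_map[[region]])
  }
  sets <- lapply(seq_len(nrow(part$pass)), function(i) {
    row <- part$pass[i, , drop = FALSE]
    build_probe_set(row, gene_id = gene_of(row$region_id))
  })
  qc <- lapply(sets, quality_filter_probe_set,
               homopolymer_len = homopolymer_len,
               poor_threshold = poor_threshold)
  kept <- vapply(qc, `[[`, logical(1), "keep")
  ps_table <- data.frame(
    probeset_id = vapply(sets, `[[`, character(1), "probeset_id"),
    gene_id = vapply(sets, `[[`, character(1), "gene_id"),
    region_id = part$pass$region_id,
    ref_position = part$pass$ref_position,
    pm1 = vapply(sets, `[[`, character(1), "pm1"),
    pm2 = vapply(sets, `[[`, character(1), "pm2"),
    kept = kept,
    discard_reason = vapply(qc, function(q) paste(q$reasons, collapse = ","),
                            character(1)),
    stringsAsFactors = FALSE)
  surviving <- ps_table[ps_table$kept, , drop = FALSE]
  selected_ids <- if (nrow(surviving)) {
    select_per_gene(surviving,
                    capacity = min(capacity, nrow(surviving)),
                    seed = seed)
  } else character(0)
  ps_table$selected <- ps_table$probeset_id %in% selected_ids
  probe_rows <- lapply(sets[ps_table$selected],
    function(ps) {
      cbind(data.frame(probeset_id = ps$probeset_id, gene_id = ps$gene_id,
                       pm1 = ps$pm1, pm2 = ps$pm2,
                       stringsAsFactors = FALSE),
            ps$probes)
    })
  probes <- if (length(probe_rows)) do.call(rbind, probe_rows) else NULL
  report <- data.frame(
    stage = c("candidates", "pass_window_filters", "built",
              "kept_after_quality", "selected"),
    n = c(nrow(cand), nrow(part$pass), length(sets), sum(kept),
          length(selected_ids)))
  list(probes = probes, probesets = ps_table,
       candidates = rbind(part$pass, part$fail), report = report)
}
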