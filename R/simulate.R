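#' Simulation configuration
#'
#' Defaults describe a desk-scale promoter-array study: 2,000 annotated
#' promoters tiled -2,200/+500 bp around the TSS, 300 factor-bound genes
#' (a tenth of whose peaks also contaminate the IgG control), a
#' single-knockdown expression experiment with two control arrays at 0.2
#' log2 units of per-array technical noise, and a 316-tumor Z-score cohort
#' in which the factor and its direct targets are co-activated in a
#' quarter of tumors with penetrance 0.6. Knockdown effects are stated in
#' units of the null SD of the tested log-ratio statistic; the default -6
#' corresponds to a ~3-fold transcript drop at the default noise level,
#' the scale of a strong, validated direct-target response.
#'
#' @param n_genes Number of annotated promoters.
#' @param promoter_upstream,promoter_downstream Window extent around the
#'   TSS, bp.
#' @param n_tumors Tumor cohort size.
#' @param background_overexp_rate Nominal background over-expression rate
#'   implied by the Z > 1.65 threshold on the standard-normal background.
#' @param noise_sd Per-array log2 technical noise SD.
#' @param n_control_arrays,n_knockdown_arrays Array counts (controls >= 2,
#'   required by [estimate_null()]).
#' @param artifact_fraction Fraction of bound genes whose peak is
#'   duplicated into the IgG control.
#' @param n_bound Factor-bound genes.
#' @param n_regulated_bound Bound genes transcriptionally dependent on the
#'   factor (planted down-regulated on knockdown).
#' @param n_indirect_down,n_indirect_up Regulated genes without promoter
#'   binding (indirect effects), by direction.
#' @param effect_size Knockdown effect for bound regulated genes, in null
#'   SD units (negative = down).
#' @param peak_width Simulated peak width, bp.
#' @param peak_jitter_sd SD of the peak center around the TSS, bp.
#' @param motif_jitter_sd SD of the planted motif around the peak center,
#'   bp.
#' @param motif_plant_rate Fraction of bound-gene peak windows receiving a
#'   planted motif instance.
#' @param coexp_active_fraction Per-tumor probability of the latent
#'   co-activation state.
#' @param coexp_penetrance Per-target probability of responding in an
#'   active tumor.
#' @param coexp_shift Z-score shift added in responding tumor/gene cells.
#' @param k4_rate_targets,k27_rate_targets Probability that a direct
#'   target's promoter carries H3K4me3 / H3K27me3.
#' @param k4_rate_other,k27_rate_other Same for non-target genes.
#' @param anchor_id Gene id of the factor itself in the tumor matrix.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       promoter_upstream = 2200,
                       promoter_downstream = 500,
                       n_tumors = 316,
                       background_overexp_rate = 0.05,
                       noise_sd = 0.2,
                       n_control_arrays = 2,
                       n_knockdown_arrays = 1,
                       artifact_fraction = 0.1,
                       n_bound = 300,
                       n_regulated_bound = 150,
                       n_indirect_down = 50,
                       n_indirect_up = 100,
                       effect_size = -6,
                       peak_width = 300,
                       peak_jitter_sd = 200,
                       motif_jitter_sd = 75,
                       motif_plant_rate = 1,
                       coexp_active_fraction = 0.25,
                       coexp_penetrance = 0.6,
                       coexp_shift = 3,
                       k4_rate_targets = 0.70,
                       k27_rate_targets = 0.02,
                       k4_rate_other = 0.40,
                       k27_rate_other = 0.10,
                       anchor_id = "TF1") {
  cfg <- as.list(environment())
  if (cfg$n_control_arrays < 2) abort("need >= 2 control arrays")
  rates <- c(cfg$background_overexp_rate, cfg$artifact_fraction,
             cfg$motif_plant_rate, cfg$coexp_active_fraction,
             cfg$coexp_penetrance, cfg$k4_rate_targets, cfg$k27_rate_targets,
             cfg$k4_rate_other, cfg$k27_rate_other)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (cfg$n_bound > cfg$n_genes) abort("more bound genes than genes")
  structure(cfg, class = "sim_config")
}

#' Synthetic promoter annotation and window sequences
#'
#' Places `n_genes` non-overlapping promoter windows (mixed strands, ~100
#' per synthetic chromosome, 1 kb gaps) and draws a uniform-composition
#' sequence for each window. Deterministic given `(cfg, seed)`.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A list with `promoters` (tibble: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `tss`) and `sequences` (named character vector, one
#'   window sequence per gene).
#' @export
make_annotation <- function(cfg = sim_config(), seed = 1) {
  set.seed(seed)
  n <- cfg$n_genes
  width <- cfg$promoter_upstream + cfg$promoter_downstream
  gene_id <- sprintf("G%05d", seq_len(n))
  per_chrom <- 100L
  chrom <- sprintf("chrS%d", ((seq_len(n) - 1L) %/% per_chrom) + 1L)
  slot <- ((seq_len(n) - 1L) %% per_chrom)
  start <- slot * (width + 1000L)
  end <- start + width
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", start + cfg$promoter_upstream,
                start + cfg$promoter_downstream)
  promoters <- tibble(gene_id = gene_id, chrom = chrom, start = start,
                      end = end, strand = strand, tss = tss)
  bases <- sample(DNA_BASES, n * width, replace = TRUE)
  sequences <- vapply(seq_len(n), function(i) {
    paste(bases[((i - 1) * width + 1):(i * width)], collapse = "")
  }, character(1))
  names(sequences) <- gene_id
  list(promoters = promoters, sequences = sequences)
}

#' Ground truth of a simulated regulatory study
#'
#' Samples which genes the factor binds, which of those peaks contaminate
#' the IgG control (artifact loci, modeled as non-functional and therefore
#' excluded from the regulated set), which genes respond to knockdown
#' (bound direct targets, all down; plus indirect down and up responders
#' among unbound genes), the chromatin-mark gene sets (H3K4me3 and
#' H3K27me3 disjoint by construction; RNA polymerase II tracking the
#' active set and most bound genes), and the latent co-activation state of
#' the tumor cohort.
#'
#' @inheritParams make_annotation
#' @param annotation Output of [make_annotation()].
#' @return A `sim_truth` list; see fields in the source. `direct_targets`
#'   holds the recoverable bound-and-regulated gene set.
#' @export
make_truth <- function(annotation, cfg = sim_config(), seed = 1) {
  set.seed(seed + 1L)
  genes <- annotation$promoters$gene_id
  bound <- sort(sample(genes, cfg$n_bound))
  n_art <- round(cfg$artifact_fraction * cfg$n_bound)
  artifact <- sort(sample(bound, n_art))
  clean_bound <- setdiff(bound, artifact)
  if (cfg$n_regulated_bound > length(clean_bound)) {
    abort("not enough artifact-free bound genes to regulate")
  }
  reg_bound <- sort(sample(clean_bound, cfg$n_regulated_bound))
  unbound <- setdiff(genes, bound)
  ind <- sample(unbound, cfg$n_indirect_down + cfg$n_indirect_up)
  ind_down <- ind[seq_len(cfg$n_indirect_down)]
  ind_up <- setdiff(ind, ind_down)
  regulated <- c(
    setNames(rep(cfg$effect_size, length(reg_bound)), reg_bound),
    setNames(rep(cfg$effect_size, length(ind_down)), ind_down),
    setNames(rep(-cfg$effect_size, length(ind_up)), ind_up)
  )
  targets <- reg_bound  # bound-and-regulated, recoverable truth
  k4 <- union(
    targets[runif(length(targets)) < cfg$k4_rate_targets],
    setdiff(genes, targets)[runif(length(genes) - length(targets)) <
                              cfg$k4_rate_other]
  )
  non_k4 <- setdiff(genes, k4)
  k27_t <- intersect(non_k4, targets)
  k27 <- union(
    k27_t[runif(length(k27_t)) < cfg$k27_rate_targets /
            max(1e-9, 1 - cfg$k4_rate_targets)],
    setdiff(non_k4, targets)[runif(length(setdiff(non_k4, targets))) <
                               cfg$k27_rate_other]
  )
  polii <- union(sample(bound, round(0.8 * length(bound))),
                 sample(k4, round(0.5 * length(k4))))
  active_tumors <- which(runif(cfg$n_tumors) < cfg$coexp_active_fraction)
  structure(list(
    bound_genes = list(factor = bound, polII = sort(polii),
                       H3K4me3 = sort(k4), H3K27me3 = sort(k27)),
    artifact_genes = artifact,
    regulated_genes = regulated,
    direct_targets = targets,
    coexp_active_tumors = active_tumors,
    penetrance = cfg$coexp_penetrance,
    seed = seed
  ), class = "sim_truth")
}

#' Simulated scored peak sets
#'
#' One peak tibble per antibody. Bound genes receive a peak of
#' `peak_width` bp centered near the TSS (Gaussian jitter, clipped to the
#' promoter window) with FDR drawn uniformly on `[0, 0.2]`; decoy peaks at
#' unbound promoters carry FDR on `(0.2, 1]`. Artifact-marked bound genes
#' have their factor peak copied verbatim into the IgG set, which also
#' contains its own non-specific peaks at unbound promoters.
#'
#' @inheritParams make_truth
#' @param truth A [make_truth()] object.
#' @return Named list of peak tibbles: `factor`, `IgG`, `polII`,
#'   `H3K4me3`, `H3K27me3`.
#' @export
make_peaksets <- function(truth, annotation, cfg = sim_config(), seed = 1) {
  stopifnot(is(truth, "sim_truth"))
  set.seed(seed + 2L)
  prom <- annotation$promoters
  if (!all(truth$bound_genes$factor %in% prom$gene_id)) {
    abort("truth and annotation disagree on gene ids")
  }
  peaks_for <- function(gene_ids, fdr_lo, fdr_hi, tag) {
    pr <- prom[match(gene_ids, prom$gene_id), , drop = FALSE]
    half <- cfg$peak_width / 2
    center <- round(pr$tss + rnorm(nrow(pr), 0, cfg$peak_jitter_sd))
    center <- pmin(pmax(center, pr$start + half), pr$end - half)
    tibble(
      chrom = pr$chrom,
      start = as.integer(center - half),
      end = as.integer(center + half),
      name = paste0(tag, "_", gene_ids),
      score = round(runif(nrow(pr), 1, 10), 3),
      strand = ".",
      fdr = round(runif(nrow(pr), fdr_lo, fdr_hi), 4)
    )
  }
  bound <- truth$bound_genes$factor
  unbound <- setdiff(prom$gene_id, bound)
  fac <- peaks_for(bound, 0, 0.2, "pk")
  n_decoy <- round(0.3 * length(bound))
  decoy_genes <- sample(unbound, n_decoy)
  decoys <- peaks_for(decoy_genes, 0.2001, 1, "decoy")
  fac_all <- dplyr::bind_rows(fac, decoys)
  igg_art <- fac[match(truth$artifact_genes, bound), , drop = FALSE]
  igg_own <- peaks_for(sample(setdiff(unbound, decoy_genes),
                              round(0.2 * length(bound))),
                       0, 0.2, "igg")
  igg <- dplyr::bind_rows(igg_art, igg_own)
  igg$name <- paste0("igg_", seq_len(nrow(igg)))
  list(
    factor = fac_all,
    IgG = igg,
    polII = peaks_for(truth$bound_genes$polII, 0, 0.2, "p2"),
    H3K4me3 = peaks_for(truth$bound_genes$H3K4me3, 0, 0.2, "k4"),
    H3K27me3 = peaks_for(truth$bound_genes$H3K27me3, 0, 0.2, "k27")
  )
}

#' Plant motif instances into bound-gene windows
#'
#' Writes the consensus of `motif` into the promoter-window sequence of
#' each bound gene (at rate `motif_plant_rate`), centered at the gene's
#' factor peak center plus Gaussian jitter (`motif_jitter_sd`), clipped to
#' the window. Returns the modified sequences and the per-gene planted
#' offset from the peak center.
#'
#' @inheritParams make_peaksets
#' @param peaksets Output of [make_peaksets()].
#' @param motif A `pwm` whose consensus is planted.
#' @return A list with `sequences` (modified named vector) and `offsets`
#'   (named numeric, planted motif-center minus peak-center, bp).
#' @export
plant_motifs <- function(truth, annotation, peaksets, motif,
                         cfg = sim_config(), seed = 1) {
  set.seed(seed + 3L)
  cons <- pwm_consensus(motif)
  w <- nchar(cons)
  seqs <- annotation$sequences
  prom <- annotation$promoters
  bound <- truth$bound_genes$factor
  planted <- bound[runif(length(bound)) < cfg$motif_plant_rate]
  fac <- peaksets$factor
  offsets <- numeric(0)
  for (g in planted) {
    i <- match(paste0("pk_", g), fac$name)
    if (is.na(i)) next
    pr <- prom[match(g, prom$gene_id), ]
    peak_center <- (fac$start[i] + fac$end[i]) / 2 - pr$start  # window coords
    off <- round(rnorm(1, 0, cfg$motif_jitter_sd))
    m_start <- round(peak_center + off - w / 2)  # 0-based within window
    m_start <- min(max(m_start, 0), nchar(seqs[[g]]) - w)
    substr(seqs[[g]], m_start + 1, m_start + w) <- cons
    offsets[g] <- (m_start + w / 2) - peak_center
  }
  list(sequences = seqs, offsets = offsets)
}

#' Extract fixed-width scan windows around peak centers
#'
#' For each factor peak assigned to a promoter, the `width` bp of window
#' sequence centered on the peak midpoint, padded with `N` where the scan
#' window runs past the promoter window. Names are gene ids (suffixed when
#' a gene has several peaks).
#'
#' @param sequences Named promoter-window sequences.
#' @param promoters Promoter tibble.
#' @param peaks Peak tibble (screened, assigned coordinates on the same
#'   genome as `promoters`).
#' @param width Scan width in bp (default 600).
#' @return Named character vector of `width`-bp windows.
#' @export
peak_windows <- function(sequences, promoters, peaks, width = 600) {
  asg <- assign_promoters(peaks, promoters)
  if (nrow(asg) == 0) return(setNames(character(0), character(0)))
  half <- width / 2
  prom <- promoters[match(asg$gene_id, promoters$gene_id), , drop = FALSE]
  out <- vapply(seq_len(nrow(asg)), function(i) {
    s <- sequences[[asg$gene_id[i]]]
    center <- round(asg$midpoint[i]) - prom$start[i]
    from <- round(center - half)       # 0-based
    to <- from + width                 # half-open
    lo <- max(from, 0); hi <- min(to, nchar(s))
    core <- substr(s, lo + 1, hi)
    paste0(strrep("N", lo - from), core, strrep("N", to - hi))
  }, character(1))
  nm <- asg$gene_id
  dup <- duplicated(nm)
  nm[dup] <- paste0(nm[dup], "_", cumsum(dup)[dup])
  setNames(out, nm)
}

#' Default PWM library for simulations
#'
#' `n_motifs` sharpish random motifs (consensus base count 70, others 10)
#' of the given width with distinct consensus sequences; the first motif
#' is the one [plant_motifs()] embeds.
#'
#' @param n_motifs Library size (default 20).
#' @param width Motif width (default 10).
#' @param seed Integer seed.
#' @return A list of `pwm` objects.
#' @export
default_pwm_library <- function(n_motifs = 20, width = 10, seed = 1) {
  set.seed(seed + 4L)
  cons <- character(0)
  while (length(cons) < n_motifs) {
    cand <- paste(sample(DNA_BASES, width, replace = TRUE), collapse = "")
    if (!cand %in% cons) cons <- c(cons, cand)
  }
  lapply(seq_len(n_motifs), function(i) {
    b <- match(strsplit(cons[i], "")[[1]], DNA_BASES)
    counts <- matrix(10, nrow = 4, ncol = width, dimnames = list(DNA_BASES))
    counts[cbind(b, seq_len(width))] <- 70
    pwm(counts, motif_id = sprintf("M%02d", i))
  })
}

#' Simulated knockdown expression arrays
#'
#' Log2 intensities: per-gene baseline uniform on 6-12, per-array Gaussian
#' technical noise of SD `noise_sd`, and the planted signed effects (in
#' null-SD units of the tested log-ratio contrast) added to the knockdown
#' array(s) of regulated genes.
#'
#' @inheritParams make_peaksets
#' @return A list with `expr` (tibble: `gene_id` + sample columns) and
#'   `design` (tibble: `sample_id`, `condition`).
#' @export
make_expression <- function(truth, annotation, cfg = sim_config(), seed = 1) {
  set.seed(seed + 5L)
  genes <- annotation$promoters$gene_id
  n <- length(genes)
  nc <- cfg$n_control_arrays; nk <- cfg$n_knockdown_arrays
  samples <- c(paste0("ctl_", seq_len(nc)), paste0("kd_", seq_len(nk)))
  baseline <- runif(n, 6, 12)
  m <- baseline + matrix(rnorm(n * (nc + nk), 0, cfg$noise_sd), nrow = n)
  colnames(m) <- samples
  sigma_contrast <- cfg$noise_sd * sqrt(1 / nk + 1 / nc)
  eff <- setNames(rep(0, n), genes)
  eff[names(truth$regulated_genes)] <- truth$regulated_genes
  kd_cols <- grep("^kd_", samples)
  m[, kd_cols] <- m[, kd_cols] + eff * sigma_contrast
  expr <- dplyr::bind_cols(tibble(gene_id = genes), as_tibble(m))
  design <- tibble(sample_id = samples,
                   condition = rep(c("control", "knockdown"), c(nc, nk)))
  list(expr = expr, design = design)
}

#' Simulated tumor Z-score matrix
#'
#' Standard-normal background; in latently active tumors the anchor gene
#' is shifted by `coexp_shift`, and each direct-target gene responds per
#' active tumor with probability `coexp_penetrance`.
#'
#' @inheritParams make_peaksets
#' @return Numeric matrix, genes (plus the anchor row) x tumors.
#' @export
make_zscores <- function(truth, annotation, cfg = sim_config(), seed = 1) {
  set.seed(seed + 6L)
  genes <- c(cfg$anchor_id, annotation$promoters$gene_id)
  nt <- cfg$n_tumors
  z <- matrix(rnorm(length(genes) * nt), nrow = length(genes),
              dimnames = list(genes, sprintf("T%03d", seq_len(nt))))
  active <- truth$coexp_active_tumors
  z[cfg$anchor_id, active] <- z[cfg$anchor_id, active] + cfg$coexp_shift
  tg <- intersect(truth$direct_targets, genes)
  if (length(tg) > 0 && length(active) > 0) {
    resp <- matrix(runif(length(tg) * length(active)) < cfg$coexp_penetrance,
                   nrow = length(tg))
    z[tg, active] <- z[tg, active] + cfg$coexp_shift * resp
  }
  z
}

#' Generate a complete synthetic study
#'
#' Runs every generator with sub-seeds derived from `seed`: annotation and
#' sequences, ground truth, peak sets (factor, IgG, polymerase, histone
#' marks), planted motifs, knockdown expression arrays and the tumor
#' Z-score cohort, plus the default PWM library whose first motif is the
#' planted one.
#'
#' @inheritParams make_annotation
#' @return A named list: `config`, `truth`, `promoters`, `sequences`
#'   (motifs planted), `motif_offsets`, `peaks`, `expr`, `design`,
#'   `zscores`, `pwm_library`.
#' @export
simulate_regulome <- function(cfg = sim_config(), seed = 1) {
  ann <- make_annotation(cfg, seed)
  truth <- make_truth(ann, cfg, seed)
  peaks <- make_peaksets(truth, ann, cfg, seed)
  lib <- default_pwm_library(seed = seed)
  pl <- plant_motifs(truth, ann, peaks, lib[[1]], cfg, seed)
  ex <- make_expression(truth, ann, cfg, seed)
  z <- make_zscores(truth, ann, cfg, seed)
  list(config = cfg, truth = truth, promoters = ann$promoters,
       sequences = pl$sequences, motif_offsets = pl$offsets,
       peaks = peaks, expr = ex$expr, design = ex$design,
       zscores = z, pwm_library = lib)
}
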