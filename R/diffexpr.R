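#' Per-gene log2 fold change between conditions
#'
#' Computes, per gene, `log2(mean knockdown / mean control)` with the means
#' taken on the linear intensity scale (stored values are log2
#' intensities, the usual form for normalized bead-array data). Genes with
#' a missing value in any required sample are dropped; their ids are
#' attached as the `"dropped_genes"` attribute.
#'
#' @param expr Expression tibble: a `gene_id` column plus one numeric
#'   column per sample (log2 intensities).
#' @param design Tibble with `sample_id` and `condition`
#'   (`"control"` / `"knockdown"`), one row per sample column of `expr`.
#' @return A tibble with `gene_id` and `lfc`.
#' @export
compute_lfc <- function(expr, design) {
  d <- check_design(expr, design)
  if (length(d$kd) < 1 || length(d$ctl) < 1) {
    abort("need at least one knockdown and one control sample")
  }
  vals <- as.matrix(expr[, c(d$ctl, d$kd), drop = FALSE])
  keep <- stats::complete.cases(vals)
  dropped <- expr$gene_id[!keep]
  vals <- vals[keep, , drop = FALSE]
  lin <- 2^vals
  m_ctl <- rowMeans(lin[, d$ctl, drop = FALSE])
  m_kd <- rowMeans(lin[, d$kd, drop = FALSE])
  if (any(m_ctl <= 0) || any(m_kd <= 0)) abort("nonpositive mean intensity")
  out <- tibble(gene_id = expr$gene_id[keep], lfc = log2(m_kd / m_ctl))
  attr(out, "dropped_genes") <- dropped
  out
}

#' Estimate the normal null of the log-ratio statistic from control arrays
#'
#' With a single array per condition the log fold change has no
#' within-condition replication; its null distribution is instead taken as
#' normal with mean and standard deviation estimated from the control
#' arrays. All ordered pairs of distinct control arrays are formed, their
#' per-gene log2 ratios pooled across genes, and the pooled mean and SD
#' returned. Pooling both orders of each pair makes the mean estimate
#' essentially zero by construction; the SD measures the technical noise
#' of a single-array-versus-single-array ratio.
#'
#' @inheritParams compute_lfc
#' @return An object of class `de_null` with fields `mu`, `sigma`,
#'   `n_genes_used`, `n_pairs` and `degenerate` (sigma indistinguishable
#'   from zero).
#' @export
estimate_null <- function(expr, design) {
  d <- check_design(expr, design)
  if (length(d$ctl) < 2) {
    abort("the null cannot be estimated: need >= 2 control arrays")
  }
  vals <- as.matrix(expr[, d$ctl, drop = FALSE])
  keep <- stats::complete.cases(vals)
  vals <- vals[keep, , drop = FALSE]
  pairs <- expand.grid(i = seq_along(d$ctl), j = seq_along(d$ctl))
  pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
  ratios <- unlist(Map(function(i, j) vals[, i] - vals[, j],
                       pairs$i, pairs$j), use.names = FALSE)
  sigma <- sd(ratios)
  structure(
    list(mu = mean(ratios), sigma = sigma, n_genes_used = sum(keep),
         n_pairs = nrow(pairs), degenerate = !is.finite(sigma) || sigma < 1e-8),
    class = "de_null"
  )
}

#' @export
print.de_null <- function(x, ...) {
  cat(sprintf(
    "<de_null> mu = %.4g, sigma = %.4g (%d genes, %d ordered control pairs)%s\n",
    x$mu, x$sigma, x$n_genes_used, x$n_pairs,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
#' @exportS3Method generics::glance
glance.de_null <- function(x, ...) {
  tibble(mu = x$mu, sigma = x$sigma, n_genes_used = x$n_genes_used,
         n_pairs = x$n_pairs, degenerate = x$degenerate)
}

#' Significance test of per-gene log fold changes against a normal null
#'
#' Two-sided p-values from the normal null, Benjamini-Hochberg adjustment,
#' and classification into `down` / `up` / `unchanged`: a gene is `down`
#' when its adjusted FDR is below `fdr_cutoff` and its log fold change
#' lies below the null mean, `up` when above, otherwise `unchanged`.
#'
#' `contrast_scale` rescales the pair-based null SD to the contrast
#' actually tested: a ratio of the mean of `n_k` knockdown to the mean of
#' `n_c` control arrays has SD `sigma_array * sqrt(1/n_k + 1/n_c)`, while
#' the control-pair estimate measures `sigma_array * sqrt(2)`; the matching
#' factor is `sqrt((1/n_k + 1/n_c) / 2)`. [run_de()] supplies it
#' automatically; `contrast_scale = 1` reproduces the unscaled recipe.
#'
#' @param lfc Tibble from [compute_lfc()] (`gene_id`, `lfc`).
#' @param null A `de_null` from [estimate_null()].
#' @param fdr_cutoff FDR threshold for the regulation call (default 0.01).
#' @param contrast_scale Multiplier applied to `null$sigma` (default 1).
#' @return A tibble with `gene_id`, `lfc`, `z`, `p_value`, `fdr`,
#'   `reg_class`.
#' @export
de_test <- function(lfc, null, fdr_cutoff = 0.01, contrast_scale = 1) {
  stopifnot(is(null, "de_null"))
  if (null$degenerate) abort("degenerate null model (sigma ~ 0)")
  if (fdr_cutoff <= 0 || fdr_cutoff >= 1) abort("`fdr_cutoff` must be in (0, 1)")
  sigma <- null$sigma * contrast_scale
  z <- (lfc$lfc - null$mu) / sigma
  p <- normal_two_sided_p(lfc$lfc, null$mu, sigma)
  fdr <- bh_adjust(p)
  cls <- dplyr::case_when(
    fdr < fdr_cutoff & lfc$lfc < null$mu ~ "down",
    fdr < fdr_cutoff & lfc$lfc > null$mu ~ "up",
    .default = "unchanged"
  )
  tibble(gene_id = lfc$gene_id, lfc = lfc$lfc, z = z,
         p_value = p, fdr = fdr, reg_class = cls)
}

#' Run the single-array differential-expression stage end to end
#'
#' [compute_lfc()], [estimate_null()] and [de_test()] chained, with the
#' null SD matched to the tested contrast (see [de_test()]) unless
#' `scale_to_contrast = FALSE`.
#'
#' @inheritParams compute_lfc
#' @inheritParams de_test
#' @param scale_to_contrast Match the null SD to the number of arrays in
#'   the tested ratio (default `TRUE`).
#' @return The [de_test()] result tibble.
#' @export
run_de <- function(expr, design, fdr_cutoff = 0.01, scale_to_contrast = TRUE) {
  d <- check_design(expr, design)
  lfc <- compute_lfc(expr, design)
  null <- estimate_null(expr, design)
  scale <- if (scale_to_contrast) {
    sqrt((1 / length(d$kd) + 1 / length(d$ctl)) / 2)
  } else 1
  de_test(lfc, null, fdr_cutoff = fdr_cutoff, contrast_scale = scale)
}

#' Genes called significantly regulated
#'
#' @param de A [de_test()] result tibble.
#' @param direction `"both"` (default), `"down"` or `"up"`.
#' @return Character vector of gene ids.
#' @export
de_genes <- function(de, direction = c("both", "down", "up")) {
  direction <- match.arg(direction)
  keep <- if (direction == "both") de$reg_class != "unchanged"
          else de$reg_class == direction
  de$gene_id[keep]
}

# ---- internal ----

check_design <- function(expr, design) {
  if (!"gene_id" %in% names(expr)) abort("`expr` must have a `gene_id` column")
  if (anyDuplicated(expr$gene_id)) abort("duplicate `gene_id` in `expr`")
  need <- c("sample_id", "condition")
  if (!all(need %in% names(design))) {
    abort("`design` must have columns `sample_id` and `condition`")
  }
  if (!all(design$condition %in% c("control", "knockdown"))) {
    abort("`condition` must be \"control\" or \"knockdown\"")
  }
  missing <- setdiff(design$sample_id, names(expr))
  if (length(missing) > 0) {
    abort(paste0("samples absent from `expr`: ", paste(missing, collapse = ", ")))
  }
  list(
    ctl = design$sample_id[design$condition == "control"],
    kd = design$sample_id[design$condition == "knockdown"]
  )
}
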