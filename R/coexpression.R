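#' Binarize a tumor Z-score matrix at the over-expression threshold
#'
#' An entry is called over-expressed when its Z-score strictly exceeds the
#' threshold; the default 1.65 marks roughly the top 5% of a standard
#' normal. Ties at the threshold are not over-expressed.
#'
#' @param z Numeric matrix, genes in rows (rownames = gene ids), tumors in
#'   columns; or a tibble with a `gene_id` column and one numeric column
#'   per tumor.
#' @param threshold Over-expression threshold (default 1.65).
#' @return A logical matrix of the same shape, dimnames preserved.
#' @export
binarize_zscores <- function(z, threshold = 1.65) {
  if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold)) {
    abort("`threshold` must be a single finite number")
  }
  z <- as_z_matrix(z)
  z > threshold
}

#' Co-upregulation test of one gene against the anchor gene
#'
#' Forms the 2x2 table over tumors — `a` both over-expressed, `b` anchor
#' only, `c` gene only, `d` neither — and reports the odds ratio
#' ([odds_ratio()], Haldane-corrected at zero cells) with a one-sided
#' Fisher p-value ([fisher_one_sided()]). `co_up` flags an odds ratio
#' above `or_threshold`; `significant` flags `p < alpha`.
#'
#' @param anchor,gene Logical vectors over the same tumors.
#' @param or_threshold Odds-ratio cutoff for the co-upregulation tendency
#'   (default 1.5).
#' @param alpha Significance cutoff (default 0.05).
#' @return A one-row tibble: `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `or_corrected`, `p_value`, `co_up`, `significant`.
#' @export
co_up_test <- function(anchor, gene, or_threshold = 1.5, alpha = 0.05) {
  if (length(anchor) != length(gene)) {
    abort("`anchor` and `gene` must cover the same tumors")
  }
  a <- sum(anchor & gene); b <- sum(anchor & !gene)
  c <- sum(!anchor & gene); d <- sum(!anchor & !gene)
  or <- odds_ratio(a, b, c, d)
  p <- fisher_one_sided(a, b, c, d)
  tibble(
    a = a, b = b, c = c, d = d,
    odds_ratio = or$estimate, or_corrected = or$corrected, p_value = p,
    co_up = or$estimate > or_threshold, significant = p < alpha
  )
}

#' Score a target gene set for co-upregulation with an anchor gene
#'
#' Every gene in the matrix (except the anchor) is tested for
#' co-upregulation with the anchor across tumors; a gene is a *hit* when
#' both its odds ratio exceeds `or_threshold` and its one-sided Fisher p
#' is below `alpha`. The hit rate within the target set is then compared
#' with the background rate by a Pearson chi-square test
#' ([chisq_2x2()]). The background is the non-target remainder by default
#' (`"disjoint"`); `"all"` uses every tested gene, matching a reading in
#' which the target set is compared against the genome-wide rate.
#'
#' @param z Z-score matrix (see [binarize_zscores()]).
#' @param anchor_gene Gene id of the anchor (must be a row of `z`).
#' @param target_genes Character vector of target gene ids (non-empty;
#'   the anchor is excluded if present).
#' @param z_threshold Over-expression threshold (default 1.65).
#' @param or_threshold Odds-ratio cutoff (default 1.5).
#' @param alpha Per-gene significance cutoff (default 0.05).
#' @param background `"disjoint"` (default) or `"all"`.
#' @param chisq_correct Yates correction for the set-level chi-square
#'   (default `FALSE`).
#' @return An object of class `coexp_screen`; see [tidy.coexp_screen()]
#'   and [glance.coexp_screen()].
#' @export
score_target_set <- function(z, anchor_gene, target_genes,
                             z_threshold = 1.65, or_threshold = 1.5,
                             alpha = 0.05,
                             background = c("disjoint", "all"),
                             chisq_correct = FALSE) {
  background <- match.arg(background)
  z <- as_z_matrix(z)
  anchor_gene <- normalize_gene_ids(anchor_gene)
  rownames(z) <- normalize_gene_ids(rownames(z))
  target_genes <- setdiff(unique(normalize_gene_ids(target_genes)), anchor_gene)
  if (!anchor_gene %in% rownames(z)) abort("anchor gene missing from matrix")
  if (length(target_genes) == 0) abort("empty target gene set")
  missing <- setdiff(target_genes, rownames(z))
  if (length(missing) > 0) {
    warn(paste0(length(missing), " target gene(s) absent from the matrix ",
                "were dropped"))
    target_genes <- setdiff(target_genes, missing)
    if (length(target_genes) == 0) abort("no target genes left in the matrix")
  }
  over <- binarize_zscores(z, z_threshold)
  anchor <- over[anchor_gene, ]
  genes <- setdiff(rownames(z), anchor_gene)
  og <- over[genes, , drop = FALSE]
  a <- as.vector(og %*% anchor)
  b <- sum(anchor) - a
  c <- rowSums(og) - a
  d <- length(anchor) - a - b - c
  or <- odds_ratio(a, b, c, d)
  p <- fisher_one_sided(a, b, c, d)
  res <- tibble(
    gene_id = genes, is_target = genes %in% target_genes,
    a = a, b = b, c = unname(c), d = unname(d),
    odds_ratio = or$estimate, or_corrected = or$corrected, p_value = p,
    co_up = or$estimate > or_threshold, significant = p < alpha
  )
  res$hit <- res$co_up & res$significant
  res <- dplyr::arrange(res, .data$p_value, .data$gene_id)

  tg <- res[res$is_target, ]
  bg <- if (background == "disjoint") res[!res$is_target, ] else res
  report <- list(
    target_tested = nrow(tg), target_hits = sum(tg$hit),
    background_tested = nrow(bg), background_hits = sum(bg$hit),
    target_hit_pct = co_up_rate_pct(sum(tg$hit), nrow(tg)),
    background_hit_pct = co_up_rate_pct(sum(bg$hit), nrow(bg)),
    background = background
  )
  if (background == "disjoint") {
    ct <- chisq_2x2(report$target_hits,
                    report$target_tested - report$target_hits,
                    report$background_hits,
                    report$background_tested - report$background_hits,
                    correct = chisq_correct)
  } else {
    ct <- chisq_2x2(report$target_hits,
                    report$target_tested - report$target_hits,
                    report$background_hits - report$target_hits,
                    (report$background_tested - report$background_hits) -
                      (report$target_tested - report$target_hits),
                    correct = chisq_correct)
  }
  report$chi2 <- ct$statistic
  report$p_value <- ct$p_value
  structure(
    list(results = res, report = report, anchor = anchor_gene,
         thresholds = list(z = z_threshold, or = or_threshold, alpha = alpha)),
    class = "coexp_screen"
  )
}

#' Hit percentage, formatted to one decimal
#'
#' The report formatter behind the screen summaries: `100 * hits / tested`
#' rounded to one decimal place (so 18 of 137 reads 13.1 and 873 of
#' 11,201 reads 7.8).
#'
#' @param hits,tested Counts.
#' @return Numeric percentage rounded to one decimal.
#' @export
co_up_rate_pct <- function(hits, tested) {
  if (any(tested <= 0)) abort("`tested` must be positive")
  round(100 * hits / tested, 1)
}

#' @export
print.coexp_screen <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0("<coexp_screen> anchor %s: %d/%d targets hit (%.1f%%) vs ",
           "%d/%d background (%.1f%%); chi2 = %.3g, p = %.3g\n"),
    x$anchor, r$target_hits, r$target_tested, r$target_hit_pct,
    r$background_hits, r$background_tested, r$background_hit_pct,
    r$chi2, r$p_value))
  invisible(x)
}

#' Per-gene co-upregulation results of a screen
#'
#' @param x A `coexp_screen`.
#' @param ... Unused.
#' @return The per-gene results tibble, ordered by p-value.
#' @export
#' @exportS3Method generics::tidy
tidy.coexp_screen <- function(x, ...) x$results

#' One-row summary of a co-upregulation screen
#'
#' @param x A `coexp_screen`.
#' @param ... Unused.
#' @return A one-row tibble with hit counts, formatted hit percentages,
#'   and the set-level chi-square statistic and p-value.
#' @export
#' @exportS3Method generics::glance
glance.coexp_screen <- function(x, ...) {
  as_tibble(x$report[c("target_tested", "target_hits", "target_hit_pct",
                       "background_tested", "background_hits",
                       "background_hit_pct", "chi2", "p_value",
                       "background")])
}

# ---- internal ----

as_z_matrix <- function(z) {
  if (is.matrix(z)) {
    if (is.null(rownames(z))) abort("Z matrix must have gene rownames")
    storage.mode(z) <- "double"
    return(z)
  }
  if (is.data.frame(z)) {
    if (!"gene_id" %in% names(z)) abort("Z tibble must have a `gene_id` column")
    if (anyDuplicated(z$gene_id)) abort("duplicate `gene_id` in Z matrix")
    m <- as.matrix(z[, setdiff(names(z), "gene_id"), drop = FALSE])
    rownames(m) <- z$gene_id
    return(m)
  }
  abort("`z` must be a matrix or a tibble")
}
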