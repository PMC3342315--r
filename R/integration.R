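#' Canonicalize gene identifiers
#'
#' Upper-cases and whitespace-strips gene symbols so sets from different
#' platforms intersect on a shared namespace.
#'
#' @param x Character vector of gene ids.
#' @return Canonicalized character vector.
#' @export
normalize_gene_ids <- function(x) {
  toupper(stringr::str_trim(x))
}

#' Pairwise co-occurrence significance of gene sets
#'
#' For every unordered pair of sets, the probability of obtaining at least
#' the observed number of shared genes by randomly sampling sets of the
#' same sizes from a common universe ([hyper_upper_tail()]). The binding
#' universe defaults to 18,511 genes when used through the pipeline
#' configuration; here it is explicit.
#'
#' @param sets Named list of character vectors (gene ids).
#' @param universe Universe size shared by all sets.
#' @return A tibble of class `cooccurrence`: `set_a`, `set_b`, `size_a`,
#'   `size_b`, `overlap`, `p_value` (one row per unordered pair).
#' @export
cooccurrence <- function(sets, universe) {
  if (length(sets) < 2) abort("need at least two gene sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a named list")
  }
  sets <- lapply(sets, function(g) unique(normalize_gene_ids(g)))
  sizes <- lengths(sets)
  if (any(sizes > universe)) abort("a set is larger than the universe")
  idx <- utils::combn(length(sets), 2)
  out <- purrr::map(seq_len(ncol(idx)), function(c0) {
    i <- idx[1, c0]; j <- idx[2, c0]
    k <- length(intersect(sets[[i]], sets[[j]]))
    tibble(
      set_a = names(sets)[i], set_b = names(sets)[j],
      size_a = sizes[[i]], size_b = sizes[[j]], overlap = k,
      p_value = hyper_upper_tail(k, sizes[[i]], sizes[[j]], universe)
    )
  })
  out <- purrr::list_rbind(out)
  class(out) <- c("cooccurrence", class(out))
  out
}

#' Symmetric p-value matrix of a co-occurrence result
#'
#' @param x A [cooccurrence()] tibble.
#' @return A symmetric matrix of p-values with `NA` on the diagonal.
#' @export
cooccurrence_pmatrix <- function(x) {
  labs <- unique(c(x$set_a, x$set_b))
  m <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(labs, labs))
  for (r in seq_len(nrow(x))) {
    m[x$set_a[r], x$set_b[r]] <- x$p_value[r]
    m[x$set_b[r], x$set_a[r]] <- x$p_value[r]
  }
  m
}

#' Direct targets: bound and transcriptionally dependent
#'
#' The intersection of the promoter-binding gene set with the genes called
#' significantly regulated (either direction) by the knockdown
#' differential-expression stage — the candidate direct target genes.
#'
#' @param chip_genes Character vector of bound gene ids.
#' @param de A [de_test()] result tibble.
#' @return Character vector of direct-target gene ids.
#' @export
direct_targets <- function(chip_genes, de) {
  chip <- unique(normalize_gene_ids(chip_genes))
  sig <- normalize_gene_ids(de_genes(de, "both"))
  intersect(chip, sig)
}

#' Enrichment of bound genes within regulation classes
#'
#' For each regulation class (`down`, `up`, `unchanged`), the
#' hypergeometric upper-tail probability of the observed overlap between
#' the bound gene set and the class, given the class size, the bound-set
#' size and the universe. Reproduces the down/up/unchanged enrichment
#' panel of an integrative binding-plus-knockdown analysis.
#'
#' @inheritParams direct_targets
#' @param universe Universe size (number of genes on the platform).
#' @return A tibble with `reg_class`, `n_class`, `n_chip`, `overlap`,
#'   `p_value`.
#' @export
category_enrichment <- function(chip_genes, de, universe) {
  chip <- unique(normalize_gene_ids(chip_genes))
  de_ids <- normalize_gene_ids(de$gene_id)
  K <- length(chip)
  purrr::map(c("down", "up", "unchanged"), function(cls) {
    cls_genes <- de_ids[de$reg_class == cls]
    n <- length(cls_genes)
    k <- length(intersect(chip, cls_genes))
    p <- if (n == 0) 1 else hyper_upper_tail(k, K, n, universe)
    tibble(reg_class = cls, n_class = n, n_chip = K, overlap = k, p_value = p)
  }) %>% purrr::list_rbind()
}

#' Chromatin-mark overlay of a target gene set
#'
#' For each mark's gene set, the count and fraction of target genes whose
#' promoters carry the mark (e.g. the fractions of direct-target promoters
#' with the active H3K4me3 versus the repressive H3K27me3 mark).
#'
#' @param targets Character vector of target gene ids.
#' @param marks Named list of character vectors, one gene set per mark.
#' @return A tibble with `mark`, `target_count`, `count`, `fraction`.
#' @export
histone_overlay <- function(targets, marks) {
  targets <- unique(normalize_gene_ids(targets))
  if (is.null(names(marks)) || any(names(marks) == "")) {
    abort("`marks` must be a named list")
  }
  purrr::imap(marks, function(g, nm) {
    k <- length(intersect(targets, unique(normalize_gene_ids(g))))
    tibble(mark = nm, target_count = length(targets), count = k,
           fraction = if (length(targets) == 0) NA_real_
                      else k / length(targets))
  }) %>% purrr::list_rbind()
}
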