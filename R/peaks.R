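#' Screen scored peaks by peak-level FDR
#'
#' Retains exactly the peaks whose vendor-assigned false-discovery score is
#' at or below `max_fdr` (the boundary is inclusive), preserving input
#' order. The default 0.2 is the screening threshold used for promoter
#' ChIP-chip peak lists.
#'
#' @param peaks A peak tibble with at least `chrom`, `start`, `end`, `fdr`
#'   (0-based half-open coordinates, BED convention).
#' @param max_fdr Maximum peak FDR to retain, in `[0, 1]`.
#' @return The filtered peak tibble.
#' @export
filter_peaks <- function(peaks, max_fdr = 0.2) {
  check_peaks(peaks)
  if (!is.numeric(max_fdr) || length(max_fdr) != 1 ||
      is.na(max_fdr) || max_fdr < 0 || max_fdr > 1) {
    abort("`max_fdr` must be a single probability")
  }
  dplyr::filter(peaks, .data$fdr <= max_fdr)
}

#' Remove peaks overlapping a control peak set
#'
#' Discards every target peak sharing at least one base with any control
#' (e.g. non-specific IgG) peak; the remainder is considered positive for
#' specific binding. Coordinates are 0-based half-open, so an interval
#' ending where another starts does not overlap.
#'
#' @param peaks Target peak tibble.
#' @param control Control peak tibble (same coordinate convention).
#' @return Target peaks with zero-overlap against every control peak,
#'   order preserved.
#' @export
subtract_control <- function(peaks, control) {
  check_peaks(peaks)
  check_peaks(control)
  if (nrow(control) == 0 || nrow(peaks) == 0) return(peaks)
  lv <- union(unique(peaks$chrom), unique(control$chrom))
  hits <- GenomicRanges::findOverlaps(
    peaks_to_granges(peaks, lv), peaks_to_granges(control, lv),
    minoverlap = 1L
  )
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop) == 0) peaks else peaks[-drop, , drop = FALSE]
}

#' Assign peaks to overlapping promoter windows
#'
#' A peak is assigned to every promoter window it overlaps by at least one
#' base; a peak spanning two windows is counted in both. The distinct
#' `gene_id` values of the result are the binding target gene set. Each row
#' also carries the peak midpoint's strand-corrected offset from the TSS
#' (negative = upstream), the coordinate used by [tss_histogram()].
#'
#' @param peaks Peak tibble (typically already FDR-screened and
#'   control-subtracted).
#' @param promoters Promoter tibble with `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `tss` (see [read_promoters()]).
#' @return A tibble with one row per (peak, promoter) overlap: `gene_id`,
#'   the peak columns, `midpoint` and `tss_offset`.
#' @export
assign_promoters <- function(peaks, promoters) {
  check_peaks(peaks)
  check_promoters(promoters)
  if (anyDuplicated(promoters$gene_id)) {
    abort("duplicate `gene_id` in promoter annotation")
  }
  if (nrow(peaks) == 0) {
    return(tibble(
      gene_id = character(), chrom = character(),
      start = integer(), end = integer(), fdr = double(),
      midpoint = double(), tss_offset = double()
    ))
  }
  lv <- union(unique(peaks$chrom), unique(promoters$chrom))
  hits <- GenomicRanges::findOverlaps(
    peaks_to_granges(peaks, lv), promoters_to_granges(promoters, lv),
    minoverlap = 1L
  )
  pk <- peaks[S4Vectors::queryHits(hits), , drop = FALSE]
  pr <- promoters[S4Vectors::subjectHits(hits), , drop = FALSE]
  midpoint <- (pk$start + pk$end) / 2
  offset <- ifelse(pr$strand == "+", midpoint - pr$tss, pr$tss - midpoint)
  dplyr::bind_cols(
    tibble(gene_id = pr$gene_id),
    pk[, intersect(c("chrom", "start", "end", "name", "score", "fdr"),
                   names(pk)), drop = FALSE],
    tibble(midpoint = midpoint, tss_offset = offset)
  )
}

#' Gene set bound by a factor, from a peak-to-promoter assignment
#'
#' @param assignment Output of [assign_promoters()].
#' @return Character vector of unique bound gene ids.
#' @export
bound_genes <- function(assignment) {
  unique(assignment$gene_id)
}

#' TSS-relative binding-position histogram
#'
#' Bins the strand-corrected peak-midpoint offsets of a peak-to-promoter
#' assignment into fixed-width bins whose edges are aligned to multiples of
#' `bin_width` (so offset 0 starts a bin). Every assigned peak event
#' contributes exactly one count.
#'
#' @param assignment Output of [assign_promoters()].
#' @param bin_width Bin width in bp (default 100).
#' @return A tibble of class `binding_histogram` with `bin_start`,
#'   `bin_end`, `bin_mid`, `count`.
#' @export
tss_histogram <- function(assignment, bin_width = 100) {
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0) {
    abort("`bin_width` must be a positive number")
  }
  offs <- assignment$tss_offset
  if (length(offs) == 0) {
    out <- tibble(bin_start = double(), bin_end = double(),
                  bin_mid = double(), count = integer())
    class(out) <- c("binding_histogram", class(out))
    return(out)
  }
  lo <- floor(min(offs) / bin_width) * bin_width
  hi <- ceiling((max(offs) + 1e-9) / bin_width) * bin_width
  if (hi == lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  idx <- findInterval(offs, edges, rightmost.closed = FALSE, left.open = FALSE)
  cnt <- tabulate(idx, nbins = length(edges) - 1)
  out <- tibble(
    bin_start = edges[-length(edges)],
    bin_end = edges[-1],
    bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
    count = as.integer(cnt)
  )
  class(out) <- c("binding_histogram", class(out))
  out
}

# ---- internal ----

check_peaks <- function(peaks) {
  need <- c("chrom", "start", "end", "fdr")
  if (!all(need %in% names(peaks))) {
    abort(paste0("peak table must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(peaks$start >= peaks$end)) abort("peak `start` must be < `end`")
  if (any(peaks$fdr < 0 | peaks$fdr > 1)) abort("peak `fdr` must lie in [0, 1]")
  invisible(TRUE)
}

check_promoters <- function(promoters) {
  need <- c("gene_id", "chrom", "start", "end", "strand", "tss")
  if (!all(need %in% names(promoters))) {
    abort(paste0("promoter table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  if (!all(promoters$strand %in% c("+", "-"))) {
    abort("promoter `strand` must be \"+\" or \"-\"")
  }
  bad <- promoters$tss < promoters$start | promoters$tss >= promoters$end
  if (any(bad)) abort("promoter `tss` must lie within [start, end)")
  invisible(TRUE)
}

# BED 0-based half-open -> GRanges 1-based closed; a shared seqlevels set
# keeps findOverlaps quiet when the two sides name different chromosomes
peaks_to_granges <- function(peaks, seqlevels = unique(peaks$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(peaks$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}

promoters_to_granges <- function(promoters,
                                 seqlevels = unique(promoters$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(promoters$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = promoters$start + 1L,
                              end = promoters$end)
  )
}
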