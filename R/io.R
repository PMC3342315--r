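#' Read a scored peak list (BED6+1)
#'
#' Tab-separated, headerless BED dialect with one extra column: `chrom`,
#' `start`, `end`, `name`, `score`, `strand`, `fdr`. Coordinates are
#' 0-based half-open.
#'
#' @param path File path.
#' @return A peak tibble.
#' @export
read_peaks <- function(path) {
  out <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand", "fdr"),
    col_types = "ciicdcd", progress = FALSE
  )
  check_peaks(out)
  out
}

#' @rdname read_peaks
#' @param peaks Peak tibble to write.
#' @export
write_peaks <- function(peaks, path) {
  check_peaks(peaks)
  cols <- c("chrom", "start", "end", "name", "score", "strand", "fdr")
  miss <- setdiff(cols, names(peaks))
  for (m in miss) peaks[[m]] <- if (m == "score") 0 else "."
  readr::write_tsv(peaks[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a promoter annotation (BED6)
#'
#' Headerless BED6 with the gene id in the `name` column. The TSS is
#' derived from the strand and the window extent: `start + upstream` for
#' `+` genes, `start + downstream` for `-` genes (whose window runs
#' `tss - downstream` to `tss + upstream`).
#'
#' @param path File path.
#' @param upstream,downstream Window extent around the TSS, bp (defaults
#'   2,200 and 500, a RefSeq-style promoter tiling).
#' @return A promoter tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`).
#' @export
read_promoters <- function(path, upstream = 2200, downstream = 500) {
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "gene_id", "score", "strand"),
    col_types = "ciicdc", progress = FALSE
  )
  out <- tibble(
    gene_id = raw$gene_id, chrom = raw$chrom, start = raw$start,
    end = raw$end, strand = raw$strand,
    tss = ifelse(raw$strand == "+", raw$start + upstream,
                 raw$start + downstream)
  )
  check_promoters(out)
  out
}

#' @rdname read_promoters
#' @param promoters Promoter tibble to write.
#' @export
write_promoters <- function(promoters, path) {
  check_promoters(promoters)
  bed <- tibble(
    chrom = promoters$chrom, start = promoters$start, end = promoters$end,
    name = promoters$gene_id, score = 0, strand = promoters$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read / write an expression matrix (TSV, genes x samples)
#'
#' Header row of sample ids after a leading `gene_id` column; values are
#' log2 intensities.
#'
#' @param path File path.
#' @return A tibble with `gene_id` plus one numeric column per sample.
#' @export
read_expression <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}

#' @rdname read_expression
#' @param expr Expression tibble to write.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Read / write a sample condition map (TSV)
#'
#' Two columns: `sample_id`, `condition` (`control` / `knockdown`).
#'
#' @param path File path.
#' @return A design tibble.
#' @export
read_design <- function(path) {
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}

#' @rdname read_design
#' @param design Design tibble to write.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path, progress = FALSE)
  invisible(path)
}

#' Read / write a tumor Z-score matrix (TSV)
#'
#' Genes in rows (leading `gene_id` column), tumors in columns.
#'
#' @param path File path.
#' @return A numeric matrix with gene rownames.
#' @export
read_zscores <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  as_z_matrix(tb)
}

#' @rdname read_zscores
#' @param z Matrix (gene rownames) to write.
#' @export
write_zscores <- function(z, path) {
  z <- as_z_matrix(z)
  tb <- dplyr::bind_cols(tibble(gene_id = rownames(z)), as_tibble(z))
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}

#' Read / write sequence windows as FASTA
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a TRANSFAC-style motif library
#'
#' Accepts the minimal dialect: an `ID <name>` line, a `P0 A C G T` header,
#' numbered count rows (`01 12 0 3 5 R`), `XX` separators and `//` record
#' terminators. Several records per file are allowed.
#'
#' @param path File path.
#' @param background,pseudocount Passed to [pwm()].
#' @return A list of `pwm` objects.
#' @export
read_transfac <- function(path, background = rep(0.25, 4), pseudocount = 1) {
  lines <- readLines(path)
  out <- list()
  id <- NULL
  rows <- list()
  flush <- function() {
    if (is.null(id)) return()
    if (length(rows) == 0) abort(paste0("TRANSFAC record ", id, " has no rows"))
    counts <- t(do.call(rbind, rows))
    out[[length(out) + 1]] <<- pwm(counts, motif_id = id,
                                   background = background,
                                   pseudocount = pseudocount)
    id <<- NULL; rows <<- list()
  }
  for (ln in lines) {
    ln <- stringr::str_trim(ln)
    if (ln == "" || ln == "XX") next
    if (ln == "//") { flush(); next }
    f <- strsplit(ln, "\\s+")[[1]]
    if (f[1] == "ID") { id <- f[2]; next }
    if (f[1] == "P0" || f[1] == "PO") next
    if (grepl("^[0-9]+$", f[1])) {
      if (length(f) < 5) abort("malformed TRANSFAC count row")
      rows[[length(rows) + 1]] <- as.numeric(f[2:5])
    }
  }
  flush()
  if (length(out) == 0) abort("no TRANSFAC records found")
  out
}

#' Read a plain 4-column position frequency matrix (TSV)
#'
#' One position per row; header `A C G T`. One motif per file.
#'
#' @param path File path.
#' @param motif_id Identifier (defaults to the file name).
#' @param background,pseudocount Passed to [pwm()].
#' @return A `pwm` object.
#' @export
read_pfm_tsv <- function(path, motif_id = NULL,
                         background = rep(0.25, 4), pseudocount = 1) {
  tb <- readr::read_tsv(path, col_types = "dddd", progress = FALSE)
  if (!identical(toupper(names(tb)), DNA_BASES)) {
    abort("PFM TSV must have header columns A, C, G, T")
  }
  if (is.null(motif_id)) {
    motif_id <- sub("\\.[^.]*$", "", basename(path))
  }
  pwm(t(as.matrix(tb)), motif_id = motif_id,
      background = background, pseudocount = pseudocount)
}

#' Write a TRANSFAC-style motif library
#'
#' @param library List of `pwm` objects.
#' @param path File path.
#' @export
write_transfac <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in library) {
    writeLines(c(paste("ID", m$motif_id), "P0\tA\tC\tG\tT"), con)
    for (j in seq_len(pwm_width(m))) {
      cons <- DNA_BASES[which.max(m$counts[, j])]
      writeLines(paste(c(sprintf("%02d", j), m$counts[, j], cons),
                       collapse = "\t"), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' Serialize / restore a simulation ground-truth record (JSON)
#'
#' @param truth A `sim_truth`.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(is(truth, "sim_truth"))
  obj <- unclass(truth)
  # named effect vector as a JSON object, so gene names survive the trip
  obj$regulated_genes <- as.list(obj$regulated_genes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$bound_genes <- lapply(x$bound_genes, as.character)
  x$artifact_genes <- as.character(x$artifact_genes)
  x$regulated_genes <- unlist(x$regulated_genes)
  x$direct_targets <- as.character(x$direct_targets)
  x$coexp_active_tumors <- as.integer(x$coexp_active_tumors)
  structure(x, class = "sim_truth")
}
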