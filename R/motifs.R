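DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' Wraps a 4 x w base-count (or frequency) matrix with its background model
#' and pseudocount. Scoring uses the log2-odds transform of
#' [pwm_log_odds()].
#'
#' @param counts 4 x w numeric matrix; rows in A, C, G, T order (rownames,
#'   if present, must be these).
#' @param motif_id Identifier string.
#' @param background Base probabilities (A, C, G, T); must sum to 1.
#' @param pseudocount Total pseudocount distributed by the background
#'   (default 1).
#' @return An object of class `pwm`.
#' @export
pwm <- function(counts, motif_id, background = rep(0.25, 4), pseudocount = 1) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) abort("`counts` must have 4 rows (A, C, G, T)")
  if (!is.null(rownames(counts)) && !identical(rownames(counts), DNA_BASES)) {
    counts <- counts[DNA_BASES, , drop = FALSE]
  }
  rownames(counts) <- DNA_BASES
  if (any(counts < 0)) abort("counts must be non-negative")
  if (any(colSums(counts) == 0) && pseudocount == 0) {
    abort("zero column total with zero pseudocount")
  }
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-6 ||
      any(background <= 0)) {
    abort("`background` must be 4 positive probabilities summing to 1")
  }
  structure(
    list(motif_id = motif_id, counts = counts,
         background = as.numeric(background), pseudocount = pseudocount),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$motif_id, " (width ", ncol(x$counts), "), consensus ",
      pwm_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Motif width
#' @param x A `pwm`.
#' @return Integer width.
#' @export
pwm_width <- function(x) ncol(x$counts)

#' Consensus sequence of a PWM
#' @param x A `pwm`.
#' @return Character string, the per-column argmax base.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$counts, 2, which.max)], collapse = "")
}

#' Log2-odds scoring matrix of a PWM
#'
#' Entry (b, j) is
#' `log2((counts[b, j] + pseudocount * background[b]) /
#'       (colsum[j] + pseudocount) / background[b])`:
#' the background-smoothed column probability over the background rate.
#'
#' @param x A `pwm`.
#' @return A 4 x w numeric matrix.
#' @export
pwm_log_odds <- function(x) {
  stopifnot(is(x, "pwm"))
  cs <- colSums(x$counts)
  prob <- sweep(x$counts + x$pseudocount * x$background, 2,
                cs + x$pseudocount, "/")
  log2(prob / x$background)
}

#' Maximum achievable log-odds score
#' @param x A `pwm`.
#' @return The sum of per-column maxima of [pwm_log_odds()].
#' @export
pwm_max_score <- function(x) sum(apply(pwm_log_odds(x), 2, max))

# reverse-complement scoring matrix: scores the - strand on + coordinates
pwm_log_odds_rc <- function(lo) {
  lo[4:1, rev(seq_len(ncol(lo))), drop = FALSE]
}

#' Scan sequence windows with a PWM
#'
#' Scores every offset of every window on both strands and reports the
#' placements whose log2-odds reach `threshold_fraction` of the motif's
#' maximum achievable score. Reverse-strand hits are reported in forward
#' coordinates. Offsets are bp between the hit center and the window
#' center (negative = left/upstream half). Windows are expected to share
#' one length (the fixed scan width, 600 bp by default upstream); windows
#' containing `N` at a scored position are skipped at that position.
#'
#' @param seqs Named character vector of equal-length A/C/G/T/N windows
#'   (or a `Biostrings::DNAStringSet`).
#' @param x A `pwm`.
#' @param threshold_fraction Fraction of the maximum score in `(0, 1]`
#'   (default 0.8).
#' @return A tibble with `region_id`, `offset`, `strand`, `log_odds`.
#' @export
scan_windows <- function(seqs, x, threshold_fraction = 0.8) {
  stopifnot(is(x, "pwm"))
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction > 1) {
    abort("`threshold_fraction` must lie in (0, 1]")
  }
  seqs <- as_seq_chr(seqs)
  if (length(seqs) == 0) abort("no sequences to scan")
  codes <- encode_seqs(seqs)
  w <- pwm_width(x)
  if (ncol(codes) < w) abort("windows shorter than the motif")
  lo <- pwm_log_odds(x)
  # tiny slack so exact-consensus hits survive float summation order
  thr <- threshold_fraction * pwm_max_score(x) - 1e-9
  fwd <- slide_scores(codes, lo)
  rev <- slide_scores(codes, pwm_log_odds_rc(lo))
  center <- (ncol(codes) + 1) / 2
  hit_tbl <- function(sc, strand) {
    idx <- which(!is.na(sc) & sc >= thr, arr.ind = TRUE)
    if (nrow(idx) == 0) {
      return(tibble(region_id = character(), offset = double(),
                    strand = character(), log_odds = double()))
    }
    tibble(
      region_id = rownames(codes)[idx[, 1]],
      offset = (idx[, 2] + (w - 1) / 2) - center,
      strand = strand,
      log_odds = sc[idx]
    )
  }
  out <- dplyr::bind_rows(hit_tbl(fwd, "+"), hit_tbl(rev, "-"))
  dplyr::arrange(out, .data$region_id, .data$offset, .data$strand)
}

#' Rank a PWM library by enrichment in peak windows
#'
#' Counts, per motif, the fraction of peak windows with at least one hit
#' and compares it with the hit rate in background windows via a binomial
#' upper tail: `p = P(Bin(total_regions, background_rate) >= hit_regions)`.
#' When no background is supplied, dinucleotide-preserving shuffles of the
#' peak windows are used (seed the R RNG for reproducibility). The
#' background rate is estimated as `(bg_hits + 0.5) / (n_bg + 1)` so the
#' tail probability stays defined (and in `(0, 1]`) when no background
#' window scores a hit.
#'
#' @param peak_seqs Named character vector (or `DNAStringSet`) of
#'   equal-length windows centered on peaks.
#' @param library A list of `pwm` objects.
#' @param background_seqs Optional background windows of the same length
#'   distribution; defaults to 2-mer-preserving shuffles of `peak_seqs`.
#' @param threshold_fraction Scan threshold, see [scan_windows()].
#' @param alpha Significance cutoff for the `enriched` flag (default 0.05).
#' @param n_shuffles Shuffled copies per peak window when no explicit
#'   background is given (default 3). The background rate is treated as
#'   known by the binomial tail, so a small background makes the test
#'   slightly anti-conservative; more shuffles (or a large explicit
#'   background) tighten the estimate.
#' @return A tibble ranked by ascending `p_value`: `motif_id`,
#'   `hit_regions`, `total_regions`, `background_rate`, `p_value`,
#'   `enriched`.
#' @export
enrich_motifs <- function(peak_seqs, library, background_seqs = NULL,
                          threshold_fraction = 0.8, alpha = 0.05,
                          n_shuffles = 3) {
  if (length(library) == 0) abort("empty motif library")
  peak_seqs <- as_seq_chr(peak_seqs)
  if (length(peak_seqs) == 0) abort("empty peak window set")
  if (is.null(background_seqs)) {
    background_seqs <- unlist(lapply(seq_len(n_shuffles), function(i) {
      vapply(peak_seqs, shuffle_dinucleotide, character(1))
    }), use.names = FALSE)
    names(background_seqs) <- paste0("shuf_", seq_along(background_seqs))
  } else {
    background_seqs <- as_seq_chr(background_seqs)
  }
  n_pk <- length(peak_seqs)
  n_bg <- length(background_seqs)
  rows <- purrr::map(library, function(m) {
    hp <- scan_windows(peak_seqs, m, threshold_fraction)
    hb <- scan_windows(background_seqs, m, threshold_fraction)
    k <- length(unique(hp$region_id))
    kb <- length(unique(hb$region_id))
    rate <- (kb + 0.5) / (n_bg + 1)
    tibble(
      motif_id = m$motif_id,
      hit_regions = k,
      total_regions = n_pk,
      background_rate = rate,
      p_value = pbinom(k - 1, n_pk, rate, lower.tail = FALSE)
    )
  })
  out <- purrr::list_rbind(rows)
  out$enriched <- out$p_value < alpha
  dplyr::arrange(out, .data$p_value, .data$motif_id)
}

#' Signed distance from each region center to its closest motif hit
#'
#' For every region with at least one hit, the hit offset closest to the
#' region center (ties broken toward the more upstream hit, then `+`
#' strand, for determinism).
#'
#' @param hits Hit tibble from [scan_windows()].
#' @return A tibble with `region_id` and `distance` (signed bp).
#' @export
closest_motif_distances <- function(hits) {
  if (nrow(hits) == 0) {
    return(tibble(region_id = character(), distance = double()))
  }
  hits %>%
    dplyr::arrange(.data$region_id, abs(.data$offset), .data$offset,
                   .data$strand) %>%
    dplyr::group_by(.data$region_id) %>%
    dplyr::summarise(distance = .data$offset[1], .groups = "drop")
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: a uniformly random Eulerian walk over the
#' 2-mer transition multigraph, preserving the exact dinucleotide (and
#' hence mononucleotide, save endpoints) composition of the input. Uses
#' the R RNG; seed for reproducibility.
#'
#' @param seq A single character string.
#' @return A shuffled string with identical 2-mer counts.
#' @export
shuffle_dinucleotide <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  if (n < 3) return(paste(s, collapse = ""))
  verts <- unique(s)
  succ <- split(s[-1], factor(s[-n], levels = verts))
  first <- s[1]; last <- s[n]
  repeat {
    # designate one out-edge per non-terminal vertex; accept if the
    # designated edges form an arborescence converging on `last`
    desig <- vapply(verts, function(v) {
      if (v == last || length(succ[[v]]) == 0) NA_character_
      else succ[[v]][sample.int(length(succ[[v]]), 1)]
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == last || length(succ[[v]]) == 0) next
      cur <- v; steps <- 0
      while (cur != last && steps <= length(verts)) {
        cur <- desig[[cur]]
        if (is.na(cur)) break
        steps <- steps + 1
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  # order each vertex's out-edges randomly, designated edge strictly last
  ordered <- lapply(verts, function(v) {
    e <- succ[[v]]
    if (length(e) <= 1) return(e)
    if (!v %in% names(desig) || is.na(desig[[v]])) return(sample(e))
    i <- which(e == desig[[v]])[1]
    c(sample(e[-i]), e[i])
  })
  names(ordered) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- first
  cur <- first
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

# ---- internal scanning machinery ----

as_seq_chr <- function(seqs) {
  if (is(seqs, "DNAStringSet")) {
    out <- as.character(seqs)
  } else {
    out <- as.character(seqs)
    names(out) <- names(seqs)
  }
  if (length(out) > 0 && is.null(names(out))) {
    names(out) <- paste0("region_", seq_along(out))
  }
  out
}

encode_seqs <- function(seqs) {
  lens <- unique(nchar(seqs))
  if (length(lens) != 1) abort("scan windows must share a single length")
  chars <- matrix(unlist(strsplit(toupper(seqs), ""), use.names = FALSE),
                  nrow = length(seqs), byrow = TRUE)
  codes <- match(chars, DNA_BASES)
  bad <- is.na(codes) & chars != "N"
  if (any(bad)) abort("sequences may contain only A, C, G, T or N")
  codes <- matrix(codes, nrow = length(seqs))
  rownames(codes) <- names(seqs)
  codes
}

# score every start position of every row of `codes` against `lo` (4 x w);
# returns an n x (len - w + 1) matrix, NA where an N fell in the window
slide_scores <- function(codes, lo) {
  n <- nrow(codes); len <- ncol(codes); w <- ncol(lo)
  np <- len - w + 1
  sc <- matrix(0, nrow = n, ncol = np)
  for (j in seq_len(w)) {
    block <- codes[, j:(j + np - 1), drop = FALSE]
    sc <- sc + matrix(lo[, j][block], nrow = n)
  }
  rownames(sc) <- rownames(codes)
  sc
}
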