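sharp_pwm <- function(consensus, id = "toy", hi = 97, lo = 1) {
  b <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  counts <- matrix(lo, 4, length(b), dimnames = list(c("A", "C", "G", "T")))
  counts[cbind(b, seq_along(b))] <- hi
  pwm(counts, motif_id = id)
}

embed_at <- function(seq, motif, start0) {
  substr(seq, start0 + 1, start0 + nchar(motif)) <- motif
  seq
}

test_that("log-odds matrix follows the smoothed closed form", {
  # uniform counts on a uniform background carry no information
  u <- pwm(matrix(5, 4, 6), "u")
  expect_equal(pwm_log_odds(u), matrix(0, 4, 6), ignore_attr = TRUE)

  # consensus columns approach +log2(4) as the pseudocount vanishes
  m <- sharp_pwm("ACGT", hi = 100, lo = 0)
  m$pseudocount <- 1e-9
  expect_equal(unname(max(pwm_log_odds(m)[, 1])), 2, tolerance = 1e-6)

  # 4x4 toy against hand-computed entries
  counts <- matrix(c(8, 0, 1, 1,
                     2, 2, 4, 2,
                     0, 10, 0, 0,
                     3, 3, 3, 1), nrow = 4, byrow = FALSE)
  rownames(counts) <- c("A", "C", "G", "T")
  tw <- pwm(counts, "hand", pseudocount = 1)
  expect_equal(
    unname(pwm_log_odds(tw)[1, 1]),
    log2(((8 + 0.25) / (10 + 1)) / 0.25)
  )
  expect_equal(
    unname(pwm_log_odds(tw)[3, 2]),
    log2(((4 + 0.25) / (10 + 1)) / 0.25)
  )
  expect_error(pwm(matrix(0, 4, 5), "z", pseudocount = 0), "zero column")
})

test_that("scanning finds planted consensus sites on both strands", {
  set.seed(21)
  m <- sharp_pwm("TTAACGGTCA")
  win <- random_dna(1, 600)
  center_start <- 300 - 5  # motif center exactly at window center
  planted <- embed_at(win, "TTAACGGTCA", center_start)
  hits <- scan_windows(c(r1 = planted), m, threshold_fraction = 0.9)
  expect_true(any(hits$strand == "+" & abs(hits$offset) < 1))

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(planted)))
  hits_rc <- scan_windows(c(r1 = rc), m, threshold_fraction = 0.9)
  expect_true(any(hits_rc$strand == "-" & abs(hits_rc$offset) < 1))
  # strand symmetry: the full hit sets mirror
  expect_setequal(hits_rc$offset, -hits$offset)
})

test_that("threshold 1.0 scanning equals exact string matching", {
  set.seed(22)
  m <- sharp_pwm("ACGTACGTAA", hi = 100, lo = 0)
  m$pseudocount <- 1e-6
  seqs <- random_dna(50, 300)
  names(seqs) <- paste0("w", seq_len(50))
  hits <- scan_windows(seqs, m, threshold_fraction = 1)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  expected <- sum(vapply(seqs, function(s)
    length(gregexpr("ACGTACGTAA", s, fixed = TRUE)[[1]] |>
             (\(x) x[x > 0])()), integer(1))) +
    sum(vapply(rc, function(s)
      length(gregexpr("ACGTACGTAA", s, fixed = TRUE)[[1]] |>
               (\(x) x[x > 0])()), integer(1)))
  expect_equal(nrow(hits), expected)

  # N positions are skipped, never scored
  withN <- c(w = embed_at(paste(rep("N", 300), collapse = ""), "ACGTACGTAA", 10))
  expect_equal(nrow(scan_windows(withN, m, 1)), 1)
  expect_error(scan_windows(c(w = "ACGTXACGTACGTAA"), m), "A, C, G, T or N")
})

test_that("closest-distance summary picks the hit nearest the center", {
  hits <- tibble::tibble(
    region_id = c("r1", "r2", "r2"),
    offset = c(0, -50, 120), strand = "+", log_odds = 10
  )
  d <- closest_motif_distances(hits)
  expect_equal(d$distance[d$region_id == "r1"], 0)
  expect_equal(d$distance[d$region_id == "r2"], -50)
  expect_equal(nrow(closest_motif_distances(hits[0, ])), 0)
})

test_that("dinucleotide shuffle preserves 2-mer composition exactly", {
  set.seed(31)
  for (len in c(30, 200, 600)) {
    s <- random_dna(1, len)
    sh <- shuffle_dinucleotide(s)
    expect_equal(nchar(sh), len)
    expect_equal(count_2mers(sh), count_2mers(s))
  }
})

test_that("a planted motif is recovered as the top-ranked enrichment", {
  set.seed(41)
  lib <- default_pwm_library(n_motifs = 10, seed = 41)
  cons <- pwm_consensus(lib[[1]])
  n <- 120
  seqs <- random_dna(n, 600)
  plant_in <- seq_len(n) <= round(0.5 * n)
  seqs[plant_in] <- vapply(seqs[plant_in], function(s)
    embed_at(s, cons, sample(0:(600 - nchar(cons)), 1)), character(1))
  names(seqs) <- paste0("w", seq_len(n))
  enr <- enrich_motifs(seqs, lib)
  expect_equal(enr$motif_id[1], lib[[1]]$motif_id)
  expect_lt(enr$p_value[1], 0.05)
  expect_true(enr$enriched[1])

  # a library whose motif was never planted is not called enriched
  enr0 <- enrich_motifs(random_dna(100, 600), lib[1])
  expect_gt(enr0$p_value[1], 0.05)
})

test_that("null enrichment p-values are calibrated", {
  # regime where the background rate is well estimated (10x background)
  # and the binomial is smooth (permissive threshold, ~20% hit rate)
  set.seed(51)
  lib <- default_pwm_library(n_motifs = 20, seed = 51)
  ps <- c(); flagged <- c()
  for (i in 1:10) {
    pk <- random_dna(100, 300)
    bg <- random_dna(1000, 300)
    e <- enrich_motifs(pk, lib, background_seqs = bg,
                       threshold_fraction = 0.6)
    ps <- c(ps, e$p_value)
    flagged <- c(flagged, sum(e$enriched))
  }
  # family-level type-I control near the nominal alpha * library size
  expect_lte(mean(flagged), 20 * 0.05 + 0.75)
  # approximate uniformity of the pooled null p-values
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})
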