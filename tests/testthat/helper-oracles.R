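# Independent oracles used across the suite.

# Hypergeometric upper tail by explicit enumeration of point masses:
# P(X >= k) = sum_i C(K, i) C(N-K, n-i) / C(N, n), independent of phyper().
oracle_hyper_upper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Brute-force subset enumeration (tiny N only): draw every size-n subset of
# 1..N and count how many intersect the fixed set 1..K in >= k elements.
oracle_hyper_bruteforce <- function(k, K, n, N) {
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# random valid 2x2 tables
random_tables <- function(n, max_cell = 30) {
  tibble::tibble(
    a = sample.int(max_cell, n, replace = TRUE) - 1L,
    b = sample.int(max_cell, n, replace = TRUE) - 1L,
    c = sample.int(max_cell, n, replace = TRUE) - 1L,
    d = sample.int(max_cell, n, replace = TRUE) - 1L
  ) |> dplyr::filter(a + b + c + d > 0)
}

# small expression fixture: n genes, nc controls, nk knockdowns, optional
# per-gene shifts (in log2 units) applied to knockdown arrays
toy_expression <- function(n = 100, nc = 2, nk = 1, noise_sd = 0.2,
                           shift = NULL) {
  genes <- sprintf("g%04d", seq_len(n))
  samples <- c(paste0("ctl_", seq_len(nc)), paste0("kd_", seq_len(nk)))
  base <- runif(n, 6, 12)
  m <- base + matrix(rnorm(n * (nc + nk), 0, noise_sd), nrow = n)
  colnames(m) <- samples
  if (!is.null(shift)) {
    kd_cols <- grep("^kd_", samples)
    m[, kd_cols] <- m[, kd_cols, drop = FALSE] + shift
  }
  list(
    expr = dplyr::bind_cols(tibble::tibble(gene_id = genes),
                            tibble::as_tibble(m)),
    design = tibble::tibble(
      sample_id = samples,
      condition = rep(c("control", "knockdown"), c(nc, nk))
    )
  )
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

count_2mers <- function(s) {
  ch <- strsplit(s, "")[[1]]
  table(paste0(ch[-length(ch)], ch[-1]))
}
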