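toy_peaks <- function(starts, ends, fdr = 0.1, chrom = "chr1") {
  tibble::tibble(
    chrom = chrom, start = as.integer(starts), end = as.integer(ends),
    name = paste0("p", seq_along(starts)), score = 1, strand = ".",
    fdr = rep_len(fdr, length(starts))
  )
}

toy_promoters <- function(gene_id, start, end, strand, tss, chrom = "chr1") {
  tibble::tibble(gene_id = gene_id, chrom = chrom, start = start,
                 end = end, strand = strand, tss = tss)
}

test_that("FDR screen is an inclusive-boundary filter", {
  pk <- toy_peaks(c(0, 100, 200), c(50, 150, 250), fdr = c(0.1, 0.2, 0.21))
  expect_equal(filter_peaks(pk, 0.2)$name, c("p1", "p2"))
  expect_equal(nrow(filter_peaks(pk[0, ], 0.2)), 0)
  expect_identical(filter_peaks(pk, 1), pk)
  expect_error(filter_peaks(pk, 1.2), "probability")
})

test_that("control subtraction uses the >= 1 bp half-open overlap rule", {
  target <- toy_peaks(100, 200)
  expect_equal(nrow(subtract_control(target, toy_peaks(199, 250))), 0)
  expect_equal(nrow(subtract_control(target, toy_peaks(200, 250))), 1)
  expect_identical(subtract_control(target, toy_peaks(1, 2)[0, ]), target)
  # different chromosome never overlaps
  expect_equal(nrow(subtract_control(target, toy_peaks(100, 200, chrom = "chr2"))), 1)
})

test_that("subtraction is monotone and commutes with the FDR screen", {
  set.seed(3)
  for (rep in 1:5) {
    s <- sort(sample.int(5000, 40)) * 10
    target <- toy_peaks(s, s + 80, fdr = runif(40))
    cs <- sample.int(50000, 10)
    c1 <- toy_peaks(cs, cs + 120, fdr = runif(10))
    cs2 <- sample.int(50000, 5)
    c2 <- dplyr::bind_rows(c1, toy_peaks(cs2, cs2 + 90))
    r1 <- subtract_control(target, c1)
    r2 <- subtract_control(target, c2)
    expect_true(all(r2$name %in% r1$name))  # more control never retains more
    expect_identical(
      filter_peaks(subtract_control(target, c1), 0.3),
      subtract_control(filter_peaks(target, 0.3), c1)
    )
  }
})

test_that("promoter assignment is per-window with >= 1 bp overlap", {
  prom <- toy_promoters(c("GA", "GB"), c(0L, 1000L), c(1000L, 2000L),
                        c("+", "+"), c(500L, 1500L))
  inside <- toy_peaks(400, 600)
  asg <- assign_promoters(inside, prom)
  expect_equal(asg$gene_id, "GA")

  spanning <- toy_peaks(950, 1050)
  expect_setequal(assign_promoters(spanning, prom)$gene_id, c("GA", "GB"))

  outside <- toy_peaks(5000, 5100)
  expect_equal(nrow(assign_promoters(outside, prom)), 0)

  dup <- prom; dup$gene_id <- c("GA", "GA")
  expect_error(assign_promoters(inside, dup), "duplicate")
})

test_that("TSS offsets are strand-corrected and histogram conserves events", {
  prom <- toy_promoters(c("GP", "GM"), c(0L, 0L), c(1000L, 1000L),
                        c("+", "-"), c(600L, 400L), chrom = c("c1", "c2"))
  pk <- tibble::tibble(
    chrom = c("c1", "c2"), start = c(650L, 0L), end = c(750L, 100L),
    name = c("a", "b"), score = 1, strand = ".", fdr = 0.1
  )
  asg <- assign_promoters(pk, prom)
  # + strand: midpoint 700, TSS 600 -> +100 downstream
  expect_equal(asg$tss_offset[asg$gene_id == "GP"], 100)
  # - strand: midpoint 50, TSS 400 -> mirrored to +350
  expect_equal(asg$tss_offset[asg$gene_id == "GM"], 350)

  h <- tss_histogram(asg, bin_width = 100)
  expect_s3_class(h, "binding_histogram")
  expect_equal(sum(h$count), nrow(asg))
  # a peak centered exactly on the TSS lands in the bin starting at 0
  center <- assign_promoters(toy_peaks(550, 650, chrom = "c1"),
                             prom[1, , drop = FALSE])
  hc <- tss_histogram(center, bin_width = 100)
  expect_equal(hc$count[hc$bin_start == 0], 1L)
})

test_that("peaks planted around the TSS give a 0-centered histogram mode", {
  cfg <- sim_config(n_genes = 400, n_bound = 200, n_regulated_bound = 100,
                    n_indirect_down = 20, n_indirect_up = 20)
  ann <- make_annotation(cfg, seed = 5)
  truth <- make_truth(ann, cfg, seed = 5)
  pks <- make_peaksets(truth, ann, cfg, seed = 5)
  kept <- subtract_control(filter_peaks(pks$factor, 0.2), pks$IgG)
  h <- tss_histogram(assign_promoters(kept, ann$promoters), bin_width = 100)
  mode_bin <- h$bin_start[which.max(h$count)]
  expect_true(mode_bin %in% c(-200, -100, 0, 100))
  expect_equal(sum(h$count), nrow(assign_promoters(kept, ann$promoters)))
})

test_that("screen recovers planted bound genes minus IgG artifacts exactly", {
  for (seed in c(2, 9)) {
    cfg <- sim_config(n_genes = 500, n_bound = 120, n_regulated_bound = 60,
                      n_indirect_down = 20, n_indirect_up = 20,
                      artifact_fraction = 0.2)
    ann <- make_annotation(cfg, seed)
    truth <- make_truth(ann, cfg, seed)
    pks <- make_peaksets(truth, ann, cfg, seed)
    kept <- subtract_control(filter_peaks(pks$factor, 0.2), pks$IgG)
    got <- sort(bound_genes(assign_promoters(kept, ann$promoters)))
    want <- sort(setdiff(truth$bound_genes$factor, truth$artifact_genes))
    expect_identical(got, want)

    # with no artifacts the recovery is the full bound set
    cfg0 <- sim_config(n_genes = 500, n_bound = 120, n_regulated_bound = 60,
                       n_indirect_down = 20, n_indirect_up = 20,
                       artifact_fraction = 0)
    truth0 <- make_truth(ann, cfg0, seed)
    pks0 <- make_peaksets(truth0, ann, cfg0, seed)
    kept0 <- subtract_control(filter_peaks(pks0$factor, 0.2), pks0$IgG)
    expect_identical(sort(bound_genes(assign_promoters(kept0, ann$promoters))),
                     sort(truth0$bound_genes$factor))
  }
})
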