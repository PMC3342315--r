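small_cfg <- function(...) {
  defaults <- list(n_genes = 300, n_bound = 80, n_regulated_bound = 40,
                   n_indirect_down = 10, n_indirect_up = 20, n_tumors = 60)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("every generator output is a pure function of (config, seed)", {
  cfg <- small_cfg()
  a <- simulate_regulome(cfg, seed = 91)
  b <- simulate_regulome(cfg, seed = 91)
  expect_identical(a$promoters, b$promoters)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$expr, b$expr)
  expect_identical(a$zscores, b$zscores)
  expect_identical(a$truth$regulated_genes, b$truth$regulated_genes)
  # a different seed changes the draw
  c <- simulate_regulome(cfg, seed = 92)
  expect_false(identical(a$zscores, c$zscores))
})

test_that("annotation has the requested size, extent and strand balance", {
  cfg <- sim_config(n_genes = 1000)
  ann <- make_annotation(cfg, seed = 93)
  expect_equal(nrow(ann$promoters), 1000)
  expect_equal(unique(ann$promoters$end - ann$promoters$start), 2700)
  expect_true(all(nchar(ann$sequences) == 2700))
  expect_true(all(ann$promoters$tss >= ann$promoters$start &
                    ann$promoters$tss < ann$promoters$end))
  # windows on one chromosome never overlap
  by_chr <- split(ann$promoters, ann$promoters$chrom)
  for (p in by_chr) {
    p <- p[order(p$start), ]
    if (nrow(p) > 1) expect_true(all(p$start[-1] >= p$end[-nrow(p)]))
  }
  frac_plus <- mean(ann$promoters$strand == "+")
  expect_gt(frac_plus, 0.4)
  expect_lt(frac_plus, 0.6)
})

test_that("planted knockdown effects land on the regulated genes only", {
  cfg <- small_cfg()
  sim <- simulate_regulome(cfg, seed = 94)
  eff <- sim$truth$regulated_genes
  expect_length(eff, 40 + 10 + 20)
  expect_equal(sum(eff < 0), 50)
  expect_equal(sum(eff > 0), 20)
  # direct targets are bound, regulated, artifact-free
  expect_true(all(sim$truth$direct_targets %in% sim$truth$bound_genes$factor))
  expect_true(all(sim$truth$direct_targets %in% names(eff)))
  expect_length(intersect(sim$truth$direct_targets,
                          sim$truth$artifact_genes), 0)

  # a null experiment yields almost no discoveries at FDR 0.01
  cfg0 <- small_cfg(n_regulated_bound = 0, n_indirect_down = 0,
                    n_indirect_up = 0)
  ann0 <- make_annotation(cfg0, seed = 95)
  truth0 <- make_truth(ann0, cfg0, seed = 95)
  ex0 <- make_expression(truth0, ann0, cfg0, seed = 95)
  de0 <- run_de(ex0$expr, ex0$design)
  expect_lte(length(de_genes(de0)), 2)
})

test_that("tumor Z-scores follow the latent co-activation model", {
  cfg <- small_cfg()
  ann <- make_annotation(cfg, seed = 96)
  truth <- make_truth(ann, cfg, seed = 96)

  # no planted signal: over-expression rate is the normal tail rate
  cfg_null <- small_cfg(coexp_penetrance = 0, coexp_shift = 0,
                        n_tumors = 316)
  truth_null <- make_truth(ann, cfg_null, seed = 96)
  z0 <- make_zscores(truth_null, ann, cfg_null, seed = 96)
  expect_lt(abs(mean(z0 > 1.65) - (1 - pnorm(1.65))), 0.005)

  # full penetrance and a decisive shift flag every active tumor
  cfg_full <- small_cfg(coexp_penetrance = 1, coexp_shift = 10)
  truth_full <- make_truth(ann, cfg_full, seed = 96)
  z1 <- make_zscores(truth_full, ann, cfg_full, seed = 96)
  act <- truth_full$coexp_active_tumors
  expect_true(all(z1[cfg_full$anchor_id, act] > 1.65))
  expect_true(all(z1[truth_full$direct_targets, act] > 1.65))
})

test_that("planted motifs sit near peak centers with the configured jitter", {
  cfg <- small_cfg()
  ann <- make_annotation(cfg, seed = 97)
  truth <- make_truth(ann, cfg, seed = 97)
  pks <- make_peaksets(truth, ann, cfg, seed = 97)
  lib <- default_pwm_library(seed = 97)
  pl <- plant_motifs(truth, ann, pks, lib[[1]], cfg, seed = 97)
  expect_length(pl$offsets, length(truth$bound_genes$factor))
  expect_lt(abs(mean(pl$offsets)), 30)
  expect_lt(abs(sd(pl$offsets) - cfg$motif_jitter_sd) / cfg$motif_jitter_sd,
            0.35)
})

test_that("ground truth serializes and round-trips through JSON", {
  cfg <- small_cfg()
  ann <- make_annotation(cfg, seed = 98)
  truth <- make_truth(ann, cfg, seed = 98)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(truth, path)
  back <- read_truth(path)
  expect_identical(back$bound_genes, truth$bound_genes)
  expect_identical(back$artifact_genes, truth$artifact_genes)
  expect_equal(back$regulated_genes, truth$regulated_genes)
  expect_identical(back$direct_targets, truth$direct_targets)
  expect_identical(back$coexp_active_tumors,
                   as.integer(truth$coexp_active_tumors))
  expect_equal(back$penetrance, truth$penetrance)
})
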