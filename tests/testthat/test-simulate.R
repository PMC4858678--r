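test_that("sim_config validates fields and names the offender", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(frac_affected = 1.2), "frac_affected")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(effect_loc = 0.1), "effect_loc")
  expect_error(sim_config(promoter_frac = -0.1), "promoter_frac")
})

test_that("simulated experiment has the configured shape and planted truth", {
  cfg <- sim_config(n_genes = 2000, n_tfs = 3, frac_affected = 0.05, seed = 3)
  sim <- simulate_experiment(cfg)
  expect_equal(nrow(sim$expr), 2000)
  expect_equal(length(expr_cols <- setdiff(names(sim$expr), "gene")),
               3 * 2 * 3)
  expect_equal(sort(expr_cols), sort(sim$samples$sample_id))
  # exactly round(n_genes * frac_affected) affected genes per TF
  counts <- table(sim$truth$effects$tf)
  expect_true(all(counts == round(2000 * 0.05)))
  # every planted magnitude clears the floor
  expect_true(all(abs(sim$truth$effects$effect) >= log10(1.5)))
  # induced means shift by the planted effect, controls do not
  eff <- sim$truth$effects[sim$truth$effects$tf == "TF01", ]
  g <- eff$gene[1]
  row <- sim$expr[sim$expr$gene == g, ]
  ind <- unlist(row[, sim$samples$sample_id[sim$samples$tf == "TF01" &
                                            sim$samples$condition == "induced"]])
  ctl <- unlist(row[, sim$samples$sample_id[sim$samples$tf == "TF01" &
                                            sim$samples$condition == "control"]])
  expect_equal(mean(ind) - mean(ctl), eff$effect[1], tolerance = 0.15)
})

test_that("frac_affected = 0 gives an all-null truth", {
  sim <- simulate_experiment(small_config(frac_affected = 0))
  expect_equal(nrow(sim$truth$effects), 0)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_config(seed = 42)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a, b)
  models <- simulate_transcript_models(cfg)
  expect_identical(models, simulate_transcript_models(cfg))
  expect_identical(simulate_atlas(cfg, a$truth), simulate_atlas(cfg, b$truth))
  expect_identical(simulate_peaks(cfg, a$truth, models),
                   simulate_peaks(cfg, b$truth, models))
})

test_that("transcript models tile synthetic chromosomes unambiguously", {
  cfg <- sim_config(n_genes = 250, n_tfs = 2, seed = 5)
  models <- simulate_transcript_models(cfg)
  expect_equal(nrow(models), 250)
  expect_equal(sort(unique(models$chrom)), c("chr1", "chr2", "chr3"))
  expect_true(all(models$symbol_score %in% c(1L, 3L)))
  expect_true(all(models$tss >= 0))
  # neighbouring TSSs are 200 kb apart on each chromosome
  gaps <- unlist(tapply(models$tss, models$chrom,
                        function(x) diff(sort(x))))
  expect_true(all(gaps == 200000))
})

test_that("atlas alignment strength controls the planted correlation", {
  cfg <- small_config(seed = 8, frac_affected = 0.1)
  sim <- simulate_experiment(cfg)
  eff <- sim$truth$effects[sim$truth$effects$tf == "TF01", ]

  eff2 <- sim$truth$effects[sim$truth$effects$tf == "TF02", ]
  only1 <- eff[!eff$gene %in% eff2$gene, ]  # no cross-TF interference
  corr_on_effect_genes <- function(strength, noise, genes, effects,
                                   frac_marker = 0.05) {
    cfg2 <- small_config(seed = 8, frac_affected = 0.1,
                         alignment_strength = strength, noise_sd = noise,
                         frac_marker = frac_marker)
    atl_raw <- simulate_atlas(cfg2, sim$truth)
    atl <- atlas_from_replicates(atl_raw$expr, atl_raw$samples)
    a <- atl[atl$tissue == "TISSUE01", ]
    cor(a$logratio[match(genes, a$gene)], effects)
  }
  # degenerate limit: strong alignment, essentially no noise, no markers
  expect_gt(corr_on_effect_genes(2, 1e-6, only1$gene, only1$effect,
                                 frac_marker = 0), 0.9999)
  # alignment off: no correlation beyond noise
  expect_lt(abs(corr_on_effect_genes(0, 0.05, eff$gene, eff$effect)), 0.35)
})

test_that("planted peaks sit in their class band, decoys beyond 50 kb", {
  cfg <- small_config(seed = 13, frac_bound = 1)
  sim <- simulate_experiment(cfg)
  models <- simulate_transcript_models(cfg)
  pk <- simulate_peaks(cfg, sim$truth, models)
  tss <- setNames(models$tss, models$symbol)
  chrom <- setNames(models$chrom, models$symbol)

  planted <- pk$truth$bound_genes
  expect_gt(nrow(planted), 0)
  # reconstruct each planted gene's nearest peak distance in sample 1
  s1 <- pk$peaks[grepl("_s1$", pk$peaks$sample_id), ]
  for (i in seq_len(nrow(planted))) {
    g <- planted$gene[i]
    same <- s1[s1$chrom == chrom[g] & s1$tf == planted$tf[i], ]
    d <- min(abs((same$start + same$end) / 2 - tss[g]))
    if (planted$class[i] == "promoter") expect_lt(d, 500)
    else expect_true(d >= 500 && d < 50000)
  }
  # every peak midpoint not near a planted gene is >50 kb from all TSSs
  mids <- (pk$peaks$start + pk$peaks$end) / 2
  near_any <- purrr::map2_lgl(pk$peaks$chrom, mids, function(ch, mm) {
    any(abs(mm - models$tss[models$chrom == ch]) < 50000)
  })
  planted_mid <- purrr::map2_lgl(pk$peaks$chrom, mids, function(ch, mm) {
    pg <- planted$gene[chrom[planted$gene] == ch]
    length(pg) > 0 && any(abs(mm - tss[pg]) < 50000)
  })
  expect_true(all(near_any == planted_mid))
})

test_that("frac_bound = 0 plants nothing", {
  cfg <- small_config(seed = 2, frac_bound = 0)
  sim <- simulate_experiment(cfg)
  models <- simulate_transcript_models(cfg)
  pk <- simulate_peaks(cfg, sim$truth, models)
  expect_equal(nrow(pk$truth$bound_genes), 0)
})
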