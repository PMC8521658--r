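test_that("config validation rejects impossible settings", {
  expect_error(sim_config(penetrance = 1.2), "probabilities")
  expect_error(sim_config(causal_pos = 3e8), "outside its chromosome")
  expect_error(sim_config(causal_chrom = "chrX"), "not in chrom_lengths")
  expect_error(sim_config(ibd_segment_length = 5e8), "smaller than")
})

test_that("identical configs replay bit-identical datasets", {
  cfg <- tiny_config(seed = 42)
  a <- simulate_cross(cfg)
  b <- simulate_cross(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(simulate_panel(cfg)$wgs$genotypes,
                   simulate_panel(cfg)$wgs$genotypes)
  expect_identical(simulate_expression(cfg)$peaks,
                   simulate_expression(cfg)$peaks)
  # different seed, same planted truth structure
  p1 <- simulate_panel(tiny_config(seed = 1))
  p2 <- simulate_panel(tiny_config(seed = 2))
  expect_false(identical(p1$wgs$genotypes, p2$wgs$genotypes))
  expect_identical(length(p1$truth$decoy_ids), length(p2$truth$decoy_ids))
  expect_identical(interval_length(p1$truth$segment),
                   interval_length(p2$truth$segment))
})

test_that("zero map distance yields intact parental haplotypes", {
  cross <- simulate_cross(tiny_config(seed = 5, cm_per_mb = 0))
  for (ch in unique(cross$markers$chrom)) {
    g <- cross$genotypes[, cross$markers$chrom == ch, drop = FALSE]
    per_ind <- apply(g, 1, function(x) length(unique(x)))
    expect_true(all(per_ind == 1))
  }
})

test_that("back-cross genotypes keep one wild-type chromosome everywhere", {
  cross <- simulate_cross(tiny_config(seed = 11))
  expect_true(all(cross$genotypes %in% c(0L, 1L)))
})

test_that("full penetrance makes phenotype deterministic in carriers", {
  cfg <- tiny_config(seed = 9, n_backcross_females = 1000,
                     penetrance = 1, p_intermediate_given_affected = 0,
                     p_intermediate_given_hom = 0)
  cross <- simulate_cross(cfg)
  n_het <- sum(cross$true_causal_genotype == "het")
  expect_identical(sum(cross$phenotypes$class == "double_lacing"), n_het)
  expect_identical(sum(cross$phenotypes$class == "pencilling"),
                   1000L - n_het)
})

test_that("penetrance sampling matches the binomial model", {
  cfg <- tiny_config(seed = 77, n_backcross_females = 10000L,
                     n_markers_per_chrom = 5L, causal_pos = 1e7)
  cross <- simulate_cross(cfg)
  het <- cross$true_causal_genotype == "het"
  affected <- cross$phenotypes$class %in% c("double_lacing", "intermediate")
  p_hat <- mean(affected[het])
  sd3 <- 3 * sqrt(0.855 * (1 - 0.855) / sum(het))
  expect_lt(abs(p_hat - 0.855), sd3)
})

test_that("recombinant fraction follows the Haldane map", {
  # two markers 10 cM apart (3.33 Mb at 3 cM/Mb), 50,000 meioses
  cfg <- sim_config(seed = 123, n_backcross_females = 50000L,
                    chrom_lengths = c(chr1 = 1e7),
                    causal_chrom = "chr1", causal_pos = 3333333,
                    n_markers_per_chrom = 2L, cm_per_mb = 3)
  cross <- simulate_cross(cfg)
  expect_identical(ncol(cross$genotypes), 2L)
  d_cm <- diff(cross$markers$pos) / 1e6 * 3
  r_true <- 0.5 * (1 - exp(-2 * d_cm / 100))
  r_hat <- mean(cross$genotypes[, 1] != cross$genotypes[, 2])
  expect_lt(abs(r_hat - r_true), 3 * sqrt(r_true * (1 - r_true) / 50000))
})

test_that("pool frequencies behave in the depth and noise limits", {
  cfg <- tiny_config(seed = 21, penetrance = 1,
                     p_intermediate_given_affected = 0,
                     p_intermediate_given_hom = 0)
  cross <- simulate_cross(cfg)
  causal_col <- which(cross$markers$is_causal)

  # exact frequencies: the back-cross contrast attains the 0.5 ceiling
  exact_a <- pool_true_raf(cross, "double_lacing")
  exact_b <- pool_true_raf(cross, "pencilling")
  expect_equal(abs(exact_a$value - exact_b$value)[causal_col], 0.5)
  expect_true(all(abs(exact_a$value - exact_b$value) <= 0.5 + 1e-12))

  # deep sampling approaches the exact value
  pools <- simulate_pools(cross, depth = 1e6, base_error = 0)
  raf <- function(p) p$ref_count / (p$ref_count + p$alt_count)
  dif <- abs(raf(pools$pool_a) - raf(pools$pool_b))
  expect_lt(abs(dif[causal_col] - 0.5), 0.002)

  # identical pools: no expected difference anywhere
  same <- simulate_pools(cross, classes_a = "pencilling",
                         classes_b = "pencilling", depth = 1e6)
  expect_lt(max(abs(raf(same$pool_a) - raf(same$pool_b))), 0.01)

  # symmetric noise at 0.5 erases all signal
  noisy <- simulate_pools(cross, depth = 1e6, base_error = 0.5)
  expect_lt(max(abs(raf(noisy$pool_a) - 0.5)), 0.005)

  expect_error(simulate_pools(cross, depth = 0), "depth")
  expect_error(simulate_pools(cross, classes_a = "intermediate"), "empty")
})

test_that("planted panel truth has exactly one fully concordant variant", {
  for (seed in c(3, 14, 25)) {
    sim <- simulate_panel(tiny_config(seed = seed))
    truth <- sim$truth
    seg <- truth$segment
    v <- sim$wgs$variants
    inside <- v$pos >= seg$start & v$pos <= seg$end
    expect_identical(sum(inside), 6L)  # causal + 5 decoys

    # carriers share the haplotype at every planted site
    for (j in which(inside)) {
      g <- sim$wgs$genotypes[, j]
      expect_true(all(g[sim$wgs$status == "carrier_hom"] == 2L))
      expect_true(all(g[sim$wgs$status == "carrier_het"] >= 1L))
    }
    # every decoy leaks into >= 1 noncarrier somewhere; the causal never does
    comb <- combine_panels(sim$wgs, sim$diagnostic)
    non <- comb$status == "noncarrier"
    for (id in truth$decoy_ids) {
      expect_gt(sum(comb$genotypes[non, id] >= 1, na.rm = TRUE), 0)
    }
    expect_identical(sum(comb$genotypes[non, truth$causal_id] >= 1,
                         na.rm = TRUE), 0L)
  }
})

test_that("noise-free expression generator hits its closed forms", {
  cfg <- tiny_config(seed = 2)
  ex <- simulate_expression(cfg, true_fold_allele_ratio = 5,
                            ct_sd = 0, peak_cv = 0, delta_ct = 6)
  ratios <- allelic_ratio(ex$peaks)
  expect_equal(ratios$ratio, rep(5, nrow(ratios)))

  ex1 <- simulate_expression(cfg, true_fold_allele_ratio = 1,
                             ct_sd = 0, peak_cv = 0)
  expect_equal(allelic_ratio(ex1$peaks)$ratio, rep(1, 3))

  ct <- ex$ct
  ct_low <- mean(ct$ct[ct$gene == "transcript_low"])
  ct_high <- mean(ct$ct[ct$gene == "transcript_high"])
  expect_equal(fold_change_from_ct(ct_low, ct_high), 64)

  expect_warning(simulate_expression(cfg, n_individuals = 1),
                 "fewer than 2")
  expect_error(simulate_expression(cfg, true_fold_allele_ratio = 0),
               "must be > 0")
})
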