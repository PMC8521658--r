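test_that("carrier panels validate their inputs", {
  g <- matrix(0L, 2, 2)
  expect_error(carrier_panel(g, "noncarrier",
                             data.frame(chrom = "chr1", pos = 1:2,
                                        id = c("a", "b"))),
               "one status per sample")
  expect_error(carrier_panel(g, c("noncarrier", "mystery"),
                             data.frame(chrom = "chr1", pos = 1:2,
                                        id = c("a", "b"))),
               "unknown carrier status")
  expect_error(carrier_panel(matrix(5L, 2, 2), rep("noncarrier", 2),
                             data.frame(chrom = "chr1", pos = 1:2,
                                        id = c("a", "b"))),
               "genotype codes")
})

test_that("IBD region spans hand-constructed compatibility patterns", {
  status <- c("carrier_hom", "carrier_hom", "carrier_het", "noncarrier")
  # identical carriers across the whole interval -> whole span returned
  g_all <- rbind(rep(2L, 10), rep(2L, 10), rep(1L, 10), rep(0L, 10))
  p <- panel_from_matrix(g_all, status)
  iv <- find_ibd_region(p, genomic_interval("chr1", 1, 2000))
  expect_equal(c(iv$start, iv$end), c(100, 1000))

  # conflicts at sites 2 and 8 bound the run to sites 3..7 (the noncarrier
  # is homozygous mutant at 1, 9 and 10, so the anchor lies inside 3..7)
  g <- g_all
  g[1, 2] <- 0L  # two hom carriers homozygous for different alleles
  g[2, 8] <- 0L
  g[4, c(1, 9, 10)] <- 2L
  p2 <- panel_from_matrix(g, status)
  iv2 <- find_ibd_region(p2, genomic_interval("chr1", 1, 2000))
  expect_equal(c(iv2$start, iv2$end), c(300, 700))

  # missing calls never veto
  g3 <- g_all
  g3[1, 5] <- NA_integer_
  iv3 <- find_ibd_region(panel_from_matrix(g3, status),
                         genomic_interval("chr1", 1, 2000))
  expect_equal(c(iv3$start, iv3$end), c(100, 1000))

  # tolerated conflicts extend the run
  iv4 <- find_ibd_region(p2, genomic_interval("chr1", 1, 2000),
                         max_conflicts = 2)
  expect_equal(c(iv4$start, iv4$end), c(100, 1000))

  expect_error(find_ibd_region(p, genomic_interval("chr2", 1, 10)),
               "no variants")
  expect_error(find_ibd_region(
    panel_from_matrix(g_all[c(1, 4), ], status[c(1, 4)]),
    genomic_interval("chr1", 1, 2000)), "two carrier")
})

test_that("IBD detection matches the all-subintervals oracle", {
  set.seed(99)
  status <- c(rep("carrier_hom", 3), rep("carrier_het", 2),
              rep("noncarrier", 5))
  for (rep in 1:60) {
    n_sites <- sample(5:50, 1)
    max_conf <- sample(0:2, 1)
    g <- matrix(sample(c(0:2, NA), 10 * n_sites, replace = TRUE,
                       prob = c(0.4, 0.3, 0.25, 0.05)),
                nrow = 10)
    # ensure at least one compatible site
    g[1:5, sample(n_sites, 1)] <- c(2L, 2L, 2L, 1L, 1L)
    p <- panel_from_matrix(g, status)
    comp <- vapply(seq_len(n_sites), function(j)
      oracle_compatible(g[, j], status), logical(1))
    score <- vapply(seq_len(n_sites), function(j) {
      gj <- g[, j]
      sum(is.na(gj) |
            (status == "carrier_hom" & gj == 2L) |
            (status == "carrier_het" & gj >= 1L) |
            (status == "noncarrier" & gj < 2L))
    }, numeric(1))
    score[!comp] <- -Inf
    anchor <- which.max(score)
    span <- oracle_ibd_span(comp, anchor, max_conf)
    iv <- find_ibd_region(p, genomic_interval("chr1", 1, n_sites * 100 + 1),
                          max_conflicts = max_conf)
    expect_equal(c(iv$start, iv$end), c(span[1] * 100, span[2] * 100))
  }
})

test_that("sample order never changes IBD or classification results", {
  sim <- simulate_panel(tiny_config(seed = 8))
  seed_iv <- genomic_interval(sim$truth$segment$chrom,
                              sim$truth$segment$start - 5e4,
                              sim$truth$segment$end + 5e4)
  base_iv <- find_ibd_region(sim$wgs, seed_iv)
  base_cls <- classify_variant_association(sim$wgs)
  set.seed(1)
  for (rep in 1:5) {
    perm <- sample(nrow(sim$wgs$genotypes))
    shuf <- carrier_panel(sim$wgs$genotypes[perm, , drop = FALSE],
                          sim$wgs$status[perm], sim$wgs$variants)
    iv <- find_ibd_region(shuf, seed_iv)
    expect_equal(c(iv$start, iv$end), c(base_iv$start, base_iv$end))
    expect_identical(classify_variant_association(shuf), base_cls)
  }
})

test_that("stage-1 association follows the carrier/noncarrier rules", {
  status <- c("carrier_hom", "carrier_het", "noncarrier", "noncarrier")
  g <- cbind(pass = c(2L, 1L, 0L, 0L),
             hom_non = c(2L, 2L, 2L, 0L),
             het_non = c(2L, 1L, 1L, 0L),   # het noncarrier passes stage 1
             bad_hom = c(1L, 1L, 0L, 0L),
             miss_ok = c(NA, 1L, NA, 0L))
  p <- panel_from_matrix(g, status)
  cls <- classify_variant_association(p)
  expect_identical(cls$stage1_pass, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_match(cls$failure_reason[2], "mutant homozygote")
  expect_match(cls$failure_reason[4], "carrier_hom")
})

test_that("stage 2 demands total absence of the mutant allele in noncarriers", {
  status <- c("carrier_hom", "carrier_het", "noncarrier", "noncarrier")
  g <- cbind(causal = c(2L, 1L, 0L, 0L),
             het_leak = c(2L, 1L, 1L, 0L))
  wgs <- panel_from_matrix(g, status)
  dx <- panel_from_matrix(cbind(causal = c(1L, 0L), het_leak = c(1L, 0L)),
                          c("carrier_het", "noncarrier"))
  out <- diagnostic_concordance(wgs, dx)
  expect_identical(out$stage2_pass[out$id == "causal"], TRUE)
  # a single heterozygous noncarrier kills stage 2 despite a stage-1 pass
  expect_identical(out$stage1_pass[out$id == "het_leak"], TRUE)
  expect_identical(out$stage2_pass[out$id == "het_leak"], FALSE)
  # passers sorted first
  expect_identical(out$id[1], "causal")
})

test_that("stage-2 passes nest inside stage-1 passes", {
  set.seed(12)
  status <- c(rep("carrier_hom", 2), rep("carrier_het", 2),
              rep("noncarrier", 6))
  for (rep in 1:25) {
    g <- matrix(sample(c(0:2, NA), 10 * 12, replace = TRUE), nrow = 10)
    wgs <- panel_from_matrix(g[, 1:6, drop = FALSE], status)
    dx <- panel_from_matrix(g[, 7:12, drop = FALSE], status)
    dx$variants$id <- wgs$variants$id
    colnames(dx$genotypes) <- wgs$variants$id
    out <- suppressMessages(diagnostic_concordance(wgs, dx))
    expect_true(all(!out$stage2_pass | out$stage1_pass))
  }
})

test_that("simulated panels resolve to exactly the planted causal variant", {
  for (seed in c(5, 17, 29)) {
    sim <- simulate_panel(tiny_config(seed = seed))
    comb <- combine_panels(sim$wgs, sim$diagnostic)

    # stage 1 on the combined panel: exactly the hom-leak decoy fails,
    # verified against a per-variant brute-force truth check
    seg <- sim$truth$segment
    cls <- classify_variant_association(comb, region = seg)
    for (i in seq_len(nrow(cls))) {
      gj <- comb$genotypes[, cls$id[i]]
      truth_pass <-
        all(gj[comb$status == "carrier_hom"] == 2L, na.rm = TRUE) &&
        all(gj[comb$status == "carrier_het"] >= 1L, na.rm = TRUE) &&
        !any(gj[comb$status == "noncarrier"] == 2L, na.rm = TRUE)
      expect_identical(cls$stage1_pass[i], truth_pass)
    }
    expect_identical(cls$id[!cls$stage1_pass], sim$truth$hom_leak_decoy)

    # stage 2 across both panels leaves only the planted causal variant
    out <- suppressMessages(
      diagnostic_concordance(sim$wgs, sim$diagnostic, region = seg))
    expect_identical(out$id[out$stage2_pass], sim$truth$causal_id)

    # the detected region overlaps the planted segment
    seed_iv <- genomic_interval(seg$chrom, seg$start - 5e4, seg$end + 5e4)
    iv <- find_ibd_region(sim$wgs, seed_iv)
    expect_true(iv$start <= seg$end && iv$end >= seg$start)
  }
})
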