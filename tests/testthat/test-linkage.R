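five_markers <- data.frame(chrom = "chr1",
                           pos = c(10000, 20000, 30000, 40000, 50000),
                           id = paste0("m", 1:5),
                           stringsAsFactors = FALSE)

gm_row <- function(...) {
  m <- matrix(as.integer(c(...)), nrow = 1,
              dimnames = list("s1", five_markers$id))
  m
}

one_inferred <- function(genotype) {
  data.frame(sample = "s1", inferred = genotype, excluded = FALSE,
             stringsAsFactors = FALSE)
}

iv15 <- genomic_interval("chr1", 10000, 50000)

test_that("informative markers require opposite fixation in the lines", {
  l1 <- matrix(c(2L, 2L, 2L, 1L, 2L, NA), nrow = 2,
               dimnames = list(c("a", "b"), c("m1", "m2", "m3")))
  l2 <- matrix(c(0L, 0L, 0L, 0L, 0L, 0L), nrow = 2,
               dimnames = list(c("c", "d"), c("m1", "m2", "m3")))
  inf <- select_informative_markers(l1, l2)
  # m2 has a het founder; m3 is informative through its non-missing founder
  expect_identical(inf$marker, c("m1", "m3"))
  expect_true(all(inf$orientation == "line1_carrier"))
  expect_error(select_informative_markers(l2, l2), "no informative")

  cross <- simulate_cross(tiny_config(seed = 6))
  inf2 <- select_informative_markers(cross$founders$line_carrier,
                                     cross$founders$line_wild)
  expect_identical(nrow(inf2), ncol(cross$genotypes))
})

test_that("phenotype classes map to causal genotypes under dominance", {
  ph <- data.frame(sample = c("a", "b", "c"),
                   class = c("double_lacing", "pencilling", "intermediate"))
  inf <- infer_causal_genotype(ph)
  expect_identical(inf$inferred, c("het", "hom", NA))
  expect_identical(inf$excluded, c(FALSE, FALSE, TRUE))
  expect_error(infer_causal_genotype(
    data.frame(sample = "x", class = "spotty")), "unknown")
  empty <- infer_causal_genotype(
    data.frame(sample = character(0), class = character(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("recombinant classes match the worked cases", {
  # all het, inferred het: nonrecombinant
  calls <- classify_recombinants(gm_row(1, 1, 1, 1, 1), five_markers,
                                 one_inferred("het"), iv15)
  expect_identical(calls$class, "nonrecombinant")

  # het,het,het,hom,hom with inferred het: single with bracket (30k, 40k)
  calls <- classify_recombinants(gm_row(1, 1, 1, 0, 0), five_markers,
                                 one_inferred("het"), iv15)
  expect_identical(calls$class, "single")
  expect_equal(c(calls$bp_left, calls$bp_right), c(30000, 40000))
  expect_identical(calls$causal_side, "left")

  # pencilling bird het at both flanking markers: the double-recombinant
  # signature of a non-penetrant carrier
  two <- five_markers[c(1, 5), ]
  gm2 <- matrix(c(1L, 1L), nrow = 1, dimnames = list("s1", two$id))
  calls <- classify_recombinants(gm2, two, one_inferred("hom"),
                                 genomic_interval("chr1", 10000, 50000))
  expect_identical(calls$class, "double")

  # a sample with all markers missing is skipped
  gmna <- gm_row(NA, NA, NA, NA, NA)
  expect_message(
    out <- classify_recombinants(gmna, five_markers, one_inferred("het"),
                                 iv15),
    "skipped")
  expect_identical(nrow(out), 0L)
})

test_that("classification agrees with the exhaustive minimal-switch oracle", {
  states <- expand.grid(rep(list(c(0L, 1L, NA)), 5))
  gm <- as.matrix(states)
  rownames(gm) <- sprintf("s%03d", seq_len(nrow(gm)))
  colnames(gm) <- five_markers$id
  for (causal in c("het", "hom")) {
    inferred <- data.frame(sample = rownames(gm), inferred = causal,
                           excluded = FALSE, stringsAsFactors = FALSE)
    calls <- suppressMessages(
      classify_recombinants(gm, five_markers, inferred, iv15))
    for (i in seq_len(nrow(gm))) {
      s <- rownames(gm)[i]
      g <- gm[i, ]
      ok <- !is.na(g)
      row <- calls[calls$sample == s, ]
      if (sum(ok) < 2) {
        expect_identical(nrow(row), 0L)
        next
      }
      exp_n <- oracle_min_switches(ifelse(g[ok] == 1L, "het", "hom"), causal)
      expect_identical(row$n_switches, exp_n)
      exp_class <- c("nonrecombinant", "single", "double")[
        pmin(exp_n, 2L) + 1L]
      if (exp_n > 2) exp_class <- "complex"
      expect_identical(row$class, exp_class)
    }
  }
})

test_that("interval refinement intersects single-recombinant constraints", {
  # affected sample: crossover in (30k,40k), causal on the het (left) side
  gm <- rbind(s1 = c(1L, 1L, 1L, 0L, 0L),
              s2 = c(1L, 1L, 0L, 0L, 0L))
  colnames(gm) <- five_markers$id
  inferred <- data.frame(sample = c("s1", "s2"),
                         inferred = c("het", "hom"),
                         excluded = FALSE, stringsAsFactors = FALSE)
  calls <- classify_recombinants(gm, five_markers, inferred, iv15)
  refined <- refine_interval(calls, iv15)
  expect_equal(c(refined$start, refined$end), c(20000, 40000))

  # monotone: refined within current
  expect_gte(refined$start, iv15$start)
  expect_lte(refined$end, iv15$end)

  # no usable recombinant: interval unchanged
  non <- classify_recombinants(gm_row(1, 1, 1, 1, 1), five_markers,
                               one_inferred("het"), iv15)
  expect_identical(refine_interval(non, iv15), iv15)

  # inconsistent constraints raise an error naming the samples
  gm_bad <- rbind(s1 = c(1L, 1L, 1L, 1L, 0L),
                  s2 = c(1L, 0L, 0L, 0L, 0L))
  colnames(gm_bad) <- five_markers$id
  inferred_bad <- data.frame(sample = c("s1", "s2"),
                             inferred = c("hom", "het"),
                             excluded = FALSE, stringsAsFactors = FALSE)
  calls_bad <- classify_recombinants(gm_bad, five_markers, inferred_bad, iv15)
  expect_error(refine_interval(calls_bad, iv15), "inconsist")

  # restricting to affected-only constraints uses only het-inferred singles
  aff <- refine_interval(calls, iv15, classes = "het")
  expect_equal(c(aff$start, aff$end), c(10000, 40000))
})

test_that("doubles never constrain the interval", {
  two <- five_markers[c(1, 5), ]
  gm2 <- matrix(c(1L, 1L), nrow = 1, dimnames = list("np", two$id))
  inferred <- data.frame(sample = "np", inferred = "hom", excluded = FALSE,
                         stringsAsFactors = FALSE)
  calls <- classify_recombinants(gm2, two, inferred,
                                 genomic_interval("chr1", 10000, 50000))
  expect_identical(calls$class, "double")
  expect_identical(refine_interval(calls, iv15), iv15)
})

test_that("penetrance estimation reproduces the proportions", {
  ph <- function(n_aff, n_tot) {
    data.frame(sample = sprintf("s%d", 1:n_tot),
               class = c(rep("double_lacing", n_aff),
                         rep("pencilling", n_tot - n_aff)))
  }
  est <- estimate_penetrance(rep("het", 62), ph(53, 62))
  expect_equal(est$estimate, 53 / 62)
  expect_identical(round(100 * est$estimate), 85)
  expect_true(est$conf_int["lower"] < 53 / 62 &&
                est$conf_int["upper"] > 53 / 62)

  expect_equal(estimate_penetrance(rep("het", 10), ph(0, 10))$estimate, 0)
  expect_equal(estimate_penetrance(rep("het", 10), ph(10, 10))$estimate, 1)
  expect_error(estimate_penetrance(rep("hom", 5), ph(2, 5)), "no heterozygous")

  # intermediates count as affected
  ph_int <- data.frame(sample = c("a", "b"),
                       class = c("intermediate", "pencilling"))
  expect_equal(estimate_penetrance(c("het", "het"), ph_int)$estimate, 0.5)
})
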