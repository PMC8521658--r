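#' Simulation configuration
#'
#' A single configuration object drives every generator in the package. The
#' defaults describe the study design the pipeline is meant for: a back-cross
#' of 126 females between a line fixed for a dominant pattern allele and a
#' wild-type line, a causal locus with ~85.5% penetrance in heterozygotes,
#' pool sequencing at 30x, and a breed panel of 12 carriers / 82 noncarriers
#' sharing a planted 21.4-kb identical-by-descent segment that contains the
#' causal variant plus 5 partially associated decoy variants.
#'
#' @param seed Integer seed; together with the other fields it fully
#'   determines every sampled value (two runs with equal config are
#'   identical). Generators derive sub-seeds by small documented offsets:
#'   cross +0, pools +1, panel +2, expression +3.
#' @param n_backcross_females Number of back-cross individuals (default 126).
#' @param penetrance P(affected phenotype | heterozygous carrier), default
#'   0.855 (53 affected of 62 genotyped heterozygotes).
#' @param p_intermediate_given_affected Among affected heterozygotes, the
#'   probability of the intermediate (rather than double-lacing) phenotype;
#'   default 10/53.
#' @param p_intermediate_given_hom Probability that a homozygous wild-type
#'   individual is scored intermediate rather than pencilling; default 13/64
#'   so that the default cross reproduces the observed 60/43/23 class split.
#'   Set to 0 for a strictly two-sided misclassification-free model.
#' @param causal_chrom,causal_pos Location of the causal variant (bp,
#'   1-based). Must lie within `chrom_lengths[causal_chrom]`.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param cm_per_mb Uniform genetic-map scale (centimorgan per megabase);
#'   recombination between loci follows the Haldane map function
#'   r = (1 - exp(-2 d / 100)) / 2 for d in cM, no interference.
#' @param n_markers_per_chrom Evenly spaced markers simulated per chromosome.
#' @param include_causal_marker If `TRUE` (default) the causal site itself is
#'   included as a genotyped marker; set `FALSE` to emulate a genotyping
#'   panel that lacks the causal variant.
#' @param pool_depth Read depth per site for pool sequencing (default 30).
#' @param base_error Per-read symmetric error probability epsilon; the
#'   sampled read frequency is p' = p (1 - eps) + (1 - p) eps.
#' @param panel_n_carriers,panel_n_noncarriers Sizes of the whole-genome
#'   carrier panel (defaults 12 and 82).
#' @param panel_n_het_carriers How many of the carriers are heterozygous
#'   (the rest are homozygous carriers); default 2.
#' @param diag_n_carriers,diag_n_noncarriers Sizes of the follow-up
#'   diagnostic genotyping panel (defaults 47 and 54, i.e. 101 samples).
#' @param ibd_segment_length Length in bp of the planted shared descent
#'   segment (default 21,400).
#' @param n_decoy_variants Number of decoy variants planted inside the
#'   descent segment; each decoy's mutant allele also occurs in at least one
#'   noncarrier, so exactly one variant (the causal one) is fully concordant.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_backcross_females = 126L,
                       penetrance = 0.855,
                       p_intermediate_given_affected = 10 / 53,
                       p_intermediate_given_hom = 13 / 64,
                       causal_chrom = "chr1",
                       causal_pos = 93852277,
                       chrom_lengths = c(chr1 = 197e6, chr2 = 149e6,
                                         chr3 = 111e6),
                       cm_per_mb = 3.0,
                       n_markers_per_chrom = 400L,
                       include_causal_marker = TRUE,
                       pool_depth = 30L,
                       base_error = 0.001,
                       panel_n_carriers = 12L,
                       panel_n_noncarriers = 82L,
                       panel_n_het_carriers = 2L,
                       diag_n_carriers = 47L,
                       diag_n_noncarriers = 54L,
                       ibd_segment_length = 21400,
                       n_decoy_variants = 5L) {
  cfg <- list(seed = as.integer(seed),
              n_backcross_females = as.integer(n_backcross_females),
              penetrance = penetrance,
              p_intermediate_given_affected = p_intermediate_given_affected,
              p_intermediate_given_hom = p_intermediate_given_hom,
              causal_chrom = as.character(causal_chrom),
              causal_pos = as.numeric(causal_pos),
              chrom_lengths = chrom_lengths,
              cm_per_mb = cm_per_mb,
              n_markers_per_chrom = as.integer(n_markers_per_chrom),
              include_causal_marker = isTRUE(include_causal_marker),
              pool_depth = as.numeric(pool_depth),
              base_error = base_error,
              panel_n_carriers = as.integer(panel_n_carriers),
              panel_n_noncarriers = as.integer(panel_n_noncarriers),
              panel_n_het_carriers = as.integer(panel_n_het_carriers),
              diag_n_carriers = as.integer(diag_n_carriers),
              diag_n_noncarriers = as.integer(diag_n_noncarriers),
              ibd_segment_length = as.numeric(ibd_segment_length),
              n_decoy_variants = as.integer(n_decoy_variants))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(penetrance = cfg$penetrance,
             p_intermediate_given_affected = cfg$p_intermediate_given_affected,
             p_intermediate_given_hom = cfg$p_intermediate_given_hom,
             base_error = cfg$base_error)
  bad <- probs < 0 | probs > 1 | is.na(probs)
  if (any(bad)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "))
  }
  if (is.null(names(cfg$chrom_lengths)) || any(names(cfg$chrom_lengths) == "")) {
    stop("chrom_lengths must be a named vector")
  }
  if (!cfg$causal_chrom %in% names(cfg$chrom_lengths)) {
    stop("causal_chrom '", cfg$causal_chrom, "' not in chrom_lengths")
  }
  if (cfg$causal_pos < 1 ||
      cfg$causal_pos > cfg$chrom_lengths[[cfg$causal_chrom]]) {
    stop("causal_pos outside its chromosome")
  }
  if (cfg$cm_per_mb < 0) stop("cm_per_mb must be >= 0")
  if (cfg$n_backcross_females < 1) stop("need at least one back-cross female")
  if (cfg$ibd_segment_length >= cfg$chrom_lengths[[cfg$causal_chrom]]) {
    stop("ibd_segment_length must be smaller than the causal chromosome")
  }
  if (cfg$panel_n_het_carriers > cfg$panel_n_carriers) {
    stop("panel_n_het_carriers cannot exceed panel_n_carriers")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | back-cross n = %d | penetrance %.3f\n",
              x$seed, x$n_backcross_females, x$penetrance))
  cat(sprintf("  causal locus %s:%s | %d markers/chrom | %.1f cM/Mb\n",
              x$causal_chrom,
              format(x$causal_pos, big.mark = ","),
              x$n_markers_per_chrom, x$cm_per_mb))
  cat(sprintf("  pools: depth %g, base error %g\n", x$pool_depth, x$base_error))
  cat(sprintf("  panel: %d carriers (%d het) / %d noncarriers; diagnostic %d/%d\n",
              x$panel_n_carriers, x$panel_n_het_carriers,
              x$panel_n_noncarriers, x$diag_n_carriers, x$diag_n_noncarriers))
  cat(sprintf("  planted descent segment %s bp with %d decoys\n",
              format(x$ibd_segment_length, big.mark = ","),
              x$n_decoy_variants))
  invisible(x)
}

# Haldane map function: cM distance -> recombination fraction
haldane_r <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

# marker map for one config: evenly spaced per chromosome, the causal site
# inserted on its chromosome (flagged)
build_marker_map <- function(cfg) {
  maps <- lapply(names(cfg$chrom_lengths), function(ch) {
    len <- cfg$chrom_lengths[[ch]]
    n <- cfg$n_markers_per_chrom
    pos <- round(seq_len(n) * len / (n + 1))
    causal <- ch == cfg$causal_chrom & pos == cfg$causal_pos
    if (ch == cfg$causal_chrom && !any(causal)) {
      pos <- c(pos, cfg$causal_pos)
      causal <- c(causal, TRUE)
      o <- order(pos)
      pos <- pos[o]
      causal <- causal[o]
    }
    keep <- !duplicated(pos)
    data.frame(chrom = ch, pos = pos[keep], is_causal = causal[keep],
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  map$id <- paste0(map$chrom, "_", map$pos)
  map
}

#' Simulate a back-cross mapping population
#'
#' Crosses a carrier line (homozygous for the pattern allele at every marker)
#' with a wild-type line, then back-crosses F1 females to wild-type males.
#' Each offspring inherits one intact wild-type gamete and one F1 gamete
#' whose crossovers follow the Haldane map at `cm_per_mb`; marker genotypes
#' are therefore coded 0 (homozygous wild-type-line) or 1 (heterozygous).
#' Phenotypes are drawn from the true causal genotype: a heterozygote is
#' affected with probability `penetrance` and an affected bird is scored
#' intermediate with probability `p_intermediate_given_affected` (otherwise
#' double lacing); an unaffected heterozygote is scored pencilling. A
#' homozygous wild-type bird is scored intermediate with probability
#' `p_intermediate_given_hom`, otherwise pencilling.
#'
#' @param config A [sim_config()].
#' @return An object of class `cross_sim`: list with `config`, `markers`
#'   (data frame chrom/pos/is_causal/id/ref/alt), `genotypes` (individuals x
#'   markers, 0/1), `phenotypes` (data frame sample/class), `true_causal_genotype`
#'   (`"het"` or `"hom_ref"` per individual), `founders` and `f1_genotypes`.
#' @examples
#' cross <- simulate_cross(sim_config(seed = 7, n_markers_per_chrom = 50))
#' table(cross$phenotypes$class)
#' @export
simulate_cross <- function(config) {
  validate_sim_config(config)
  map <- build_marker_map(config)
  if (!any(map$chrom == config$causal_chrom)) {
    stop("no markers on the causal chromosome; increase n_markers_per_chrom")
  }
  set.seed(config$seed)
  n <- config$n_backcross_females
  # ref allele = wild-type-line allele, alt = carrier-line allele
  map$ref <- sample(c("A", "C", "G", "T"), nrow(map), replace = TRUE)
  map$alt <- vapply(map$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))

  geno <- matrix(0L, nrow = n, ncol = nrow(map))
  # causal genotype bookkeeping even when the causal marker is dropped later
  causal_state <- integer(n)
  for (ch in names(config$chrom_lengths)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos[idx]
    cm <- pos / 1e6 * config$cm_per_mb
    r <- haldane_r(diff(cm))
    state <- matrix(0L, nrow = n, ncol = length(idx))
    state[, 1] <- stats::rbinom(n, 1L, 0.5)
    if (length(idx) > 1) {
      for (j in 2:length(idx)) {
        sw <- stats::rbinom(n, 1L, r[j - 1])
        state[, j] <- bitwXor(state[, j - 1], sw)
      }
    }
    geno[, idx] <- state
    if (ch == config$causal_chrom) {
      causal_state <- state[, which(map$is_causal[idx])]
    }
  }

  het <- causal_state == 1L
  affected <- logical(n)
  affected[het] <- stats::rbinom(sum(het), 1L, config$penetrance) == 1L
  class <- rep("pencilling", n)
  inter_aff <- stats::rbinom(sum(affected), 1L,
                             config$p_intermediate_given_affected) == 1L
  class[affected] <- ifelse(inter_aff, "intermediate", "double_lacing")
  hom_unaff <- !het
  inter_hom <- stats::rbinom(sum(hom_unaff), 1L,
                             config$p_intermediate_given_hom) == 1L
  class[hom_unaff][inter_hom] <- "intermediate"

  samples <- sprintf("bc_%03d", seq_len(n))
  rownames(geno) <- samples
  colnames(geno) <- map$id

  if (!config$include_causal_marker) {
    drop <- which(map$is_causal)
    geno <- geno[, -drop, drop = FALSE]
    map_out <- map[-drop, , drop = FALSE]
  } else {
    map_out <- map
  }
  rownames(map_out) <- NULL

  founders <- list(
    line_carrier = matrix(2L, nrow = 2, ncol = nrow(map_out),
                          dimnames = list(c("carrier_f1", "carrier_f2"),
                                          map_out$id)),
    line_wild = matrix(0L, nrow = 2, ncol = nrow(map_out),
                       dimnames = list(c("wild_f1", "wild_f2"), map_out$id)))
  f1 <- matrix(1L, nrow = 1, ncol = nrow(map_out),
               dimnames = list("f1_01", map_out$id))

  structure(list(config = config,
                 markers = map_out,
                 genotypes = geno,
                 phenotypes = data.frame(sample = samples, class = class,
                                         stringsAsFactors = FALSE),
                 true_causal_genotype = ifelse(het, "het", "hom_ref"),
                 founders = founders,
                 f1_genotypes = f1),
            class = "cross_sim")
}

#' @export
print.cross_sim <- function(x, ...) {
  cat(sprintf("<cross_sim> %d back-cross individuals, %d markers on %d chromosome(s)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$markers$chrom))))
  print(table(x$phenotypes$class))
  invisible(x)
}

# exact wild-type (reference) allele frequency per marker for a pool
pool_exact_ref_freq <- function(cross, members) {
  g <- cross$genotypes[members, , drop = FALSE]
  1 - colMeans(g) / 2
}

pool_members <- function(cross, classes) {
  cross$phenotypes$sample[cross$phenotypes$class %in% classes]
}

#' Exact pool allele-frequency track (no read sampling)
#'
#' Returns, for the pool of individuals in the given phenotype class(es), the
#' exact reference (wild-type-line) allele frequency at every marker: the
#' depth-to-infinity limit of pool sequencing. Useful for theoretical checks
#' such as the 0.5 ceiling on the pool frequency difference in a het-vs-hom
#' back-cross contrast.
#'
#' @param cross A `cross_sim`.
#' @param classes Character vector of phenotype classes forming the pool.
#' @return A `scan_track` with statistic `"raf"`.
#' @export
pool_true_raf <- function(cross, classes) {
  stopifnot(inherits(cross, "cross_sim"))
  members <- pool_members(cross, classes)
  if (length(members) == 0) stop("pool is empty for classes: ",
                                 paste(classes, collapse = ", "))
  new_scan_track(data.frame(chrom = cross$markers$chrom,
                            pos = cross$markers$pos,
                            value = pool_exact_ref_freq(cross, members),
                            stringsAsFactors = FALSE),
                 statistic = "raf")
}

#' Simulate pooled sequencing of two phenotype pools
#'
#' Builds two DNA pools from phenotype classes (by default double lacing vs
#' pencilling; intermediates are excluded) and draws per-site read counts
#' from Binomial(depth, p') where p is the pool's exact reference-allele
#' frequency and p' = p (1 - eps) + (1 - p) eps applies the symmetric base
#' error. No overdispersion term is modelled.
#'
#' @param cross A `cross_sim`.
#' @param classes_a,classes_b Phenotype classes pooled on each side.
#' @param depth Reads per site (> 0).
#' @param base_error Symmetric per-read error probability.
#' @param seed Seed for read sampling; defaults to the cross seed + 1.
#' @return List with elements `pool_a` and `pool_b`, each a `pool_counts`
#'   data frame (chrom, pos, ref, alt, ref_count, alt_count).
#' @export
simulate_pools <- function(cross,
                           classes_a = "double_lacing",
                           classes_b = "pencilling",
                           depth = cross$config$pool_depth,
                           base_error = cross$config$base_error,
                           seed = cross$config$seed + 1L) {
  stopifnot(inherits(cross, "cross_sim"))
  if (depth <= 0) stop("pool depth must be > 0")
  mem_a <- pool_members(cross, classes_a)
  mem_b <- pool_members(cross, classes_b)
  if (length(mem_a) == 0) stop("pool A is empty (classes: ",
                               paste(classes_a, collapse = ","), ")")
  if (length(mem_b) == 0) stop("pool B is empty (classes: ",
                               paste(classes_b, collapse = ","), ")")
  set.seed(seed)
  draw <- function(members) {
    p <- pool_exact_ref_freq(cross, members)
    p_err <- p * (1 - base_error) + (1 - p) * base_error
    ref <- stats::rbinom(length(p), round(depth), p_err)
    data.frame(chrom = cross$markers$chrom,
               pos = cross$markers$pos,
               ref = cross$markers$ref,
               alt = cross$markers$alt,
               ref_count = ref,
               alt_count = round(depth) - ref,
               stringsAsFactors = FALSE)
  }
  list(pool_a = new_pool_counts(draw(mem_a)),
       pool_b = new_pool_counts(draw(mem_b)))
}

#' Simulate a carrier breed panel with a planted descent segment
#'
#' Plants a shared identical-by-descent haplotype of length
#' `ibd_segment_length` centred on the causal position. Inside the segment
#' the panel segregates the causal variant plus `n_decoy_variants` decoys:
#' carriers are homozygous (or heterozygous, for het carriers) for the mutant
#' allele at all of them, but each decoy's mutant allele also appears in at
#' least one noncarrier (heterozygous leaks in the whole-genome panel; for
#' the first decoy additionally one homozygous-mutant noncarrier in the
#' diagnostic panel), so that exactly the causal variant is fully concordant.
#' Variants outside the segment are unstructured noise (independent
#' Hardy-Weinberg draws) and are therefore incompatible with a shared
#' haplotype with high probability.
#'
#' @param config A [sim_config()].
#' @param n_outside_variants Unstructured variants flanking the segment.
#' @param region_flank Flank (bp) on each side of the segment over which
#'   outside variants are placed.
#' @param missing_rate Fraction of missing calls sprinkled over outside
#'   variants (inside-segment calls are kept intact so the planted truth is
#'   exact).
#' @param seed Seed; defaults to the config seed + 2.
#' @return Object of class `panel_sim`: list with `wgs` and `diagnostic`
#'   [carrier_panel()] objects and a `truth` list (planted `segment`
#'   interval, `causal_id`, `decoy_ids`, `hom_leak_decoy`).
#' @export
simulate_panel <- function(config,
                           n_outside_variants = 60L,
                           region_flank = 1e5,
                           missing_rate = 0.01,
                           seed = config$seed + 2L) {
  validate_sim_config(config)
  if (config$panel_n_carriers < 1) stop("need at least one carrier")
  set.seed(seed)
  ch <- config$causal_chrom
  len <- config$ibd_segment_length
  seg_start <- max(1, config$causal_pos - floor((len - 1) / 2))
  seg_end <- seg_start + len - 1
  segment <- genomic_interval(ch, seg_start, seg_end)

  n_decoy <- config$n_decoy_variants
  inside_pos <- config$causal_pos
  if (n_decoy > 0) {
    cand <- setdiff(seq(seg_start, seg_end), config$causal_pos)
    inside_pos <- sort(c(config$causal_pos, sample(cand, n_decoy)))
  }
  lo <- max(1, seg_start - region_flank)
  hi <- seg_end + region_flank
  out_cand <- setdiff(seq(lo, hi), seq(seg_start, seg_end))
  outside_pos <- sort(sample(out_cand, n_outside_variants))
  pos <- sort(c(inside_pos, outside_pos))
  inside <- pos %in% inside_pos
  vid <- ifelse(pos == config$causal_pos, "causal",
                ifelse(inside, "decoy", "bg"))
  vid <- paste0(vid, "_", ch, "_", pos)
  variants <- data.frame(chrom = ch, pos = pos, id = vid,
                         ref = "A", alt = "T", stringsAsFactors = FALSE)
  causal_idx <- which(pos == config$causal_pos)
  decoy_idx <- which(inside & pos != config$causal_pos)

  make_panel <- function(n_hom, n_het, n_non, prefix) {
    status <- c(rep("carrier_hom", n_hom), rep("carrier_het", n_het),
                rep("noncarrier", n_non))
    ids <- sprintf("%s_%03d", prefix, seq_along(status))
    g <- matrix(NA_integer_, nrow = length(status), ncol = nrow(variants),
                dimnames = list(ids, variants$id))
    # unstructured outside variants
    for (j in which(!inside)) {
      maf <- stats::runif(1, 0.1, 0.5)
      g[, j] <- stats::rbinom(length(status), 2L, maf)
    }
    # shared haplotype inside the segment
    for (j in c(causal_idx, decoy_idx)) {
      g[status == "carrier_hom", j] <- 2L
      g[status == "carrier_het", j] <- 1L
      g[status == "noncarrier", j] <- 0L
    }
    if (missing_rate > 0 && any(!inside)) {
      out_cells <- which(!inside[col(g)])
      nmiss <- stats::rbinom(1L, length(out_cells), missing_rate)
      if (nmiss > 0) g[sample(out_cells, nmiss)] <- NA_integer_
    }
    carrier_panel(g, status, variants)
  }

  wgs <- make_panel(config$panel_n_carriers - config$panel_n_het_carriers,
                    config$panel_n_het_carriers,
                    config$panel_n_noncarriers, "wgs")
  diag <- make_panel(0L, config$diag_n_carriers, config$diag_n_noncarriers,
                     "dx")

  # decoy leaks: het noncarriers in the WGS panel for every decoy, plus one
  # homozygous-mutant noncarrier in the diagnostic panel for the first decoy
  wgs_non <- which(wgs$status == "noncarrier")
  dx_non <- which(diag$status == "noncarrier")
  hom_leak <- if (n_decoy > 0) variants$id[decoy_idx[1]] else NA_character_
  for (k in seq_along(decoy_idx)) {
    j <- decoy_idx[k]
    n_leak <- 1L + stats::rbinom(1L, 2L, 0.5)
    wgs$genotypes[sample(wgs_non, n_leak), j] <- 1L
    if (k == 1L) {
      diag$genotypes[sample(dx_non, 1L), j] <- 2L
    } else if (stats::runif(1) < 0.5) {
      diag$genotypes[sample(dx_non, 1L), j] <- 1L
    }
  }

  structure(list(config = config,
                 wgs = wgs,
                 diagnostic = diag,
                 truth = list(segment = segment,
                              causal_id = variants$id[causal_idx],
                              decoy_ids = variants$id[decoy_idx],
                              hom_leak_decoy = hom_leak)),
            class = "panel_sim")
}

#' @export
print.panel_sim <- function(x, ...) {
  cat(sprintf("<panel_sim> WGS panel %d samples, diagnostic panel %d samples, %d variants\n",
              nrow(x$wgs$genotypes), nrow(x$diagnostic$genotypes),
              nrow(x$wgs$variants)))
  cat("planted segment: ", format(x$truth$segment), " (causal ",
      x$truth$causal_id, ", ", length(x$truth$decoy_ids), " decoys)\n",
      sep = "")
  invisible(x)
}

#' Simulate qPCR and allele-peak expression data
#'
#' Generates (a) a cycle-threshold table for a reference gene and two target
#' transcripts separated by a planted Ct difference, with Gaussian replicate
#' noise, and (b) biallelic peak heights for cDNA and genomic DNA from the
#' same individuals, where the cDNA mutant/wild-type ratio is centred on
#' `true_fold_allele_ratio`, the gDNA ratio is centred on 1, and both carry
#' the same allele-specific peak bias (removed by gDNA normalisation) and
#' multiplicative log-normal noise.
#'
#' @param config A [sim_config()] (used for the seed).
#' @param true_fold_allele_ratio True cDNA allelic expression ratio
#'   (mutant over wild-type allele); must be > 0.
#' @param n_individuals Individuals measured (a warning is raised below 2:
#'   the imbalance test needs at least two per template).
#' @param delta_ct Planted Ct difference between the low- and high-expressed
#'   transcript (default 6 cycles).
#' @param ct_sd Gaussian SD of Ct replicates (cycles).
#' @param peak_cv Log-normal SD of multiplicative peak-height noise.
#' @param peak_bias Allele-specific peak-height bias shared by cDNA and gDNA.
#' @param n_replicates qPCR replicates per sample and gene.
#' @param seed Seed; defaults to the config seed + 3.
#' @return Object of class `expression_sim`: list with `ct` (sample, group,
#'   tissue, gene, replicate, ct) and `peaks` (sample, template, marker,
#'   height_m, height_wt) data frames.
#' @export
simulate_expression <- function(config,
                                true_fold_allele_ratio = 5,
                                n_individuals = 3L,
                                delta_ct = 6,
                                ct_sd = 0.15,
                                peak_cv = 0.08,
                                peak_bias = 1.25,
                                n_replicates = 3L,
                                seed = config$seed + 3L) {
  if (true_fold_allele_ratio <= 0) stop("true_fold_allele_ratio must be > 0")
  if (n_individuals < 2) {
    warning("fewer than 2 individuals: the allelic-imbalance test needs >= 2 per template")
  }
  set.seed(seed)
  samples <- sprintf("ind_%02d", seq_len(n_individuals))
  base_ct <- c(ref_gene = 20, transcript_high = 22.9,
               transcript_low = 22.9 + delta_ct)
  ct <- expand.grid(sample = samples, gene = names(base_ct),
                    replicate = seq_len(n_replicates),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ct <- ct[order(ct$sample, ct$gene, ct$replicate), , drop = FALSE]
  noise <- if (ct_sd > 0) stats::rnorm(nrow(ct), 0, ct_sd) else 0
  ct$ct <- base_ct[ct$gene] + noise
  ct$group <- "heterozygote"
  ct$tissue <- "feather_follicle"
  ct <- ct[, c("sample", "group", "tissue", "gene", "replicate", "ct")]
  rownames(ct) <- NULL

  lnoise <- function(n) {
    if (peak_cv > 0) exp(stats::rnorm(n, 0, peak_cv)) else rep(1, n)
  }
  peaks <- do.call(rbind, lapply(samples, function(s) {
    h_g <- 800 * lnoise(1)
    h_c <- 600 * lnoise(1)
    data.frame(sample = s,
               template = c("gDNA", "cDNA"),
               marker = "allele_marker_1",
               height_m = c(h_g * peak_bias * lnoise(1),
                            h_c * peak_bias * true_fold_allele_ratio * lnoise(1)),
               height_wt = c(h_g * lnoise(1), h_c * lnoise(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(peaks) <- NULL
  structure(list(ct = ct, peaks = peaks), class = "expression_sim")
}
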