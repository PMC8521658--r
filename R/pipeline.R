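#' Run the full mapping pipeline on a simulated study
#'
#' Executes the stages in the order the mapping logic requires, each stage
#' feeding the next:
#' \enumerate{
#'   \item simulate the back-cross, pools, carrier panels and expression data;
#'   \item genome scan: pool allele frequencies, absRAFdif, per-site F_ST and
#'     windowed ZF_ST; the top absRAFdif peak defines the candidate region;
#'   \item linkage: recombinant classification inside the (padded) peak
#'     region and interval refinement from single recombinants;
#'   \item IBD: shared-haplotype region among panel carriers inside the
#'     refined interval;
#'   \item concordance: two-stage candidate-variant filter over the IBD
#'     region using the whole-genome and diagnostic panels;
#'   \item expression: delta-delta-Ct relative expression and the
#'     gDNA-normalised allelic-imbalance test.
#' }
#'
#' By default only affected (double-lacing) single recombinants constrain
#' the refinement: with incomplete penetrance an affected phenotype proves
#' carrier status while an unaffected one does not, so pencilling-derived
#' constraints can silently exclude the causal position when a non-penetrant
#' carrier recombines. Set `unaffected_constraints = TRUE` to use both
#' classes.
#'
#' @param config A [sim_config()] (or path to a YAML file readable by
#'   [read_sim_config()]).
#' @param out_dir Optional directory; when given, stage outputs (TSV/BED/
#'   VCF) and a JSON manifest are written there.
#' @param peak_threshold absRAFdif threshold for peak calling (applied to
#'   window means; the genome-wide null mean of the absolute difference at
#'   30x pool depth is about 0.11, the linked-region signal about 0.4).
#' @param peak_window,peak_step Window and step (bp) for averaging the
#'   absRAFdif track before peak calling.
#' @param peak_min_run Minimum run length (windows) for a peak.
#' @param interval_pad Padding (bp) added around the called peak before
#'   recombinant classification.
#' @param unaffected_constraints Logical; include pencilling-derived
#'   constraints in refinement (default `FALSE`).
#' @param zfst_window,zfst_step,zfst_min_sites Windowing for the ZF_ST scan;
#'   defaults are sized to the simulated marker spacing.
#' @return Object of class `melmap_run`: list with the per-stage results
#'   (`cross`, `pools`, `tracks`, `peaks`, `seed_interval`,
#'   `recombinants`, `refined_interval`, `penetrance`, `panel`,
#'   `ibd_region`, `concordance`, `expression`) and a `manifest` list
#'   (config snapshot, seed, stage summaries, output paths).
#' @export
run_pipeline <- function(config,
                         out_dir = NULL,
                         peak_threshold = 0.3,
                         peak_window = 4e6,
                         peak_step = 2e6,
                         peak_min_run = 2L,
                         interval_pad = 6e6,
                         unaffected_constraints = FALSE,
                         zfst_window = 2e6,
                         zfst_step = 1e6,
                         zfst_min_sites = 2L) {
  if (is.character(config)) config <- read_sim_config(config)
  validate_sim_config(config)
  stage_log <- list()
  note <- function(stage, ...) {
    stage_log[[stage]] <<- sprintf(...)
  }

  # 1. simulate
  cross <- simulate_cross(config)
  pools <- simulate_pools(cross)
  panel <- simulate_panel(config)
  expr <- simulate_expression(config)
  note("simulate", "%d back-cross (%s), panel %d+%d samples",
       nrow(cross$genotypes),
       paste(sprintf("%d %s", as.integer(table(cross$phenotypes$class)),
                     names(table(cross$phenotypes$class))), collapse = ", "),
       nrow(panel$wgs$genotypes), nrow(panel$diagnostic$genotypes))

  # 2. scan
  raf_a <- suppressMessages(pool_raf(pools$pool_a))
  raf_b <- suppressMessages(pool_raf(pools$pool_b))
  dif <- abs_raf_dif(raf_a, raf_b)
  fst <- per_site_fst(raf_a, raf_b)
  zf <- windowed_zfst(fst, window = zfst_window, step = zfst_step,
                      min_sites = zfst_min_sites)
  # peak calling on the window-averaged track: read noise at realistic pool
  # depths fragments per-site runs, window means do not
  dif_w <- windowed_mean(dif, window = peak_window, step = peak_step,
                         min_sites = zfst_min_sites)
  peaks <- call_peak_region(dif_w, threshold = peak_threshold,
                            min_run = peak_min_run)
  if (length(peaks) == 0) {
    stop("scan stage: no absRAFdif peak above threshold ", peak_threshold)
  }
  top <- peaks[[1]]
  seed_iv <- genomic_interval(top$chrom,
                              max(1, top$start - interval_pad),
                              min(config$chrom_lengths[[top$chrom]],
                                  top$end + interval_pad))
  note("scan", "top peak %s (absRAFdif %.3f), seed interval %s",
       format(top), attr(top, "peak_value"), format(seed_iv))

  # 3. linkage
  inferred <- infer_causal_genotype(cross$phenotypes)
  calls <- suppressMessages(
    classify_recombinants(cross$genotypes, cross$markers, inferred, seed_iv))
  classes <- if (unaffected_constraints) c("het", "hom") else "het"
  refined <- refine_interval(calls, seed_iv, classes = classes)
  pen <- estimate_penetrance(
    stats::setNames(ifelse(cross$true_causal_genotype == "het", "het", "hom"),
                    cross$phenotypes$sample),
    cross$phenotypes)
  note("linkage", "%d singles, %d doubles; refined interval %s (%.0f bp); penetrance %.3f",
       sum(calls$class == "single"), sum(calls$class == "double"),
       format(refined), interval_length(refined), pen$estimate)

  # 4. IBD
  ibd <- find_ibd_region(panel$wgs, refined)
  note("ibd", "IBD region %s (%d compatible sites)",
       format(ibd), attr(ibd, "n_sites"))

  # 5. concordance
  conc <- suppressMessages(
    diagnostic_concordance(panel$wgs, panel$diagnostic, region = ibd))
  note("concordance", "%d stage-1 / %d stage-2 passer(s): %s",
       sum(conc$stage1_pass), sum(conc$stage2_pass),
       paste(conc$id[conc$stage2_pass], collapse = ", "))

  # 6. expression
  rel <- relative_expression(expr$ct, target = "transcript_high",
                             reference_gene = "ref_gene",
                             reference_sample = expr$ct$sample[1])
  ar <- suppressMessages(allelic_ratio(expr$peaks))
  imb <- suppressMessages(
    allelic_imbalance_test(ar$raw_cdna, ar$raw_gdna))
  note("expression", "allelic imbalance %s, p = %.3g",
       imb$direction, imb$p_value)

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_pool_counts(pools, p("pool_counts.tsv"))
    write_phenotypes(cross$phenotypes, p("phenotypes.tsv"))
    write_genotype_tsv(cross$genotypes, p("backcross_genotypes.tsv"))
    write_scan_track(dif, p("absrafdif.tsv"))
    write_scan_track(zf, p("zfst.tsv"))
    write_bed(peaks, p("peaks.bed"))
    write_bed(refined, p("refined_interval.bed"))
    write_bed(ibd, p("ibd_region.bed"))
    write_vcf_genotypes(panel$wgs$genotypes, panel$wgs$variants,
                        p("panel_wgs.vcf"))
    utils::write.table(as.data.frame(conc), p("concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- list(pool_counts = p("pool_counts.tsv"),
                  phenotypes = p("phenotypes.tsv"),
                  genotypes = p("backcross_genotypes.tsv"),
                  absrafdif = p("absrafdif.tsv"),
                  zfst = p("zfst.tsv"),
                  peaks = p("peaks.bed"),
                  refined_interval = p("refined_interval.bed"),
                  ibd_region = p("ibd_region.bed"),
                  panel_vcf = p("panel_wgs.vcf"),
                  concordance = p("concordance.tsv"))
  }

  manifest <- list(package_version = as.character(utils::packageVersion("melmap")),
                   seed = config$seed,
                   config = unclass(config),
                   stages = stage_log,
                   outputs = paths)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(list(cross = cross, pools = pools,
                 tracks = list(raf_a = raf_a, raf_b = raf_b,
                               absrafdif = dif, fst = fst, zfst = zf),
                 peaks = peaks, seed_interval = seed_iv,
                 recombinants = calls, refined_interval = refined,
                 penetrance = pen, panel = panel, ibd_region = ibd,
                 concordance = conc,
                 expression = list(relative = rel, ratios = ar, test = imb),
                 manifest = manifest),
            class = "melmap_run")
}

#' @export
print.melmap_run <- function(x, ...) {
  cat("<melmap_run>\n")
  for (s in names(x$manifest$stages)) {
    cat(sprintf("  %-12s %s\n", s, x$manifest$stages[[s]]))
  }
  invisible(x)
}
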