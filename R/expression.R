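#' Relative expression by the delta-delta-Ct method
#'
#' Replicate Ct values are averaged per sample and gene; for each sample
#' dCt = mean Ct(target) - mean Ct(reference gene), ddCt = dCt(sample) -
#' dCt(reference sample), and the relative expression is
#' efficiency^(-ddCt), i.e. 1 for the reference sample itself. Samples
#' without a reference-gene measurement are dropped with a message.
#'
#' @param ct Long data frame with columns `sample`, `gene`, `ct` (one row
#'   per replicate; other columns are ignored).
#' @param target Target transcript id (a value of `gene`).
#' @param reference_gene Reference (housekeeping) gene id.
#' @param reference_sample Sample whose expression defines 1.
#' @param efficiency Amplification factor per cycle (> 1; 2 = perfect
#'   doubling, the default).
#' @return Data frame with `sample`, `dct`, `ddct`, `rel_expr`.
#' @export
relative_expression <- function(ct, target, reference_gene, reference_sample,
                                efficiency = 2) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  if (efficiency <= 1) stop("amplification efficiency must be > 1")
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    stop("Ct values must be positive and finite")
  }
  mt <- ct[ct$gene == target, , drop = FALSE]
  mr <- ct[ct$gene == reference_gene, , drop = FALSE]
  if (nrow(mt) == 0) stop("no Ct records for target '", target, "'")
  if (nrow(mr) == 0) stop("no Ct records for reference gene '",
                          reference_gene, "'")
  t_mean <- tapply(mt$ct, mt$sample, mean)
  r_mean <- tapply(mr$ct, mr$sample, mean)
  samples <- names(t_mean)
  no_ref <- setdiff(samples, names(r_mean))
  if (length(no_ref)) {
    message(length(no_ref),
            " sample(s) dropped (no reference-gene measurement): ",
            paste(no_ref, collapse = ", "))
    samples <- setdiff(samples, no_ref)
  }
  if (!reference_sample %in% samples) {
    stop("reference sample '", reference_sample,
         "' has no usable measurements")
  }
  dct <- t_mean[samples] - r_mean[samples]
  ddct <- dct - dct[[reference_sample]]
  data.frame(sample = samples,
             dct = as.numeric(dct),
             ddct = as.numeric(ddct),
             rel_expr = efficiency^(-as.numeric(ddct)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fold change between two transcripts from raw Ct values
#'
#' fold = efficiency^(ct_low_expr - ct_high_expr): how many times more
#' abundant the highly expressed transcript is than the lowly expressed one,
#' given their Ct values in the same sample. Example: Ct 28.9 vs 22.9 at
#' efficiency 2 gives 2^6 = 64-fold.
#'
#' @param ct_low_expr Ct of the lowly expressed transcript (larger Ct).
#' @param ct_high_expr Ct of the highly expressed transcript.
#' @param efficiency Amplification factor per cycle (> 1).
#' @return Fold difference (numeric).
#' @export
fold_change_from_ct <- function(ct_low_expr, ct_high_expr, efficiency = 2) {
  if (efficiency <= 1) stop("amplification efficiency must be > 1")
  efficiency^(ct_low_expr - ct_high_expr)
}

#' Allelic expression ratios normalised against genomic DNA
#'
#' Per sample and marker, the raw ratio mutant/wild-type peak height is
#' computed for the cDNA and the gDNA template; the normalised ratio is
#' raw(cDNA) / raw(gDNA). Since a heterozygote's gDNA carries the two
#' alleles 1:1, the gDNA ratio measures pure allele-specific peak bias and
#' dividing by it removes that bias. Samples lacking either template are
#' excluded with a message.
#'
#' @param peaks Data frame with columns `sample`, `template` (`"cDNA"` /
#'   `"gDNA"`), `marker`, `height_m`, `height_wt` (both > 0).
#' @return Data frame with `sample`, `marker`, `raw_cdna`, `raw_gdna`,
#'   `ratio` (normalised).
#' @export
allelic_ratio <- function(peaks) {
  req <- c("sample", "template", "marker", "height_m", "height_wt")
  stopifnot(all(req %in% names(peaks)))
  if (any(peaks$height_m <= 0 | peaks$height_wt <= 0)) {
    stop("peak heights must be > 0")
  }
  peaks$raw <- peaks$height_m / peaks$height_wt
  key <- function(tmpl) {
    sub <- peaks[peaks$template == tmpl, , drop = FALSE]
    stats::setNames(sub$raw, paste(sub$sample, sub$marker))
  }
  cd <- key("cDNA")
  gd <- key("gDNA")
  shared <- intersect(names(cd), names(gd))
  dropped <- setdiff(union(names(cd), names(gd)), shared)
  if (length(dropped)) {
    message(length(dropped),
            " sample/marker record(s) excluded (missing template partner)")
  }
  parts <- do.call(rbind, strsplit(shared, " ", fixed = TRUE))
  out <- data.frame(sample = parts[, 1], marker = parts[, 2],
                    raw_cdna = as.numeric(cd[shared]),
                    raw_gdna = as.numeric(gd[shared]),
                    stringsAsFactors = FALSE)
  out$ratio <- out$raw_cdna / out$raw_gdna
  out[order(out$sample, out$marker), , drop = FALSE]
}

#' Test for allelic imbalance
#'
#' Welch two-sample t test comparing log2 raw peak ratios between cDNA and
#' gDNA templates. Under the null (no cis effect) both log-ratios are centred
#' on the same allele-specific peak bias, so any shift measures allelic
#' imbalance; the log scale makes x-fold up and x-fold down symmetric. If
#' both groups have zero variance and equal means, p = 1 is returned with a
#' message (and p = 0 if the constant means differ).
#'
#' @param cdna_ratios,gdna_ratios Numeric vectors of raw (not normalised)
#'   mutant/wild-type ratios per sample, >= 2 values each.
#' @return Object of class `imbalance_test`: list with `t`, `df`, `p_value`,
#'   `direction` (`"up"`, `"down"` or `"none"` for the mutant allele) and
#'   `log2_shift` (mean log2 cDNA - mean log2 gDNA).
#' @export
allelic_imbalance_test <- function(cdna_ratios, gdna_ratios) {
  if (length(cdna_ratios) < 2 || length(gdna_ratios) < 2) {
    stop("need >= 2 samples per template class")
  }
  if (any(c(cdna_ratios, gdna_ratios) <= 0)) stop("ratios must be > 0")
  lc <- log2(cdna_ratios)
  lg <- log2(gdna_ratios)
  shift <- mean(lc) - mean(lg)
  if (stats::sd(lc) == 0 && stats::sd(lg) == 0) {
    if (shift == 0) {
      message("zero variance in both groups with equal means; p = 1")
      res <- list(t = 0, df = NA_real_, p_value = 1, direction = "none",
                  log2_shift = 0)
    } else {
      res <- list(t = sign(shift) * Inf, df = NA_real_, p_value = 0,
                  direction = if (shift > 0) "up" else "down",
                  log2_shift = shift)
    }
    return(structure(res, class = "imbalance_test"))
  }
  ht <- stats::t.test(lc, lg, var.equal = FALSE)
  direction <- if (ht$p.value < 1 && shift > 0) "up"
    else if (ht$p.value < 1 && shift < 0) "down" else "none"
  if (shift == 0) direction <- "none"
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, direction = direction,
                 log2_shift = shift),
            class = "imbalance_test")
}

#' @export
print.imbalance_test <- function(x, ...) {
  cat(sprintf(
    "Allelic imbalance (Welch t on log2 ratios): t = %.3f, df = %.2f, p = %.4g\n",
    x$t, x$df, x$p_value))
  cat(sprintf("  mutant-allele direction: %s (log2 shift %.3f, ~%.2f-fold)\n",
              x$direction, x$log2_shift, 2^x$log2_shift))
  invisible(x)
}
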