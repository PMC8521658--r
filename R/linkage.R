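#' Select markers fixed for different alleles in the parental lines
#'
#' A marker is informative for back-cross mapping when one line's founders
#' are all homozygous carrier (code 2) and the other line's are all
#' homozygous wild-type (code 0). Missing founder genotypes are tolerated as
#' long as the remaining founders are fixed.
#'
#' @param founders_line1,founders_line2 Founder genotype matrices
#'   (individuals x markers, codes 0/1/2/NA) with identical marker columns.
#' @return Data frame with `marker` and `orientation` (`"line1_carrier"` or
#'   `"line2_carrier"`) for every informative marker.
#' @export
select_informative_markers <- function(founders_line1, founders_line2) {
  if (nrow(founders_line1) < 1 || nrow(founders_line2) < 1) {
    stop("need at least one founder per line")
  }
  stopifnot(identical(colnames(founders_line1), colnames(founders_line2)))
  fixed_at <- function(m, code) {
    ok <- !is.na(m) & m == code
    colSums(ok | is.na(m)) == nrow(m) & colSums(!is.na(m)) > 0
  }
  l1_carrier <- fixed_at(founders_line1, 2L) & fixed_at(founders_line2, 0L)
  l2_carrier <- fixed_at(founders_line1, 0L) & fixed_at(founders_line2, 2L)
  keep <- l1_carrier | l2_carrier
  if (!any(keep)) stop("no informative marker: no marker is fixed for different alleles")
  data.frame(marker = colnames(founders_line1)[keep],
             orientation = ifelse(l1_carrier[keep], "line1_carrier",
                                  "line2_carrier"),
             stringsAsFactors = FALSE)
}

#' Infer the causal genotype from the phenotype
#'
#' Under the dominant model with no reverse misclassification between the
#' clear classes: double lacing implies heterozygous carrier, pencilling
#' implies homozygous wild-type, and intermediate birds are excluded from
#' mapping (they are neither pooled nor used as clear classes).
#'
#' @param phenotypes Data frame with columns `sample` and `class`
#'   (`"pencilling"`, `"intermediate"`, `"double_lacing"`).
#' @return Data frame with `sample`, `inferred` (`"het"`, `"hom"` or NA) and
#'   `excluded` (logical, TRUE for intermediates).
#' @export
infer_causal_genotype <- function(phenotypes) {
  stopifnot(all(c("sample", "class") %in% names(phenotypes)))
  known <- c("pencilling", "intermediate", "double_lacing")
  bad <- setdiff(unique(phenotypes$class), known)
  if (length(bad)) stop("unknown phenotype class: ", paste(bad, collapse = ", "))
  inferred <- ifelse(phenotypes$class == "double_lacing", "het",
                     ifelse(phenotypes$class == "pencilling", "hom",
                            NA_character_))
  data.frame(sample = phenotypes$sample,
             inferred = inferred,
             excluded = phenotypes$class == "intermediate",
             stringsAsFactors = FALSE)
}

# minimal number of haplotype-state switches when the causal state `c` is
# inserted strictly between two adjacent observed markers
min_switches_with_causal <- function(states, causal) {
  m <- length(states)
  if (m < 2) return(NA_integer_)
  s0 <- sum(states[-1] != states[-m])
  best <- Inf
  for (k in 1:(m - 1)) {
    val <- s0 - (states[k] != states[k + 1]) +
      (states[k] != causal) + (causal != states[k + 1])
    if (val < best) best <- val
  }
  as.integer(best)
}

#' Classify back-cross recombinants against the phenotype-inferred genotype
#'
#' For each sample, the ordered marker genotypes inside `interval` are read
#' as haplotype states of the F1 gamete (het = carrier segment, hom =
#' wild-type segment). The phenotype-inferred causal genotype must sit
#' somewhere strictly between the flanking markers; the class is the minimal
#' number of state switches the full sequence then requires: 0 =
#' nonrecombinant, 1 = single, 2 = double, more = complex. A sample het at
#' every marker but phenotypically wild-type is therefore a "double
#' recombinant" -- over a short interval the far more likely reading is a
#' non-penetrant heterozygote, which is why doubles are excluded from
#' interval refinement.
#'
#' @param gm Back-cross genotype matrix (samples x markers, codes 0/1/NA).
#'   Column names must match `markers$id`.
#' @param markers Data frame with `id`, `chrom`, `pos` for the matrix columns.
#' @param inferred Output of [infer_causal_genotype()].
#' @param interval `genomic_interval` to scan (markers inside it are used).
#' @return Data frame of class `recombinant_calls`: sample, inferred, class,
#'   n_switches, and for singles the breakpoint bracket (`bp_left`,
#'   `bp_right`) plus `causal_side` (`"left"`/`"right"`). Samples with fewer
#'   than two non-missing markers, or excluded/unknown phenotypes, are
#'   dropped with a message.
#' @export
classify_recombinants <- function(gm, markers, inferred, interval) {
  stopifnot(inherits(interval, "genomic_interval"))
  idx <- which(markers$chrom == interval$chrom &
                 markers$pos >= interval$start &
                 markers$pos <= interval$end)
  if (length(idx) < 2) stop("need >= 2 informative markers inside the interval")
  idx <- idx[order(markers$pos[idx])]
  pos <- markers$pos[idx]
  cols <- match(markers$id[idx], colnames(gm))
  pos <- pos[!is.na(cols)]
  cols <- cols[!is.na(cols)]
  if (length(cols) < 2) stop("need >= 2 genotyped markers inside the interval")
  use <- inferred[!inferred$excluded & !is.na(inferred$inferred), , drop = FALSE]
  dropped <- 0L
  rows <- lapply(seq_len(nrow(use)), function(i) {
    s <- use$sample[i]
    g <- gm[s, cols]
    ok <- !is.na(g)
    if (sum(ok) < 2) return(NULL)
    states <- ifelse(g[ok] == 1L, "het", "hom")
    p <- pos[ok]
    causal <- ifelse(use$inferred[i] == "het", "het", "hom")
    nsw <- min_switches_with_causal(states, causal)
    cls <- if (nsw == 0) "nonrecombinant" else if (nsw == 1) "single"
      else if (nsw == 2) "double" else "complex"
    bp_left <- bp_right <- NA_real_
    side <- NA_character_
    if (cls == "single") {
      # a single has exactly one observed switch; its bracket localises the
      # crossover and the causal allele lies on the side matching `causal`
      sw <- which(states[-1] != states[-length(states)])
      bp_left <- p[sw]
      bp_right <- p[sw + 1]
      side <- if (states[sw] == causal) "left" else "right"
    }
    data.frame(sample = s, inferred = use$inferred[i], class = cls,
               n_switches = nsw, bp_left = bp_left, bp_right = bp_right,
               causal_side = side, stringsAsFactors = FALSE)
  })
  n_null <- sum(vapply(rows, is.null, logical(1)))
  if (n_null > 0) message(n_null, " sample(s) skipped (insufficient genotypes)")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(sample = character(0),
                                      inferred = character(0),
                                      class = character(0),
                                      n_switches = integer(0),
                                      bp_left = numeric(0),
                                      bp_right = numeric(0),
                                      causal_side = character(0))
  class(out) <- c("recombinant_calls", "data.frame")
  out
}

#' @export
print.recombinant_calls <- function(x, ...) {
  cat("<recombinant_calls>\n")
  print(table(class = x$class, inferred = x$inferred))
  invisible(x)
}

#' Refine a candidate interval from single recombinants
#'
#' Every single recombinant constrains the causal position to the side of
#' its crossover bracket that matches its inferred causal genotype; the
#' constraint is closed at the far bracket marker (the reported interval
#' includes both boundary markers, mirroring how marker-defined endpoints
#' are reported). The result is the intersection of all constraints with
#' `current`. Double recombinants never contribute: over a short interval
#' they are read as phenotype misclassification (non-penetrant carriers),
#' not as two crossovers.
#'
#' @param calls A `recombinant_calls` data frame.
#' @param current `genomic_interval` to refine.
#' @param classes Which inferred genotypes may contribute constraints;
#'   default both `"het"` and `"hom"`. Restricting to `"het"`
#'   (affected-only) makes every constraint immune to non-penetrance, since
#'   an affected phenotype proves carrier status while an unaffected one
#'   does not.
#' @return The refined `genomic_interval` (always a subset of `current`);
#'   `current` unchanged when no usable single recombinant exists. Errors,
#'   naming the conflicting samples, if the constraints are inconsistent.
#' @export
refine_interval <- function(calls, current, classes = c("het", "hom")) {
  stopifnot(inherits(current, "genomic_interval"))
  singles <- calls[calls$class == "single" & calls$inferred %in% classes, ,
                   drop = FALSE]
  if (nrow(singles) == 0) return(current)
  start <- current$start
  end <- current$end
  lower_by <- upper_by <- character(0)
  for (i in seq_len(nrow(singles))) {
    if (singles$causal_side[i] == "left") {
      if (singles$bp_right[i] < end) end <- singles$bp_right[i]
      upper_by <- c(upper_by, singles$sample[i])
    } else {
      if (singles$bp_left[i] > start) start <- singles$bp_left[i]
      lower_by <- c(lower_by, singles$sample[i])
    }
  }
  if (start > end) {
    stop("recombinant constraints are inconsistent (empty interval); ",
         "conflicting samples: ",
         paste(unique(c(lower_by, upper_by)), collapse = ", "))
  }
  genomic_interval(current$chrom, start, end)
}

#' Estimate penetrance among genotyped carriers
#'
#' Penetrance is the fraction of heterozygous carriers (established by a
#' diagnostic marker) whose phenotype shows any effect of the allele, i.e.
#' double lacing or intermediate. A Wilson score 95% confidence interval is
#' attached. The canonical worked example: 53 affected of 62 heterozygotes
#' gives 0.855, reported as 85% to the nearest percent.
#'
#' @param carrier_genotype Named character vector (`"het"`/`"hom"`, names =
#'   sample ids) from a diagnostic marker, or an unnamed vector aligned with
#'   `phenotypes` rows.
#' @param phenotypes Data frame with `sample` and `class`.
#' @param conf_level Confidence level for the Wilson interval.
#' @return Object of class `penetrance_est`: list with `estimate`,
#'   `n_affected`, `n_het`, `conf_int`, `conf_level`.
#' @export
estimate_penetrance <- function(carrier_genotype, phenotypes,
                                conf_level = 0.95) {
  if (!is.null(names(carrier_genotype))) {
    carrier_genotype <- carrier_genotype[phenotypes$sample]
  }
  stopifnot(length(carrier_genotype) == nrow(phenotypes))
  het <- !is.na(carrier_genotype) & carrier_genotype == "het"
  n_het <- sum(het)
  if (n_het == 0) stop("no heterozygous carriers among the genotyped samples")
  affected <- phenotypes$class %in% c("double_lacing", "intermediate")
  k <- sum(affected & het)
  est <- k / n_het
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  centre <- (est + z^2 / (2 * n_het)) / (1 + z^2 / n_het)
  half <- z * sqrt(est * (1 - est) / n_het + z^2 / (4 * n_het^2)) /
    (1 + z^2 / n_het)
  structure(list(estimate = est, n_affected = k, n_het = n_het,
                 conf_int = c(lower = max(0, centre - half),
                              upper = min(1, centre + half)),
                 conf_level = conf_level),
            class = "penetrance_est")
}

#' @export
print.penetrance_est <- function(x, ...) {
  cat(sprintf("Penetrance: %.4f (%d of %d carriers affected), %.0f%% CI [%.4f, %.4f]\n",
              x$estimate, x$n_affected, x$n_het, 100 * x$conf_level,
              x$conf_int["lower"], x$conf_int["upper"]))
  invisible(x)
}
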