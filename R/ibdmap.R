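#' Carrier panel
#'
#' A genotyped sample panel with known carrier status per sample. Statuses
#' are inputs (from pedigree or phenotype), never inferred here. Genotypes
#' are coded 0 = homozygous wild-type, 1 = heterozygous, 2 = homozygous
#' mutant, NA = no call.
#'
#' @param genotypes Integer matrix, samples x variants, codes 0/1/2/NA.
#' @param status Character vector per sample: `"carrier_hom"`,
#'   `"carrier_het"` or `"noncarrier"`.
#' @param variants Data frame with columns `chrom`, `pos`, `id` (and
#'   optionally `ref`, `alt`) describing the matrix columns; positions must
#'   be sorted within chromosome.
#' @return An object of class `carrier_panel`.
#' @export
carrier_panel <- function(genotypes, status, variants) {
  stopifnot(is.matrix(genotypes))
  allowed <- c("carrier_hom", "carrier_het", "noncarrier")
  if (length(status) != nrow(genotypes)) {
    stop("one status per sample required")
  }
  bad <- setdiff(unique(status), allowed)
  if (length(bad)) stop("unknown carrier status: ", paste(bad, collapse = ", "))
  stopifnot(all(c("chrom", "pos", "id") %in% names(variants)),
            nrow(variants) == ncol(genotypes))
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p)) stop("variant positions must be sorted within ", ch)
  }
  ok <- is.na(genotypes) | genotypes %in% 0:2
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA")
  colnames(genotypes) <- variants$id
  structure(list(genotypes = genotypes, status = status, variants = variants),
            class = "carrier_panel")
}

#' @export
print.carrier_panel <- function(x, ...) {
  cat(sprintf("<carrier_panel> %d samples (%s), %d variants\n",
              nrow(x$genotypes),
              paste(sprintf("%d %s", as.integer(table(x$status)),
                            names(table(x$status))), collapse = ", "),
              ncol(x$genotypes)))
  invisible(x)
}

#' Combine two carrier panels over their shared variant set
#'
#' @param a,b `carrier_panel` objects; variants are matched by id, and the
#'   intersection (in `a`'s order) is used.
#' @return A `carrier_panel` with the samples of both panels.
#' @export
combine_panels <- function(a, b) {
  stopifnot(inherits(a, "carrier_panel"), inherits(b, "carrier_panel"))
  shared <- intersect(a$variants$id, b$variants$id)
  if (length(shared) == 0) stop("panels share no variants")
  ia <- match(shared, a$variants$id)
  ib <- match(shared, b$variants$id)
  carrier_panel(rbind(a$genotypes[, ia, drop = FALSE],
                      b$genotypes[, ib, drop = FALSE]),
                c(a$status, b$status),
                a$variants[ia, , drop = FALSE])
}

# A site is compatible with a shared descent haplotype iff some allele can
# be carried by every carrier: homozygous carriers must be homozygous for
# it, het carriers must carry at least one copy; missing calls never veto.
site_compatible <- function(g, status) {
  hom <- g[status == "carrier_hom"]
  het <- g[status == "carrier_het"]
  for (allele in c(0L, 2L)) {  # 2 = mutant allele hom code, 0 = wild-type
    hom_ok <- all(is.na(hom) | hom == allele)
    het_ok <- if (allele == 2L) {
      all(is.na(het) | het >= 1L)
    } else {
      all(is.na(het) | het <= 1L)
    }
    if (hom_ok && het_ok) return(TRUE)
  }
  FALSE
}

# count of samples whose genotype matches the perfect carrier/noncarrier
# pattern for the mutant allele (missing calls count as matches)
site_association_score <- function(g, status) {
  match_ok <- is.na(g) |
    (status == "carrier_hom" & g == 2L) |
    (status == "carrier_het" & g >= 1L) |
    (status == "noncarrier" & g < 2L)
  sum(match_ok)
}

#' Find the shared identical-by-descent region of a carrier panel
#'
#' Scans the variants of `panel` inside `seed_interval` for sites compatible
#' with a haplotype shared by every carrier (homozygous carriers homozygous
#' for one allele, het carriers carrying at least one copy; missing calls
#' are compatible -- allele sharing is assessed without phasing). The region
#' returned is the maximal run of compatible sites containing the
#' most-associated site, reported as the inclusive span from its first to
#' its last compatible site. Runs may tolerate up to `max_conflicts`
#' isolated incompatible sites (default 0, since clean panels should need
#' none; real panels contain genotyping errors).
#'
#' @param panel A [carrier_panel()] with at least two carriers.
#' @param seed_interval `genomic_interval` to scan within.
#' @param max_conflicts Incompatible sites tolerated inside the run.
#' @return A `genomic_interval` with attributes `n_sites` (compatible sites
#'   in the run), `n_conflicts` (tolerated conflicts), `anchor_id` (the
#'   most-associated variant) and `runs` (data frame of all maximal runs,
#'   leftmost first).
#' @export
find_ibd_region <- function(panel, seed_interval, max_conflicts = 0L) {
  stopifnot(inherits(panel, "carrier_panel"),
            inherits(seed_interval, "genomic_interval"))
  if (sum(panel$status != "noncarrier") < 2) {
    stop("need at least two carrier samples")
  }
  idx <- which(panel$variants$chrom == seed_interval$chrom &
                 panel$variants$pos >= seed_interval$start &
                 panel$variants$pos <= seed_interval$end)
  if (length(idx) == 0) stop("no variants inside the seed interval")
  idx <- idx[order(panel$variants$pos[idx])]
  g <- panel$genotypes[, idx, drop = FALSE]
  comp <- vapply(seq_along(idx), function(j)
    site_compatible(g[, j], panel$status), logical(1))
  if (!any(comp)) stop("no site is compatible with a shared carrier haplotype")
  score <- vapply(seq_along(idx), function(j)
    site_association_score(g[, j], panel$status), numeric(1))
  score[!comp] <- -Inf
  anchor <- which.max(score)  # ties: leftmost

  # all maximal stretches [i, j] with compatible endpoints and at most
  # max_conflicts incompatible interior sites (O(n^2), panels are small)
  n <- length(idx)
  bad_cum <- c(0L, cumsum(!comp))
  runs <- lapply(which(comp), function(i) {
    best_j <- i
    for (j in seq(i, n)) {
      if (!comp[j]) next
      if (bad_cum[j + 1L] - bad_cum[i] <= max_conflicts) best_j <- j else break
    }
    c(i, best_j)
  })
  # keep maximal runs only
  runs_df <- unique(do.call(rbind, lapply(runs, function(r)
    data.frame(from = r[1], to = r[2]))))
  keep <- vapply(seq_len(nrow(runs_df)), function(k) {
    !any(runs_df$from <= runs_df$from[k] & runs_df$to >= runs_df$to[k] &
           seq_len(nrow(runs_df)) != k)
  }, logical(1))
  runs_df <- runs_df[keep, , drop = FALSE]
  runs_df <- runs_df[order(runs_df$from), , drop = FALSE]

  hit <- which(runs_df$from <= anchor & runs_df$to >= anchor)
  if (length(hit) == 0) {
    # anchor is always compatible, so it is inside some run; guard anyway
    hit <- 1L
  }
  # longest run containing the anchor; ties broken leftmost
  hit <- hit[order(-(runs_df$to[hit] - runs_df$from[hit]), runs_df$from[hit])]
  span <- runs_df[hit[1], ]
  pos <- panel$variants$pos[idx]
  iv <- genomic_interval(seed_interval$chrom, pos[span$from], pos[span$to])
  attr(iv, "n_sites") <- sum(comp[span$from:span$to])
  attr(iv, "n_conflicts") <- sum(!comp[span$from:span$to])
  attr(iv, "anchor_id") <- panel$variants$id[idx[anchor]]
  runs_df$start <- pos[runs_df$from]
  runs_df$end <- pos[runs_df$to]
  attr(iv, "runs") <- runs_df[, c("start", "end")]
  iv
}

#' Stage-1 association filter for candidate variants
#'
#' A variant passes stage 1 (full association in the whole-genome panel)
#' iff every homozygous carrier is homozygous mutant, every het carrier
#' carries the mutant allele (het or homozygous mutant), and no noncarrier
#' is homozygous mutant. Missing genotypes never veto. Variants flagged as
#' multi-allelic in `panel$variants$multiallelic` are skipped with a
#' message.
#'
#' @param panel A [carrier_panel()].
#' @param region Optional `genomic_interval`; only variants inside it are
#'   classified (default: all).
#' @return Data frame of class `variant_classification`: id, chrom, pos,
#'   stage1_pass, failure_reason.
#' @export
classify_variant_association <- function(panel, region = NULL) {
  stopifnot(inherits(panel, "carrier_panel"))
  v <- panel$variants
  take <- seq_len(nrow(v))
  if (!is.null(region)) {
    stopifnot(inherits(region, "genomic_interval"))
    take <- which(v$chrom == region$chrom & v$pos >= region$start &
                    v$pos <= region$end)
  }
  if ("multiallelic" %in% names(v)) {
    skip <- take[v$multiallelic[take] %in% TRUE]
    if (length(skip)) {
      message(length(skip), " multi-allelic variant(s) skipped")
      take <- setdiff(take, skip)
    }
  }
  status <- panel$status
  rows <- lapply(take, function(j) {
    g <- panel$genotypes[, j]
    reasons <- character(0)
    if (any(status == "carrier_hom" & !is.na(g) & g != 2L)) {
      reasons <- c(reasons, "carrier_hom not homozygous mutant")
    }
    if (any(status == "carrier_het" & !is.na(g) & g < 1L)) {
      reasons <- c(reasons, "carrier_het lacks the mutant allele")
    }
    n_hom_non <- sum(status == "noncarrier" & !is.na(g) & g == 2L)
    if (n_hom_non > 0) {
      reasons <- c(reasons,
                   sprintf("mutant homozygote in %d noncarrier(s)", n_hom_non))
    }
    data.frame(id = v$id[j], chrom = v$chrom[j], pos = v$pos[j],
               stage1_pass = length(reasons) == 0,
               failure_reason = paste(reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("variant_classification", "data.frame")
  out
}

#' Stage-2 diagnostic concordance filter
#'
#' Stage 2 requires, on top of a stage-1 pass in the whole-genome panel,
#' that the mutant allele is entirely absent (no het, no hom) from every
#' noncarrier across both the whole-genome and the diagnostic panels. The
#' output is sorted with passers first. Variants absent from the diagnostic
#' panel are evaluated on the available data and flagged.
#'
#' @param panel Whole-genome [carrier_panel()] (stage-1 evidence).
#' @param diagnostic Follow-up [carrier_panel()] typed for (a subset of) the
#'   same variants.
#' @param region Optional `genomic_interval` restriction, as in
#'   [classify_variant_association()].
#' @return Data frame of class `variant_classification`: id, chrom, pos,
#'   stage1_pass, stage2_pass, in_diagnostic, failure_reason.
#' @export
diagnostic_concordance <- function(panel, diagnostic, region = NULL) {
  stopifnot(inherits(diagnostic, "carrier_panel"))
  s1 <- classify_variant_association(panel, region)
  in_dx <- s1$id %in% diagnostic$variants$id
  if (any(!in_dx)) {
    message(sum(!in_dx),
            " variant(s) absent from the diagnostic panel; stage 2 evaluated on available data")
  }
  mutant_noncarrier <- function(p, id) {
    j <- match(id, p$variants$id)
    if (is.na(j)) return(0L)
    g <- p$genotypes[, j]
    sum(p$status == "noncarrier" & !is.na(g) & g >= 1L)
  }
  s1$stage2_pass <- FALSE
  s1$in_diagnostic <- in_dx
  for (i in seq_len(nrow(s1))) {
    n_leak <- mutant_noncarrier(panel, s1$id[i]) +
      mutant_noncarrier(diagnostic, s1$id[i])
    if (s1$stage1_pass[i] && n_leak == 0) {
      s1$stage2_pass[i] <- TRUE
    } else if (s1$stage1_pass[i] && n_leak > 0) {
      s1$failure_reason[i] <- sprintf(
        "mutant allele present in %d noncarrier(s) across panels", n_leak)
    }
  }
  out <- s1[order(!s1$stage2_pass, !s1$stage1_pass, s1$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_classification", "data.frame")
  out[, c("id", "chrom", "pos", "stage1_pass", "stage2_pass",
          "in_diagnostic", "failure_reason")]
}

#' @export
print.variant_classification <- function(x, ...) {
  cat(sprintf("<variant_classification> %d variants, %d stage-1 pass",
              nrow(x), sum(x$stage1_pass)))
  if ("stage2_pass" %in% names(x)) {
    cat(sprintf(", %d stage-2 pass", sum(x$stage2_pass)))
  }
  cat("\n")
  print.data.frame(x)
  invisible(x)
}
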