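#' Write intervals as BED
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention: `start_bed = start - 1`, `end_bed = end`. The
#' round trip through [read_bed()] restores the coordinates exactly.
#'
#' @param intervals A `genomic_interval` or list of them.
#' @param path Output file.
#' @export
write_bed <- function(intervals, path) {
  if (inherits(intervals, "genomic_interval")) intervals <- list(intervals)
  lines <- vapply(intervals, function(iv) {
    stopifnot(inherits(iv, "genomic_interval"))
    if (iv$start < 1) stop("BED export requires start >= 1")
    sprintf("%s\t%.0f\t%.0f", iv$chrom, iv$start - 1, iv$end)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file into 1-based inclusive intervals
#'
#' @param path BED file (first three columns used).
#' @return List of `genomic_interval`s.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    genomic_interval(df[i, 1], df[i, 2] + 1, df[i, 3]))
}

#' Write a pair of pool count tables to TSV
#'
#' Columns: chrom, pos, ref, alt, refN_poolA, altN_poolA, refN_poolB,
#' altN_poolB. Pools must cover the same site list.
#'
#' @param pools List with elements `pool_a` and `pool_b` (`pool_counts`).
#' @param path Output TSV.
#' @export
write_pool_counts <- function(pools, path) {
  a <- pools$pool_a
  b <- pools$pool_b
  stopifnot(identical(a$pos, b$pos), identical(a$chrom, b$chrom))
  df <- data.frame(chrom = a$chrom, pos = a$pos, ref = a$ref, alt = a$alt,
                   refN_poolA = a$ref_count, altN_poolA = a$alt_count,
                   refN_poolB = b$ref_count, altN_poolB = b$alt_count)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pool count TSV written by [write_pool_counts()]
#'
#' @param path Input TSV.
#' @return List with `pool_a` and `pool_b` `pool_counts` tables.
#' @export
read_pool_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  mk <- function(rc, ac) new_pool_counts(
    data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
               ref_count = df[[rc]], alt_count = df[[ac]],
               stringsAsFactors = FALSE))
  list(pool_a = mk("refN_poolA", "altN_poolA"),
       pool_b = mk("refN_poolB", "altN_poolB"))
}

#' Write a scan track to TSV or BEDGRAPH
#'
#' @param track A `scan_track`.
#' @param path Output file.
#' @param format `"tsv"` (all columns, 1-based) or `"bedgraph"`
#'   (chrom/start0/end/value, 0-based half-open).
#' @export
write_scan_track <- function(track, path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- as.data.frame(track)
    df$statistic <- attr(track, "statistic")
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (all(c("start", "end") %in% names(track))) {
      df <- data.frame(track$chrom, track$start - 1, track$end, track$value)
    } else {
      df <- data.frame(track$chrom, track$pos - 1, track$pos, track$value)
    }
    df <- df[!is.na(df[[4]]), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write phenotypes / genotype matrices / carrier status as TSV
#'
#' @param phenotypes Data frame with `sample` and `class`.
#' @param path Output TSV.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a genotype matrix as wide TSV
#'
#' First column `sample`, then one column per marker (column name = marker
#' id), codes 0/1/2 with missing as `NA`.
#'
#' @param gm Genotype matrix (samples x markers).
#' @param path Output TSV.
#' @export
write_genotype_tsv <- function(gm, path) {
  df <- data.frame(sample = rownames(gm), gm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample
  m
}

#' Write genotypes as a minimal GT-only VCF
#'
#' Emits an uncompressed VCFv4.2 body with a GT FORMAT field only, coding
#' 0 -> 0/0, 1 -> 0/1, 2 -> 1/1, NA -> ./.. Positions are written 1-based as
#' in the input.
#'
#' @param genotypes Matrix samples x variants (codes 0/1/2/NA).
#' @param variants Data frame with `chrom`, `pos`, `id`, and optionally
#'   `ref`, `alt`.
#' @param path Output file.
#' @export
write_vcf_genotypes <- function(genotypes, variants, path) {
  stopifnot(nrow(variants) == ncol(genotypes))
  ref <- if ("ref" %in% names(variants)) variants$ref else "A"
  alt <- if ("alt" %in% names(variants)) variants$alt else "T"
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(genotypes)),
                    collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(j) {
    g <- genotypes[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(variants$chrom[j], format(variants$pos[j], scientific = FALSE),
            variants$id[j], ref[min(j, length(ref))],
            alt[min(j, length(alt))], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF (GT field)
#'
#' Parses with `vcfR` and codes 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2,
#' ./. -> NA (phased separators are accepted). Non-biallelic records are
#' skipped with a message. Positions stay 1-based as in the VCF.
#'
#' @param path VCF file (plain text or gzipped).
#' @param sample_subset Optional character vector of sample names to keep;
#'   an unknown name is an error listing the available samples.
#' @return List with `genotypes` (samples x variants integer matrix) and
#'   `variants` (data frame chrom, pos, id, ref, alt).
#' @export
read_vcf_genotypes <- function(path, sample_subset = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    warning("VCF has no records")
    return(list(genotypes = matrix(integer(0), 0, 0),
                variants = data.frame(chrom = character(0), pos = numeric(0),
                                      id = character(0), ref = character(0),
                                      alt = character(0))))
  }
  biallelic <- !is.na(fix$ALT) & !grepl(",", fix$ALT)
  if (any(!biallelic)) {
    message(sum(!biallelic), " non-biallelic record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  if (!is.null(sample_subset)) {
    missing <- setdiff(sample_subset, colnames(gt))
    if (length(missing)) {
      stop("sample(s) not found: ", paste(missing, collapse = ", "),
           "; available: ", paste(colnames(gt), collapse = ", "))
    }
    gt <- gt[, sample_subset, drop = FALSE]
  }
  code <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    out
  }
  m <- t(apply(gt, 2, code))
  if (nrow(fix) == 1) m <- matrix(m, ncol = 1,
                                  dimnames = list(colnames(gt), NULL))
  id <- ifelse(is.na(fix$ID) | fix$ID == ".",
               paste0(fix$CHROM, "_", fix$POS), fix$ID)
  variants <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                         id = id, ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  colnames(m) <- variants$id
  list(genotypes = m, variants = variants)
}

#' Read a simulation config from YAML
#'
#' The file maps 1:1 to the [sim_config()] fields; absent fields take the
#' defaults. `chrom_lengths` is a named mapping.
#'
#' @param path YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$chrom_lengths)) {
    y$chrom_lengths <- unlist(y$chrom_lengths)
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, y)
}

#' Load the bundled candidate-variant diagnostic panel
#'
#' The package ships a plain-text encoding of a six-variant candidate panel
#' (four SNPs and two short indels around 93.85 Mb on chicken chromosome 1)
#' genotyped across carrier and noncarrier breed groups, split into a
#' whole-genome panel (12 carriers, 82 noncarriers) and a diagnostic
#' follow-up panel (47 carriers, 54 noncarriers). Group rows are expanded
#' into one sample per animal.
#'
#' @return List with `wgs` and `diagnostic` [carrier_panel()] objects.
#' @export
load_candidate_panel <- function() {
  vpath <- system.file("extdata", "candidate_variants.tsv", package = "melmap",
                       mustWork = TRUE)
  gpath <- system.file("extdata", "candidate_panel_groups.tsv",
                       package = "melmap", mustWork = TRUE)
  variants <- utils::read.table(vpath, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  groups <- utils::read.table(gpath, sep = "\t", header = TRUE,
                              check.names = FALSE, stringsAsFactors = FALSE)
  code_map <- c(WT = 0L, Het = 1L, Mutant = 2L, NoCall = NA_integer_)
  build <- function(panel_name) {
    sub <- groups[groups$panel == panel_name, , drop = FALSE]
    rows <- list()
    status <- character(0)
    ids <- character(0)
    for (i in seq_len(nrow(sub))) {
      codes <- code_map[as.character(sub[i, variants$id])]
      for (k in seq_len(sub$n[i])) {
        rows <- c(rows, list(codes))
        status <- c(status, sub$status[i])
        ids <- c(ids, sprintf("%s_%s_%02d", panel_name,
                              gsub("[^A-Za-z0-9]+", "_", sub$group[i]), k))
      }
    }
    g <- do.call(rbind, rows)
    rownames(g) <- ids
    carrier_panel(g, status, variants)
  }
  list(wgs = build("wgs"), diagnostic = build("diagnostic"))
}
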