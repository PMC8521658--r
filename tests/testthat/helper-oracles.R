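# Small configs and independent brute-force oracles used across test files.

# a cheap config: one short chromosome, few markers
tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, chrom_lengths = c(chr1 = 2e7),
               causal_chrom = "chr1", causal_pos = 1e7,
               n_markers_per_chrom = 30L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# oracle: minimal switch count by explicit enumeration of merged sequences
oracle_min_switches <- function(states, causal) {
  m <- length(states)
  if (m < 2) return(NA_integer_)
  best <- Inf
  for (k in 1:(m - 1)) {
    merged <- c(states[1:k], causal, states[(k + 1):m])
    sw <- sum(merged[-1] != merged[-length(merged)])
    if (sw < best) best <- sw
  }
  as.integer(best)
}

# oracle: per-window means by direct rescan
oracle_window_means <- function(track, window, step) {
  out <- list()
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch & !is.na(track$value), , drop = FALSE]
    if (nrow(sub) == 0) next
    for (s in seq(1, max(sub$pos), by = step)) {
      hit <- sub$pos >= s & sub$pos < s + window
      if (any(hit)) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = s, mean_fst = mean(sub$value[hit]),
          n_sites = sum(hit))
      }
    }
  }
  do.call(rbind, out)
}

# oracle: site compatibility with a shared carrier haplotype, coded afresh
oracle_compatible <- function(g, status) {
  ok_for <- function(a) {
    hom <- g[status == "carrier_hom"]
    het <- g[status == "carrier_het"]
    hom <- hom[!is.na(hom)]
    het <- het[!is.na(het)]
    # hom carriers: both chromosomes from the shared haplotype
    if (length(hom) && !all(hom == a)) return(FALSE)
    # het carriers: at least one copy of the shared allele
    carries <- if (a == 2L) het >= 1L else het <= 1L
    length(het) == 0 || all(carries)
  }
  ok_for(0L) || ok_for(2L)
}

# oracle: longest sub-interval of compatible endpoints containing `anchor`
# with at most max_conflicts incompatible sites; ties -> leftmost
oracle_ibd_span <- function(comp, anchor, max_conflicts = 0L) {
  n <- length(comp)
  best <- NULL
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!comp[i] || !comp[j]) next
      if (sum(!comp[i:j]) > max_conflicts) next
      if (anchor < i || anchor > j) next
      if (is.null(best) || (j - i) > (best[2] - best[1])) best <- c(i, j)
    }
  }
  best
}

# oracle: above-threshold runs by linear rescan (no merging)
oracle_runs <- function(values, threshold, min_run) {
  above <- !is.na(values) & values >= threshold
  runs <- list()
  i <- 1
  while (i <= length(values)) {
    if (above[i]) {
      j <- i
      while (j < length(values) && above[j + 1]) j <- j + 1
      if (j - i + 1 >= min_run) runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  runs
}

# build a carrier panel from a plain matrix for hand-made cases
panel_from_matrix <- function(g, status, pos = NULL, chrom = "chr1") {
  if (is.null(pos)) pos <- seq_len(ncol(g)) * 100
  ids <- if (is.null(colnames(g))) paste0("v", seq_len(ncol(g))) else colnames(g)
  carrier_panel(g, status,
                data.frame(chrom = chrom, pos = pos, id = ids,
                           stringsAsFactors = FALSE))
}
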