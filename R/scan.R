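#' Pool count tables
#'
#' A `pool_counts` object is a data frame with one row per variant and
#' columns `chrom`, `pos` (bp, 1-based), `ref`, `alt`, `ref_count`,
#' `alt_count`. Positions must be strictly increasing within each chromosome.
#'
#' @param df Data frame with the columns above.
#' @return The validated data frame with class `pool_counts` prepended.
#' @export
new_pool_counts <- function(df) {
  req <- c("chrom", "pos", "ref", "alt", "ref_count", "alt_count")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("pool counts missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$ref_count < 0 | df$alt_count < 0, na.rm = TRUE)) {
    stop("read counts must be >= 0")
  }
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  class(df) <- c("pool_counts", "data.frame")
  df
}

new_scan_track <- function(df, statistic) {
  stopifnot(statistic %in% c("raf", "absrafdif", "fst", "zfst"))
  class(df) <- c("scan_track", "data.frame")
  attr(df, "statistic") <- statistic
  df
}

#' @export
print.scan_track <- function(x, ...) {
  cat(sprintf("<scan_track> statistic '%s', %d records on %d chromosome(s)\n",
              attr(x, "statistic"), nrow(x), length(unique(x$chrom))))
  utils::str(as.data.frame(utils::head(x, 3)))
  invisible(x)
}

#' Relative allele frequency per site from pool counts
#'
#' value = ref_count / (ref_count + alt_count). Sites whose total depth is
#' below `min_depth` (including zero-depth sites) are emitted with a missing
#' value rather than dropped; the number of such sites is reported in a
#' message.
#'
#' @param counts A [new_pool_counts()] table.
#' @param min_depth Minimum total reads for a site to receive a value.
#' @return A `scan_track` (statistic `"raf"`) with columns chrom, pos, value,
#'   depth.
#' @export
pool_raf <- function(counts, min_depth = 1L) {
  stopifnot(inherits(counts, "pool_counts"))
  total <- counts$ref_count + counts$alt_count
  value <- ifelse(total >= min_depth & total > 0,
                  counts$ref_count / total, NA_real_)
  n_low <- sum(is.na(value))
  if (n_low > 0) {
    message(n_low, " site(s) below min_depth emitted as missing")
  }
  new_scan_track(data.frame(chrom = counts$chrom, pos = counts$pos,
                            value = value, depth = total,
                            stringsAsFactors = FALSE),
                 statistic = "raf")
}

# align two per-site tracks on their shared (chrom, pos) site list
align_tracks <- function(track_a, track_b) {
  key_a <- paste(track_a$chrom, track_a$pos)
  key_b <- paste(track_b$chrom, track_b$pos)
  shared <- intersect(key_a, key_b)
  if (length(shared) == 0) stop("tracks share no sites")
  n_drop <- (length(key_a) - length(shared)) + (length(key_b) - length(shared))
  if (n_drop > 0) message(n_drop, " unshared site(s) dropped from comparison")
  list(a = track_a[match(shared, key_a), , drop = FALSE],
       b = track_b[match(shared, key_b), , drop = FALSE])
}

#' Absolute difference in relative allele frequencies between pools
#'
#' value = |p_A - p_B| per shared site; missing where either input is
#' missing. For a heterozygote-vs-homozygote back-cross contrast the
#' theoretical maximum is 0.5 (attained at a fully informative site with
#' exact frequencies); this ceiling is a property of the design and is not
#' enforced on the data.
#'
#' @param track_a,track_b `scan_track`s with statistic `"raf"` over the same
#'   (or overlapping) site list; the intersection is used.
#' @return A `scan_track` with statistic `"absrafdif"`.
#' @export
abs_raf_dif <- function(track_a, track_b) {
  al <- align_tracks(track_a, track_b)
  new_scan_track(data.frame(chrom = al$a$chrom, pos = al$a$pos,
                            value = abs(al$a$value - al$b$value),
                            stringsAsFactors = FALSE),
                 statistic = "absrafdif")
}

#' Per-site F_ST between two pools
#'
#' Nei-style two-population G_ST on pool frequencies:
#' Hs = mean(2 p_A (1 - p_A), 2 p_B (1 - p_B)), p-bar = (p_A + p_B) / 2,
#' Ht = 2 p-bar (1 - p-bar), F_ST = (Ht - Hs) / Ht, defined as 0 when
#' Ht = 0. Negative estimates are clamped to 0. No sample-size correction is
#' applied (pool depths are assumed large).
#'
#' @inheritParams abs_raf_dif
#' @return A `scan_track` with statistic `"fst"`.
#' @export
per_site_fst <- function(track_a, track_b) {
  al <- align_tracks(track_a, track_b)
  pa <- al$a$value
  pb <- al$b$value
  hs <- (2 * pa * (1 - pa) + 2 * pb * (1 - pb)) / 2
  pbar <- (pa + pb) / 2
  ht <- 2 * pbar * (1 - pbar)
  fst <- ifelse(ht == 0, 0, (ht - hs) / ht)
  fst <- pmax(fst, 0)
  new_scan_track(data.frame(chrom = al$a$chrom, pos = al$a$pos, value = fst,
                            stringsAsFactors = FALSE),
                 statistic = "fst")
}

#' Windowed mean of a per-site track
#'
#' Tiles each chromosome with windows of `window` bp advanced by `step` bp
#' (first window starts at position 1) and averages the per-site values over
#' the sites falling in \[start, start + window). Windows with fewer than
#' `min_sites` non-missing sites are dropped. Smoothing a noisy per-site
#' track this way is the usual prelude to peak calling.
#'
#' @param track A per-site `scan_track`.
#' @param window,step Window and step size in bp; `window >= step > 0`.
#' @param min_sites Minimum non-missing sites per emitted window.
#' @return A `scan_track` with the same statistic, columns chrom, start, end
#'   (1-based inclusive), value (window mean), n_sites.
#' @export
windowed_mean <- function(track, window, step, min_sites = 1L) {
  stopifnot(inherits(track, "scan_track"))
  wins <- tile_window_means(track, window, step)
  wins <- wins[wins$n_sites >= min_sites, , drop = FALSE]
  if (nrow(wins) == 0) stop("no window meets min_sites = ", min_sites)
  out <- data.frame(chrom = wins$chrom, start = wins$start, end = wins$end,
                    value = wins$win_mean, n_sites = wins$n_sites,
                    stringsAsFactors = FALSE)
  new_scan_track(out, statistic = attr(track, "statistic"))
}

# shared tiling: per-window means of a per-site track
tile_window_means <- function(track, window, step) {
  if (!(window >= step && step > 0)) stop("need window >= step > 0")
  pieces <- lapply(unique(track$chrom), function(ch) {
    sub <- track[track$chrom == ch & !is.na(track$value), , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    max_pos <- max(sub$pos)
    starts <- seq(1, max_pos, by = step)
    idx <- findInterval(sub$pos, starts)
    # a site at pos belongs to every window with start in (pos-window, pos]
    k_per <- ceiling(window / step)
    rows <- lapply(seq_len(k_per), function(off) {
      w <- idx - off + 1L
      keep <- w >= 1L & sub$pos < starts[pmax(w, 1L)] + window
      data.frame(win = w[keep], val = sub$value[keep])
    })
    hits <- do.call(rbind, rows)
    agg_n <- tapply(hits$val, hits$win, length)
    agg_m <- tapply(hits$val, hits$win, mean)
    win_id <- as.integer(names(agg_n))
    data.frame(chrom = ch,
               start = starts[win_id],
               end = starts[win_id] + window - 1,
               win_mean = as.numeric(agg_m),
               n_sites = as.integer(agg_n),
               stringsAsFactors = FALSE)
  })
  wins <- do.call(rbind, pieces)
  if (is.null(wins) || nrow(wins) == 0) stop("no sites available for windowing")
  wins[order(wins$chrom, wins$start), , drop = FALSE]
}

#' Windowed Z-scored F_ST
#'
#' Averages per-site F_ST in sliding windows (see [windowed_mean()]) and
#' Z-standardises the window means genome-wide over all windows with at
#' least `min_sites` non-missing sites. If the window means have zero
#' variance all Z values are set to 0 with a warning.
#'
#' @param fst A per-site `scan_track` with statistic `"fst"`.
#' @param window,step Window and step size in bp; `window >= step > 0`.
#' @param min_sites Minimum sites for a window to enter the Z normalisation.
#' @return A `scan_track` with statistic `"zfst"`, columns chrom, start, end
#'   (1-based inclusive), value (Z), mean_fst, n_sites.
#' @export
windowed_zfst <- function(fst, window = 40000, step = 20000, min_sites = 10L) {
  stopifnot(inherits(fst, "scan_track"))
  wins <- tile_window_means(fst, window, step)
  wins$mean_fst <- wins$win_mean
  wins <- wins[wins$n_sites >= min_sites, , drop = FALSE]
  if (nrow(wins) == 0) stop("no window meets min_sites = ", min_sites)
  s <- stats::sd(wins$mean_fst)
  if (is.na(s) || s == 0) {
    warning("window means have zero variance; all Z set to 0")
    z <- rep(0, nrow(wins))
  } else {
    z <- (wins$mean_fst - mean(wins$mean_fst)) / s
  }
  out <- data.frame(chrom = wins$chrom, start = wins$start, end = wins$end,
                    value = z, mean_fst = wins$mean_fst,
                    n_sites = wins$n_sites, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  new_scan_track(out, statistic = "zfst")
}

#' Call peak regions from a scan track
#'
#' Finds maximal runs of at least `min_run` consecutive records (sites or
#' windows, per chromosome) with value >= threshold; runs separated by a gap
#' of fewer than `min_run` below-threshold records are merged. Returns
#' 1-based inclusive intervals sorted by their peak value (highest first).
#'
#' @param track A `scan_track` (per-site or windowed).
#' @param threshold Value threshold.
#' @param min_run Minimum run length (records).
#' @return A list of `genomic_interval`s, each with attributes `peak_value`
#'   and `n_records`; empty list if nothing exceeds the threshold.
#' @export
call_peak_region <- function(track, threshold, min_run = 3L) {
  stopifnot(inherits(track, "scan_track"))
  windowed <- all(c("start", "end") %in% names(track))
  out <- list()
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    if (windowed) {
      sub <- sub[order(sub$start), , drop = FALSE]
    } else {
      sub <- sub[order(sub$pos), , drop = FALSE]
    }
    above <- !is.na(sub$value) & sub$value >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    # merge runs separated by short gaps
    if (nrow(runs) > 1) {
      merged <- runs[1, , drop = FALSE]
      for (i in 2:nrow(runs)) {
        gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
        if (gap < min_run) {
          merged$end[nrow(merged)] <- runs$end[i]
        } else {
          merged <- rbind(merged, runs[i, , drop = FALSE])
        }
      }
      runs <- merged
    }
    n_above <- vapply(seq_len(nrow(runs)), function(i)
      sum(above[runs$start[i]:runs$end[i]]), integer(1))
    runs <- runs[n_above >= min_run, , drop = FALSE]
    for (i in seq_len(nrow(runs))) {
      sl <- runs$start[i]:runs$end[i]
      iv <- if (windowed) {
        genomic_interval(ch, min(sub$start[sl]), max(sub$end[sl]))
      } else {
        genomic_interval(ch, min(sub$pos[sl]), max(sub$pos[sl]))
      }
      attr(iv, "peak_value") <- max(sub$value[sl], na.rm = TRUE)
      attr(iv, "n_records") <- length(sl)
      out <- c(out, list(iv))
    }
  }
  if (length(out) == 0) return(list())
  out[order(vapply(out, function(iv) attr(iv, "peak_value"), numeric(1)),
            decreasing = TRUE)]
}

#' Plot a scan track
#'
#' Simple base-graphics Manhattan-style view: one panel, chromosomes laid
#' end to end, per-site or windowed values on the y axis.
#'
#' @param x A `scan_track`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scan_track <- function(x, ...) {
  pos <- if ("pos" %in% names(x)) x$pos else (x$start + x$end) / 2
  chroms <- unique(x$chrom)
  offsets <- c(0, cumsum(vapply(chroms, function(ch)
    max(pos[x$chrom == ch]), numeric(1))))[seq_along(chroms)]
  names(offsets) <- chroms
  gx <- pos + offsets[x$chrom]
  cols <- (match(x$chrom, chroms) %% 2) + 1
  graphics::plot(gx, x$value, pch = 16, cex = 0.4,
                 col = c("grey30", "steelblue")[cols],
                 xlab = "genome position (bp, chromosomes concatenated)",
                 ylab = attr(x, "statistic"), ...)
  invisible(x)
}
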