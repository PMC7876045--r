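# Pause score: 3' end count at a position divided by the median count in
# a 51-nt window centered there.  A site is a pause when the score is at
# least 20-fold and the count is at least 10 per million library reads.

running_median <- function(x, window, circular = FALSE,
                           exclude_center = FALSE) {
  n <- length(x)
  half <- window %/% 2L
  if (n == 0L) return(numeric(0))
  if (circular) {
    if (n < window) stop("circular window larger than contig")
    xp <- c(tail(x, half), x, head(x, half))
    if (exclude_center) {
      return(vapply(seq_len(n), function(i) {
        w <- xp[i:(i + 2L * half)]
        median(w[-(half + 1L)])
      }, numeric(1)))
    }
    return(as.numeric(stats::runmed(xp, window,
                                    endrule = "keep")[(half + 1L):(half + n)]))
  }
  if (exclude_center || n < window) {
    return(vapply(seq_len(n), function(i) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      w <- x[lo:hi]
      if (exclude_center) w <- w[-(i - lo + 1L)]
      if (!length(w)) return(NA_real_)
      median(w)
    }, numeric(1)))
  }
  out <- as.numeric(stats::runmed(x, window, endrule = "keep"))
  # truncated (not shrunken-symmetric) windows at the contig edges
  for (i in seq_len(half)) {
    out[i] <- median(x[1L:min(n, i + half)])
    j <- n - i + 1L
    out[j] <- median(x[max(1L, j - half):n])
  }
  out
}

#' Median 3'-end count in a centered window
#'
#' @param track An `EndCountTrack`.
#' @param contig,position,strand Position of interest (0-based).
#' @param window Odd window width in nt (default 51); the center position
#'   is part of the window unless `exclude_center`.
#' @param circular Treat the contig as circular (wrap-around window).
#' @param exclude_center Drop the center position from the window.
#' @return The median count over the window, truncated at contig edges
#'   unless `circular`.
#' @export
window_median <- function(track, contig, position, strand, window = 51L,
                          circular = FALSE, exclude_center = FALSE) {
  check_window(window)
  v <- track$counts[[strand]][[contig]]
  stopifnot(!is.null(v), position >= 0L, position < length(v))
  half <- window %/% 2L
  n <- length(v)
  i <- position + 1L
  if (circular) {
    idx <- ((i - 1L + seq(-half, half)) %% n) + 1L
    w <- v[idx]
    if (exclude_center) w <- w[-(half + 1L)]
    return(median(w))
  }
  lo <- max(1L, i - half); hi <- min(n, i + half)
  w <- v[lo:hi]
  if (exclude_center) w <- w[-(i - lo + 1L)]
  median(w)
}

check_window <- function(window) {
  if (window %% 2L == 0L || window < 3L)
    stop("window must be an odd integer >= 3")
}

#' Per-position pause scores over a whole strand track
#'
#' @inheritParams window_median
#' @param median_floor Lower bound applied to the window median before
#'   division, guarding sparse tracks against division by zero.
#' @return A data.frame with one row per position: `count`, `med`
#'   (window median), `score` (`count / max(med, median_floor)`), `cpm`.
#' @export
score_track <- function(track, contig, strand, window = 51L,
                        median_floor = 1, circular = FALSE,
                        exclude_center = FALSE) {
  check_window(window)
  v <- track$counts[[strand]][[contig]]
  stopifnot(!is.null(v))
  med <- running_median(v, window, circular, exclude_center)
  data.frame(position = seq_along(v) - 1L, count = v, med = med,
             score = v / pmax(med, median_floor),
             cpm = v * 1e6 / track$total_reads)
}

#' Call pause sites by the dual fold/CPM threshold
#'
#' A position is a pause site when its 3'-end count is at least
#' `min_fold` times the median count in the centered `window`, and at
#' least `min_cpm` counts per million library reads, and it is not
#' masked.  Adjacent qualifying positions are reported individually (no
#' peak merging).
#'
#' @param track An `EndCountTrack` with `total_reads > 0`.
#' @param mask A `MaskSet` of excluded intervals (strandless), or NULL.
#' @param min_fold Minimum pause score (default 20).
#' @param min_cpm Minimum counts per million (default 10); CPM uses the
#'   library-wide total over both strands.
#' @param window Median window width, odd (default 51).
#' @param median_floor Floor on the window median (default 1 read).
#' @param circular,exclude_center See [window_median()].
#' @return An `sp_pauses` data.frame sorted by (contig, position,
#'   strand): `contig`, `position`, `strand`, `count`, `window_median`,
#'   `pause_score`, `cpm`.
#' @export
call_pauses <- function(track, mask = NULL, min_fold = 20, min_cpm = 10,
                        window = 51L, median_floor = 1, circular = FALSE,
                        exclude_center = FALSE) {
  check_window(window)
  if (track$total_reads == 0L) {
    warning("empty track: no pauses callable")
    return(empty_pauses())
  }
  min_count <- min_cpm * track$total_reads / 1e6
  res <- list()
  for (s in c("+", "-")) for (ctg in names(track$counts[[s]])) {
    v <- track$counts[[s]][[ctg]]
    # necessary conditions before computing any medians
    cand <- which(v >= min_count & v >= min_fold * median_floor)
    if (!length(cand)) next
    med <- vapply(cand - 1L, function(p)
      window_median(track, ctg, p, s, window, circular, exclude_center),
      numeric(1))
    score <- v[cand] / pmax(med, median_floor)
    cpm <- v[cand] * 1e6 / track$total_reads
    keep <- score >= min_fold & cpm >= min_cpm
    if (!is.null(mask)) keep <- keep & !in_mask(mask, rep(ctg, length(cand)),
                                               cand - 1L)
    if (!any(keep)) next
    res[[length(res) + 1L]] <- data.frame(
      contig = ctg, position = cand[keep] - 1L, strand = s,
      count = v[cand][keep], window_median = med[keep],
      pause_score = score[keep], cpm = cpm[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(res)) return(empty_pauses())
  out <- do.call(rbind, res)
  out <- out[order(out$contig, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sp_pauses", "data.frame")
  out
}

empty_pauses <- function() {
  df <- data.frame(contig = character(), position = integer(),
                   strand = character(), count = integer(),
                   window_median = numeric(), pause_score = numeric(),
                   cpm = numeric(), stringsAsFactors = FALSE)
  class(df) <- c("sp_pauses", "data.frame")
  df
}
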