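# Cross-dataset comparison of pause sets, the in vitro pause-strength
# arithmetic, and per-group summary statistics.

#' Overlap (Venn) of two pause sets
#'
#' A pause in A is shared when B contains a same-contig, same-strand
#' pause within `tolerance` nt; matching is greedy nearest in position
#' order and each B pause matches at most one A pause.  At tolerance 0
#' the shared count is symmetric in A and B.
#'
#' @param A,B Pause data.frames (`contig`, `position`, `strand`).
#' @param tolerance Maximal coordinate difference in nt (default 0,
#'   exact 3'-coordinate identity).
#' @return An `OverlapResult` list: `n_A_only`, `n_B_only`, `n_shared`,
#'   `fraction_A_shared`, `fraction_B_shared`, `tolerance`.
#' @export
overlap_sets <- function(A, B, tolerance = 0L) {
  stopifnot(tolerance >= 0L)
  shared <- 0L
  for (s in c("+", "-")) {
    for (ctg in union(A$contig[A$strand == s], B$contig[B$strand == s])) {
      a <- sort(A$position[A$strand == s & A$contig == ctg])
      b <- sort(B$position[B$strand == s & B$contig == ctg])
      used <- logical(length(b))
      for (p in a) {
        cand <- which(!used & abs(b - p) <= tolerance)
        if (length(cand)) {
          used[cand[which.min(abs(b[cand] - p))]] <- TRUE
          shared <- shared + 1L
        }
      }
    }
  }
  structure(list(
    n_A_only = nrow(A) - shared, n_B_only = nrow(B) - shared,
    n_shared = shared,
    fraction_A_shared = if (nrow(A)) shared / nrow(A) else NA_real_,
    fraction_B_shared = if (nrow(B)) shared / nrow(B) else NA_real_,
    tolerance = tolerance), class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat("OverlapResult: shared", x$n_shared, "| A only", x$n_A_only,
      "| B only", x$n_B_only, "| A shared",
      format(100 * x$fraction_A_shared, digits = 3), "%\n")
  invisible(x)
}

#' Matched fraction from matched/unmatched counts
#'
#' @param matched,unmatched Non-negative counts (vectors are summed, so
#'   per-category counts can be combined in one call).
#' @return `sum(matched) / (sum(matched) + sum(unmatched))`.
#' @export
matched_fraction <- function(matched, unmatched) {
  stopifnot(all(matched >= 0), all(unmatched >= 0),
            sum(matched) + sum(unmatched) > 0)
  sum(matched) / (sum(matched) + sum(unmatched))
}

#' In vitro pause strength from gel band intensities
#'
#' Pause strength = I(paused) / (I(paused) + I(run-off)); it is
#' scale-invariant in the two intensities.
#'
#' @param intensity_paused,intensity_runoff Non-negative intensities
#'   (vectorized).
#' @return Values in `[0, 1]`.
#' @export
pause_strength <- function(intensity_paused, intensity_runoff) {
  stopifnot(all(intensity_paused >= 0), all(intensity_runoff >= 0))
  if (any(intensity_paused + intensity_runoff == 0))
    stop("pause strength undefined when both intensities are zero")
  intensity_paused / (intensity_paused + intensity_runoff)
}

#' Pause strength relative to a reference condition
#'
#' The reference condition (e.g. no Gre factors, or the wild-type
#' promoter) is set to 1.
#'
#' @param ps Pause strength(s).
#' @param ps_reference Reference pause strength, > 0.
#' @return `ps / ps_reference`.
#' @export
relative_strength <- function(ps, ps_reference) {
  if (any(ps_reference <= 0)) stop("reference pause strength must be > 0")
  ps / ps_reference
}

#' Per-group pause-score summaries and rank-sum comparisons
#'
#' Computes, per distance group, the count, mean, median, quartiles and
#' Tukey 1.5 x IQR whiskers of a value column, and all pairwise
#' two-sided Wilcoxon rank-sum (Mann-Whitney U) tests between groups.
#'
#' @param annotations Annotated pause table with a `group` column.
#' @param value Name of the numeric column to summarize (default
#'   `"pause_score"`).
#' @param exact Use the exact rank-sum distribution when both groups
#'   have n <= 10 and no ties (default TRUE; larger groups use the
#'   normal approximation with tie correction, as `stats::wilcox.test`
#'   does).
#' @return A list with `summary` (data.frame, one row per group) and
#'   `tests` (data.frame of pairwise comparisons with `W` and
#'   `p_value`; pairs where either group has n < 2 are reported with NA
#'   and a note).
#' @export
group_summary <- function(annotations, value = "pause_score", exact = TRUE) {
  x <- annotations[[value]]
  g <- annotations$group
  stopifnot(!is.null(x), !is.null(g))
  groups <- split(x, g)
  summ <- do.call(rbind, lapply(names(groups), function(nm) {
    v <- groups[[nm]]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo <- min(v[v >= q[1] - 1.5 * iqr])
    hi <- max(v[v <= q[3] + 1.5 * iqr])
    data.frame(group = nm, n = length(v), mean = mean(v), median = q[2],
               q1 = q[1], q3 = q[3], whisker_lo = lo, whisker_hi = hi,
               stringsAsFactors = FALSE)
  }))
  pairs <- if (length(groups) >= 2L) utils::combn(names(groups), 2L) else
    matrix(character(0), 2L, 0L)
  tests <- do.call(rbind, c(list(data.frame(
    group_a = character(), group_b = character(), W = numeric(),
    p_value = numeric(), note = character(), stringsAsFactors = FALSE)),
    lapply(seq_len(ncol(pairs)), function(k) {
      a <- groups[[pairs[1L, k]]]; b <- groups[[pairs[2L, k]]]
      if (length(a) < 2L || length(b) < 2L) {
        return(data.frame(group_a = pairs[1L, k], group_b = pairs[2L, k],
                          W = NA_real_, p_value = NA_real_,
                          note = "group with n < 2: test skipped",
                          stringsAsFactors = FALSE))
      }
      use_exact <- exact && length(a) <= 10L && length(b) <= 10L &&
        !any(duplicated(c(a, b)))
      wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                         exact = use_exact, correct = TRUE))
      data.frame(group_a = pairs[1L, k], group_b = pairs[2L, k],
                 W = unname(wt$statistic), p_value = wt$p.value, note = "",
                 stringsAsFactors = FALSE)
    })))
  list(summary = summ, tests = tests)
}
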