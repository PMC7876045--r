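# RNase-protected footprint lengths report the translocation register of
# the paused polymerase: 16-17 nt post-translocated, 18 nt
# pre-translocated, >18 nt backtracked.  Reads shorter than 16 nt arise
# so close to the promoter that the nuclease cannot resolve the state.

#' Read-length histogram and translocation-state fractions
#'
#' @param reads An `sp_reads` data.frame.
#' @param annotations Optional annotated pause table ([annotate_pauses()]);
#'   when given together with `by = "group"`, each read is assigned the
#'   distance group of the pause at its 3' end (contig/position/strand
#'   match) and one distribution is returned per group (reads not at an
#'   annotated pause are pooled under `"unassigned"`).
#' @param by `"all"` (one pooled distribution) or `"group"`.
#' @param post,pre Length bins of the post- and pre-translocated states
#'   (defaults 16:17 and 18); lengths above `max(pre)` are backtracked,
#'   lengths below `min(post)` indeterminate.
#' @return A `FootprintDistribution` (list with `histogram`, `total`,
#'   `mean_length`, `fractions`), or a named list of them for
#'   `by = "group"`.
#' @export
length_distribution <- function(reads, annotations = NULL,
                                by = c("all", "group"),
                                post = 16:17, pre = 18L) {
  by <- match.arg(by)
  if (by == "all") return(footprint_dist(reads$length, post, pre))
  stopifnot(!is.null(annotations))
  key <- paste(annotations$contig, annotations$position, annotations$strand)
  grp <- annotations$group[match(paste(reads$contig, reads$end3,
                                       reads$strand), key)]
  grp[is.na(grp)] <- "unassigned"
  lapply(split(reads$length, grp), footprint_dist, post = post, pre = pre)
}

footprint_dist <- function(lengths, post = 16:17, pre = 18L) {
  stopifnot(all(lengths >= 1L))
  hist <- table(factor(lengths, levels = seq(min(lengths), max(lengths))))
  hist <- setNames(as.integer(hist), names(hist))
  structure(list(histogram = hist, total = length(lengths),
                 mean_length = mean(lengths),
                 fractions = state_fractions(hist, post, pre)),
            class = "FootprintDistribution")
}

#' Translocation-state fractions from a length histogram
#'
#' @param hist Named integer vector: `hist[["L"]]` is the number of reads
#'   of length L.
#' @param post,pre See [length_distribution()].
#' @return Named numeric vector `(indeterminate, post, pre, backtracked)`
#'   summing to 1, or an all-NA vector (with a warning) for an empty
#'   histogram.  Fractions are invariant under scaling of the histogram.
#' @export
state_fractions <- function(hist, post = 16:17, pre = 18L) {
  out <- setNames(rep(NA_real_, 4L),
                  c("indeterminate", "post", "pre", "backtracked"))
  total <- sum(hist)
  if (length(hist) == 0L || total == 0) {
    warning("empty footprint histogram: fractions undefined")
    return(out)
  }
  len <- as.integer(names(hist))
  stopifnot(!anyNA(len))
  out["indeterminate"] <- sum(hist[len < min(post)]) / total
  out["post"] <- sum(hist[len %in% post]) / total
  out["pre"] <- sum(hist[len %in% pre]) / total
  out["backtracked"] <- sum(hist[len > max(pre)]) / total
  out
}

#' @export
print.FootprintDistribution <- function(x, ...) {
  cat("FootprintDistribution:", x$total, "reads | mean",
      format(x$mean_length, digits = 4), "nt | backtracked",
      format(x$fractions[["backtracked"]], digits = 3), "\n")
  invisible(x)
}
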