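# Individual-information (Ri) model of the sigma70 -10 hexamer and the
# promoter-element annotation built on it: -10R location and Ri, spacer
# length, the YRY triplet at the start site, and the downstream -10-like
# region (-10LR) whose recognition by sigma70 drives distal pausing.

BASES <- c("A", "C", "G", "T")

#' Build a per-position frequency / individual-information model
#'
#' Weights follow the individual-information convention for DNA:
#' `w(b, l) = 2 + log2 f(b, l)` bits, so a uniformly random position
#' contributes 0 bits and an invariant position contributes 2 bits to
#' its consensus base.  `Rsequence = sum_l sum_b f(b,l) w(b,l)` is the
#' model's mean information.
#'
#' @param aligned_seqs Character vector (or DNAStringSet) of >= 2
#'   equal-length sequences over A/C/G/T.
#' @param pseudocount Added per base and position before normalization
#'   (default 0.25); 0 gives exact small-sample identities but -Inf
#'   weights for unseen bases.
#' @return An `RiModel`: list with `width`, `freq` (4 x width), `weights`
#'   (bits), `rsequence`, `n_train`, `pseudocount`.
#' @export
build_ri_model <- function(aligned_seqs, pseudocount = 0.25) {
  seqs <- toupper(as.character(aligned_seqs))
  stopifnot(length(seqs) >= 2L)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("training sequences must have equal length")
  chars <- do.call(rbind, strsplit(seqs, ""))
  bad <- !(chars %in% BASES)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(chars)), arr.ind = TRUE)
    stop("ambiguous base(s) at sequence ", idx[1, 1], " position ", idx[1, 2])
  }
  counts <- apply(chars, 2L, function(col) table(factor(col, levels = BASES)))
  freq <- (counts + pseudocount) / (length(seqs) + 4 * pseudocount)
  weights <- 2 + log2(freq)
  rseq <- sum(ifelse(freq > 0, freq * weights, 0))
  structure(list(width = w, freq = freq, weights = weights,
                 rsequence = rseq, n_train = length(seqs),
                 pseudocount = pseudocount),
            class = "RiModel")
}

#' @export
print.RiModel <- function(x, ...) {
  cat("RiModel: width", x$width, "| Rsequence",
      format(x$rsequence, digits = 4), "bits | n_train", x$n_train, "\n")
  invisible(x)
}

#' Individual information (Ri) of sequences under a model
#'
#' @param model An `RiModel`.
#' @param seqs Character vector of sequences of the model width.
#' @return Numeric vector of Ri in bits (sum of per-position weights);
#'   can be negative -- 0 bits is the conventional threshold for a
#'   recognizable site.
#' @export
ri_score <- function(model, seqs) {
  seqs <- toupper(as.character(seqs))
  if (any(nchar(seqs) != model$width))
    stop("sequence length must equal model width (", model$width, ")")
  vapply(seqs, function(s) {
    b <- match(strsplit(s, "")[[1]], BASES)
    if (anyNA(b)) stop("ambiguous base in '", s, "'")
    sum(model$weights[cbind(b, seq_len(model$width))])
  }, numeric(1), USE.NAMES = FALSE)
}

# Sequence at TSS-relative offsets from..to (0 = TSS base), read 5'->3'
# on the TSS strand; NULL when out of contig bounds.
tss_window_seq <- function(genome, contig, position, strand, from, to) {
  len <- Biostrings::width(genome[contig])
  if (strand == "+") {
    s <- position + from; e <- position + to
    if (s < 0L || e >= len) return(NULL)
    as.character(Biostrings::subseq(genome[[contig]], s + 1L, e + 1L))
  } else {
    s <- position - to; e <- position - from
    if (s < 0L || e >= len) return(NULL)
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(genome[[contig]], s + 1L, e + 1L)))
  }
}

# spacer tie-break preference: 6, 7, then outward from 6
spacer_rank <- function(s) {
  pref <- c(6L, 7L, 5L, 8L, 4L, 9L, 3L)
  r <- match(s, pref)
  ifelse(is.na(r), 100L + abs(s - 6L), r)
}

#' Locate the -10 element upstream of a TSS
#'
#' Scans every hexamer whose spacer (bases strictly between the hexamer
#' 3' end and the TSS base, on the TSS strand) lies in `spacer_range`
#' and returns the maximal-Ri placement.  Ties prefer spacer 6, then 7
#' (the spacer lengths typical of strong pause-prone promoters), then
#' spacers outward from 6.
#'
#' @param model An `RiModel` of width 6.
#' @param genome Named DNAStringSet.
#' @param tss One-row `sp_tss` data.frame (or list with `contig`,
#'   `position`, `strand`).
#' @param spacer_range Integer vector of admissible spacers (default
#'   3:9).
#' @return A list `(start, seq, ri, spacer)` where `start` is the
#'   genomic 0-based coordinate of the hexamer's 5' base on the TSS
#'   strand, or NULL when no placement fits the contig.
#' @export
find_minus10 <- function(model, genome, tss, spacer_range = 3:9) {
  stopifnot(model$width == 6L)
  cand <- list()
  for (s in spacer_range) {
    # hexamer occupies TSS-relative offsets -(s+6) .. -(s+1)
    hx <- tss_window_seq(genome, tss$contig, tss$position, tss$strand,
                         -(s + 6L), -(s + 1L))
    if (is.null(hx)) next
    cand[[length(cand) + 1L]] <- list(spacer = s, seq = hx)
  }
  if (!length(cand)) {
    warning("no -10 search window fits the contig for TSS at ",
            tss$position)
    return(NULL)
  }
  ri <- ri_score(model, vapply(cand, `[[`, character(1), "seq"))
  sp <- vapply(cand, `[[`, integer(1), "spacer")
  ord <- order(-ri, spacer_rank(sp))
  best <- cand[[ord[1L]]]
  start <- if (tss$strand == "+") tss$position - best$spacer - 6L
           else tss$position + best$spacer + 6L
  list(start = start, seq = best$seq, ri = ri[ord[1L]], spacer = best$spacer)
}

#' Classify the 3-nt region centered at the TSS
#'
#' @param genome Named DNAStringSet.
#' @param tss One-row `sp_tss` data.frame.
#' @return A list `(triplet, is_yry)` -- the bases at TSS-1, TSS, TSS+1
#'   on the TSS strand, and whether they match the
#'   pyrimidine/purine/pyrimidine pattern `[CT][AG][CT]` characteristic
#'   of strong pause-prone promoters -- or NULL at a contig edge.
#' @export
classify_tssr <- function(genome, tss) {
  tri <- tss_window_seq(genome, tss$contig, tss$position, tss$strand, -1L, 1L)
  if (is.null(tri)) return(NULL)
  list(triplet = tri, is_yry = grepl("^[CT][AG][CT]$", tri))
}

#' Scan for the -10-like region downstream of the TSS
#'
#' Considers hexamers whose second base sits at TSS-relative offsets in
#' `anchor_range` (default -1..+2; offset 0 is the TSS base itself) and
#' returns the maximal-Ri one.  Ties go to the leftmost anchor.  The Ri
#' is reported even when it is non-positive; `weak = TRUE` flags
#' `ri <= 0`, the conventional threshold below which the site is not a
#' recognizable sigma70 -10 match.
#'
#' @param model An `RiModel` of width 6.
#' @param genome Named DNAStringSet.
#' @param tss One-row `sp_tss` data.frame.
#' @param anchor_range Integer offsets of the hexamer's second base
#'   (default -1:2).
#' @param anchor `"second"` (default, offsets refer to the hexamer's
#'   second base) or `"start"` (offsets refer to its first base).
#' @return A list `(start, anchor, seq, ri, weak)` with `start` the
#'   genomic 0-based coordinate of the hexamer's 5' base on the TSS
#'   strand, or NULL when the sequence is insufficient.
#' @export
scan_minus10_like <- function(model, genome, tss, anchor_range = -1:2,
                              anchor = c("second", "start")) {
  anchor <- match.arg(anchor)
  stopifnot(model$width == 6L)
  shift <- if (anchor == "second") 1L else 0L
  cand <- list()
  for (a in sort(as.integer(anchor_range))) {
    from <- a - shift
    hx <- tss_window_seq(genome, tss$contig, tss$position, tss$strand,
                         from, from + 5L)
    if (is.null(hx)) next
    cand[[length(cand) + 1L]] <- list(a = a, from = from, seq = hx)
  }
  if (!length(cand)) return(NULL)
  ri <- ri_score(model, vapply(cand, `[[`, character(1), "seq"))
  best <- cand[[which.max(ri)]]  # ties -> leftmost anchor (sorted order)
  start <- if (tss$strand == "+") tss$position + best$from
           else tss$position - best$from
  list(start = start, anchor = best$a, seq = best$seq,
       ri = max(ri), weak = max(ri) <= 0)
}

#' Annotate promoter elements for a set of TSSs
#'
#' Runs [find_minus10()], [classify_tssr()] and [scan_minus10_like()]
#' for every TSS and assembles one table.
#'
#' @param model An `RiModel` of width 6 (trained on aligned -10
#'   hexamers).
#' @param genome Named DNAStringSet.
#' @param tss An `sp_tss` data.frame.
#' @param spacer_range,anchor_range Passed through.
#' @return A data.frame with one row per TSS: `tss_id`, `minus10_start`,
#'   `minus10_seq`, `minus10_ri`, `spacer`, `tssr`, `is_yry`,
#'   `minus10lr_start`, `minus10lr_anchor`, `minus10lr_seq`,
#'   `minus10lr_ri`, `minus10lr_weak`.  Elements that do not fit the
#'   contig are NA.
#' @export
promoter_elements <- function(model, genome, tss, spacer_range = 3:9,
                              anchor_range = -1:2) {
  rows <- lapply(seq_len(nrow(tss)), function(i) {
    t1 <- tss[i, , drop = FALSE]
    m10 <- suppressWarnings(find_minus10(model, genome, t1, spacer_range))
    tr <- classify_tssr(genome, t1)
    lr <- scan_minus10_like(model, genome, t1, anchor_range)
    data.frame(
      tss_id = t1$id,
      minus10_start = if (is.null(m10)) NA_integer_ else m10$start,
      minus10_seq = if (is.null(m10)) NA_character_ else m10$seq,
      minus10_ri = if (is.null(m10)) NA_real_ else m10$ri,
      spacer = if (is.null(m10)) NA_integer_ else m10$spacer,
      tssr = if (is.null(tr)) NA_character_ else tr$triplet,
      is_yry = if (is.null(tr)) NA else tr$is_yry,
      minus10lr_start = if (is.null(lr)) NA_integer_ else lr$start,
      minus10lr_anchor = if (is.null(lr)) NA_integer_ else lr$anchor,
      minus10lr_seq = if (is.null(lr)) NA_character_ else lr$seq,
      minus10lr_ri = if (is.null(lr)) NA_real_ else lr$ri,
      minus10lr_weak = if (is.null(lr)) NA else lr$weak,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Joint spacer-length / Ri distribution of annotated promoters
#'
#' @param elements Output of [promoter_elements()].
#' @param ri_breaks Bin edges for Ri in bits; default integer-bit bins
#'   covering the observed range.
#' @return A list with `counts` (spacer x Ri-bin matrix), `spacer_marginal`
#'   and `ri_marginal`.
#' @export
spacer_ri_table <- function(elements, ri_breaks = NULL) {
  keep <- !is.na(elements$spacer) & !is.na(elements$minus10_ri)
  sp <- elements$spacer[keep]
  ri <- elements$minus10_ri[keep]
  if (!length(sp)) {
    return(list(counts = matrix(0L, 0L, 0L),
                spacer_marginal = integer(0), ri_marginal = integer(0)))
  }
  if (is.null(ri_breaks))
    ri_breaks <- seq(floor(min(ri)), ceiling(max(ri)) + 1e-9)
  bin <- cut(ri, ri_breaks, include.lowest = TRUE, right = FALSE)
  counts <- table(spacer = factor(sp, levels = sort(unique(sp))), ri = bin)
  counts <- unclass(counts)
  list(counts = counts,
       spacer_marginal = rowSums(counts),
       ri_marginal = colSums(counts))
}

#' Per-position information profile of an alignment (logo heights)
#'
#' @param aligned_seqs Equal-length sequences over A/C/G/T.
#' @return A list: `info` (per position `2 - H(l)` bits, where `H(l)` is
#'   the Shannon entropy of the base frequencies), `heights` (4 x width
#'   matrix `f(b,l) * info(l)`, the stacked letter heights of a sequence
#'   logo) and `freq`.
#' @export
info_profile <- function(aligned_seqs) {
  seqs <- toupper(as.character(aligned_seqs))
  w <- unique(nchar(seqs))
  stopifnot(length(w) == 1L)
  chars <- do.call(rbind, strsplit(seqs, ""))
  freq <- apply(chars, 2L, function(col)
    table(factor(col, levels = BASES)) / length(col))
  h <- apply(freq, 2L, function(f) -sum(ifelse(f > 0, f * log2(f), 0)))
  info <- 2 - h
  heights <- sweep(freq, 2L, info, `*`)
  list(info = info, heights = heights, freq = freq)
}
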