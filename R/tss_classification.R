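# TSS-relative classification of pauses.  Distance convention: d = 0
# means the pause 3' end sits on the TSS base; positive d is downstream
# along the TSS strand.  Groups are inclusive integer windows:
# G0 -2..3, G1p 10..15, G1d 16..20, G2 31..39; everything else "other".

#' Signed distance from a pause to the nearest same-strand TSS
#'
#' @param pauses An `sp_pauses` data.frame.
#' @param tss An `sp_tss` data.frame.
#' @return The pause table with `tss_id` and `distance` columns appended
#'   (NA when no same-strand TSS exists on the contig).  Among
#'   equidistant TSSs the one placing the pause downstream (non-negative
#'   distance) wins: pauses are products of transcription initiated
#'   upstream.
#' @export
nearest_tss <- function(pauses, tss) {
  n <- nrow(pauses)
  tss_id <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    cand <- tss[tss$strand == pauses$strand[i] &
                tss$contig == pauses$contig[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    d <- if (pauses$strand[i] == "+") pauses$position[i] - cand$position
         else cand$position - pauses$position[i]
    best <- which(abs(d) == min(abs(d)))
    if (length(best) > 1L) best <- best[which.max(d[best] >= 0L)]
    tss_id[i] <- cand$id[best]
    distance[i] <- d[best]
  }
  pauses$tss_id <- tss_id
  pauses$distance <- distance
  pauses
}

#' Assign the TSS-distance group of a pause
#'
#' @param distance Integer vector of signed TSS distances (NA allowed).
#' @return Character vector over \{"G0","G1p","G1d","G2","other"\}; the
#'   five labels partition the integers (boundaries inclusive), NA maps
#'   to "other".
#' @export
classify_distance <- function(distance) {
  out <- rep("other", length(distance))
  out[!is.na(distance) & distance >= -2L & distance <= 3L] <- "G0"
  out[!is.na(distance) & distance >= 10L & distance <= 15L] <- "G1p"
  out[!is.na(distance) & distance >= 16L & distance <= 20L] <- "G1d"
  out[!is.na(distance) & distance >= 31L & distance <= 39L] <- "G2"
  out
}

#' Annotate pauses with TSS link, distance group and feature category
#'
#' @param pauses An `sp_pauses` data.frame.
#' @param tss An `sp_tss` data.frame.
#' @param features Optional feature table from [load_features()]; adds a
#'   `feature` column via [feature_category()].
#' @param max_utr See [feature_category()].
#' @return The pause table with `tss_id`, `distance`, `group` (and
#'   `feature`) columns.
#' @export
annotate_pauses <- function(pauses, tss, features = NULL, max_utr = 300L) {
  out <- nearest_tss(pauses, tss)
  out$group <- classify_distance(out$distance)
  if (!is.null(features)) out$feature <- feature_category(out, features,
                                                          tss, max_utr)
  out
}

#' Keep only the strongest pause per TSS
#'
#' When several pauses map to the same TSS, only the one with the
#' maximal pause score is retained (ties: smaller |distance|, then
#' smaller coordinate).  Pauses without a TSS link are kept as-is.
#'
#' @param annotations Output of [annotate_pauses()] / [nearest_tss()].
#' @return The filtered table, at most one row per `tss_id`, in input
#'   order of the retained rows after sorting by (contig, position).
#' @export
strongest_per_tss <- function(annotations) {
  linked <- !is.na(annotations$tss_id)
  a <- annotations[linked, , drop = FALSE]
  if (nrow(a) > 0L) {
    ord <- order(a$tss_id, -a$pause_score, abs(a$distance), a$position)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(a$tss_id), , drop = FALSE]
  }
  out <- rbind(a, annotations[!linked, , drop = FALSE])
  out <- out[order(out$contig, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign a genomic feature category to each pause
#'
#' Same-strand overlap wins with precedence rRNA > tRNA > ncRNA > CDS >
#' UTR; structural RNAs outrank CDS because they dominate false-positive
#' peak statistics.  A pause overlapping only an opposite-strand feature
#' is "Antisense" (antisense to CDS, tRNA, rRNA or ncRNA alike);
#' otherwise "intergenic".  The 5' UTR of a gene is the span from a TSS
#' to the start of the nearest downstream same-strand CDS within
#' `max_utr` nt, unless the GFF3 provides explicit `five_prime_UTR`
#' rows.
#'
#' @param pauses An `sp_pauses` data.frame.
#' @param features Feature table ([load_features()]).
#' @param tss Optional `sp_tss` table used to derive UTR spans.
#' @param max_utr Maximal derived UTR length in nt.
#' @return Character vector of categories.
#' @export
feature_category <- function(pauses, features, tss = NULL, max_utr = 300L) {
  type <- tolower(features$type)
  type[type %in% c("five_prime_utr", "5'utr", "utr")] <- "utr"
  keep <- type %in% c("rrna", "trna", "ncrna", "cds", "utr")
  feats <- features[keep, , drop = FALSE]
  feats$type <- type[keep]
  utrs <- derive_utrs(feats, tss, max_utr)
  if (!is.null(utrs)) feats <- rbind(feats[, names(utrs)], utrs)
  prec <- c(rrna = 1L, trna = 2L, ncrna = 3L, cds = 4L, utr = 5L)
  label <- c(rrna = "rRNA", trna = "tRNA", ncrna = "ncRNA", cds = "CDS",
             utr = "UTR")
  vapply(seq_len(nrow(pauses)), function(i) {
    p <- pauses$position[i]
    ov <- feats$contig == pauses$contig[i] & feats$start <= p & feats$end > p
    same <- ov & feats$strand == pauses$strand[i]
    if (any(same)) {
      t <- feats$type[same]
      return(label[[t[which.min(prec[t])]]])
    }
    if (any(ov)) return("Antisense")
    "intergenic"
  }, character(1))
}

derive_utrs <- function(feats, tss, max_utr) {
  if (is.null(tss) || nrow(tss) == 0L) return(NULL)
  cds <- feats[feats$type == "cds", , drop = FALSE]
  if (nrow(cds) == 0L) return(NULL)
  rows <- lapply(seq_len(nrow(tss)), function(i) {
    cc <- cds[cds$contig == tss$contig[i] & cds$strand == tss$strand[i], ,
              drop = FALSE]
    if (nrow(cc) == 0L) return(NULL)
    if (tss$strand[i] == "+") {
      d <- cc$start - tss$position[i]
      ok <- d > 0L & d <= max_utr
      if (!any(ok)) return(NULL)
      s <- tss$position[i]; e <- min(cc$start[ok])
    } else {
      d <- tss$position[i] - (cc$end - 1L)
      ok <- d > 0L & d <= max_utr
      if (!any(ok)) return(NULL)
      s <- max(cc$end[ok]); e <- tss$position[i] + 1L
    }
    data.frame(contig = tss$contig[i], start = s, end = e,
               strand = tss$strand[i], type = "utr",
               id = paste0("utr_", tss$id[i]), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' TSS-anchored normalized count matrix
#'
#' For each TSS, extracts the strand-oriented window (default -50..+200,
#' the position axis running 5' to 3' of the TSS strand) of 3'-end
#' counts, normalizes the sense lane to each row's own maximum (in
#' `[0, 1]`) and the antisense lane to its own maximum negated (in
#' `[-1, 0]`).  All-zero lanes stay zero.  Rows whose window leaves the
#' contig are dropped with a warning.
#'
#' @param track An `EndCountTrack`.
#' @param tss An `sp_tss` data.frame; duplicated (contig, position,
#'   strand) rows -- e.g. regions shared by several pauses -- are
#'   collapsed to one row.
#' @param window Integer length-2 vector `c(upstream, downstream)`
#'   relative to the TSS (default `c(-50, 200)`).
#' @return A list with matrices `sense` and `antisense` (rows named by
#'   TSS id, columns by TSS-relative offset) and the retained `tss`
#'   table.
#' @export
region_matrix <- function(track, tss, window = c(-50L, 200L)) {
  stopifnot(window[1] < 0, window[2] > 0)
  dup <- duplicated(tss[, c("contig", "position", "strand")])
  tss <- tss[!dup, , drop = FALSE]
  offs <- window[1]:window[2]
  ok <- logical(nrow(tss))
  sense <- antisense <- matrix(0, nrow(tss), length(offs),
                               dimnames = list(tss$id, offs))
  for (i in seq_len(nrow(tss))) {
    len <- track$contig_lengths[[tss$contig[i]]]
    pos <- if (tss$strand[i] == "+") tss$position[i] + offs
           else tss$position[i] - offs
    if (min(pos) < 0L || max(pos) >= len) next
    ok[i] <- TRUE
    anti <- if (tss$strand[i] == "+") "-" else "+"
    s <- track$counts[[tss$strand[i]]][[tss$contig[i]]][pos + 1L]
    a <- track$counts[[anti]][[tss$contig[i]]][pos + 1L]
    if (max(s) > 0) sense[i, ] <- s / max(s)
    if (max(a) > 0) antisense[i, ] <- -a / max(a)
  }
  if (any(!ok)) warning(sum(!ok), " TSS region(s) out of contig bounds dropped")
  list(sense = sense[ok, , drop = FALSE],
       antisense = antisense[ok, , drop = FALSE],
       tss = tss[ok, , drop = FALSE])
}
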