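#' @importFrom stats median quantile rpois runif setNames wilcox.test
#' @importFrom utils read.delim write.table head tail
NULL

# All genomic coordinates inside the package are 0-based, half-open
# ([start, end)), matching BED.  The TSV TSS dialect is 1-based and is
# converted on input.  The RNA 3' end of a read is the last transcribed
# base: end - 1 on the plus strand, start on the minus strand.

#' Read aligned nascent-read records from a BED6 file
#'
#' Each line describes the RNase-protected 3'-proximal fragment of one
#' nascent transcript as an aligned interval.  Coordinates are taken at
#' face value (BED is 0-based half-open); no alignment post-processing is
#' performed -- reads are assumed uniquely mapped and deduplicated
#' upstream.
#'
#' @param path Path to a 6-column tab-separated BED file.
#' @return A data.frame of class `sp_reads` with columns `contig`,
#'   `start`, `end`, `name`, `strand`, `length` (nt) and `end3` (0-based
#'   genomic coordinate of the RNA 3' end).
#' @details Lines with `end <= start` are rejected individually with a
#'   warning naming the line number; a file without a strand column is
#'   rejected outright.  An empty file yields an empty record set with a
#'   warning.
#' @export
load_reads <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    warning("no read records in ", path)
    return(empty_reads())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 6L)) {
    stop("BED6 required: line(s) ", paste(which(ncol < 6L), collapse = ","),
         " of ", path, " have fewer than 6 columns (no strand?)")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  strand <- m[, 6L]
  if (!all(strand %in% c("+", "-"))) {
    stop("strand column must be '+' or '-' in ", path)
  }
  start <- as.integer(m[, 2L])
  end <- as.integer(m[, 3L])
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad)) {
    warning("rejecting ", length(bad), " malformed read line(s): ",
            paste(head(bad, 10L), collapse = ","))
    keep <- setdiff(seq_along(lines), bad)
    m <- m[keep, , drop = FALSE]
    start <- start[keep]; end <- end[keep]; strand <- strand[keep]
  }
  reads(contig = m[, 1L], start = start, end = end,
        name = m[, 4L], strand = strand)
}

#' Construct a read record set from vectors
#'
#' @param contig,start,end,strand,name Per-read fields; coordinates
#'   0-based half-open.
#' @return An `sp_reads` data.frame (see [load_reads()]).
#' @export
reads <- function(contig, start, end, strand, name = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(all(strand %in% c("+", "-")), all(end > start), all(start >= 0L))
  if (is.null(name)) {
    name <- if (length(start)) paste0("r", seq_along(start)) else character(0)
  }
  df <- data.frame(contig = as.character(contig), start = start, end = end,
                   name = as.character(name), strand = as.character(strand),
                   stringsAsFactors = FALSE)
  df$length <- df$end - df$start
  df$end3 <- ifelse(df$strand == "+", df$end - 1L, df$start)
  class(df) <- c("sp_reads", "data.frame")
  df
}

empty_reads <- function() {
  reads(character(), integer(), integer(), character())[0L, ]
}

#' Build strand-specific 3'-end count tracks
#'
#' Tallies, per contig and strand, the number of reads whose RNA 3' end
#' falls at each genomic position.
#'
#' @param reads An `sp_reads` data.frame.
#' @param contig_lengths Named integer vector of contig lengths.
#' @return An `EndCountTrack`: a list with `counts[[strand]][[contig]]`
#'   (integer vector, index `p + 1` holds the count at 0-based position
#'   `p`), `contig_lengths`, and `total_reads`.
#' @export
build_track <- function(reads, contig_lengths) {
  stopifnot(!is.null(names(contig_lengths)), all(contig_lengths > 0))
  contig_lengths <- setNames(as.integer(contig_lengths), names(contig_lengths))
  unknown <- setdiff(unique(reads$contig), names(contig_lengths))
  if (length(unknown)) stop("reads on undeclared contig(s): ",
                            paste(unknown, collapse = ","))
  over <- reads$end > contig_lengths[reads$contig] | reads$start < 0L
  if (any(over)) {
    stop("read(s) beyond contig bounds: ",
         paste(head(reads$name[over], 5L), collapse = ","))
  }
  counts <- list()
  for (s in c("+", "-")) {
    counts[[s]] <- lapply(names(contig_lengths), function(ctg) {
      sel <- reads$strand == s & reads$contig == ctg
      tabulate(reads$end3[sel] + 1L, nbins = contig_lengths[[ctg]])
    })
    names(counts[[s]]) <- names(contig_lengths)
  }
  structure(list(counts = counts, contig_lengths = contig_lengths,
                 total_reads = nrow(reads)),
            class = "EndCountTrack")
}

#' @export
print.EndCountTrack <- function(x, ...) {
  cat("EndCountTrack:", length(x$contig_lengths), "contig(s),",
      x$total_reads, "reads\n")
  invisible(x)
}

#' Read transcription start sites
#'
#' Accepts BED6 (`position = start`, 0-based) or a 3/4-column TSV
#' `chrom position strand [id]` in which `position` is 1-based and is
#' converted to the internal 0-based convention.
#'
#' @param path Input file.
#' @param format `"bed"`, `"tsv"`, or `"auto"` (by extension; anything
#'   not ending in `.bed` must be declared explicitly).
#' @return An `sp_tss` data.frame with `contig`, `position` (0-based),
#'   `strand`, `id`.
#' @export
load_tss <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    if (grepl("\\.bed$", path, ignore.case = TRUE)) format <- "bed"
    else if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) format <- "tsv"
    else stop("cannot infer TSS dialect from '", path,
              "': pass format = 'bed' or 'tsv'")
  }
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (format == "bed") {
    stopifnot(ncol(tab) >= 6L)
    out <- tss(contig = tab[[1L]], position = tab[[2L]], strand = tab[[6L]],
               id = tab[[4L]])
  } else {
    stopifnot(ncol(tab) >= 3L)
    id <- if (ncol(tab) >= 4L) tab[[4L]] else paste0("tss", seq_len(nrow(tab)))
    out <- tss(contig = tab[[1L]], position = as.integer(tab[[2L]]) - 1L,
               strand = tab[[3L]], id = id)
  }
  out
}

#' Construct a TSS record set
#' @param contig,position,strand,id Per-TSS fields, `position` 0-based.
#' @return An `sp_tss` data.frame.
#' @export
tss <- function(contig, position, strand, id = NULL) {
  position <- as.integer(position)
  stopifnot(all(strand %in% c("+", "-")), all(position >= 0L))
  if (is.null(id)) id <- paste0("tss", seq_along(position))
  if (anyDuplicated(id)) stop("TSS ids must be unique")
  df <- data.frame(contig = as.character(contig), position = position,
                   strand = as.character(strand), id = as.character(id),
                   stringsAsFactors = FALSE)
  class(df) <- c("sp_tss", "data.frame")
  df
}

#' Read a strandless exclusion mask (rRNA/tRNA/repeats) from BED
#'
#' Intervals are merged and sorted per contig; masking is strandless
#' because a repetitive locus contaminates peak statistics on both
#' strands.
#'
#' @param path BED file (first three columns used).
#' @return A `MaskSet`: per contig a two-column matrix of merged 0-based
#'   half-open intervals.
#' @export
load_mask <- function(path) {
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) return(mask_set(list()))
  stopifnot(ncol(tab) >= 3L)
  iv <- split(data.frame(start = as.integer(tab[[2L]]),
                         end = as.integer(tab[[3L]])),
              as.character(tab[[1L]]))
  mask_set(lapply(iv, function(d) cbind(start = d$start, end = d$end)))
}

#' Construct a mask set from raw intervals
#' @param intervals Named list (by contig) of 2-column matrices
#'   `start`,`end`, 0-based half-open; overlapping intervals are merged.
#' @return A `MaskSet`.
#' @export
mask_set <- function(intervals) {
  merged <- lapply(intervals, function(m) {
    if (is.null(dim(m))) m <- matrix(m, ncol = 2L)
    stopifnot(all(m[, 2L] > m[, 1L]), all(m[, 1L] >= 0L))
    ir <- IRanges::reduce(IRanges::IRanges(start = m[, 1L] + 1L,
                                           end = m[, 2L]))
    cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
  structure(list(intervals = merged), class = "MaskSet")
}

#' Test mask membership
#' @param mask A `MaskSet` (or NULL for no masking).
#' @param contig,position Vectors of positions (0-based).
#' @return Logical vector: TRUE where the position lies in a masked
#'   interval.
#' @export
in_mask <- function(mask, contig, position) {
  if (is.null(mask)) return(rep(FALSE, length(position)))
  stopifnot(inherits(mask, "MaskSet"))
  out <- logical(length(position))
  for (ctg in unique(contig)) {
    m <- mask$intervals[[ctg]]
    if (is.null(m)) next
    sel <- contig == ctg
    p <- position[sel]
    hit <- vapply(p, function(x) any(x >= m[, 1L] & x < m[, 2L]), logical(1))
    out[sel] <- hit
  }
  out
}

#' Write called pauses as BED6 plus a TSV table
#'
#' The BED interval is the single 3'-end base `[p, p+1)`; the BED score
#' column carries the pause score (capped at 1000 per BED convention,
#' uncapped in the TSV).  The TSV carries every column of the pause
#' table, including any annotation and promoter-element columns.
#'
#' @param pauses A pause data.frame (from [call_pauses()], possibly
#'   annotated).
#' @param prefix Output path prefix: writes `<prefix>.bed` and
#'   `<prefix>.tsv`.
#' @return Invisibly, the two paths written.
#' @export
write_pauses <- function(pauses, prefix) {
  bed <- data.frame(pauses$contig, pauses$position, pauses$position + 1L,
                    paste0("pause", seq_len(nrow(pauses))),
                    pmin(round(pauses$pause_score), 1000L), pauses$strand)
  bed_path <- paste0(prefix, ".bed")
  tsv_path <- paste0(prefix, ".tsv")
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(pauses, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed = bed_path, tsv = tsv_path))
}

#' Read back a pause TSV written by [write_pauses()]
#' @param path The `.tsv` path.
#' @return A pause data.frame.
#' @export
load_pauses <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$position <- as.integer(df$position)
  class(df) <- c("sp_pauses", "data.frame")
  df
}

#' Write per-strand bedGraph tracks of 3'-end counts
#' @param track An `EndCountTrack`.
#' @param prefix Output prefix: writes `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph` (nonzero positions only).
#' @return Invisibly, the paths written.
#' @export
write_bedgraph <- function(track, prefix) {
  paths <- c()
  for (s in c("+", "-")) {
    rows <- do.call(rbind, lapply(names(track$counts[[s]]), function(ctg) {
      v <- track$counts[[s]][[ctg]]
      nz <- which(v > 0L)
      if (!length(nz)) return(NULL)
      data.frame(ctg, nz - 1L, nz, v[nz])
    }))
    p <- paste0(prefix, if (s == "+") ".plus" else ".minus", ".bedgraph")
    if (is.null(rows)) rows <- data.frame(a = character(), b = integer(),
                                          c = integer(), d = integer())
    write.table(rows, p, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Load a genome FASTA
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
load_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Load gene/feature annotations from GFF3
#'
#' Parsed with rtracklayer and converted to the package's 0-based
#' half-open convention.
#'
#' @param path GFF3 file.
#' @return A data.frame with `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `type`, `id`.
#' @export
load_features <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  id <- as.character(S4Vectors::mcols(gr)$ID)
  if (is.null(id) || all(is.na(id))) id <- paste0("feat", seq_along(gr))
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = id,
    stringsAsFactors = FALSE
  )
}
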