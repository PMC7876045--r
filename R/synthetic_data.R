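# Synthetic genomes and nascent-read datasets with planted ground truth.
# The generator emulates the structure the analysis assumes: Poisson
# 3'-end background over transcribed spans (lower rate elsewhere),
# deterministic pause spikes of a configured fold over the local
# background, promoter elements (-10 hexamer, spacer, YRY start-site
# triplet, and for distal-pause promoters a -10-like region one helical
# turn downstream of the -10), and class-specific read-length mixtures.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
CONSENSUS10 <- c("T", "A", "T", "A", "A", "T")

#' Simulation configuration
#'
#' @param seed Integer seed; all randomness in [generate_genome()] and
#'   [simulate_reads()] flows from it.
#' @param genome_length Contig length in nt.
#' @param gc_content GC fraction of the background sequence.
#' @param n_g1p,n_g1d,n_none Promoters per class.  G1p promoters plant a
#'   pause 10-15 nt downstream of the TSS with short (<= offset + 1)
#'   reads; G1d promoters plant one 16-20 nt downstream with 16-20-nt
#'   reads including a backtracked (>18 nt) mass, plus a -10-like
#'   hexamer whose start sits 11 nt downstream of the -10 element start;
#'   "none" promoters transcribe without a planted pause.
#' @param background_rate Mean 3' ends per transcribed position
#'   (Poisson).
#' @param intergenic_rate Mean 3' ends per untranscribed position.
#' @param transcribed_span Transcribed nt downstream of each TSS.
#' @param fold Planted spike multiplier; the spike count is the
#'   deterministic `round(fold * background_rate)` so threshold behavior
#'   is exact.
#' @param spacer Planted spacer length (nt strictly between the -10
#'   hexamer and the TSS).
#' @param minus10_strength,minus10lr_strength Per-base probability of
#'   the consensus TATAAT base at the planted elements (1 = consensus).
#' @param backtrack_mass Probability mass on >18-nt read lengths at G1d
#'   pauses (split evenly over 19/20; the rest is uniform on 16-18).
#' @param total_reads Optional target library size; when set, both
#'   background rates are scaled so the expected total matches.
#' @param min_spacing Minimal distance between promoter TSSs (the
#'   generator refuses layouts with promoters closer than this).
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 120000L,
                       gc_content = 0.5, n_g1p = 50L, n_g1d = 50L,
                       n_none = 0L, background_rate = 2,
                       intergenic_rate = 0.05, transcribed_span = 250L,
                       fold = 30, spacer = 6L, minus10_strength = 1,
                       minus10lr_strength = 1, backtrack_mass = 0.2,
                       total_reads = NULL, min_spacing = 600L) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              gc_content = gc_content, n_g1p = as.integer(n_g1p),
              n_g1d = as.integer(n_g1d), n_none = as.integer(n_none),
              background_rate = background_rate,
              intergenic_rate = intergenic_rate,
              transcribed_span = as.integer(transcribed_span),
              fold = fold, spacer = as.integer(spacer),
              minus10_strength = minus10_strength,
              minus10lr_strength = minus10lr_strength,
              backtrack_mass = backtrack_mass, total_reads = total_reads,
              min_spacing = as.integer(min_spacing))
  stopifnot(cfg$gc_content > 0, cfg$gc_content < 1, cfg$fold > 1,
            cfg$background_rate > 0, cfg$intergenic_rate >= 0,
            cfg$spacer >= 3L, cfg$spacer <= 9L,
            cfg$backtrack_mass >= 0, cfg$backtrack_mass <= 1,
            cfg$transcribed_span > 25L)
  class(cfg) <- "SimConfig"
  cfg
}

sim_n_prom <- function(cfg) cfg$n_g1p + cfg$n_g1d + cfg$n_none

set_tss_offset_base <- function(seq, tss_pos, strand, offset, base) {
  if (strand == "+") seq[tss_pos + offset + 1L] <- base
  else seq[tss_pos - offset + 1L] <- COMPLEMENT[[base]]
  seq
}

sample_element <- function(strength) {
  vapply(CONSENSUS10, function(b)
    if (runif(1) < strength) b else sample(BASES, 1L), character(1))
}

#' Generate a synthetic genome with planted promoters
#'
#' Draw order (fixed for reproducibility): background sequence, promoter
#' strands, class permutation, then per promoter the -10 hexamer, the
#' class-specific start-site / -10-like bases, and the pause offset.
#'
#' @param config A `SimConfig`.
#' @return A list: `genome` (DNAStringSet, one contig "chrSim"), `truth`
#'   (data.frame, one row per promoter: tss id/position/strand, class,
#'   planted element sequences and coordinates, pause offset/position,
#'   fold, expected spike count) and `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  n <- sim_n_prom(config)
  L <- config$genome_length
  margin <- 400L
  step <- if (n > 0L) (L - 2L * margin) %/% n else L
  if (n > 0L && step < config$min_spacing)
    stop("promoters do not fit: spacing ", step, " nt < min_spacing ",
         config$min_spacing)
  set.seed(config$seed)
  p_gc <- config$gc_content / 2
  seq <- sample(BASES, L, replace = TRUE,
                prob = c((1 - config$gc_content) / 2, p_gc, p_gc,
                         (1 - config$gc_content) / 2))
  if (n == 0L) {
    return(list(genome = Biostrings::DNAStringSet(
      setNames(paste(seq, collapse = ""), "chrSim")),
      truth = NULL, config = config))
  }
  tss_pos <- margin + step %/% 2L + step * (seq_len(n) - 1L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  class <- sample(rep(c("G1p", "G1d", "none"),
                      c(config$n_g1p, config$n_g1d, config$n_none)))
  truth <- data.frame(tss_id = sprintf("p%03d", seq_len(n)),
                      contig = "chrSim", tss = tss_pos, strand = strand,
                      class = class, stringsAsFactors = FALSE)
  truth$minus10_seq <- NA_character_
  truth$minus10_start <- NA_integer_
  truth$spacer <- config$spacer
  truth$tssr <- NA_character_
  truth$minus10lr_seq <- NA_character_
  truth$minus10lr_start <- NA_integer_
  truth$pause_offset <- NA_integer_
  truth$pause_pos <- NA_integer_
  truth$fold <- ifelse(class == "none", NA_real_, config$fold)
  truth$expected_count <- ifelse(class == "none", NA_real_,
                                 round(config$fold * config$background_rate))
  sgn <- ifelse(strand == "+", 1L, -1L)
  for (i in seq_len(n)) {
    sp <- config$spacer
    # -10 element at TSS-strand offsets -(sp+6) .. -(sp+1)
    hex <- sample_element(config$minus10_strength)
    for (k in seq_len(6L)) {
      seq <- set_tss_offset_base(seq, tss_pos[i], strand[i],
                                 -(sp + 7L) + k, hex[k])
    }
    truth$minus10_seq[i] <- paste(hex, collapse = "")
    truth$minus10_start[i] <- tss_pos[i] - sgn[i] * (sp + 6L)
    if (class[i] == "G1p") {
      tri <- c(sample(c("C", "T"), 1L), sample(c("A", "G"), 1L),
               sample(c("C", "T"), 1L))
      for (k in 1:3) seq <- set_tss_offset_base(seq, tss_pos[i], strand[i],
                                                k - 2L, tri[k])
      truth$tssr[i] <- paste(tri, collapse = "")
    } else if (class[i] == "G1d") {
      # -10LR start 11 nt downstream of the -10 start: offset 5 - spacer
      lr <- sample_element(config$minus10lr_strength)
      off0 <- 5L - sp
      for (k in seq_len(6L)) {
        seq <- set_tss_offset_base(seq, tss_pos[i], strand[i],
                                   off0 + k - 1L, lr[k])
      }
      truth$minus10lr_seq[i] <- paste(lr, collapse = "")
      truth$minus10lr_start[i] <- tss_pos[i] + sgn[i] * off0
    }
    truth$tssr[i] <- paste(
      vapply(-1:1, function(k) {
        b <- seq[tss_pos[i] + sgn[i] * k + 1L]
        if (strand[i] == "+") b else COMPLEMENT[[b]]
      }, character(1)), collapse = "")
    if (class[i] != "none") {
      truth$pause_offset[i] <- if (class[i] == "G1p") sample(10:15, 1L)
                               else sample(16:20, 1L)
      truth$pause_pos[i] <- tss_pos[i] + sgn[i] * truth$pause_offset[i]
    }
  }
  genome <- Biostrings::DNAStringSet(setNames(paste(seq, collapse = ""),
                                              "chrSim"))
  list(genome = genome, truth = truth, config = config)
}

#' Extract the TSS table of a simulation
#' @param sim Output of [generate_genome()].
#' @return An `sp_tss` data.frame.
#' @export
truth_tss <- function(sim) {
  tss(contig = sim$truth$contig, position = sim$truth$tss,
      strand = sim$truth$strand, id = sim$truth$tss_id)
}

g1d_length_probs <- function(mass) {
  c(rep((1 - mass) / 3, 3L), rep(mass / 2, 2L))  # lengths 16..20
}

#' Simulate nascent reads over a synthetic genome
#'
#' Per-position 3'-end counts are Poisson: `background_rate` over each
#' promoter's transcribed span (on its strand), `intergenic_rate`
#' elsewhere on both strands.  The planted pause position's count is set
#' to the deterministic `round(fold * background_rate)`.  Read lengths:
#' at G1p pauses `min(offset + 1, U{10..15})` (the 5' end cannot extend
#' upstream of the TSS); at G1d pauses a categorical over 16-20 with
#' `backtrack_mass` above 18 nt; elsewhere 16-18 nt centered on 17,
#' truncated at the TSS inside transcribed spans and at contig bounds.
#' Seeding: uses `config$seed + 1` so the read stage is reproducible
#' independently of the genome stage.
#'
#' @param sim Output of [generate_genome()].
#' @return A list: `reads` (`sp_reads`), `expected_counts` (data.frame of
#'   planted pause positions with their deterministic spike counts).
#' @export
simulate_reads <- function(sim) {
  config <- sim$config
  truth <- sim$truth
  L <- config$genome_length
  set.seed(config$seed + 1L)
  lambda <- config$background_rate
  lambda_i <- config$intergenic_rate
  spike <- round(config$fold * lambda)
  if (!is.null(config$total_reads)) {
    n_spikes <- sum(!is.na(truth$pause_pos))
    span_pos <- sim_n_prom(config) * config$transcribed_span
    expected_bg <- span_pos * lambda + (2L * L - span_pos) * lambda_i
    scale <- (config$total_reads - n_spikes * spike) / expected_bg
    if (scale <= 0) stop("total_reads target too small for the spikes")
    lambda <- lambda * scale
    lambda_i <- lambda_i * scale
  }
  counts <- list("+" = rpois(L, lambda_i), "-" = rpois(L, lambda_i))
  prom_of <- list("+" = integer(L), "-" = integer(L))  # 1-based index
  for (i in seq_len(nrow(truth))) {
    s <- truth$strand[i]
    pos <- if (s == "+") truth$tss[i] + 0:(config$transcribed_span - 1L)
           else truth$tss[i] - 0:(config$transcribed_span - 1L)
    pos <- pos[pos >= 0L & pos < L]
    counts[[s]][pos + 1L] <- rpois(length(pos), lambda)
    prom_of[[s]][pos + 1L] <- i
  }
  pp <- !is.na(truth$pause_pos)
  for (i in which(pp)) {
    counts[[truth$strand[i]]][truth$pause_pos[i] + 1L] <- spike
  }
  if (sum(counts[["+"]]) + sum(counts[["-"]]) == 0L)
    stop("simulation produced zero reads")
  out <- list()
  for (s in c("+", "-")) {
    v <- counts[[s]]
    nz <- which(v > 0L)
    pos <- rep(nz - 1L, v[nz])
    prom <- rep(prom_of[[s]][nz], v[nz])
    n <- length(pos)
    len <- sample(16:18, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    # class-specific lengths at planted pauses; G1d keeps its drawn
    # mixture (the configured backtracked mass is authoritative), so it
    # is exempt from the TSS cap below, which would otherwise erode the
    # >18-nt fraction at 16-17-nt offsets
    g1d_read <- logical(n)
    for (i in which(pp & truth$strand == s)) {
      at <- which(pos == truth$pause_pos[i])
      if (!length(at)) next
      if (truth$class[i] == "G1p") {
        len[at] <- pmin(truth$pause_offset[i] + 1L,
                        sample(10:15, length(at), replace = TRUE))
      } else {
        len[at] <- sample(16:20, length(at), replace = TRUE,
                          prob = g1d_length_probs(config$backtrack_mass))
        g1d_read[at] <- TRUE
      }
    }
    # truncate the 5' end at the TSS inside transcribed spans
    trunc <- prom > 0L & !g1d_read
    if (any(trunc)) {
      d <- abs(pos[trunc] - truth$tss[prom[trunc]])
      len[trunc] <- pmin(len[trunc], d + 1L)
    }
    # truncate at contig bounds
    len <- if (s == "+") pmin(len, pos + 1L) else pmin(len, L - pos)
    start <- if (s == "+") pos - len + 1L else pos
    end <- start + len
    out[[s]] <- data.frame(contig = "chrSim", start = start, end = end,
                           strand = s, stringsAsFactors = FALSE)
  }
  df <- rbind(out[["+"]], out[["-"]])
  rd <- reads(contig = df$contig, start = df$start, end = df$end,
              strand = df$strand)
  expected <- truth[pp, c("tss_id", "contig", "pause_pos", "strand",
                          "class", "pause_offset")]
  expected$expected_count <- spike
  list(reads = rd, expected_counts = expected)
}

#' Write a simulated dataset to disk
#'
#' Writes `genome.fa`, `reads.bed`, `tss.bed`, `mask.bed` (empty by
#' default) and `truth.tsv` under `outdir`.
#'
#' @param sim Output of [generate_genome()].
#' @param reads Output of [simulate_reads()] (or an `sp_reads` table).
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_sim <- function(sim, reads, outdir) {
  if (!is.null(reads$reads)) reads <- reads$reads
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, fa)
  bed <- file.path(outdir, "reads.bed")
  write.table(data.frame(reads$contig, reads$start, reads$end, reads$name,
                         0L, reads$strand),
              bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  tssf <- file.path(outdir, "tss.bed")
  tt <- truth_tss(sim)
  write.table(data.frame(tt$contig, tt$position, tt$position + 1L, tt$id,
                         0L, tt$strand),
              tssf, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  maskf <- file.path(outdir, "mask.bed")
  file.create(maskf)
  truthf <- file.path(outdir, "truth.tsv")
  write.table(sim$truth, truthf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(genome = fa, reads = bed, tss = tssf, mask = maskf,
              truth = truthf))
}
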