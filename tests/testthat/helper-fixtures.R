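# Shared fixtures and independent oracles.  Oracles deliberately use
# naive formulations (explicit loops, sort-and-pick medians, exhaustive
# enumeration) so they stay independent of the package implementation.

make_track <- function(plus, minus = integer(length(plus)),
                       contig = "chr1", total = NULL) {
  rows <- list()
  add <- function(v, s) {
    nz <- which(v > 0L)
    if (!length(nz)) return(NULL)
    pos <- rep(nz - 1L, v[nz])
    if (s == "+") data.frame(contig = contig, start = pos, end = pos + 1L,
                             strand = s)
    else data.frame(contig = contig, start = pos, end = pos + 1L, strand = s)
  }
  df <- rbind(add(as.integer(plus), "+"), add(as.integer(minus), "-"))
  if (is.null(df)) {
    rd <- sigmapause::reads(character(), integer(), integer(), character())
  } else {
    rd <- sigmapause::reads(df$contig, df$start, df$end, df$strand)
  }
  tr <- sigmapause::build_track(rd, setNames(length(plus), contig))
  if (!is.null(total)) tr$total_reads <- total
  tr
}

# sort-and-pick-middle median of the truncated window, written without
# stats::median or runmed
naive_window_median <- function(x, i, half) {
  w <- sort(x[max(1L, i - half):min(length(x), i + half)])
  n <- length(w)
  if (n %% 2L == 1L) w[(n + 1L) %/% 2L] else (w[n %/% 2L] + w[n %/% 2L + 1L]) / 2
}

# naive O(n w log w) pause caller used as the dual-route check
naive_call <- function(counts, total, min_fold = 20, min_cpm = 10,
                       window = 51L, floor = 1) {
  half <- window %/% 2L
  called <- integer(0)
  for (i in seq_along(counts)) {
    med <- naive_window_median(counts, i, half)
    score <- counts[i] / max(med, floor)
    cpm <- counts[i] * 1e6 / total
    if (score >= min_fold && cpm >= min_cpm) called <- c(called, i - 1L)
  }
  called
}

# per-position Ri by explicit table lookup, independent of ri_score
naive_ri <- function(model, s) {
  b <- strsplit(s, "")[[1]]
  tot <- 0
  for (l in seq_along(b)) {
    tot <- tot + 2 + log2(model$freq[b[l], l])
  }
  unname(tot)
}

all_hexamers <- function() {
  g <- expand.grid(rep(list(c("A", "C", "G", "T")), 6),
                   stringsAsFactors = FALSE)
  apply(g[, 6:1], 1L, paste, collapse = "")
}

random_seqs <- function(n, width, seed) {
  set.seed(seed)
  replicate(n, paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
                     collapse = ""))
}

write_bed6 <- function(df, path = tempfile(fileext = ".bed")) {
  writeLines(apply(df, 1L, paste, collapse = "\t"), path)
  path
}

# two-sided permutation test for a location difference in ranks
perm_ranksum_p <- function(a, b, nperm = 2000, seed = 7) {
  set.seed(seed)
  pooled <- c(a, b)
  obs <- sum(rank(pooled)[seq_along(a)])
  stat <- replicate(nperm, {
    idx <- sample(length(pooled), length(a))
    sum(rank(pooled)[idx])
  })
  mu <- length(a) * (length(pooled) + 1) / 2
  mean(abs(stat - mu) >= abs(obs - mu))
}
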