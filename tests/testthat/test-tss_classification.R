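fake_pauses <- function(position, strand = "+", contig = "chr1",
                        score = 100) {
  df <- data.frame(contig = contig, position = as.integer(position),
                   strand = strand, count = 50L, window_median = 1,
                   pause_score = score, cpm = 50, stringsAsFactors = FALSE)
  class(df) <- c("sp_pauses", "data.frame")
  df
}

test_that("nearest_tss distance follows the stated strand convention", {
  tt <- tss("chr1", 1000L, "+", "t1")
  a <- nearest_tss(fake_pauses(1010L), tt)
  expect_equal(a$distance, 10L)
  ttm <- tss("chr1", 1000L, "-", "t1")
  am <- nearest_tss(fake_pauses(990L, strand = "-"), ttm)
  expect_equal(am$distance, 10L)
  # no same-strand TSS -> NA link, group "other"
  none <- nearest_tss(fake_pauses(10L, strand = "-"), tt)
  expect_true(is.na(none$tss_id))
  expect_equal(classify_distance(none$distance), "other")
})

test_that("equidistant TSS ties resolve to the downstream assignment", {
  # exhaustive two-TSS scan: pause between two + TSSs at varying gaps
  for (gap in seq(2L, 40L, 2L)) {
    tt <- tss(c("chr1", "chr1"), c(1000L, 1000L + 2L * gap), "+",
              c("up", "dn"))
    a <- nearest_tss(fake_pauses(1000L + gap), tt)
    expect_equal(a$tss_id, "up")       # downstream of the upstream TSS
    expect_equal(a$distance, gap)
  }
  # minus strand mirror of the same rule
  tt <- tss(c("chr1", "chr1"), c(970L, 1030L), "-", c("dn", "up"))
  a <- nearest_tss(fake_pauses(1000L, strand = "-"), tt)
  expect_equal(a$tss_id, "up")
  expect_equal(a$distance, 30L)
})

test_that("distance groups partition the integers with inclusive bounds", {
  d <- -100:150
  g <- classify_distance(d)
  expect_true(all(g %in% c("G0", "G1p", "G1d", "G2", "other")))
  expect_equal(classify_distance(c(-2L, 0L, 3L)), rep("G0", 3))
  expect_equal(classify_distance(c(10L, 12L, 15L)), rep("G1p", 3))
  expect_equal(classify_distance(c(16L, 17L, 20L)), rep("G1d", 3))
  expect_equal(classify_distance(c(31L, 39L)), rep("G2", 2))
  expect_equal(classify_distance(c(-3L, 4L, 9L, 21L, 25L, 30L, 40L)),
               rep("other", 7))
  # windows recover exactly the printed sets
  expect_equal(d[g == "G0"], -2:3)
  expect_equal(d[g == "G1p"], 10:15)
  expect_equal(d[g == "G1d"], 16:20)
  expect_equal(d[g == "G2"], 31:39)
})

test_that("nearest_tss is invariant under translation and mirroring", {
  tt <- tss(c("chr1", "chr1"), c(500L, 900L), "+", c("a", "b"))
  p <- fake_pauses(c(512L, 880L))
  d0 <- nearest_tss(p, tt)$distance
  shift <- 1234L
  d1 <- nearest_tss(fake_pauses(p$position + shift),
                    tss("chr1", tt$position + shift, "+", tt$id))$distance
  expect_equal(d0, d1)
  L <- 2000L  # mirror: x -> L - 1 - x, strand flip
  d2 <- nearest_tss(fake_pauses(L - 1L - p$position, strand = "-"),
                    tss("chr1", L - 1L - tt$position, "-", tt$id))$distance
  expect_equal(sort(d0), sort(d2))
})

test_that("strongest_per_tss keeps one maximal record with stated ties", {
  tt <- tss("chr1", 1000L, "+", "t1")
  p <- nearest_tss(fake_pauses(c(1010L, 1014L), score = c(50, 500)), tt)
  kept <- strongest_per_tss(p)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$pause_score, 500)
  # single pause per TSS is untouched
  single <- nearest_tss(fake_pauses(1012L), tt)
  expect_equal(strongest_per_tss(single)$position, 1012L)
  # equal scores: smaller |distance| wins, under any input order
  for (ord in list(1:2, 2:1)) {
    p2 <- nearest_tss(fake_pauses(c(1011L, 1014L)[ord], score = 100), tt)
    expect_equal(strongest_per_tss(p2)$distance, 11L)
  }
})

test_that("strongest_per_tss output is order-independent and per-TSS unique", {
  set.seed(31)
  tt <- tss("chr1", c(100L, 600L, 1200L), "+", c("a", "b", "c"))
  p <- fake_pauses(sample(c(105:118, 604:616, 1210:1216)),
                   score = runif(34, 10, 900))
  a1 <- strongest_per_tss(nearest_tss(p, tt))
  a2 <- strongest_per_tss(nearest_tss(p[sample(nrow(p)), ], tt))
  expect_equal(a1$position, a2$position)
  expect_false(anyDuplicated(a1$tss_id) > 0)
})

test_that("feature categories follow precedence, antisense and UTR rules", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\t.\tgene\t1\t2000\t.\t+\t.\tID=g1",
    "chr1\t.\tCDS\t501\t900\t.\t+\t.\tID=cds1",
    "chr1\t.\trRNA\t850\t1000\t.\t+\t.\tID=rrn1",
    "chr1\t.\tCDS\t1201\t1400\t.\t-\t.\tID=cds2"
  ), gff)
  feats <- load_features(gff)
  tt <- tss("chr1", 440L, "+", "t1")  # UTR span 440..500 (0-based)
  p <- fake_pauses(c(600L, 880L, 1250L, 460L, 1800L),
                   strand = c("+", "+", "+", "+", "+"))
  got <- feature_category(p, feats, tt)
  expect_equal(got, c("CDS", "rRNA",        # rRNA outranks CDS
                      "Antisense",          # only opposite-strand CDS
                      "UTR",                # between TSS and start codon
                      "intergenic"))
  # a minus-strand pause inside the minus-strand CDS is CDS, not antisense
  pm <- fake_pauses(1250L, strand = "-")
  expect_equal(feature_category(pm, feats, tt), "CDS")
})

test_that("region_matrix normalizes each row to [-1, 1] per its own max", {
  rd <- rbind(
    data.frame(contig = "c", start = 150L, end = 151L, strand = "+"),
    data.frame(contig = "c", start = rep(120L, 3L), end = 121L, strand = "-"),
    data.frame(contig = "c", start = rep(130L, 6L), end = 131L, strand = "-"))
  tr <- build_track(reads(rd$contig, rd$start, rd$end, rd$strand),
                    c(c = 700L))
  tt <- tss("c", 140L, "+", "t1")
  rm <- region_matrix(tr, tt)
  expect_equal(rm$sense["t1", "10"], 1)          # single sense count -> 1
  expect_equal(rm$antisense["t1", "-10"], -1)    # max antisense -> -1
  expect_equal(rm$antisense["t1", "-20"], -0.5)
  expect_true(all(rm$sense >= 0 & rm$sense <= 1))
  expect_true(all(rm$antisense >= -1 & rm$antisense <= 0))
  # all-zero region stays zero without division errors
  tt0 <- tss("c", 300L, "+", "t0")
  rm0 <- region_matrix(tr, tt0)
  expect_true(all(rm0$sense == 0) && all(rm0$antisense == 0))
  # out-of-bounds rows are dropped with a warning
  expect_warning(region_matrix(tr, tss("c", 10L, "+", "edge")), "dropped")
})

test_that("region_matrix rows equal a naive per-cell recomputation", {
  set.seed(17)
  x <- rpois(500L, 1); y <- rpois(500L, 1)
  tr <- make_track(x, y, contig = "c")
  for (s in c("+", "-")) {
    tt <- tss("c", 250L, s, "t")
    rm <- region_matrix(tr, tt)
    offs <- -50:200
    pos <- if (s == "+") 250L + offs else 250L - offs
    sv <- (if (s == "+") x else y)[pos + 1L]
    av <- (if (s == "+") y else x)[pos + 1L]
    expect_equal(unname(rm$sense[1, ]),
                 if (max(sv) > 0) sv / max(sv) else sv + 0)
    expect_equal(unname(rm$antisense[1, ]),
                 if (max(av) > 0) -av / max(av) else av + 0)
  }
  # duplicate regions (several pauses sharing a TSS) collapse to one row
  tt2 <- tss(c("c", "c"), c(250L, 250L), "+", c("a", "b"))
  tt2$position <- c(250L, 250L)
  expect_equal(nrow(region_matrix(tr, tt2)$sense), 1L)
})
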