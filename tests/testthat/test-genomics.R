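# Promoter windows, interval intersection, peak-gene maps and
# coverage signal.

test_that("promoter windows are TSS-anchored and strand-aware", {
  plus <- gintervals("chr1", 1000, 5000, strand = "+", name = "gp")
  w <- as_bed_df(promoter_windows(plus, upstream = 500, downstream = 500))
  expect_equal(w$start, 500)
  expect_equal(w$end, 1500)
  minus <- gintervals("chr1", 2000, 3000, strand = "-", name = "gm")
  wm <- as_bed_df(promoter_windows(minus, upstream = 500,
                                   downstream = 500))
  expect_equal(wm$start, 2500)
  expect_equal(wm$end, 3500)
  near0 <- gintervals("chr1", 100, 2100, strand = "+")
  w0 <- as_bed_df(promoter_windows(near0, upstream = 500,
                                   downstream = 500))
  expect_equal(w0$start, 0)   # clipped at the chromosome start
  expect_equal(w0$end, 600)
  un <- gintervals("chr1", 1000, 2000, strand = ".")
  expect_error(promoter_windows(un), "unstranded")
  both <- as_bed_df(promoter_windows(un, upstream = 300,
                                     unstranded = "both-sides"))
  expect_equal(both$end - both$start, 600)
})

test_that("interval intersection is half-open and matches brute force", {
  a <- gintervals("chr1", 0, 10)
  b <- gintervals("chr1", 5, 15)
  hit <- intersect_intervals(a, b)
  expect_equal(hit$overlap_bp, 5)
  abut <- intersect_intervals(gintervals("chr1", 0, 5),
                              gintervals("chr1", 5, 10))
  expect_equal(nrow(abut), 0)
  set.seed(3)
  sizes <- c(chr1 = 1e5, chr2 = 8e4, chr3 = 6e4)
  adf <- random_intervals(300, sizes)
  bdf <- random_intervals(300, sizes)
  ours <- intersect_intervals(gintervals(adf$chrom, adf$start, adf$end),
                              gintervals(bdf$chrom, bdf$start, bdf$end))
  brute <- brute_intersect(adf, bdf)
  expect_equal(nrow(ours), nrow(brute))
  expect_equal(ours$overlap_bp, brute$overlap_bp)
  expect_equal(ours$a_idx, brute$a_idx)
  expect_equal(ours$b_idx, brute$b_idx)
  # overlap lengths are symmetric
  flip <- intersect_intervals(gintervals(bdf$chrom, bdf$start, bdf$end),
                              gintervals(adf$chrom, adf$start, adf$end))
  expect_equal(sort(flip$overlap_bp), sort(ours$overlap_bp))
})

test_that("peak-gene mapping joins by symbol or by summit position", {
  genes <- gintervals(c("chr1", "chr1"), c(1000, 9000), c(3000, 11000),
                      strand = c("+", "+"), name = c("NCOR1", "OCT4"))
  pk <- gintervals("chr1", 700, 900, name = "p1")
  pk$gene_symbol <- "Ncor1"
  m <- map_peaks_to_genes(pk, genes, mode = "symbol")
  expect_equal(m$gene, "NCOR1")
  pk2 <- pk
  pk2$gene_symbol <- NULL
  expect_error(map_peaks_to_genes(pk2, genes, mode = "symbol"),
               "gene_symbol")
  pk2$summit <- 100L   # absolute 0-based position 800, in [TSS-500, TSS+500)
  m2 <- map_peaks_to_genes(pk2, genes, mode = "interval",
                           upstream = 500, downstream = 500)
  expect_equal(m2$gene, "NCOR1")
  # a summit inside two overlapping promoter windows maps to both genes
  close_genes <- gintervals(c("chr1", "chr1"), c(1000, 1200),
                            c(3000, 3200), strand = c("+", "+"),
                            name = c("gA", "gB"))
  mid <- gintervals("chr1", 1050, 1250, name = "pm")
  mid$summit <- 60L    # position 1110: in both [TSS +/- 500) windows
  m3 <- map_peaks_to_genes(mid, close_genes, mode = "interval",
                           upstream = 500, downstream = 500)
  expect_setequal(m3$gene, c("gA", "gB"))
})

test_that("region signal reproduces RPM/RPKM identities", {
  # 0.01 reads/bp over a 1 kb region = 10 reads; library of 1e6 reads
  trk <- coverage_track(
    {
      gr <- gintervals("chr1", 1000, 2000)
      gr$score <- 0.01
      gr
    },
    total_reads = 1e6)
  region <- gintervals("chr1", 1000, 2000)
  expect_equal(region_signal(trk, region, "raw"), 10)
  expect_equal(region_signal(trk, region, "rpm"), 10)
  expect_equal(region_signal(trk, region, "rpkm"), 10)
  # doubling scores and total reads leaves RPM unchanged
  trk2 <- coverage_track(
    {
      gr <- gintervals("chr1", 1000, 2000)
      gr$score <- 0.02
      gr
    },
    total_reads = 2e6)
  expect_equal(region_signal(trk2, region, "rpm"),
               region_signal(trk, region, "rpm"))
  # raw signal is additive over a partition of the region
  halves <- gintervals(c("chr1", "chr1"), c(1000, 1500), c(1500, 2000))
  expect_equal(sum(region_signal(trk, halves, "raw")),
               region_signal(trk, region, "raw"))
  expect_warning(sig0 <- region_signal(trk, gintervals("chrX", 0, 100)),
                 "absent")
  expect_equal(sig0, 0)
})

test_that("coverage from reads integrates back to the read count", {
  set.seed(5)
  starts <- sample(0:5000, 200, replace = TRUE)
  reads <- gintervals("chr1", starts, starts + 50)
  trk <- coverage_from_reads(reads, read_length = 50)
  expect_equal(trk$total_reads, 200)
  whole <- gintervals("chr1", 0, 6000)
  expect_equal(region_signal(trk, whole, "raw"), 200, tolerance = 1e-9)
})

test_that("summit matrices are centered, consistent and zero-padded", {
  gr <- gintervals("chr1", 0, 20000)
  gr$score <- 0.05
  trk <- coverage_track(gr, total_reads = 1e6)
  pk <- gintervals("chr1", 9900, 10100, name = "p1",
                   seqlengths = c(chr1 = 20000))
  pk$summit <- 100L
  flat <- summit_matrix(trk, pk, flank = 2000, n_bins = 40)
  expect_equal(max(flat) - min(flat), 0, tolerance = 1e-9)
  # a single spike at the summit lands in one of the two central bins
  spike <- gintervals("chr1", 9999, 10001)
  spike$score <- 5
  trk_sp <- coverage_track(spike, total_reads = 1e6)
  sp <- summit_matrix(trk_sp, pk, flank = 2000, n_bins = 40)
  expect_true(which.max(sp[1, ]) %in% c(20, 21))
  # row sums relate to the full-window signal: sum(bins) = n_bins * rpkm
  win <- gintervals("chr1", 8000, 12000)
  expect_equal(sum(flat[1, ]), 40 * region_signal(trk, win, "rpkm"),
               tolerance = 1e-9)
  # window past the chromosome end is zero-padded with a warning
  edge_pk <- gintervals("chr1", 100, 300, name = "pe",
                        seqlengths = c(chr1 = 20000))
  edge_pk$summit <- 100L
  expect_warning(em <- summit_matrix(trk, edge_pk, flank = 2000,
                                     n_bins = 40),
                 "zero-padded")
  expect_equal(unname(em[1, 1:10]), rep(0, 10))
  expect_error(summit_matrix(trk, pk, flank = 2000, n_bins = 39), "even")
})

test_that("bedGraph round-trips coverage tracks", {
  gr <- gintervals(c("chr1", "chr1", "chr2"), c(0, 500, 100),
                   c(300, 900, 400))
  gr$score <- c(0.5, 1.25, 2)
  trk <- coverage_track(gr, total_reads = 5000)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(trk, path)
  back <- read_bedgraph(path, total_reads = 5000)
  expect_equal(as_bed_df(back$intervals)[c("chrom", "start", "end")],
               as_bed_df(trk$intervals)[c("chrom", "start", "end")])
  expect_equal(back$intervals$score, trk$intervals$score)
  expect_equal(back$total_reads, 5000)
})

test_that("interval constructors enforce their invariants", {
  expect_error(gintervals("chr1", 10, 10), "start < end")
  expect_error(gintervals("chr1", -1, 10), "start < end|0 <=")
  expect_error(gintervals("chr1", 0, 200, seqlengths = c(chr1 = 100)),
               "exceeds")
  expect_error(coverage_track({
    gr <- gintervals("chr1", c(0, 50), c(100, 150))
    gr$score <- c(1, 1)
    gr
  }), "non-overlapping")
})
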