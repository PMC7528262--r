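feat <- function(chrom, start, end, cls, gid) {
  data.table(chrom = chrom, start = start, end = end, feature_class = cls, gene_id = gid)
}

test_that("overlap_genes honours the 1 bp boundary and half-open touching", {
  cn <- iv("chr1", 100, 200)
  # 1 bp overlap counts
  r <- overlap_genes(cn, feat("chr1", 199, 300, "exon", "gA"))
  expect_equal(r$genes_overlapped, "gA")
  expect_equal(r$genes_exon_overlapped, "gA")
  # book-ended feature does not overlap
  r <- overlap_genes(cn, feat("chr1", 200, 300, "exon", "gA"))
  expect_equal(r$genes_overlapped, character())
  # intron-only overlap keeps the gene out of the exon set
  fe <- rbind(feat("chr1", 150, 180, "intron", "gB"), feat("chr1", 500, 600, "exon", "gB"))
  r <- overlap_genes(cn, fe)
  expect_equal(r$genes_overlapped, "gB")
  expect_equal(r$genes_exon_overlapped, character())
})

test_that("overlap_genes matches the per-base oracle on random fixtures", {
  set.seed(909)
  for (rep in 1:20) {
    cn <- random_intervals(sample(1:6, 1), 20000, min_len = 50, max_len = 4000)
    fe <- random_intervals(sample(3:12, 1), 20000, min_len = 20, max_len = 2000)
    fe[, `:=`(feature_class = sample(c("exon", "intron", "lncRNA"), .N, TRUE),
              gene_id = sprintf("g%d", sample(1:5, .N, TRUE)))]
    got <- overlap_genes(cn, fe)
    cnv_bases <- base_cover(cn, 20000)
    hit <- vapply(seq_len(nrow(fe)), function(i) any(cnv_bases[seq(fe$start[i] + 1, fe$end[i])]), TRUE)
    expect_equal(got$genes_overlapped, sort(unique(fe$gene_id[hit])))
    expect_equal(got$genes_exon_overlapped,
                 sort(unique(fe$gene_id[hit & fe$feature_class == "exon"])))
  }
})

test_that("feature_class_enrichment computes O/E from length fractions", {
  sizes <- c(chr1 = 100000)
  # class covers 10% of the genome; CNVRs spend 5% of their bp in it -> O/E 0.5
  cn <- iv("chr1", 0, 20000)
  fe <- feat("chr1", 19000, 29000, "exon", "g1")   # 10,000 bp class, 1,000 in CNVR
  r <- feature_class_enrichment(cn, fe, sizes)
  expect_equal(r$observed, 0.05)
  expect_equal(r$expected, 0.1)
  expect_equal(r$oe, 0.5)
  # zero-bp class errors (degenerate annotation)
  expect_error(feature_class_enrichment(cn, fe[0], sizes), "zero bp")
})

test_that("enrichment matches the per-base oracle on random two-class fixtures", {
  set.seed(111)
  for (rep in 1:20) {
    size <- 30000
    cn <- random_intervals(sample(2:6, 1), size, min_len = 100, max_len = 5000)
    fe <- rbind(
      cbind(random_intervals(sample(2:6, 1), size, min_len = 50, max_len = 3000),
            feature_class = "exon", gene_id = "g1"),
      cbind(random_intervals(sample(2:6, 1), size, min_len = 50, max_len = 3000),
            feature_class = "pseudogene", gene_id = "g2")
    )
    r <- feature_class_enrichment(cn, fe, c(chr1 = size))
    cnv_b <- base_cover(cn, size)
    for (cl in unique(fe$feature_class)) {
      cl_b <- base_cover(fe[feature_class == cl], size)
      expect_equal(r[feature_class == cl]$observed_bp, sum(cnv_b & cl_b))
      expect_equal(r[feature_class == cl]$observed, sum(cnv_b & cl_b) / sum(cnv_b))
      expect_equal(r[feature_class == cl]$expected, sum(cl_b) / size)
    }
  }
})

test_that("window_density tiles chromosomes and conserves covered bp", {
  sizes <- c(chr1 = 2500000)
  cn <- iv("chr1", c(0, 1100000), c(850000, 1150000))
  w <- window_density(cn, sizes)
  expect_equal(nrow(w), 3L)
  expect_equal(w$window_bp, c(1e6, 1e6, 5e5))      # short terminal window kept
  expect_equal(w$covered_bp, c(850000, 50000, 0))
  expect_equal(w$covered_fraction[1], 0.85)
  # conservation: sum of window coverage == union length
  expect_equal(sum(w$covered_bp), 850000 + 50000)

  # per-base oracle on a small genome with small windows
  set.seed(222)
  for (rep in 1:20) {
    size <- 50000
    cn <- random_intervals(sample(2:8, 1), size, min_len = 100, max_len = 9000)
    w <- window_density(cn, c(chr1 = size), window_size = 7000)
    b <- base_cover(cn, size)
    exp_cov <- vapply(seq_len(nrow(w)), function(i) sum(b[seq(w$start[i] + 1, w$end[i])]), 0)
    expect_equal(w$covered_bp, exp_cov)
    expect_equal(sum(w$covered_bp), sum(b))
  }
})

test_that("detect_clusters is strict at 0.80 and merges adjacent windows", {
  w <- data.table(chrom = "chr1", start = 0:4 * 1e6, end = 1:5 * 1e6,
                  window_bp = 1e6, covered_bp = c(850000, 800000, 900000, 810000, 100000))
  w[, covered_fraction := covered_bp / window_bp]
  cl <- detect_clusters(w)
  # window 2 at exactly 0.80 is NOT a cluster ("over 80%" is strict), so the
  # 0.85 window stands alone and windows 3-4 merge into a 2 Mb region
  expect_equal(cl[, .(start, end, n_windows)],
               data.table(start = c(0, 2e6), end = c(1e6, 4e6), n_windows = c(1L, 2L)))
  # windows on different chromosomes never merge
  w2 <- data.table(chrom = c("chr1", "chr2"), start = 0, end = 1e6,
                   window_bp = 1e6, covered_bp = 9e5, covered_fraction = 0.9)
  expect_equal(nrow(detect_clusters(w2)), 2L)
})

test_that("breed_sharing and shared_by_all enumerate patterns", {
  st <- rbind(
    data.table(sample_id = c("a1", "a2"), breed = "Angus", subspecies = "taurine"),
    data.table(sample_id = c("n1", "n2"), breed = "Nelore", subspecies = "indicine"),
    data.table(sample_id = c("g1", "g2"), breed = "Gir", subspecies = "indicine")
  )
  cn <- data.table(
    cnvr_id = sprintf("r%d", 1:5), chrom = "chr1",
    start = 0:4 * 1000, end = 0:4 * 1000 + 500,
    samples = list(c("a1", "n1", "g1"), c("a1", "a2"), c("n1", "g2"),
                   c("a2", "n2", "g1"), c("g1"))
  )
  sh <- breed_sharing(cn, st)
  expect_equal(shared_by_all(sh), 2L)
  expect_equal(sh$pattern_counts[pattern == "Angus"]$n, 1L)
  expect_equal(sh$pattern_counts[pattern == "Gir"]$n, 1L)
  expect_equal(sh$pattern_counts[pattern == "Gir,Nelore"]$n, 1L)
  expect_equal(sh$per_cnvr$subspecies[[2]], "taurine")
})

test_that("subspecies_comparison partitions CNVRs and reports 2-decimal sharing", {
  st <- tiny_sheet(2, 2)
  cn <- data.table(
    cnvr_id = sprintf("r%d", 1:4), chrom = "chr1", start = 0:3 * 1000, end = 0:3 * 1000 + 500,
    samples = list(c("T01", "I01"), c("T02", "I02"), c("T01", "T02"), c("I01"))
  )
  r <- subspecies_comparison(cn, st)
  expect_equal(r$shared_percentage, 50.00)
  expect_equal(r$shared, c("r1", "r2"))
  expect_equal(r$specific$taurine, "r3")
  expect_equal(r$specific$indicine, "r4")
  # partition invariant
  expect_equal(length(r$shared) + sum(lengths(r$specific)), nrow(cn))
  # all shared -> 100.00
  cn2 <- cn[1:2]
  expect_equal(subspecies_comparison(cn2, st)$shared_percentage, 100.00)
})

test_that("specific_sequences applies the strict length and inclusive depth cuts", {
  # one 600 bp interval at depth 2 passes both filters
  r <- specific_sequences(iv("chr1", 0, 600, depth = 2))
  expect_equal(r$total_bp, 600)
  # 400 bp at depth 5 fails the length cut
  expect_equal(specific_sequences(iv("chr1", 0, 400, depth = 5))$total_bp, 0)
  # exactly 500 bp is dropped ("over 500 bp" is strict); depth 2 is kept ("at least 2")
  expect_equal(specific_sequences(iv("chr1", 0, 500, depth = 9))$total_bp, 0)
  expect_equal(specific_sequences(iv("chr1", 0, 501, depth = 2))$total_bp, 501)
  expect_equal(specific_sequences(iv("chr1", 0, 501, depth = 1))$total_bp, 0)
  # book-ended runs merge: [0,300)@2 + [300,400)@3 -> 400 bp, dropped;
  # adding [400,650)@2 -> merged [0,650), kept
  two <- iv("chr1", c(0, 300), c(300, 400), depth = c(2, 3))
  expect_equal(specific_sequences(two)$total_bp, 0)
  three <- rbind(two, iv("chr1", 400, 650, depth = 2))
  r <- specific_sequences(three)
  expect_equal(r$intervals[, .(start, end)], data.table(start = 0, end = 650))
  expect_equal(r$total_bp, 650)
  # sub-threshold depth breaks a run
  gap <- iv("chr1", c(0, 300, 400), c(300, 400, 1000), depth = c(2, 1, 2))
  expect_equal(specific_sequences(gap)$intervals[, .(start, end)],
               data.table(start = 400, end = 1000))
  expect_error(specific_sequences(iv("chr1", 0, 100, depth = -1)), "negative depth")
})
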