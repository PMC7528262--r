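test_that("class_frequencies tallies genotype classes per population", {
  st <- tiny_sheet(4, 2)
  m <- matrix(2L, nrow = 3, ncol = 6, dimnames = list(
    c("chr1:0-100", "chr1:200-300", "chr1:400-500"), st$sample_id))
  m[1, c("T03", "T04")] <- 0L
  f <- class_frequencies(m, st, "taurine")
  expect_equal(f$N, 4)
  expect_equal(unname(f$freq[1, ]), c(0.5, 0, 0.5, 0, 0))
  expect_equal(unname(f$freq[2, ]), c(0, 0, 1, 0, 0))
  expect_true(all(abs(rowSums(f$freq) - 1) < 1e-12))
  expect_error(class_frequencies(m, st, "zebu"), "no samples")

  # hand tally on a 3 x 6 fixture
  m[2, ] <- c(0L, 1L, 1L, 2L, 3L, 4L)
  f2 <- class_frequencies(m, st, "taurine")
  expect_equal(unname(f2$freq[2, ]), c(1, 2, 1, 0, 0) / 4)
})

test_that("compute_fst reproduces the hand-evaluated cases exactly", {
  # identical populations -> Hs == Ht -> 0
  x <- class_freq(c("1" = 0.5, "2" = 0.5), 4, "X")
  r <- compute_fst(x, class_freq(c("1" = 0.5, "2" = 0.5), 7, "Y"))
  expect_equal(r$fst, 0, tolerance = 1e-12)

  # opposite fixation, Nx = Ny = 2 -> Ht 0.5, Hs 0, fst 1
  r <- compute_fst(class_freq(c("2" = 1), 2), class_freq(c("0" = 1), 2))
  expect_equal(unname(r$t[c("0", "2")]), c(0.5, 0.5))
  expect_equal(r$Ht, 0.5, tolerance = 1e-12)
  expect_equal(r$Hs, 0, tolerance = 1e-12)
  expect_equal(r$fst, 1, tolerance = 1e-12)

  # mixed case -> Ht 0.375, Hs 0.25, fst 1/3
  r <- compute_fst(class_freq(c("1" = 0.5, "2" = 0.5), 2), class_freq(c("1" = 1), 2))
  expect_equal(unname(r$t[c("1", "2")]), c(0.75, 0.25))
  expect_equal(r$Ht, 0.375, tolerance = 1e-12)
  expect_equal(r$Hs, 0.25, tolerance = 1e-12)
  expect_equal(r$fst, 1 / 3, tolerance = 1e-12)

  # both populations fixed for the same class: Ht == 0 -> fst 0 by definition
  r <- compute_fst(class_freq(c("2" = 1), 3), class_freq(c("2" = 1), 5))
  expect_equal(r$fst, 0)
})

test_that("F_ST is bounded, symmetric, matches the oracle, and is 0 iff equal", {
  set.seed(505)
  for (rep in 1:300) {
    fx <- random_freq(); fy <- random_freq()
    nx <- sample(1:50, 1); ny <- sample(1:50, 1)
    a <- compute_fst(class_freq(fx, nx), class_freq(fy, ny))
    b <- compute_fst(class_freq(fy, ny), class_freq(fx, nx))
    expect_gte(a$fst, 0)
    expect_lte(a$fst, 1)
    expect_equal(a$fst, b$fst, tolerance = 1e-12)
    expect_equal(a$fst, oracle_fst(fx * nx, fy * ny), tolerance = 1e-9)
  }
  # equal N: fst == 0 iff frequencies agree
  for (rep in 1:50) {
    fx <- random_freq()
    same <- compute_fst(class_freq(fx, 10), class_freq(fx, 10))
    expect_equal(same$fst, 0, tolerance = 1e-12)
    fy <- random_freq()
    if (max(abs(fx - fy)) > 1e-6) {
      expect_gt(compute_fst(class_freq(fx, 10), class_freq(fy, 10))$fst, 0)
    }
  }
})

test_that("F_ST grows monotonically with fixation difference", {
  x <- class_freq(c("2" = 1), 10)
  lam <- seq(0, 1, by = 0.05)
  fst <- vapply(lam, function(l) {
    y <- class_freq(c("0" = l, "2" = 1 - l), 10)
    compute_fst(x, y)$fst
  }, 0)
  expect_true(all(diff(fst) >= -1e-12))
  expect_equal(fst[1], 0)
  expect_equal(fst[length(fst)], 1)
})

test_that("fst_scan matches compute_fst per segment", {
  set.seed(606)
  st <- tiny_sheet(5, 5)
  m <- matrix(sample(0:4, 40, replace = TRUE, prob = c(.1, .15, .5, .15, .1)), 4, 10,
              dimnames = list(sprintf("chr1:%d-%d", 0:3 * 100, 0:3 * 100 + 60), st$sample_id))
  storage.mode(m) <- "integer"
  sc <- fst_scan(m, st)
  for (i in 1:4) {
    fx <- class_frequencies(m[i, , drop = FALSE], st, "taurine")
    fy <- class_frequencies(m[i, , drop = FALSE], st, "indicine")
    r <- compute_fst(class_freq(fx$freq[1, ], fx$N), class_freq(fy$freq[1, ], fy$N))
    expect_equal(sc$fst[i], r$fst, tolerance = 1e-12)
    expect_equal(sc$Ht[i], r$Ht, tolerance = 1e-12)
    expect_equal(sc$Hs[i], r$Hs, tolerance = 1e-12)
  }
})

test_that("rank_segments applies ceil and keeps ties at the cut", {
  rec <- data.table(segment_id = sprintf("s%05d", 1:1000), fst = seq(0, 0.999, length.out = 1000))
  top <- rank_segments(rec, 0.001)
  expect_equal(nrow(top), 1L)             # ceil(1) with no ties
  expect_equal(top$rank, 1L)
  expect_equal(top$segment_id, rec[which.max(fst)]$segment_id)

  # 159 of 15,900 at the top 1% with distinct values
  rec2 <- data.table(segment_id = sprintf("s%05d", 1:15900),
                     fst = seq(0, 1, length.out = 15900))
  expect_equal(nrow(rank_segments(rec2, 0.01)), 159L)

  # all tied -> the whole set comes back
  rec3 <- data.table(segment_id = sprintf("s%02d", 1:50), fst = 0.5)
  expect_equal(nrow(rank_segments(rec3, 0.1)), 50L)

  expect_error(rank_segments(rec[0], 0.01), "empty")
  expect_error(rank_segments(rec, 1.5))
})

test_that("status_rates partitions classes into loss/normal/gain", {
  st <- tiny_sheet(4, 4)
  m <- matrix(2L, 3, 8, dimnames = list(sprintf("chr1:%d-%d", 0:2 * 100, 0:2 * 100 + 60),
                                        st$sample_id))
  m[1, st$sample_id[st$subspecies == "indicine"]] <- 0L      # all loss
  m[2, c("T01", "T02")] <- c(0L, 1L)                         # (0,1,2,2) in taurine
  m[3, "T01"] <- 3L
  r <- status_rates(m, st)
  expect_equal(r[segment_id == rownames(m)[1] & population == "indicine"]$loss, 1)
  row2 <- r[segment_id == rownames(m)[2] & population == "taurine"]
  expect_equal(c(row2$loss, row2$normal, row2$gain), c(0.5, 0.5, 0))
  expect_gt(r[segment_id == rownames(m)[3] & population == "taurine"]$gain, 0)
  expect_true(all(abs(r$loss + r$normal + r$gain - 1) < 1e-12))
})

test_that("pca_coordinates is deterministic and respects rank", {
  set.seed(707)
  m <- matrix(sample(0:4, 30, TRUE), 6, 5,
              dimnames = list(sprintf("chr1:%d-%d", 0:5 * 100, 0:5 * 100 + 60),
                              sprintf("s%d", 1:5)))
  m[, 2] <- m[, 1]                       # two identical samples
  co <- pca_coordinates(m, 2)
  expect_equal(co[1, ], co[2, ], tolerance = 1e-9)

  # a constant segment adds no variance: coordinates unchanged
  m2 <- rbind(m, "chr9:0-100" = rep(2L, 5))
  expect_equal(abs(pca_coordinates(m2, 2)), abs(pca_coordinates(m, 2)), tolerance = 1e-9)

  expect_error(pca_coordinates(m, 50), "rank")
})

test_that("PC1 separates two populations with planted differential segments", {
  set.seed(808)
  st <- tiny_sheet(6, 6)
  n_seg <- 60
  m <- matrix(sample(c(1L, 2L, 3L), n_seg * 12, TRUE, prob = c(.1, .8, .1)), n_seg, 12,
              dimnames = list(sprintf("chr1:%d-%d", 0:(n_seg - 1) * 1000,
                                      0:(n_seg - 1) * 1000 + 500), st$sample_id))
  diff_rows <- 1:10
  m[diff_rows, st$subspecies == "indicine"] <- 0L
  m[diff_rows, st$subspecies == "taurine"] <- 2L
  co <- pca_coordinates(m, 2)
  pc1 <- co[, 1]
  t_rng <- range(pc1[st$subspecies == "taurine"])
  i_rng <- range(pc1[st$subspecies == "indicine"])
  expect_true(t_rng[2] < i_rng[1] || i_rng[2] < t_rng[1])  # linearly separable on PC1
})
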