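# Brute-force per-base oracles and small fixture builders.
# All oracles are deliberately naive (per-base vectors, O(n^2) graphs) and
# independent of the package's interval arithmetic.

library(data.table)

# quick interval-table builder
iv <- function(chrom, start, end, ...) data.table(chrom = chrom, start = start, end = end, ...)

# call-table builder
mk_call <- function(sample_id, chrom, start, end, cnv_type, copy_class = NA_integer_,
                    source_caller = NA_character_, normalized_depth = NA_real_) {
  data.table(sample_id = sample_id, chrom = chrom, start = start, end = end,
             cnv_type = cnv_type, copy_class = copy_class,
             source_caller = source_caller, normalized_depth = normalized_depth,
             quality = NA_real_)
}

# per-base coverage bitmap of the union of intervals over [0, size)
base_cover <- function(intervals, size) {
  v <- logical(size)
  for (i in seq_len(nrow(intervals))) {
    v[seq(intervals$start[i] + 1, intervals$end[i])] <- TRUE
  }
  v
}

# union-find closure over the pairwise strict-overlap graph; returns the
# component span table (single chromosome assumed)
oracle_merge <- function(intervals) {
  n <- nrow(intervals)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          intervals$chrom[i] == intervals$chrom[j] &&
          min(intervals$end[i], intervals$end[j]) - max(intervals$start[i], intervals$start[j]) > 0) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- data.table(intervals, comp = comp)[, .(
    chrom = chrom[1], start = min(start), end = max(end)
  ), by = comp][, comp := NULL]
  setorder(out, chrom, start)
  out
}

# per-base segment dissection oracle: maximal runs with a constant,
# non-empty set of covering calls (single chromosome region)
oracle_dissect <- function(calls, region_start, region_end, min_len = 50) {
  pos <- seq(region_start, region_end - 1)
  key <- vapply(pos, function(p) {
    cov <- which(pmax(calls$start, region_start) <= p & pmin(calls$end, region_end) > p)
    paste(cov, collapse = ",")
  }, "")
  segs <- list()
  run_start <- 1L
  for (i in seq_along(pos)) {
    if (i == length(pos) || key[i + 1] != key[i]) {
      if (nzchar(key[run_start])) {
        segs[[length(segs) + 1L]] <- data.table(start = pos[run_start], end = pos[i] + 1)
      }
      run_start <- i + 1L
    }
  }
  out <- rbindlist(segs)
  if (!nrow(out)) return(data.table(start = numeric(), end = numeric()))
  out[end - start > min_len]
}

# independent F_ST from two genotype-class count tables
oracle_fst <- function(counts_x, counts_y) {
  x <- counts_x / sum(counts_x); y <- counts_y / sum(counts_y)
  nx <- sum(counts_x); ny <- sum(counts_y)
  t_i <- (x * nx + y * ny) / (nx + ny)
  ht <- 1 - sum(t_i^2)
  hs <- ((1 - sum(x^2)) * nx + (1 - sum(y^2)) * ny) / (nx + ny)
  if (ht == 0) 0 else (ht - hs) / ht
}

# random interval table on one small chromosome
random_intervals <- function(n, size, min_len = 10, max_len = size %/% 4, chrom = "chr1") {
  len <- sample(min_len:max_len, n, replace = TRUE)
  start <- sample(0:(size - min_len), n, replace = TRUE)
  end <- pmin(start + len, size)
  iv(chrom, start, end)[end > start]
}

# random frequency vector over the 5 genotype classes
random_freq <- function() {
  g <- rgamma(5, shape = 0.8)
  stats::setNames(g / sum(g), as.character(0:4))
}

# minimal sample sheet: n_t taurine + n_i indicine animals, 1 breed each
tiny_sheet <- function(n_t = 2, n_i = 2) {
  rbind(
    data.table(sample_id = sprintf("T%02d", seq_len(n_t)), breed = "BreedT", subspecies = "taurine"),
    data.table(sample_id = sprintf("I%02d", seq_len(n_i)), breed = "BreedI", subspecies = "indicine")
  )
}
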