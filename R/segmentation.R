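# CNVR dissection into boundary-consistent segments and per-animal
# genotyping into the five copy-number classes {0,1,2,3,>=4}.
#
# Segments are delimited by the union of confident-call breakpoints inside
# a CNVR, so every individual is genotyped over identical intervals.

#' Dissect CNVRs into boundary-consistent CNV segments
#'
#' Within each CNVR, all member-call start/end positions (clipped to the
#' region) are pooled and sorted; consecutive breakpoints delimit candidate
#' segments.  Candidates covered by no call (gaps inside a mixed region)
#' are dropped, as are segments of length `<= min_len` bp (the length
#' filter is strict: a 50 bp segment is removed at the default).
#'
#' @param cnvrs CNVR table from [build_cnvrs()].
#' @param confident_calls confident calls across all samples; calls are
#'   assigned to CNVRs by overlap.
#' @param min_len segments must be strictly longer than this (default 50).
#' @return `data.table` with `segment_id` (`chrom:start-end`), `chrom`,
#'   `start`, `end`, `cnvr_id`; segments within a CNVR are sorted and
#'   non-overlapping.
#' @export
dissect_segments <- function(cnvrs, confident_calls, min_len = 50) {
  cn <- check_intervals(data.table::as.data.table(cnvrs), "CNVRs")
  calls <- check_intervals(data.table::as.data.table(confident_calls), "confident calls")
  empty <- data.table::data.table(segment_id = character(), chrom = character(),
                                  start = numeric(), end = numeric(),
                                  cnvr_id = character())
  if (!nrow(cn) || !nrow(calls)) return(empty)
  cn <- data.table::copy(cn)
  if (!"cnvr_id" %in% names(cn)) cn[, cnvr_id := interval_id(chrom, start, end)]
  q <- calls[, .(chrom, start, end)]
  data.table::setkey(q, chrom, start, end)
  ov <- data.table::foverlaps(cn[, .(cnvr_id, chrom, start, end)], q,
                              type = "any", nomatch = NULL)
  if (!nrow(ov)) return(empty)
  # clip member-call intervals to the region
  ov[, `:=`(cs = pmax(start, i.start), ce = pmin(end, i.end))]
  segs <- ov[, {
    bp <- sort(unique(c(cs, ce)))
    a <- bp[-length(bp)]
    b <- bp[-1L]
    # coverage is constant between adjacent breakpoints; test containment
    covered <- vapply(seq_along(a), function(j) any(cs <= a[j] & ce >= b[j]), TRUE)
    keep <- covered & (b - a > min_len)
    list(start = a[keep], end = b[keep])
  }, by = .(cnvr_id, chrom)]
  if (!nrow(segs)) return(empty)
  segs[, segment_id := interval_id(chrom, start, end)]
  data.table::setcolorder(segs, c("segment_id", "chrom", "start", "end", "cnvr_id"))
  data.table::setorder(segs, chrom, start, end)
  segs[]
}

#' Genotype every sample at every CNV segment
#'
#' A sample's genotype at a segment is the copy-number class of a confident
#' call of that sample that fully contains the segment; samples with no
#' containing call are diploid (class 2).  When several calls of one sample
#' contain the same segment with conflicting classes, the most extreme
#' class (farthest from 2) wins; remaining ties resolve to the lower class.
#' Conflicts are counted and reported.
#'
#' @param segments segment table from [dissect_segments()].
#' @param confident_calls confident calls across all samples.
#' @param sample_table validated sample sheet; defines the column set.
#' @return integer matrix, rows = segments (rownames `segment_id`),
#'   columns = `sample_id`, values in 0..4 (4 means ">=4").
#' @export
genotype_segments <- function(segments, confident_calls, sample_table) {
  st <- validate_sample_table(sample_table)
  segs <- check_intervals(data.table::as.data.table(segments), "segments")
  calls <- check_intervals(data.table::as.data.table(confident_calls), "confident calls")
  segs <- data.table::copy(segs)
  if (!"segment_id" %in% names(segs)) segs[, segment_id := interval_id(chrom, start, end)]
  mat <- matrix(2L, nrow = nrow(segs), ncol = nrow(st),
                dimnames = list(segs$segment_id, st$sample_id))
  if (!nrow(segs) || !nrow(calls)) return(mat)
  extra <- setdiff(calls$sample_id, st$sample_id)
  if (length(extra)) stop("confident calls contain samples absent from sample sheet: ",
                          paste(extra, collapse = ", "))
  q <- calls[, .(sample_id, chrom, start, end, copy_class)]
  data.table::setkey(q, chrom, start, end)
  ov <- data.table::foverlaps(segs[, .(segment_id, chrom, start, end)], q,
                              type = "any", nomatch = NULL)
  # full containment of the segment by the call
  ov <- ov[start <= i.start & end >= i.end]
  if (!nrow(ov)) return(mat)
  conflicts <- ov[, data.table::uniqueN(copy_class), by = .(segment_id, sample_id)][V1 > 1]
  if (nrow(conflicts)) {
    message(nrow(conflicts), " segment/sample genotype conflict(s) resolved by ",
            "most-extreme-class precedence")
  }
  ov[, score_ := abs(copy_class - 2)]
  data.table::setorder(ov, segment_id, sample_id, -score_, copy_class)
  best <- ov[!duplicated(paste(segment_id, sample_id, sep = "\r"))]
  mat[cbind(match(best$segment_id, rownames(mat)),
            match(best$sample_id, colnames(mat)))] <- as.integer(best$copy_class)
  mat
}

#' Per-segment variant frequency
#'
#' Frequency of non-diploid genotypes: the fraction of samples whose class
#' differs from 2 at the segment.
#'
#' @param mat genotype matrix from [genotype_segments()].
#' @return named numeric vector of frequencies in `[0, 1]`.
#' @export
segment_frequency <- function(mat) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) == 0L) stop("genotype matrix has zero samples")
  rowMeans(mat != 2L)
}

#' High-frequency CNV segments
#'
#' Segments whose variant frequency reaches `threshold` (inclusive: a
#' segment at exactly 50% is retained at the default).
#'
#' @inheritParams segment_frequency
#' @param threshold inclusive frequency cut (default 0.5).
#' @return character vector of segment ids.
#' @export
high_frequency_segments <- function(mat, threshold = 0.5) {
  f <- segment_frequency(mat)
  names(f)[f >= threshold]
}
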