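# Dual-caller call integration: confident calls, distinct CNVs, CNVRs.
#
# A confident call is a boundary-caller (split-read/paired-end) call that a
# same-type read-depth call corroborates.  The confident interval is the
# boundary caller's verbatim (single-base boundary resolution); the integer
# copy-number class comes from the read-depth caller's normalised depth.

#' Intersect boundary-caller and depth-caller calls for one sample
#'
#' A boundary-caller call becomes a confident call when at least one
#' depth-caller call of the same CNV type (loss/gain) overlaps it by
#' `min_overlap_bp` and, if `reciprocal_fraction > 0`, by that fraction of
#' both call lengths.  The copy-number class is taken from the overlapping
#' same-type depth call with the largest overlap (ties broken by the
#' smallest symmetric difference with the boundary call, then leftmost):
#' `copy_class = clamp(round_half_up(2 * normalized_depth), 0, 4)`, then
#' forced consistent with the call type (loss < 2, gain > 2).
#'
#' @param boundary_calls,depth_calls raw-call tables for a single sample
#'   (from [read_sv_vcf()] / [read_depth_calls()]).
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @param reciprocal_fraction minimum reciprocal overlap fraction (default 0).
#' @return `data.table` of confident calls: `sample_id`, `chrom`, `start`,
#'   `end`, `cnv_type`, `copy_class` (integer in 0..4, 4 meaning ">=4").
#' @export
intersect_calls <- function(boundary_calls, depth_calls,
                            min_overlap_bp = 1, reciprocal_fraction = 0) {
  stopifnot(min_overlap_bp >= 0, reciprocal_fraction >= 0, reciprocal_fraction <= 1)
  b <- check_intervals(data.table::as.data.table(boundary_calls), "boundary calls")
  d <- check_intervals(data.table::as.data.table(depth_calls), "depth calls")
  sid <- unique(c(b$sample_id, d$sample_id))
  if (length(sid) > 1L) stop("intersect_calls expects calls from a single sample, got: ",
                             paste(sid, collapse = ", "))
  empty <- data.table::data.table(sample_id = character(), chrom = character(),
                                  start = numeric(), end = numeric(),
                                  cnv_type = character(), copy_class = integer())
  if (!nrow(b) || !nrow(d)) return(empty)
  b <- data.table::copy(b)[, bid_ := .I]
  dd <- d[, .(chrom, d_start = start, d_end = end, d_type = cnv_type,
              normalized_depth)]
  data.table::setnames(dd, c("d_start", "d_end"), c("start", "end"))
  data.table::setkey(dd, chrom, start, end)
  ov <- data.table::foverlaps(b[, .(bid_, chrom, start, end, cnv_type)], dd,
                              type = "any", nomatch = NULL)
  # foverlaps: query columns prefixed i.
  ov <- ov[cnv_type == d_type]
  if (!nrow(ov)) return(empty)
  ov[, ov_bp := overlap_bp(i.start, i.end, start, end)]
  ov <- ov[ov_bp >= min_overlap_bp]
  if (reciprocal_fraction > 0) {
    ov <- ov[ov_bp >= reciprocal_fraction * (i.end - i.start) &
             ov_bp >= reciprocal_fraction * (end - start)]
  }
  if (!nrow(ov)) return(empty)
  # largest overlap wins; ties: depth call most similar in extent, then leftmost
  ov[, symdiff_ := (i.end - i.start - ov_bp) + (end - start - ov_bp)]
  data.table::setorder(ov, bid_, -ov_bp, symdiff_, start)
  best <- ov[!duplicated(bid_)]
  cls <- pmin(pmax(half_up(2 * best$normalized_depth), 0), 4)
  cls <- ifelse(best$cnv_type == "loss", pmin(cls, 1L), pmax(cls, 3L))
  out <- best[, .(sample_id = sid, chrom, start = i.start, end = i.end,
                  cnv_type)]
  out[, copy_class := as.integer(cls)]
  data.table::setorder(out, chrom, start, end)
  out[]
}

#' Collapse confident calls into distinct CNVs
#'
#' Calls identical in (chrom, start, end, type) across samples collapse into
#' one distinct CNV recording its supporting samples; the total number of
#' call events equals the sum of supporter counts.
#'
#' @param confident_calls confident-call table across all samples.
#' @return `data.table` with `chrom`, `start`, `end`, `cnv_type`,
#'   `samples` (list column of supporting sample ids), `n_samples`.
#' @export
collapse_distinct <- function(confident_calls) {
  x <- check_intervals(data.table::as.data.table(confident_calls), "confident calls")
  if (!nrow(x)) {
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), cnv_type = character(),
                                  samples = list(), n_samples = integer()))
  }
  out <- x[, .(samples = list(sort(unique(sample_id))),
               n_samples = data.table::uniqueN(sample_id)),
           by = .(chrom, start, end, cnv_type)]
  data.table::setorder(out, chrom, start, end, cnv_type)
  out[]
}

#' Merge distinct CNVs into CNV regions (CNVRs)
#'
#' Single-linkage merge of distinct CNVs overlapping by at least 1 bp,
#' regardless of type (book-ended intervals, `end == start`, do not merge).
#' The region type is `loss` or `gain` when all members agree, `mixed`
#' otherwise.  Regions supported by fewer than `min_support` distinct
#' animals are discarded.
#'
#' @param distinct_cnvs output of [collapse_distinct()].
#' @param min_support minimum number of supporting animals (default 4).
#' @return `data.table` of CNVRs: `cnvr_id`, `chrom`, `start`, `end`,
#'   `region_type`, `samples` (list), `n_samples`, `n_members`.
#' @export
build_cnvrs <- function(distinct_cnvs, min_support = 4) {
  stopifnot(min_support >= 1)
  x <- check_intervals(data.table::as.data.table(distinct_cnvs), "distinct CNVs")
  if (!nrow(x)) {
    return(data.table::data.table(cnvr_id = character(), chrom = character(),
                                  start = numeric(), end = numeric(),
                                  region_type = character(), samples = list(),
                                  n_samples = integer(), n_members = integer()))
  }
  x <- data.table::copy(x)
  if (!"samples" %in% names(x)) x[, samples := lapply(sample_id, identity)]
  data.table::setorder(x, chrom, start, end)
  # strict overlap: a new region starts when start >= running max end
  x[, grp := cumsum(start >= shift(cummax(end), fill = -Inf)), by = chrom]
  out <- x[, .(
    start = min(start), end = max(end),
    region_type = {
      tt <- unique(cnv_type)
      if (length(tt) == 1L) tt else "mixed"
    },
    samples = list(sort(unique(unlist(samples)))),
    n_members = .N
  ), by = .(chrom, grp)]
  out[, n_samples := vapply(samples, length, 1L)]
  out <- out[n_samples >= min_support]
  out[, grp := NULL]
  data.table::setorder(out, chrom, start, end)
  out[, cnvr_id := interval_id(chrom, start, end)]
  data.table::setcolorder(out, c("cnvr_id", "chrom", "start", "end", "region_type",
                                 "samples", "n_samples", "n_members"))
  out[]
}

#' Integrate a cohort of per-sample caller outputs
#'
#' Convenience wrapper: for every sample in the sample sheet, read its
#' boundary-caller VCF (`<vcf_dir>/<sample_id>.vcf`) and depth-caller text
#' (`<depth_dir>/<sample_id>.txt`), intersect them, and pool the confident
#' calls.  Chromosomes absent from `chrom_sizes` (non-autosomal contigs)
#' are dropped with a reported count.
#'
#' @param sample_table validated sample sheet.
#' @param vcf_dir,depth_dir directories of per-sample caller outputs.
#' @param chrom_sizes optional chromosome sizes; when given, calls on other
#'   contigs are dropped.
#' @inheritParams intersect_calls
#' @return pooled confident-call `data.table`.
#' @export
integrate_cohort <- function(sample_table, vcf_dir, depth_dir, chrom_sizes = NULL,
                             min_overlap_bp = 1, reciprocal_fraction = 0) {
  st <- validate_sample_table(sample_table)
  res <- vector("list", nrow(st))
  dropped <- 0L
  for (i in seq_len(nrow(st))) {
    sid <- st$sample_id[i]
    b <- read_sv_vcf(file.path(vcf_dir, paste0(sid, ".vcf")), sid)
    d <- read_depth_calls(file.path(depth_dir, paste0(sid, ".txt")), sid)
    if (!is.null(chrom_sizes)) {
      cs <- as_chrom_sizes(chrom_sizes)
      nb <- nrow(b); nd <- nrow(d)
      b <- b[chrom %in% cs$chrom]
      d <- d[chrom %in% cs$chrom]
      dropped <- dropped + (nb - nrow(b)) + (nd - nrow(d))
    }
    res[[i]] <- intersect_calls(b, d, min_overlap_bp, reciprocal_fraction)
  }
  if (dropped > 0L) message(dropped, " call(s) on contigs outside chrom_sizes dropped")
  data.table::rbindlist(res)[]
}
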