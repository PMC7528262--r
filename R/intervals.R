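# Internal interval arithmetic on 0-based half-open intervals.
#
# Every interval table in the package is a data.table with at least
# (chrom, start, end), start/end integer-valued doubles or integers,
# 0 <= start < end.  All public readers convert 1-based input coordinates
# at the boundary so nothing past io_formats ever sees another convention.

#' @import data.table
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".I", ".SD", "chrom", "start", "end", "cnv_type", "sample_id",
  "copy_class", "normalized_depth", "source_caller", "cnvr_id", "segment_id",
  "region_type", "n_samples", "samples", "grp", "run_end", "ov_bp", "score_",
  "i.start", "i.end", "i.sample_id", "i.copy_class", "i.cnv_type",
  "feature_class", "gene_id", "depth", "size", "breed", "subspecies",
  "covered_fraction", "covered_bp", "window_bp", "pattern", "fst",
  "event_id", "label", "carriers", "symdiff_", "d_start", "d_end", "rd",
  "seqnames", "type", "ID", "Parent", "biotype_", "type_", "parent_", "id_",
  "class_", "V1", "extra", "bid_", "d_type", "cs", "ce", "bp", "rank", "n",
  "oe", "observed", "expected", "observed_bp", "class_bp", "breeds"
))

# Validate an interval table; `what` names the offender in errors.
check_intervals <- function(x, what = "interval table") {
  if (!is.data.frame(x)) stop(what, " must be a data.frame/data.table")
  x <- data.table::as.data.table(x)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop(what, " lacks column(s): ", paste(miss, collapse = ", "))
  if (is.integer(x$start) || is.integer(x$end)) {
    # doubles throughout: integer columns break -Inf sentinels in scans
    x <- data.table::copy(x)
    x[, `:=`(start = as.numeric(start), end = as.numeric(end))]
  }
  if (nrow(x)) {
    if (any(x$start < 0)) stop(what, ": negative start")
    if (any(x$end <= x$start)) stop(what, ": empty or inverted interval (end <= start)")
  }
  x
}

# Overlap in bp between two half-open intervals (vectorised); 0 if disjoint.
overlap_bp <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

# Half-up rounding (R's round() is banker's).
half_up <- function(x) floor(x + 0.5)

# Union of intervals per chromosome.  `merge_touching` controls whether
# book-ended intervals ([a,b) + [b,c)) coalesce: TRUE for base-coverage
# arithmetic, FALSE would keep them apart (not needed for coverage).
interval_union <- function(x) {
  x <- check_intervals(x)
  if (!nrow(x)) return(data.table::data.table(chrom = character(), start = numeric(), end = numeric()))
  x <- x[, .(chrom, start = as.numeric(start), end = as.numeric(end))]
  data.table::setorder(x, chrom, start, end)
  x[, grp := {
    re <- shift(cummax(end), fill = -Inf)
    cumsum(start > re)  # start > prev-max end => gap (book-ended merges)
  }, by = chrom]
  x[, .(start = min(start), end = max(end)), by = .(chrom, grp)][, grp := NULL][]
}

# Total bp covered by the union of `x`.
union_bp <- function(x) {
  u <- interval_union(x)
  if (!nrow(u)) return(0)
  sum(u$end - u$start)
}

# bp of intersection between the unions of two interval tables.
intersect_union_bp <- function(a, b) {
  ua <- interval_union(a); ub <- interval_union(b)
  if (!nrow(ua) || !nrow(ub)) return(0)
  data.table::setkey(ub, chrom, start, end)
  ov <- data.table::foverlaps(ua, ub, type = "any", nomatch = NULL)
  if (!nrow(ov)) return(0)
  sum(overlap_bp(ov$i.start, ov$i.end, ov$start, ov$end))
}

# Intersection of union(a) with union(b) as an interval table.
intersect_union <- function(a, b) {
  ua <- interval_union(a); ub <- interval_union(b)
  empty <- data.table::data.table(chrom = character(), start = numeric(), end = numeric())
  if (!nrow(ua) || !nrow(ub)) return(empty)
  data.table::setkey(ub, chrom, start, end)
  ov <- data.table::foverlaps(ua, ub, type = "any", nomatch = NULL)
  if (!nrow(ov)) return(empty)
  out <- ov[, .(chrom, start = pmax(start, i.start), end = pmin(end, i.end))]
  out[end > start][order(chrom, start)]
}

# Stable human-readable id for a half-open interval.
interval_id <- function(chrom, start, end) sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))

# Parse "chrom:start-end" back into a table (inverse of interval_id).
parse_interval_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):([0-9]+)-([0-9]+)$", id))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed interval id: ", id[bad][1])
  data.table::data.table(
    chrom = vapply(m, `[`, "", 2L),
    start = as.numeric(vapply(m, `[`, "", 3L)),
    end   = as.numeric(vapply(m, `[`, "", 4L))
  )
}

# Normalise a chrom-sizes argument (data.table or named vector) to a
# data.table(chrom, size).
as_chrom_sizes <- function(chrom_sizes) {
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    return(data.table::data.table(chrom = names(chrom_sizes), size = as.numeric(chrom_sizes)))
  }
  x <- data.table::as.data.table(chrom_sizes)
  if (!all(c("chrom", "size") %in% names(x))) stop("chrom_sizes needs columns chrom, size")
  if (any(x$size <= 0)) stop("chromosome sizes must be positive")
  if (anyDuplicated(x$chrom)) stop("duplicated chromosome in chrom_sizes")
  x[, .(chrom, size = as.numeric(size))]
}
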