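# Genomic summaries over CNVRs: gene/exon overlap, feature-class
# enrichment (O/E), 1-Mb window density and CNV clusters, breed and
# subspecies sharing, and subspecies-specific sequence filtering.

#' Genes overlapped by CNVRs
#'
#' A gene is affected when any of its features (exon, intron, lncRNA or
#' pseudogene span) overlaps any CNVR by at least `min_overlap_bp`
#' ("at least one bp" by default, inclusive; book-ended intervals do not
#' overlap).  Exon-affected genes are the subset where an exon overlaps.
#'
#' @param cnvrs CNVR table (needs `chrom`, `start`, `end`).
#' @param features feature table from [read_gff3_features()].
#' @param min_overlap_bp minimum overlap (default 1).
#' @return list with character vectors `genes_overlapped` and
#'   `genes_exon_overlapped` (sorted).
#' @export
overlap_genes <- function(cnvrs, features, min_overlap_bp = 1) {
  cn <- check_intervals(data.table::as.data.table(cnvrs), "CNVRs")
  fe <- check_intervals(data.table::as.data.table(features), "features")
  if (!nrow(cn) || !nrow(fe)) {
    return(list(genes_overlapped = character(), genes_exon_overlapped = character()))
  }
  q <- cn[, .(chrom, start, end)]
  data.table::setkey(q, chrom, start, end)
  ov <- data.table::foverlaps(fe[, .(chrom, start, end, feature_class, gene_id)], q,
                              type = "any", nomatch = NULL)
  ov <- ov[overlap_bp(i.start, i.end, start, end) >= min_overlap_bp]
  list(
    genes_overlapped = sort(unique(ov$gene_id)),
    genes_exon_overlapped = sort(unique(ov[feature_class == "exon"]$gene_id))
  )
}

#' Observed/expected CNVR overlap per feature class
#'
#' Observed: the fraction of total CNVR bp falling inside the union of each
#' feature class.  Expected: the fraction of the autosomal genome (sum of
#' chromosome sizes) the class covers.  O/E above 1 means the class is
#' CNVR-enriched.
#'
#' @inheritParams overlap_genes
#' @param chrom_sizes chromosome sizes (`data.table` or named vector).
#' @return `data.table` with `feature_class`, `observed_bp`, `class_bp`,
#'   `observed`, `expected`, `oe`.
#' @export
feature_class_enrichment <- function(cnvrs, features, chrom_sizes) {
  cn <- check_intervals(data.table::as.data.table(cnvrs), "CNVRs")
  fe <- check_intervals(data.table::as.data.table(features), "features")
  cs <- as_chrom_sizes(chrom_sizes)
  genome_bp <- sum(cs$size)
  cnvr_bp <- union_bp(cn)
  if (cnvr_bp == 0) stop("CNVR set covers zero bp")
  if (!nrow(fe)) stop("feature set covers zero bp")
  classes <- sort(unique(fe$feature_class))
  out <- data.table::rbindlist(lapply(classes, function(cl) {
    cls <- fe[feature_class == cl]
    class_bp <- union_bp(cls)
    if (class_bp == 0) stop("feature class '", cl, "' covers zero bp")
    obs_bp <- intersect_union_bp(cn, cls)
    data.table::data.table(feature_class = cl, observed_bp = obs_bp,
                           class_bp = class_bp,
                           observed = obs_bp / cnvr_bp,
                           expected = class_bp / genome_bp)
  }))
  out[, oe := observed / expected]
  out[]
}

#' CNV density in non-overlapping genome windows
#'
#' Tiles every chromosome into non-overlapping windows (default 1 Mb; the
#' terminal window of a chromosome may be shorter and keeps its true length
#' as denominator) and reports the bp and fraction of each window covered
#' by the union of CNVRs.
#'
#' @inheritParams feature_class_enrichment
#' @param window_size window width in bp (default 1e6).
#' @return `data.table` with `chrom`, `start`, `end`, `window_bp`,
#'   `covered_bp`, `covered_fraction`.
#' @export
window_density <- function(cnvrs, chrom_sizes, window_size = 1e6) {
  stopifnot(window_size >= 1)
  cs <- as_chrom_sizes(chrom_sizes)
  cn <- check_intervals(data.table::as.data.table(cnvrs), "CNVRs")
  u <- interval_union(cn)
  wins <- cs[, {
    s <- seq(0, size - 1, by = window_size)
    list(start = s, end = pmin(s + window_size, size))
  }, by = chrom]
  wins[, `:=`(window_bp = end - start, covered_bp = 0)]
  if (nrow(u)) {
    data.table::setkey(u, chrom, start, end)
    ov <- data.table::foverlaps(wins[, .(chrom, start, end)], u,
                                type = "any", nomatch = NULL)
    if (nrow(ov)) {
      cov <- ov[, .(bp = sum(overlap_bp(i.start, i.end, start, end))),
                by = .(chrom, win_start = i.start)]
      wins[cov, covered_bp := bp, on = c("chrom", start = "win_start")]
    }
  }
  wins[, covered_fraction := covered_bp / window_bp]
  data.table::setorder(wins, chrom, start)
  wins[]
}

#' CNV clusters from window densities
#'
#' Windows whose covered fraction strictly exceeds `threshold` ("over 80%"
#' at the default) qualify; maximal runs of adjacent qualifying windows on
#' a chromosome merge into one cluster region (a single window is a
#' cluster of one).
#'
#' @param densities output of [window_density()].
#' @param threshold strict lower bound on `covered_fraction` (default 0.8).
#' @return `data.table` with `chrom`, `start`, `end`, `n_windows`.
#' @export
detect_clusters <- function(densities, threshold = 0.8) {
  x <- data.table::as.data.table(densities)
  data.table::setorder(x, chrom, start)
  q <- x[covered_fraction > threshold]
  if (!nrow(q)) {
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), n_windows = integer()))
  }
  q[, grp := cumsum(start != shift(end, fill = -1)), by = chrom]
  out <- q[, .(start = min(start), end = max(end), n_windows = .N),
           by = .(chrom, grp)][, grp := NULL]
  data.table::setorder(out, chrom, start)
  out[]
}

#' Breed-sharing patterns of CNVRs
#'
#' Maps each CNVR's supporting samples to breeds (and subspecies) and
#' counts CNVRs per breed-sharing pattern.
#'
#' @param cnvrs CNVR table with the `samples` list column.
#' @param sample_table validated sample sheet.
#' @return list: `per_cnvr` (`cnvr_id`, `breeds`, `subspecies` list columns,
#'   `pattern`), `pattern_counts`, and `all_breeds`.
#' @export
breed_sharing <- function(cnvrs, sample_table) {
  st <- validate_sample_table(sample_table)
  cn <- data.table::as.data.table(cnvrs)
  if (!"samples" %in% names(cn)) stop("CNVR table needs the 'samples' list column")
  breed_of <- stats::setNames(st$breed, st$sample_id)
  sub_of <- stats::setNames(st$subspecies, st$breed)
  per <- cn[, .(cnvr_id,
                breeds = lapply(samples, function(s) sort(unique(unname(breed_of[s])))))]
  per[, subspecies := lapply(breeds, function(b) sort(unique(unname(sub_of[b]))))]
  per[, pattern := vapply(breeds, paste, "", collapse = ",")]
  counts <- per[, .(n = .N), by = pattern][order(-n)]
  list(per_cnvr = per[], pattern_counts = counts[],
       all_breeds = sort(unique(st$breed)))
}

#' Count CNVRs shared by all breeds
#'
#' @param sharing output of [breed_sharing()].
#' @return integer count of CNVRs whose breed set equals the full breed set.
#' @export
shared_by_all <- function(sharing) {
  sum(vapply(sharing$per_cnvr$breeds, function(b) identical(b, sharing$all_breeds), TRUE))
}

#' Subspecies sharing of CNVRs
#'
#' Partitions CNVRs into those supported by samples of both subspecies
#' (shared) and those exclusive to one, and reports the shared percentage
#' (2 decimals).
#'
#' @inheritParams breed_sharing
#' @return list: `shared` (character vector of cnvr ids), `specific` (named
#'   list of cnvr-id vectors, one per subspecies), `shared_percentage`.
#' @export
subspecies_comparison <- function(cnvrs, sample_table) {
  st <- validate_sample_table(sample_table)
  cn <- data.table::as.data.table(cnvrs)
  if (!"samples" %in% names(cn)) stop("CNVR table needs the 'samples' list column")
  sub_of <- stats::setNames(st$subspecies, st$sample_id)
  all_subs <- sort(unique(st$subspecies))
  sets <- lapply(cn$samples, function(s) sort(unique(unname(sub_of[s]))))
  if (any(vapply(sets, length, 1L) == 0L)) stop("CNVR with no supporting subspecies")
  shared <- cn$cnvr_id[vapply(sets, function(s) length(s) == length(all_subs), TRUE)]
  specific <- lapply(all_subs, function(p) {
    cn$cnvr_id[vapply(sets, function(s) identical(s, p), TRUE)]
  })
  names(specific) <- all_subs
  list(shared = shared, specific = specific,
       shared_percentage = round(100 * length(shared) / nrow(cn), 2))
}

#' Subspecies-specific sequence intervals from remapped-read coverage
#'
#' Keeps coverage intervals with depth at or above `min_depth` (inclusive,
#' "at least 2 reads"), merges adjacent and book-ended runs, and retains
#' merged intervals strictly longer than `min_length` ("over 500 bp").
#'
#' @param coverage bedGraph-style table (`chrom`, `start`, `end`, `depth`),
#'   non-overlapping per chromosome.
#' @param min_length strict length cut in bp (default 500).
#' @param min_depth inclusive depth cut (default 2).
#' @return list: `intervals` (merged `data.table`) and `total_bp`.
#' @export
specific_sequences <- function(coverage, min_length = 500, min_depth = 2) {
  x <- check_intervals(data.table::as.data.table(coverage), "coverage")
  if (!"depth" %in% names(x)) stop("coverage table needs a 'depth' column")
  if (nrow(x) && any(x$depth < 0)) stop("negative depth in coverage")
  keep <- x[depth >= min_depth]
  merged <- interval_union(keep)          # book-ended runs coalesce
  merged <- merged[end - start > min_length]
  list(intervals = merged[], total_bp = if (nrow(merged)) sum(merged$end - merged$start) else 0)
}
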