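# End-to-end convenience wrapper over the core stages.

#' Run the CNV comparison pipeline from per-sample caller files
#'
#' Reads the sample sheet, chromosome sizes and per-sample caller outputs
#' from a directory laid out like [simulate_cnv_cohort()]'s
#' (`vcf/<sample>.vcf`, `depth/<sample>.txt`, `sample_sheet.tsv`,
#' `chrom.sizes`), then integrates calls, builds CNVRs, dissects segments
#' and genotypes every animal.
#'
#' @param dir input directory.
#' @param min_support minimum supporting animals per CNVR (default 4).
#' @param min_len strict segment length cut in bp (default 50).
#' @inheritParams intersect_calls
#' @return list with `sample_table`, `chrom_sizes`, `confident_calls`,
#'   `distinct_cnvs`, `cnvrs`, `segments`, `genotypes` (matrix).
#' @export
run_cnv_pipeline <- function(dir, min_support = 4, min_len = 50,
                             min_overlap_bp = 1, reciprocal_fraction = 0) {
  st <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  cs <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  conf <- integrate_cohort(st, file.path(dir, "vcf"), file.path(dir, "depth"),
                           chrom_sizes = cs, min_overlap_bp = min_overlap_bp,
                           reciprocal_fraction = reciprocal_fraction)
  distinct <- collapse_distinct(conf)
  cnvrs <- build_cnvrs(distinct, min_support = min_support)
  segs <- dissect_segments(cnvrs, conf, min_len = min_len)
  mat <- genotype_segments(segs, conf, st)
  list(sample_table = st, chrom_sizes = cs, confident_calls = conf,
       distinct_cnvs = distinct, cnvrs = cnvrs, segments = segs,
       genotypes = mat)
}
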