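# Two-subspecies synthetic CNV cohort generator with known truth.
#
# Emulates the statistical structure of a multi-breed resequencing panel:
# two subspecies, several breeds each, per-animal paired dual-caller call
# sets (boundary-caller VCF + depth-caller text) over a small
# multi-chromosome genome, with
#   * breed-shared CNVRs carried across both subspecies,
#   * lineage-differential fixed-deletion segments (loss fixed in one
#     population, diploid in the other),
#   * background CNVs private to a few animals,
#   * boundary jitter between the two callers (depth caller only, so the
#     boundary caller keeps single-base-exact planted boundaries), and
#   * normalised read depth around class/2 with truncated noise so
#     round_half_up(2*RD) always recovers the true class.

#' Simulation configuration
#'
#' Defaults describe the stated world used throughout the test suite:
#' a 5 x 10 Mb genome, 2 breeds per subspecies, 5 animals per breed,
#' 12,000 background CNVs with log-uniform lengths 500-10,000 bp, 200
#' breed-shared CNVRs, one fixed-deletion differential segment (loss
#' frequency 0 in taurine, 1 in indicine), 20 bp caller boundary jitter,
#' and depth noise sd 0.05 around class/2.
#'
#' @param seed integer RNG seed; all outputs are reproducible from it.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param breeds named list: subspecies -> character vector of breed names.
#' @param animals_per_breed animals per breed.
#' @param n_background_cnvs number of background (mostly private) CNV events.
#' @param background_len_range log-uniform length bounds in bp.
#' @param background_carrier_range integer bounds on carriers per background
#'   event (animals drawn uniformly from the whole cohort).
#' @param n_shared_cnvrs number of breed-shared events (each animal carries
#'   one with probability `shared_carrier_prob`; at least 4 carriers).
#' @param shared_carrier_prob per-animal carrier probability for shared events.
#' @param n_differential_segments number of planted lineage-differential
#'   fixed-deletion segments.
#' @param differential_fixation length-2 numeric: loss frequency of each
#'   differential segment in population X (first subspecies) and Y (second).
#' @param differential_len_range uniform length bounds for differential
#'   segments in bp.
#' @param boundary_jitter_sd sd (bp) of the rounded normal jitter applied to
#'   the depth caller's endpoints.
#' @param depth_noise_sd sd of normalised-depth noise around class/2
#'   (truncated to +/- 0.24 so the class always survives rounding).
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = stats::setNames(rep(10e6, 5), paste0("chr", 1:5)),
                       breeds = list(taurine = c("Angus", "Holstein"),
                                     indicine = c("Nelore", "Gir")),
                       animals_per_breed = 5L,
                       n_background_cnvs = 12000L,
                       background_len_range = c(500, 10000),
                       background_carrier_range = c(1L, 8L),
                       n_shared_cnvrs = 200L,
                       shared_carrier_prob = 0.5,
                       n_differential_segments = 1L,
                       differential_fixation = c(0, 1),
                       differential_len_range = c(2000, 5000),
                       boundary_jitter_sd = 20,
                       depth_noise_sd = 0.05) {
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0),
            !is.null(names(chrom_lengths)),
            length(breeds) == 2, all(lengths(breeds) >= 1),
            animals_per_breed >= 1,
            n_background_cnvs >= 0, n_shared_cnvrs >= 0,
            n_differential_segments >= 0,
            all(background_len_range > 0), diff(background_len_range) >= 0,
            all(background_carrier_range >= 1),
            shared_carrier_prob > 0, shared_carrier_prob <= 1,
            length(differential_fixation) == 2,
            all(differential_fixation >= 0), all(differential_fixation <= 1),
            boundary_jitter_sd >= 0, depth_noise_sd >= 0)
  structure(list(
    seed = as.integer(seed), chrom_lengths = chrom_lengths, breeds = breeds,
    animals_per_breed = as.integer(animals_per_breed),
    n_background_cnvs = as.integer(n_background_cnvs),
    background_len_range = background_len_range,
    background_carrier_range = as.integer(background_carrier_range),
    n_shared_cnvrs = as.integer(n_shared_cnvrs),
    shared_carrier_prob = shared_carrier_prob,
    n_differential_segments = as.integer(n_differential_segments),
    differential_fixation = differential_fixation,
    differential_len_range = differential_len_range,
    boundary_jitter_sd = boundary_jitter_sd,
    depth_noise_sd = depth_noise_sd
  ), class = "sim_config")
}

# sample an event class: losses weighted 2:1 over gains, class 2 reserved
# for non-carriers
sample_event_class <- function(n) {
  sample(c(0L, 1L, 3L, 4L), n, replace = TRUE, prob = c(1, 1, 0.5, 0.5) / 3)
}

# draw n intervals on the genome; lengths via `draw_len(n)`; reject (and
# resample) intervals crossing chromosome ends or overlapping any `avoid`
# interval.  Counts rejections.
draw_intervals <- function(n, chrom_lengths, draw_len, avoid = NULL) {
  chroms <- names(chrom_lengths)
  rejected <- 0L
  chrom_v <- character(n); start_v <- numeric(n); end_v <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      chr_ <- sample(chroms, 1L, prob = chrom_lengths)
      len_ <- max(2, round(draw_len(1L)))
      s_ <- floor(stats::runif(1, 0, chrom_lengths[[chr_]]))
      e_ <- s_ + len_
      if (e_ > chrom_lengths[[chr_]]) { rejected <- rejected + 1L; next }
      if (!is.null(avoid) && nrow(avoid)) {
        a <- avoid[avoid$chrom == chr_]
        if (nrow(a) && any(overlap_bp(a$start, a$end, s_, e_) > 0)) {
          rejected <- rejected + 1L; next
        }
      }
      chrom_v[i] <- chr_; start_v[i] <- s_; end_v[i] <- e_
      break
    }
  }
  out <- data.table::data.table(chrom = chrom_v, start = start_v, end = end_v)
  attr(out, "rejected") <- rejected
  out
}

#' Simulate a two-population dual-caller CNV cohort
#'
#' Writes, under `out_dir`: per-animal boundary-caller VCFs (`vcf/`),
#' per-animal depth-caller text files (`depth/`), `sample_sheet.tsv`,
#' `chrom.sizes`, and `truth.tsv`.  Returns the truth table, sample sheet
#' and chromosome sizes.  Outputs are byte-identical across runs with the
#' same config.
#'
#' For each planted event an animal carries, its files contain one
#' boundary-caller call with the exact planted interval and one same-type
#' depth-caller call with jittered endpoints (truncated to preserve >= 1 bp
#' overlap) and normalised depth `class/2` plus truncated noise.
#' Differential and shared/background intervals never overlap each other,
#' so differential segments survive dissection intact.
#'
#' @param config a [sim_config()] object.
#' @param out_dir output directory (created if missing).
#' @return list: `truth` (`data.table`: `event_id`, `chrom`, `start`, `end`,
#'   `label`, `cnv_type`, `copy_class`, `carriers` list column),
#'   `sample_table`, `chrom_sizes`, `paths`.
#' @export
simulate_cnv_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cl <- config$chrom_lengths

  # cohort -----------------------------------------------------------------
  st <- data.table::rbindlist(lapply(names(config$breeds), function(sub) {
    data.table::rbindlist(lapply(config$breeds[[sub]], function(br) {
      data.table::data.table(
        sample_id = sprintf("%s_%02d", br, seq_len(config$animals_per_breed)),
        breed = br, subspecies = sub)
    }))
  }))
  st <- validate_sample_table(st)
  animals <- st$sample_id
  pops <- names(config$breeds)   # X = first, Y = second

  # planted events ----------------------------------------------------------
  events <- list()
  # differential fixed-deletion segments, placed first and kept clear of
  # everything else
  ndiff <- config$n_differential_segments
  diff_iv <- draw_intervals(ndiff, cl,
                            function(n) stats::runif(n, config$differential_len_range[1],
                                                     config$differential_len_range[2]))
  if (ndiff > 0) {
    carriers <- lapply(seq_len(ndiff), function(i) {
      unlist(lapply(seq_along(pops), function(pi) {
        ids <- st$sample_id[st$subspecies == pops[pi]]
        k <- round(config$differential_fixation[pi] * length(ids))
        if (k == 0) character() else sort(sample(ids, k))
      }))
    })
    events$differential <- data.table::data.table(
      chrom = diff_iv$chrom, start = diff_iv$start, end = diff_iv$end,
      label = "differential", copy_class = 0L, carriers = carriers)
  }
  avoid <- diff_iv
  # breed-shared events: every animal carries with prob shared_carrier_prob,
  # redrawn until >= 4 carriers so shared regions always survive the
  # min-support filter
  if (config$n_shared_cnvrs > 0) {
    sh_iv <- draw_intervals(config$n_shared_cnvrs, cl,
                            function(n) exp(stats::runif(n, log(config$background_len_range[1]),
                                                         log(config$background_len_range[2]))),
                            avoid = avoid)
    carriers <- lapply(seq_len(config$n_shared_cnvrs), function(i) {
      repeat {
        c_ <- animals[stats::runif(length(animals)) < config$shared_carrier_prob]
        if (length(c_) >= 4L) return(sort(c_))
      }
    })
    events$shared <- data.table::data.table(
      chrom = sh_iv$chrom, start = sh_iv$start, end = sh_iv$end,
      label = "shared", copy_class = sample_event_class(config$n_shared_cnvrs),
      carriers = carriers)
  }
  # background events: private to a few animals
  if (config$n_background_cnvs > 0) {
    bg_iv <- draw_intervals(config$n_background_cnvs, cl,
                            function(n) exp(stats::runif(n, log(config$background_len_range[1]),
                                                         log(config$background_len_range[2]))),
                            avoid = avoid)
    nc <- sample(seq(config$background_carrier_range[1], config$background_carrier_range[2]),
                 config$n_background_cnvs, replace = TRUE)
    carriers <- lapply(nc, function(k) sort(sample(animals, k)))
    events$background <- data.table::data.table(
      chrom = bg_iv$chrom, start = bg_iv$start, end = bg_iv$end,
      label = "background", copy_class = sample_event_class(config$n_background_cnvs),
      carriers = carriers)
  }
  truth <- data.table::rbindlist(events, use.names = TRUE)
  if (!nrow(truth)) stop("configuration plants no events")
  data.table::setorder(truth, chrom, start, end)
  truth[, event_id := sprintf("ev%06d", .I)]
  truth[, cnv_type := ifelse(copy_class < 2L, "loss", "gain")]
  data.table::setcolorder(truth, c("event_id", "chrom", "start", "end", "label",
                                   "cnv_type", "copy_class", "carriers"))
  rej <- attr(diff_iv, "rejected")
  if (!is.null(rej) && rej > 0) message(rej, " planted interval(s) resampled")

  # per-animal caller files --------------------------------------------------
  dir.create(file.path(out_dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "depth"), recursive = TRUE, showWarnings = FALSE)
  # expand truth to (event, carrier) pairs with jittered depth calls
  pairs <- truth[, .(sample_id = carriers[[1]]), by = .(event_id, chrom, start, end, cnv_type, copy_class)]
  n <- nrow(pairs)
  j1 <- half_up(stats::rnorm(n, 0, config$boundary_jitter_sd))
  j2 <- half_up(stats::rnorm(n, 0, config$boundary_jitter_sd))
  ds <- pmin(pmax(pairs$start + j1, 0), pairs$end - 1)
  de <- pmin(pmax(pairs$end + j2, pairs$start + 1), cl[pairs$chrom])
  de <- pmax(de, ds + 1)
  noise <- pmin(pmax(stats::rnorm(n, 0, config$depth_noise_sd), -0.24), 0.24)
  rd <- pmax(pairs$copy_class / 2 + noise, 0)
  pairs[, `:=`(d_start = ds, d_end = de, rd = rd)]

  vcf_header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(cl), as.integer(cl)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"), collapse = "\t")
  )
  for (sid in animals) {
    p <- pairs[sample_id == sid][order(chrom, start, end)]
    svtype <- ifelse(p$cnv_type == "loss", "DEL", "DUP")
    rec <- sprintf("%s\t%d\t%s\t%s\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d",
                   p$chrom, as.integer(p$start + 1), p$event_id, "N",
                   svtype, svtype, as.integer(p$end))
    writeLines(c(vcf_header, rec), file.path(out_dir, "vcf", paste0(sid, ".vcf")))
    dtype <- ifelse(p$cnv_type == "loss", "deletion", "duplication")
    dl <- sprintf("%s\t%s:%d-%d\t%d\t%.4f",
                  dtype, p$chrom, as.integer(p$d_start + 1), as.integer(p$d_end),
                  as.integer(p$d_end - p$d_start), p$rd)
    writeLines(dl, file.path(out_dir, "depth", paste0(sid, ".txt")))
  }
  data.table::fwrite(st, file.path(out_dir, "sample_sheet.tsv"), sep = "\t")
  writeLines(sprintf("%s\t%d", names(cl), as.integer(cl)),
             file.path(out_dir, "chrom.sizes"))
  tr_out <- data.table::copy(truth)
  tr_out[, carriers := vapply(carriers, paste, "", collapse = ",")]
  data.table::fwrite(tr_out, file.path(out_dir, "truth.tsv"), sep = "\t")

  list(truth = truth, sample_table = st,
       chrom_sizes = data.table::data.table(chrom = names(cl), size = as.numeric(cl)),
       paths = list(dir = out_dir,
                    vcf_dir = file.path(out_dir, "vcf"),
                    depth_dir = file.path(out_dir, "depth"),
                    sample_sheet = file.path(out_dir, "sample_sheet.tsv"),
                    chrom_sizes = file.path(out_dir, "chrom.sizes"),
                    truth = file.path(out_dir, "truth.tsv")))
}

#' Expected genotype matrix from simulation truth
#'
#' Independent (brute-force) construction of the genotype a faithful
#' pipeline should recover at given segments: for each segment and sample,
#' the planted events of that sample fully containing the segment determine
#' the class under the same precedence rule as [genotype_segments()]
#' (farthest from 2, ties to the lower class); no event means diploid.
#'
#' @param truth truth table from [simulate_cnv_cohort()].
#' @param segments segment table (`segment_id`, `chrom`, `start`, `end`).
#' @param sample_table sample sheet defining the columns.
#' @return integer matrix, segments x samples.
#' @export
truth_genotype_matrix <- function(truth, segments, sample_table) {
  st <- validate_sample_table(sample_table)
  segs <- data.table::as.data.table(segments)
  mat <- matrix(2L, nrow = nrow(segs), ncol = nrow(st),
                dimnames = list(segs$segment_id, st$sample_id))
  for (i in seq_len(nrow(segs))) {
    ev <- truth[chrom == segs$chrom[i] & start <= segs$start[i] & end >= segs$end[i]]
    if (!nrow(ev)) next
    for (sid in st$sample_id) {
      cls <- ev$copy_class[vapply(ev$carriers, function(cc) sid %in% cc, TRUE)]
      if (!length(cls)) next
      cls <- cls[order(-abs(cls - 2), cls)]
      mat[i, sid] <- as.integer(cls[1])
    }
  }
  mat
}

#' Generate a GFF3 annotation fixture on the simulated genome
#'
#' Places non-overlapping genes uniformly: protein-coding genes with 1-5
#' exons (introns arise between them), lncRNAs and pseudogenes, and writes
#' them as GFF3.  Reproducible from the config seed (offset so it does not
#' collide with the cohort stream).
#'
#' @param config a [sim_config()] object.
#' @param path output GFF3 path.
#' @param n_genes number of genes to place.
#' @return the feature table as read back by [read_gff3_features()] would
#'   see it: `chrom`, `start`, `end`, `feature_class`, `gene_id` plus a
#'   `gene_class` per gene in the `genes` attribute.
#' @export
generate_annotation_fixture <- function(config, path, n_genes = 30) {
  stopifnot(inherits(config, "sim_config"), n_genes >= 0)
  set.seed(config$seed + 104729L)  # independent stream from the cohort
  cl <- config$chrom_lengths
  placed <- data.table::data.table(chrom = character(), start = numeric(), end = numeric())
  lines <- c("##gff-version 3")
  feats <- list()
  for (g in seq_len(n_genes)) {
    iv <- draw_intervals(1L, cl, function(n) stats::runif(n, 2000, 20000), avoid = placed)
    placed <- rbind(placed, iv[, .(chrom, start, end)])
    gid <- sprintf("gene%03d", g)
    cls <- sample(c("protein_coding", "lncRNA", "pseudogene"), 1L, prob = c(0.6, 0.2, 0.2))
    lines <- c(lines, sprintf("%s\tsim\tgene\t%d\t%d\t.\t+\t.\tID=%s;biotype=%s",
                              iv$chrom, as.integer(iv$start + 1), as.integer(iv$end), gid, cls))
    if (cls == "protein_coding") {
      n_ex <- sample(1:5, 1L)
      len <- iv$end - iv$start
      bnd <- sort(stats::runif(2L * n_ex - 2L, 0.05, 0.95))
      cuts <- unique(as.integer(iv$start + c(0, bnd, 1) * len))
      # alternate exon/intron blocks starting and ending with an exon
      starts <- cuts[-length(cuts)]; ends <- cuts[-1]
      keep <- ends > starts
      starts <- starts[keep]; ends <- ends[keep]
      ex_idx <- seq_along(starts) %% 2 == 1
      lines <- c(lines, sprintf("%s\tsim\texon\t%d\t%d\t.\t+\t.\tParent=%s",
                                iv$chrom, as.integer(starts[ex_idx] + 1),
                                as.integer(ends[ex_idx]), gid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
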