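# Readers and writers for every external format the pipeline touches.
#
# Internal convention: 0-based half-open intervals everywhere.  VCF and
# depth-caller text are 1-based inclusive on disk and converted here, at the
# boundary, so the rest of the package never handles another convention.
# Caller vocabulary (DEL/DUP, deletion/duplication) is normalised to
# loss/gain at ingest.

CNV_CLASSES <- 0:4  # copy-number classes; 4 encodes ">=4", 2 is diploid

# empty RawCall table with the canonical column set
empty_raw_calls <- function() {
  data.table::data.table(
    sample_id = character(), chrom = character(), start = numeric(),
    end = numeric(), cnv_type = character(), source_caller = character(),
    normalized_depth = numeric(), quality = numeric()
  )
}

#' Read structural-variant CNV calls from a VCF file
#'
#' Parses a LUMPY-style structural-variant VCF and returns the DEL/DUP
#' records as raw boundary-caller CNV calls.  Only the `SVTYPE` and `END`
#' INFO keys are consumed; records of any other SVTYPE are skipped (a count
#' is reported).  VCF `POS` is 1-based; output intervals are 0-based
#' half-open, so a record with POS=101, END=200 becomes [100, 200).
#'
#' @param path path to a VCF 4.x file with `SVTYPE` and `END` INFO keys.
#' @param sample_id sample identifier attached to every returned call.
#' @return A `data.table` of raw calls with columns `sample_id`, `chrom`,
#'   `start`, `end`, `cnv_type` (`"loss"`/`"gain"`), `source_caller`
#'   (`"boundary_caller"`), `normalized_depth` (`NA`), `quality`.
#' @export
read_sv_vcf <- function(path, sample_id) {
  stopifnot(length(sample_id) == 1L, nzchar(sample_id))
  lines <- readLines(path)
  idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(idx)) return(empty_raw_calls())
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 8L)) stop("malformed VCF record at line ", idx[which(nf < 8L)[1]], " of ", path)
  field <- function(k) vapply(parts, `[`, "", k)
  pos <- suppressWarnings(as.numeric(field(2)))
  if (anyNA(pos)) stop("malformed VCF record at line ", idx[which(is.na(pos))[1]],
                       " of ", path, ": non-numeric POS")
  info <- field(8)
  has_sv <- grepl("(^|;)SVTYPE=", info)
  svtype <- ifelse(has_sv, sub(".*(^|;)SVTYPE=([^;]+).*", "\\2", info), NA_character_)
  keep <- !is.na(svtype) & svtype %in% c("DEL", "DUP")
  skipped <- sum(!keep)
  if (any(keep & !grepl("(^|;)END=", info))) {
    bad <- which(keep & !grepl("(^|;)END=", info))[1]
    stop("malformed VCF record at line ", idx[bad], " of ", path, ": missing END")
  }
  endv <- suppressWarnings(as.numeric(ifelse(grepl("(^|;)END=", info),
                                             sub(".*(^|;)END=([^;]+).*", "\\2", info),
                                             NA)))
  if (anyNA(endv[keep])) {
    stop("malformed VCF record at line ", idx[which(keep & is.na(endv))[1]],
         " of ", path, ": non-numeric END")
  }
  rejected <- keep & endv <= pos - 1
  if (any(rejected)) {
    warning(sum(rejected), " VCF record(s) rejected (END <= POS), first at line ",
            idx[which(rejected)[1]])
    keep <- keep & !rejected
  }
  if (skipped > 0L) message(skipped, " non-DEL/DUP record(s) skipped in ", basename(path))
  if (!any(keep)) return(empty_raw_calls())
  data.table::data.table(
    sample_id = sample_id, chrom = field(1)[keep], start = pos[keep] - 1,
    end = endv[keep],
    cnv_type = ifelse(svtype[keep] == "DEL", "loss", "gain"),
    source_caller = "boundary_caller", normalized_depth = NA_real_,
    quality = suppressWarnings(as.numeric(field(6)[keep]))
  )
}

#' Read read-depth CNV calls from CNVnator-style text
#'
#' Parses whitespace-delimited lines of the form
#' `type chrom:start-end size normalized_RD [extra...]` where `type` is
#' `deletion` or `duplication` and coordinates are 1-based inclusive.
#' Output intervals are 0-based half-open.  If the size column disagrees
#' with `end - start + 1` by more than 1 bp a warning is raised and the
#' coordinates win.  Extra columns are preserved opaquely in `extra`.
#'
#' @param path path to the text file.
#' @param sample_id sample identifier attached to every returned call.
#' @return A `data.table` of raw calls (`source_caller = "depth_caller"`,
#'   `normalized_depth` populated; 1.0 is approximately diploid).
#' @export
read_depth_calls <- function(path, sample_id) {
  stopifnot(length(sample_id) == 1L, nzchar(sample_id))
  lines <- readLines(path)
  idx <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(idx)) {
    res <- empty_raw_calls()
    res[, extra := character()]
    return(res[])
  }
  parts <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 4L)) stop("unparseable depth-caller line ", idx[which(nf < 4L)[1]], " of ", path)
  type <- vapply(parts, `[`, "", 1)
  bad_type <- !(type %in% c("deletion", "duplication"))
  if (any(bad_type)) {
    i <- which(bad_type)[1]
    stop("unparseable depth-caller line ", idx[i], " of ", path,
         ": unknown type '", type[i], "'")
  }
  reg <- vapply(parts, `[`, "", 2)
  m <- regmatches(reg, regexec("^(.+):([0-9]+)-([0-9]+)$", reg))
  bad_reg <- lengths(m) != 4L
  if (any(bad_reg)) {
    i <- which(bad_reg)[1]
    stop("unparseable depth-caller line ", idx[i], " of ", path, ": bad region '", reg[i], "'")
  }
  chrom <- vapply(m, `[`, "", 2)
  s1 <- as.numeric(vapply(m, `[`, "", 3))
  e1 <- as.numeric(vapply(m, `[`, "", 4))
  if (any(e1 < s1)) {
    stop("unparseable depth-caller line ", idx[which(e1 < s1)[1]], " of ", path, ": end < start")
  }
  size <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  rd <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 4)))
  if (anyNA(rd) || any(rd < 0)) {
    stop("unparseable depth-caller line ", idx[which(is.na(rd) | rd < 0)[1]],
         " of ", path, ": bad normalized depth")
  }
  mismatch <- !is.na(size) & abs(size - (e1 - s1 + 1)) > 1
  if (any(mismatch)) {
    warning(sum(mismatch), " size column(s) disagree with coordinates in ", path,
            ", first at line ", idx[which(mismatch)[1]], " (coordinates win)")
  }
  extra_col <- vapply(parts, function(f) {
    if (length(f) > 4L) paste(f[-(1:4)], collapse = " ") else NA_character_
  }, "")
  data.table::data.table(
    sample_id = sample_id, chrom = chrom, start = s1 - 1, end = e1,
    cnv_type = ifelse(type == "deletion", "loss", "gain"),
    source_caller = "depth_caller", normalized_depth = rd,
    quality = NA_real_, extra = extra_col
  )
}

#' Read gene features from a GFF3 annotation
#'
#' Builds the feature set used for CNVR annotation: exons and introns of
#' protein-coding genes, plus lncRNA and pseudogene spans.  Introns are
#' computed as the gene span minus its exons.  Gene classification uses the
#' `biotype`/`gene_biotype` attribute when present, falling back on the GFF
#' `type` column (`pseudogene`, `lnc_RNA`).
#'
#' @param path path to a GFF3 file.
#' @return A `data.table` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `feature_class` (`exon`, `intron`, `lncRNA`, `pseudogene`)
#'   and `gene_id`.
#' @export
read_gff3_features <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  df <- data.table::as.data.table(as.data.frame(g))
  df[, `:=`(chrom = as.character(seqnames), start = start - 1, end = end)]
  mc <- names(df)
  bio_col <- intersect(c("biotype", "gene_biotype"), mc)
  df[, biotype_ := if (length(bio_col)) as.character(df[[bio_col[1]]]) else NA_character_]
  df[, type_ := as.character(type)]
  # Parent is a CharacterList from rtracklayer
  parent <- vapply(df$Parent, function(p) if (length(p)) sub("^gene:", "", p[[1]]) else NA_character_, "")
  df[, parent_ := parent]
  df[, id_ := if ("ID" %in% mc) sub("^gene:", "", as.character(ID)) else NA_character_]

  is_gene_row <- df$type_ %in% c("gene", "pseudogene", "lnc_RNA", "ncRNA_gene")
  genes <- df[is_gene_row]
  genes[, class_ := data.table::fcase(
    type_ == "pseudogene" | biotype_ %in% c("pseudogene", "processed_pseudogene"), "pseudogene",
    type_ %in% c("lnc_RNA", "ncRNA_gene") | biotype_ %in% c("lncRNA", "lincRNA"), "lncRNA",
    default = "protein_coding"
  )]
  exons <- df[type_ == "exon"]
  if (nrow(exons) && anyNA(exons$parent_)) stop("exon without Parent attribute in ", path)
  # resolve exon parents through transcript rows to a gene when needed
  if (nrow(exons)) {
    tx_parent <- df$parent_[match(exons$parent_, df$id_)]
    resolved <- ifelse(exons$parent_ %in% genes$id_, exons$parent_, tx_parent)
    if (anyNA(resolved)) stop("exon without resolvable parent gene in ", path)
    if (!all(resolved %in% genes$id_)) stop("exon without resolvable parent gene in ", path)
    exons[, gene_id := resolved]
  }

  feats <- list()
  pc <- genes[class_ == "protein_coding"]
  if (nrow(exons)) {
    bad <- !exons$gene_id %in% genes$id_
    if (any(bad)) stop("exon without parent gene in ", path)
    feats$exon <- exons[, .(chrom, start, end, feature_class = "exon", gene_id)]
    # containment check against the gene span
    gs <- genes[match(exons$gene_id, id_)]
    if (any(exons$start < gs$start | exons$end > gs$end)) {
      stop("exon outside its gene span in ", path)
    }
  }
  # introns: per protein-coding gene, span minus exon union
  if (nrow(pc)) {
    intr <- data.table::rbindlist(lapply(seq_len(nrow(pc)), function(i) {
      gid <- pc$id_[i]
      ex <- exons[exons$gene_id == gid]
      if (!nrow(ex)) return(NULL)
      u <- interval_union(ex)
      gaps_s <- c(pc$start[i], u$end)
      gaps_e <- c(u$start, pc$end[i])
      keep <- gaps_e > gaps_s
      if (!any(keep)) return(NULL)
      data.table::data.table(chrom = pc$chrom[i], start = gaps_s[keep],
                             end = gaps_e[keep], feature_class = "intron",
                             gene_id = gid)
    }))
    if (nrow(intr)) feats$intron <- intr
  }
  other <- genes[class_ != "protein_coding"]
  if (nrow(other)) {
    feats$other <- other[, .(chrom, start, end,
                             feature_class = ifelse(class_ == "lncRNA", "lncRNA", "pseudogene"),
                             gene_id = id_)]
  }
  res <- data.table::rbindlist(feats, use.names = TRUE)
  if (!nrow(res)) {
    return(data.table::data.table(chrom = character(), start = numeric(), end = numeric(),
                                  feature_class = character(), gene_id = character()))
  }
  data.table::setorder(res, chrom, start, end)
  res[]
}

#' Read and write BED intervals
#'
#' BED is natively 0-based half-open, matching the internal convention, so
#' coordinates pass through untouched.  `write_bed` emits BED3 plus any
#' additional columns in `x` (e.g. `name`, `score`); `read_bed` names the
#' first six columns per the BED spec.
#'
#' @param x interval table with at least `chrom`, `start`, `end`.
#' @param path file path.
#' @return `read_bed` returns a `data.table`; `write_bed` returns `path`
#'   invisibly.
#' @export
write_bed <- function(x, path) {
  x <- check_intervals(x, "BED table")
  lead <- c("chrom", "start", "end")
  extra <- setdiff(names(x), lead)
  data.table::fwrite(x[, c(lead, extra), with = FALSE], path,
                     sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  x <- data.table::fread(path, header = FALSE, sep = "\t")
  bed_names <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(x, seq_len(min(ncol(x), 6L)), bed_names[seq_len(min(ncol(x), 6L))])
  check_intervals(x, "BED file")[]
}

#' Read bedGraph coverage intervals
#'
#' @param path bedGraph file (`chrom start end depth`, 0-based half-open).
#' @return `data.table` with `chrom`, `start`, `end`, `depth`.  Overlapping
#'   intervals on a chromosome violate bedGraph semantics and raise an error.
#' @export
read_bedgraph <- function(path) {
  x <- data.table::fread(path, header = FALSE, sep = "\t",
                         col.names = c("chrom", "start", "end", "depth"))
  x <- check_intervals(x, "bedGraph")
  if (any(x$depth < 0)) stop("negative depth in bedGraph ", path)
  data.table::setorder(x, chrom, start)
  ov <- x[, if (.N < 2) FALSE else any(start[-1] < cummax(as.numeric(end))[-.N]),
          by = chrom]$V1
  if (any(ov)) stop("overlapping bedGraph intervals in ", path)
  x[]
}

#' Read a two-column chromosome-sizes file
#'
#' @param path whitespace-delimited `chrom size` file.
#' @return `data.table` with `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  x <- data.table::fread(path, header = FALSE, col.names = c("chrom", "size"))
  as_chrom_sizes(x)
}

#' Read the sample sheet
#'
#' @param path TSV with header `sample_id breed subspecies`.
#' @return validated `data.table`; `sample_id` unique, each breed mapped to
#'   exactly one subspecies.
#' @export
read_sample_sheet <- function(path) {
  x <- data.table::fread(path, header = TRUE, sep = "\t")
  validate_sample_table(x)
}

#' @rdname read_sample_sheet
#' @param x a data.frame with columns `sample_id`, `breed`, `subspecies`.
#' @export
validate_sample_table <- function(x) {
  x <- data.table::as.data.table(x)
  need <- c("sample_id", "breed", "subspecies")
  if (!all(need %in% names(x))) stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(x$sample_id)) stop("duplicated sample_id in sample sheet")
  multi <- x[, data.table::uniqueN(subspecies), by = breed][V1 > 1]
  if (nrow(multi)) stop("breed mapped to more than one subspecies: ", paste(multi$breed, collapse = ", "))
  x[, .(sample_id = as.character(sample_id), breed = as.character(breed),
        subspecies = as.character(subspecies))]
}

#' Write and read the segment genotype matrix
#'
#' TSV with segment ids (`chrom:start-end`) in the first column and one
#' integer column per sample.  `read_genotype_matrix(write_genotype_matrix(m))`
#' is the identity.
#'
#' @param mat integer matrix, rows = segments (rownames are segment ids),
#'   columns = samples; values in 0..4.
#' @param path file path.
#' @export
write_genotype_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  dt <- data.table::data.table(segment_id = rownames(mat))
  dt <- cbind(dt, data.table::as.data.table(mat))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_genotype_matrix
#' @export
read_genotype_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  ids <- dt$segment_id
  m <- as.matrix(dt[, -1L, with = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (nrow(m) && !all(m %in% CNV_CLASSES)) stop("genotype classes outside 0..4 in ", path)
  m
}
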