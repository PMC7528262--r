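# Population differentiation of CNV segments.
#
# F_ST here operates on genotype-class frequencies (classes 0,1,2,3,>=4 per
# individual), not chromosome-allele frequencies:
#   t_i = (x_i * Nx + y_i * Ny) / (Nx + Ny)
#   Ht  = 1 - sum_i t_i^2
#   Hs  = ((1 - sum_i x_i^2) * Nx + (1 - sum_i y_i^2) * Ny) / (Nx + Ny)
#   F_ST = (Ht - Hs) / Ht,  with F_ST := 0 when Ht == 0
# (both populations fixed for the same class carry no measurable divergence).

#' Construct a class-frequency record for one population
#'
#' @param freq numeric vector of genotype-class proportions; names are the
#'   classes (defaults to `"0".."4"`).  Must sum to 1.
#' @param n number of individuals (>= 1).
#' @param label population label.
#' @return list with elements `label`, `N`, `freq` (class `"class_freq"`).
#' @export
class_freq <- function(freq, n, label = "pop") {
  if (is.null(names(freq))) {
    # unnamed partial vectors are not accepted: classes must be explicit
    stopifnot(length(freq) == length(CNV_CLASSES))
    names(freq) <- as.character(CNV_CLASSES)
  }
  full <- stats::setNames(numeric(length(CNV_CLASSES)), as.character(CNV_CLASSES))
  bad <- setdiff(names(freq), names(full))
  if (length(bad)) stop("unknown genotype class: ", paste(bad, collapse = ", "))
  full[names(freq)] <- freq
  if (n < 1) stop("population size N must be >= 1")
  if (any(full < 0) || any(full > 1) || abs(sum(full) - 1) > 1e-9) {
    stop("class frequencies must lie in [0,1] and sum to 1")
  }
  structure(list(label = label, N = n, freq = full), class = "class_freq")
}

#' Genotype-class frequencies per segment for one population
#'
#' @param mat genotype matrix from [genotype_segments()].
#' @param sample_table validated sample sheet.
#' @param population subspecies label selecting the samples.
#' @param by which sample-sheet column `population` refers to
#'   (`"subspecies"` or `"breed"`).
#' @return list with `label`, `N`, and `freq`: a segments x 5 matrix of
#'   class proportions (columns `"0".."4"`, rows sum to 1).
#' @export
class_frequencies <- function(mat, sample_table, population, by = "subspecies") {
  st <- validate_sample_table(sample_table)
  stopifnot(by %in% c("subspecies", "breed"))
  sel <- st$sample_id[st[[by]] == population]
  sel <- intersect(colnames(mat), sel)
  if (!length(sel)) stop("no samples selected for population '", population, "'")
  sub <- mat[, sel, drop = FALSE]
  freq <- vapply(CNV_CLASSES, function(k) rowMeans(sub == k), numeric(nrow(mat)))
  if (nrow(mat) == 1L) freq <- matrix(freq, nrow = 1L)
  dimnames(freq) <- list(rownames(mat), as.character(CNV_CLASSES))
  list(label = population, N = length(sel), freq = freq)
}

#' F_ST between two populations at one segment
#'
#' Implements the genotype-class F_ST above.  `Ht == 0` (both populations
#' fixed for the same class) yields `fst = 0` by definition.
#'
#' @param x,y `class_freq` records over the same class set.
#' @return list with `t` (weighted average class frequencies), `Ht`, `Hs`,
#'   `fst`, `Nx`, `Ny`.
#' @export
compute_fst <- function(x, y) {
  stopifnot(inherits(x, "class_freq"), inherits(y, "class_freq"))
  if (x$N <= 0 || y$N <= 0) stop("population size must be positive")
  if (!identical(names(x$freq), names(y$freq))) stop("class sets differ between populations")
  nx <- x$N; ny <- y$N
  t_i <- (x$freq * nx + y$freq * ny) / (nx + ny)
  ht <- 1 - sum(t_i^2)
  hs <- ((1 - sum(x$freq^2)) * nx + (1 - sum(y$freq^2)) * ny) / (nx + ny)
  fst <- if (ht == 0) 0 else (ht - hs) / ht
  list(t = t_i, Ht = ht, Hs = hs, fst = fst, Nx = nx, Ny = ny)
}

#' Genome-wide F_ST scan over a genotype matrix
#'
#' Vectorised per-segment F_ST between two populations defined in the
#' sample sheet (default taurine vs indicine, pooling breeds within
#' subspecies).
#'
#' @inheritParams class_frequencies
#' @param pop_x,pop_y labels of the two populations.
#' @return `data.table` with `segment_id`, `Nx`, `Ny`, `Ht`, `Hs`, `fst`.
#' @export
fst_scan <- function(mat, sample_table, pop_x = "taurine", pop_y = "indicine",
                     by = "subspecies") {
  fx <- class_frequencies(mat, sample_table, pop_x, by = by)
  fy <- class_frequencies(mat, sample_table, pop_y, by = by)
  nx <- fx$N; ny <- fy$N
  t_i <- (fx$freq * nx + fy$freq * ny) / (nx + ny)
  ht <- 1 - rowSums(t_i^2)
  hs <- ((1 - rowSums(fx$freq^2)) * nx + (1 - rowSums(fy$freq^2)) * ny) / (nx + ny)
  fst <- ifelse(ht == 0, 0, (ht - hs) / ht)
  data.table::data.table(segment_id = rownames(mat), Nx = nx, Ny = ny,
                         Ht = ht, Hs = hs, fst = fst)
}

#' Top-percentile F_ST segments
#'
#' Segments sorted by F_ST descending; the `ceil(top_fraction * n)` highest
#' are returned, and any segment tied with the value at the cut is included
#' rather than broken arbitrarily.
#'
#' @param fst_records output of [fst_scan()] (needs `segment_id`, `fst`).
#' @param top_fraction fraction in (0, 1), e.g. 0.01 or 0.001.
#' @return `data.table` subset ordered by decreasing `fst` with a `rank`
#'   column (1 = most divergent; ties share min rank order by segment id).
#' @export
rank_segments <- function(fst_records, top_fraction) {
  x <- data.table::as.data.table(fst_records)
  if (!nrow(x)) stop("empty F_ST record set")
  stopifnot(top_fraction > 0, top_fraction < 1)
  data.table::setorder(x, -fst, segment_id)
  k <- ceiling(top_fraction * nrow(x))
  cutoff <- x$fst[k]
  out <- x[fst >= cutoff]
  out[, rank := seq_len(.N)]
  out[]
}

#' Per-population loss/normal/gain rates per segment
#'
#' For each segment and population, the proportions of individuals whose
#' class is below 2 (loss), exactly 2 (normal), or above 2 (gain).
#'
#' @inheritParams class_frequencies
#' @return `data.table` with `segment_id`, `population`, `loss`, `normal`,
#'   `gain` (each row sums to 1).
#' @export
status_rates <- function(mat, sample_table, by = "subspecies") {
  st <- validate_sample_table(sample_table)
  pops <- sort(unique(st[[by]]))
  out <- lapply(pops, function(p) {
    sel <- intersect(colnames(mat), st$sample_id[st[[by]] == p])
    sub <- mat[, sel, drop = FALSE]
    data.table::data.table(
      segment_id = rownames(mat), population = p,
      loss = rowMeans(sub < 2L), normal = rowMeans(sub == 2L),
      gain = rowMeans(sub > 2L)
    )
  })
  data.table::rbindlist(out)[]
}

#' Principal-component coordinates of samples from the genotype matrix
#'
#' Centers the segments x samples genotype matrix and projects samples onto
#' the leading principal axes.  Deterministic up to the sign of each axis.
#'
#' @param mat genotype matrix (segments x samples).
#' @param n_components number of components requested.
#' @return numeric matrix, samples x `n_components`.
#' @export
pca_coordinates <- function(mat, n_components = 2) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2, n_components >= 1)
  x <- t(mat)                       # samples in rows
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(p$sdev > max(p$sdev[1], 1e-12) * 1e-9)
  if (n_components > rank) {
    stop("n_components (", n_components, ") exceeds matrix rank (", rank, ")")
  }
  coords <- p$x[, seq_len(n_components), drop = FALSE]
  rownames(coords) <- colnames(mat)
  coords
}
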