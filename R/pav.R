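#' Parameters for presence-absence variation detection
#'
#' Large FNB deletions are not representable as indel records; they appear
#' as windows of near-zero coverage in the mutant while the control keeps
#' normal coverage. A window is flagged when the mutant's normalized depth
#' is at most `max_mutant_ratio` times the control's, and the control's
#' normalized depth is at least `min_control_norm_depth` (regions poorly
#' covered in both samples — e.g. a deletion shared with the control —
#' are never called). Flagged windows are clustered, allowing up to
#' `merge_gap_windows` unflagged windows inside a run, and clusters with at
#' least `min_windows` flagged windows become calls.
#'
#' @param window_size window width in bp (default 500).
#' @param max_mutant_ratio maximum mutant/control normalized-depth ratio
#'   inside a deletion (default 0.1; nonzero to tolerate mismapped reads).
#' @param min_control_norm_depth minimum control normalized depth for a
#'   window to be informative (default 0.5).
#' @param min_windows minimum flagged windows per call (default 2).
#' @param merge_gap_windows maximum unflagged gap bridged when merging
#'   (default 1).
#' @return an object of class `fnb_pav_params`.
#' @export
pav_params <- function(window_size = 500L, max_mutant_ratio = 0.1,
                       min_control_norm_depth = 0.5, min_windows = 2L,
                       merge_gap_windows = 1L) {
  stopifnot(window_size > 0, max_mutant_ratio > 0, max_mutant_ratio < 1,
            min_control_norm_depth > 0, min_windows > 0,
            merge_gap_windows >= 0)
  structure(list(window_size = as.integer(window_size),
                 max_mutant_ratio = max_mutant_ratio,
                 min_control_norm_depth = min_control_norm_depth,
                 min_windows = as.integer(min_windows),
                 merge_gap_windows = as.integer(merge_gap_windows)),
            class = "fnb_pav_params")
}

new_depth_track <- function(sample_id, windows) {
  windows <- windows[order(windows$chrom, windows$start), , drop = FALSE]
  rownames(windows) <- NULL
  # windows must tile each chromosome without overlap
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, ]
    if (nrow(w) > 1 && any(w$start[-1] != w$end[-nrow(w)]))
      stop("depth windows do not tile chromosome ", ch,
           " (gaps or overlaps found)")
  }
  pos <- windows$mean_depth[windows$mean_depth > 0]
  normalizer <- if (length(pos)) median(pos) else NA_real_
  structure(list(sample_id = sample_id, windows = windows,
                 window_size = max(windows$end - windows$start),
                 normalizer = normalizer),
            class = "fnb_depth_track")
}

#' @export
print.fnb_depth_track <- function(x, ...) {
  cat("fnb_depth_track:", x$sample_id, "-", nrow(x$windows), "windows of",
      x$window_size, "bp, normalizer =", format(x$normalizer, digits = 4), "\n")
  invisible(x)
}

#' Read a windowed depth track from a BED-like file
#'
#' Expects four tab-separated columns — chrom, start, end, mean depth —
#' with half-open 0-based intervals tiling each chromosome. The
#' normalizer (genome-wide median of per-window mean depth over nonzero
#' windows) is computed on load; normalized depth is
#' `mean_depth / normalizer`.
#'
#' @param path path to the depth file.
#' @param sample_id sample label for the track.
#' @return an object of class `fnb_depth_track`.
#' @export
read_depth_track <- function(path, sample_id = basename(path)) {
  if (!file.exists(path)) stop("depth file not found: ", path)
  d <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "start", "end", "mean_depth"),
                  colClasses = c("character", "integer", "integer", "numeric"))
  new_depth_track(sample_id, d)
}

#' Compute a windowed depth track from an alignment file
#'
#' Tiles every reference sequence in the BAM header into fixed windows and
#' computes per-window mean depth from pileup counts.
#'
#' @param path coordinate-sorted, indexed BAM file.
#' @param window_size window width in bp.
#' @param sample_id sample label.
#' @return an object of class `fnb_depth_track`.
#' @export
depth_track_from_alignment <- function(path, window_size = 500L,
                                       sample_id = basename(path)) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  idx <- paste0(path, ".bai")
  if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", path)))
    stop("alignment must be coordinate-sorted and indexed (no .bai found for ",
         path, ")")
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  if (!length(hdr)) stop("no reference sequences in BAM header of ", path)
  pp <- Rsamtools::PileupParam(max_depth = 100000L, min_base_quality = 0L,
                               min_mapq = 0L, min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = FALSE)
  pu <- Rsamtools::pileup(path, pileupParam = pp)
  rows <- list()
  for (ch in names(hdr)) {
    len <- hdr[[ch]]
    starts <- seq(0L, max(0L, len - 1L), by = window_size)
    ends <- pmin(starts + window_size, len)
    cov <- numeric(length(starts))
    p <- pu[pu$seqnames == ch, , drop = FALSE]
    if (nrow(p)) {
      wi <- (p$pos - 1L) %/% window_size + 1L
      agg <- tapply(p$count, wi, sum)
      cov[as.integer(names(agg))] <- as.numeric(agg)
    }
    rows[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                             mean_depth = cov / (ends - starts),
                             stringsAsFactors = FALSE)
  }
  new_depth_track(sample_id, do.call(rbind, rows))
}

#' Detect large deletions as read-depth presence-absence variations
#'
#' Compares a mutant depth track against a control on an identical window
#' grid. Both tracks are normalized by their genome-wide median window
#' depth, so calls are invariant to overall sequencing-depth differences.
#' See [pav_params()] for the flagging and merging rules. Calls are
#' annotated `HOMOZYGOUS_LOSS` when the mean mutant normalized depth over
#' the call is at most 0.1, else `PARTIAL_LOSS` (a heterozygous deletion
#' sits near 0.5).
#'
#' @param mutant,control `fnb_depth_track` objects on the same window grid.
#' @param params an [pav_params()] object.
#' @return an object of class `fnb_pav_calls`: data frame with chrom,
#'   start, end (half-open), n_windows (flagged), mean mutant/control
#'   normalized depths and zygosity hint.
#' @export
detect_pav <- function(mutant, control, params = pav_params()) {
  stopifnot(inherits(mutant, "fnb_depth_track"),
            inherits(control, "fnb_depth_track"),
            inherits(params, "fnb_pav_params"))
  mw <- mutant$windows; cw <- control$windows
  if (nrow(mw) != nrow(cw) ||
      !all(mw$chrom == cw$chrom & mw$start == cw$start & mw$end == cw$end))
    stop("mutant and control depth tracks are on different window grids")
  if (is.na(mutant$normalizer) || mutant$normalizer <= 0 ||
      is.na(control$normalizer) || control$normalizer <= 0)
    stop("zero or undefined depth normalizer; tracks cannot be compared")

  mnorm <- mw$mean_depth / mutant$normalizer
  cnorm <- cw$mean_depth / control$normalizer
  flagged <- cnorm >= params$min_control_norm_depth &
    mnorm <= params$max_mutant_ratio * cnorm

  calls <- list()
  for (ch in unique(mw$chrom)) {
    sel <- which(mw$chrom == ch)
    fi <- sel[flagged[sel]]
    if (!length(fi)) next
    # cluster flagged windows, bridging gaps of <= merge_gap_windows
    brk <- c(0L, which(diff(fi) > params$merge_gap_windows + 1L), length(fi))
    for (b in seq_len(length(brk) - 1L)) {
      run <- fi[(brk[b] + 1L):brk[b + 1L]]
      if (length(run) < params$min_windows) next
      mm <- mean(mnorm[run]); cm <- mean(cnorm[run])
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = ch, start = mw$start[run[1]], end = mw$end[run[length(run)]],
        n_windows = length(run),
        mean_mutant_norm_depth = mm, mean_control_norm_depth = cm,
        depth_ratio = mm / cm,
        zygosity_hint = if (mm <= 0.1) "HOMOZYGOUS_LOSS" else "PARTIAL_LOSS",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_windows = integer(0), mean_mutant_norm_depth = numeric(0),
               mean_control_norm_depth = numeric(0), depth_ratio = numeric(0),
               zygosity_hint = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "params") <- params
  class(out) <- c("fnb_pav_calls", "data.frame")
  out
}
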