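read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

config_to_objects <- function(config) {
  if (is.null(config$design)) stop("configuration error: 'design' missing")
  design <- study_design(config$design)
  r <- config$roles
  if (is.null(r$mutant_pool) || is.null(r$wildtype_control))
    stop("configuration error: roles must name mutant_pool and wildtype_control")
  roles <- sample_roles(mutant_pool = r$mutant_pool,
                        wildtype_control = r$wildtype_control,
                        wildtype_like_pool = r$wildtype_like_pool,
                        irrelevant_mutants = unlist(r$irrelevant_mutants %||% character()))
  validate_design(design, roles)
  th <- config$thresholds %||% list()
  thresholds <- quality_thresholds(
    min_site_qual = th$min_site_qual %||% 30,
    min_genotype_quality = th$min_genotype_quality %||% 20,
    min_depth = th$min_depth %||% 5)
  pv <- config$pav %||% list()
  pparams <- pav_params(
    window_size = pv$window_size %||% 500L,
    max_mutant_ratio = pv$max_mutant_ratio %||% 0.1,
    min_control_norm_depth = pv$min_control_norm_depth %||% 0.5,
    min_windows = pv$min_windows %||% 2L,
    merge_gap_windows = pv$merge_gap_windows %||% 1L)
  list(design = design, roles = roles, thresholds = thresholds,
       pav = pparams, pav_tracks = pv[c("mutant_track", "control_track")],
       lenient_missing = isTRUE(config$lenient_missing))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full candidate-deletion pipeline from a configuration
#'
#' Executes the complete analysis: read the joint-called VCF, apply the
#' quality filter, deletion selection, design genotype pattern and cohort
#' subtraction, classify surviving deletions against the GFF3 annotation,
#' rank them by consequence severity, and (when depth tracks are
#' configured) detect large presence-absence deletions. Configuration is
#' validated before any file I/O; on error, partially written outputs are
#' removed.
#'
#' The YAML configuration names `design`, `roles` (mutant_pool,
#' wildtype_control, optional wildtype_like_pool and irrelevant_mutants),
#' `vcf`, `gff3`, optional `thresholds`, optional `pav` (mutant_track,
#' control_track plus [pav_params()] overrides) and optional `output_dir`.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return an object of class `fnb_report`: ranked candidate table,
#'   per-record filter decisions, stage counts, PAV calls (or NULL),
#'   parameter echo and package version. When `output_dir` is set the
#'   report files (`candidates.vcf`, `decisions.tsv`, `report.tsv`,
#'   `pav_calls.bed`, `pav_ratios.tsv`) are written there.
#' @export
run_pipeline <- function(config) {
  config <- read_pipeline_config(config)
  obj <- config_to_objects(config)         # validate before any I/O
  if (is.null(config$vcf)) stop("configuration error: 'vcf' missing")
  if (is.null(config$gff3)) stop("configuration error: 'gff3' missing")

  out_dir <- config$output_dir
  written <- character(0)
  ok <- FALSE
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    on.exit(if (!ok && length(written)) unlink(written), add = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  v <- stage("read_vcf", read_vcf(config$vcf, obj$roles))
  message("fnbfind: read ", n_variants(v), " decomposed records from ",
          config$vcf)
  fr <- stage("filter", filter_candidates(v, obj$design, obj$roles,
                                          obj$thresholds, obj$lenient_missing))
  cnt <- fr$stage_counts
  message("fnbfind: filter stages — ",
          paste(names(cnt), as.integer(cnt), sep = "=", collapse = ", "))
  idx <- stage("annotation", load_annotation(config$gff3))
  calls <- stage("classify", classify_deletions(fr$candidates, idx))
  ranked <- prioritize(calls)
  message("fnbfind: ", nrow(ranked), " candidate deletion(s), ",
          sum(ranked$effect %in% c("FRAMESHIFT", "WHOLE_OR_PARTIAL_GENE_LOSS",
                                   "IN_FRAME_DELETION")), " coding")

  pav <- NULL
  tr <- obj$pav_tracks
  if (!is.null(tr$mutant_track) && !is.null(tr$control_track)) {
    pav <- stage("pav", detect_pav(
      read_depth_track(tr$mutant_track, "mutant"),
      read_depth_track(tr$control_track, "control"), obj$pav))
    message("fnbfind: ", nrow(pav), " presence-absence call(s)")
    if (nrow(pav)) {
      gid <- vapply(seq_len(nrow(pav)), function(i)
        paste(annotation_query(idx, pav$chrom[i], pav$start[i] + 1L,
                               pav$end[i]), collapse = ","), character(1))
      pav$gene_ids <- gid
    }
  }

  report <- structure(list(
    candidates = ranked, decisions = fr$decisions,
    stage_counts = fr$stage_counts, pav_calls = pav,
    design = obj$design, roles = obj$roles, thresholds = obj$thresholds,
    pav_params = obj$pav,
    version = as.character(utils::packageVersion("fnbfind"))),
    class = "fnb_report")

  if (!is.null(out_dir)) {
    pth <- function(f) file.path(out_dir, f)
    write_vcf(fr$candidates, pth("candidates.vcf"))
    written <- c(written, pth("candidates.vcf"))
    write.table(fr$decisions, pth("decisions.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, pth("decisions.tsv"))
    rep_tab <- ranked[, setdiff(names(ranked), "severity"), drop = FALSE]
    write.table(rep_tab, pth("report.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, pth("report.tsv"))
    if (!is.null(pav)) {
      write.table(pav[, c("chrom", "start", "end", "zygosity_hint")],
                  pth("pav_calls.bed"), sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      write.table(pav, pth("pav_ratios.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      written <- c(written, pth("pav_calls.bed"), pth("pav_ratios.tsv"))
    }
  }
  ok <- TRUE
  report
}

#' @export
print.fnb_report <- function(x, ...) {
  cat("fnbfind candidate report (v", x$version, ")\n", sep = "")
  cat("  design:", x$design$mode, "\n")
  cnt <- x$stage_counts
  cat("  input records:", sum(cnt), "| excluded:",
      paste(names(cnt)[1:4], as.integer(cnt)[1:4], sep = "=", collapse = ", "),
      "\n")
  cat("  candidates:", nrow(x$candidates), "\n")
  if (nrow(x$candidates)) {
    show <- x$candidates[, c("rank", "chrom", "start", "end", "length",
                             "region_class", "effect", "gene_ids",
                             "cds_bases_deleted")]
    print(utils::head(show, 10), row.names = FALSE)
    if (nrow(x$candidates) > 10) cat("  ...\n")
  }
  if (!is.null(x$pav_calls))
    cat("  presence-absence calls:", nrow(x$pav_calls), "\n")
  invisible(x)
}
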