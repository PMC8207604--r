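#' Site and genotype quality filter
#'
#' A record passes when site QUAL >= `min_site_qual` and, for every role
#' sample, GQ >= `min_genotype_quality` and DP >= `min_depth`. Records with
#' a missing QUAL, GQ or DP value fail the corresponding check whenever the
#' threshold is positive: the pattern filter downstream presupposes
#' confidently called genotypes.
#'
#' @param v an `fnb_variants` object.
#' @param thresholds an [quality_thresholds()] object.
#' @param roles an [sample_roles()] object; only role samples are checked.
#' @return logical vector, one element per record.
#' @export
quality_filter <- function(v, thresholds = quality_thresholds(),
                           roles) {
  stopifnot(inherits(v, "fnb_variants"), inherits(thresholds, "fnb_thresholds"),
            inherits(roles, "fnb_roles"))
  smp <- role_samples(roles)
  miss <- setdiff(smp, v$samples)
  if (length(miss))
    stop("configuration error: role sample(s) not in variants: ",
         paste(miss, collapse = ", "))
  qual <- v$sites$qual
  pass <- if (thresholds$min_site_qual > 0) {
    !is.na(qual) & qual >= thresholds$min_site_qual
  } else rep(TRUE, n_variants(v))
  gq <- v$gq[, smp, drop = FALSE]
  dp <- v$dp[, smp, drop = FALSE]
  if (thresholds$min_genotype_quality > 0)
    pass <- pass & apply(!is.na(gq) & gq >= thresholds$min_genotype_quality, 1, all)
  if (thresholds$min_depth > 0)
    pass <- pass & apply(!is.na(dp) & dp >= thresholds$min_depth, 1, all)
  unname(pass)
}

#' Match variants against the design's expected genotype pattern
#'
#' Evaluates, per record, whether each role sample shows the genotype class
#' the design expects ([expected_pattern()]): homozygous mutant in the
#' mutant pool, the design-specific class in the wild-type-like pool,
#' homozygous wild type in the control, and homozygous wild type in every
#' irrelevant-mutant cohort sample (the cohort background subtraction).
#' A `MISSING` genotype never matches an expectation; with
#' `lenient_missing = TRUE` a missing call is tolerated in
#' irrelevant-mutant samples only.
#'
#' A mismatch at the mutant pool, wild-type-like pool or control is
#' recorded as stage `PATTERN`; a mismatch at an irrelevant mutant as stage
#' `COHORT`, with the failing sample named.
#'
#' @param v an `fnb_variants` object (normally already quality-filtered).
#' @param design an `fnb_design`.
#' @param roles an `fnb_roles`.
#' @param lenient_missing allow missing genotypes in irrelevant mutants.
#' @return data frame with one row per record: `passed`, `failed_stage`
#'   (`PATTERN`, `COHORT` or `NONE`), `failing_sample`, plus the observed
#'   genotype class per role sample.
#' @export
matches_pattern <- function(v, design, roles, lenient_missing = FALSE) {
  stopifnot(inherits(v, "fnb_variants"))
  validate_design(design, roles)
  pat <- expected_pattern(design)
  n <- n_variants(v)
  failed_stage <- rep("NONE", n)
  failing <- rep(NA_character_, n)

  core <- c(mutant_pool = roles$mutant_pool,
            wildtype_like_pool = if (design$mode == "INDIVIDUAL") NULL
                                 else roles$wildtype_like_pool,
            wildtype_control = roles$wildtype_control)
  for (rl in names(core)) {
    obs <- v$gt_class[, core[[rl]]]
    bad <- failed_stage == "NONE" & obs != pat[[rl]]
    failed_stage[bad] <- "PATTERN"
    failing[bad] <- core[[rl]]
  }
  for (smp in roles$irrelevant_mutants) {
    obs <- v$gt_class[, smp]
    ok <- obs == "HOM_REF"
    if (lenient_missing) ok <- ok | obs == "MISSING"
    bad <- failed_stage == "NONE" & !ok
    failed_stage[bad] <- "COHORT"
    failing[bad] <- smp
  }

  obs_classes <- v$gt_class[, role_samples(roles), drop = FALSE]
  colnames(obs_classes) <- paste0("gt_", colnames(obs_classes))
  data.frame(passed = failed_stage == "NONE",
             failed_stage = failed_stage,
             failing_sample = failing,
             obs_classes,
             stringsAsFactors = FALSE)
}

FILTER_STAGES <- c("QUALITY", "CLASS", "PATTERN", "COHORT", "NONE")

#' Filter joint-called variants down to candidate causative deletions
#'
#' Runs the filtering cascade in a fixed order for reproducible
#' provenance: (1) site/genotype quality, (2) deletion selection — only
#' DELETION-class variants are eligible candidates, SNVs and insertions are
#' set aside with stage `CLASS` —, (3) the design genotype pattern, and
#' (4) the irrelevant-mutant cohort condition. Every excluded record is
#' logged with the first stage at which it failed.
#'
#' @inheritParams matches_pattern
#' @param thresholds an [quality_thresholds()] object.
#' @return an object of class `fnb_filter_result`: list with `candidates`
#'   (`fnb_variants`, genomic order), `decisions` (data frame, one row per
#'   input record: site key, per-role genotype class, `failed_stage`,
#'   `failing_sample`, `passed`) and `stage_counts`.
#' @export
filter_candidates <- function(v, design, roles,
                              thresholds = quality_thresholds(),
                              lenient_missing = FALSE) {
  stopifnot(inherits(v, "fnb_variants"))
  validate_design(design, roles)
  n <- n_variants(v)
  stage <- rep("NONE", n)
  failing <- rep(NA_character_, n)

  q_ok <- quality_filter(v, thresholds, roles)
  stage[!q_ok] <- "QUALITY"
  not_del <- !is_deletion(v)
  stage[stage == "NONE" & not_del] <- "CLASS"

  open <- stage == "NONE"
  if (any(open)) {
    pm <- matches_pattern(v[open], design, roles, lenient_missing)
    stage[open] <- pm$failed_stage
    failing[open] <- pm$failing_sample
  }

  passed <- stage == "NONE"
  ord <- order(v$sites$chrom, v$sites$pos, v$sites$alt)
  cand <- v[ord[passed[ord]]]

  obs <- v$gt_class[, role_samples(roles), drop = FALSE]
  colnames(obs) <- paste0("gt_", colnames(obs))
  decisions <- data.frame(
    chrom = v$sites$chrom, pos = v$sites$pos,
    ref = v$sites$ref, alt = v$sites$alt,
    variant_class = v$sites$variant_class,
    obs,
    failed_stage = stage, failing_sample = failing, passed = passed,
    stringsAsFactors = FALSE)
  decisions <- decisions[ord, , drop = FALSE]
  rownames(decisions) <- NULL

  counts <- table(factor(stage, levels = FILTER_STAGES))
  structure(list(candidates = cand, decisions = decisions,
                 stage_counts = counts, design = design, roles = roles,
                 thresholds = thresholds),
            class = "fnb_filter_result")
}

#' @export
print.fnb_filter_result <- function(x, ...) {
  n <- sum(x$stage_counts)
  cat("fnb_filter_result:", n, "input records ->",
      n_variants(x$candidates), "candidate deletion(s)\n")
  cat("  design:", x$design$mode, "\n")
  cat("  excluded:",
      paste(names(x$stage_counts)[1:4], as.integer(x$stage_counts)[1:4],
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
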