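DESIGN_MODES <- c("RECESSIVE_BSA", "NONRECESSIVE_F3", "INDIVIDUAL")

#' Declare the experimental design of an FNB mapping experiment
#'
#' Three scenarios are supported. `RECESSIVE_BSA`: the mutant segregates as
#' a single recessive locus (F2 mutant:wild-type-like close to 1:3), the
#' mutant pool is expected homozygous mutant at the causal site and the
#' wild-type-like pool — a mixture of homozygous wild-type and heterozygous
#' plants — is expected heterozygous. `NONRECESSIVE_F3`: the wild-type-like
#' pool is built from F3 families that no longer segregate, so it is
#' expected homozygous wild type. `INDIVIDUAL`: no segregating population;
#' only the mutant pool and a wild-type control are compared.
#'
#' @param mode one of `"RECESSIVE_BSA"`, `"NONRECESSIVE_F3"`, `"INDIVIDUAL"`.
#' @return an object of class `fnb_design`.
#' @seealso [expected_pattern()], [chisq_segregation()] for choosing between
#'   the two segregating-population modes.
#' @export
study_design <- function(mode = DESIGN_MODES) {
  mode <- match.arg(mode)
  structure(list(mode = mode), class = "fnb_design")
}

#' @export
print.fnb_design <- function(x, ...) {
  cat("fnb_design:", x$mode, "\n")
  invisible(x)
}

#' Map VCF sample names to experimental roles
#'
#' @param mutant_pool sample name of the (pooled) mutant DNA.
#' @param wildtype_control sample name of the wild-type accession control.
#' @param wildtype_like_pool sample name of the wild-type-like pool
#'   (required for the two segregating-population designs, absent for
#'   `INDIVIDUAL`).
#' @param irrelevant_mutants character vector (possibly empty) of
#'   independently derived mutant lines included in the joint calling as
#'   mutual controls; shared background variants are homozygous in them too
#'   and get filtered out.
#' @return an object of class `fnb_roles`.
#' @export
sample_roles <- function(mutant_pool, wildtype_control,
                         wildtype_like_pool = NULL,
                         irrelevant_mutants = character()) {
  r <- list(mutant_pool = as.character(mutant_pool),
            wildtype_like_pool = if (is.null(wildtype_like_pool)) NULL
                                 else as.character(wildtype_like_pool),
            wildtype_control = as.character(wildtype_control),
            irrelevant_mutants = as.character(irrelevant_mutants))
  all_s <- role_samples(r)
  if (anyDuplicated(all_s))
    stop("configuration error: duplicated sample in roles: ",
         paste(unique(all_s[duplicated(all_s)]), collapse = ", "))
  structure(r, class = "fnb_roles")
}

#' @export
print.fnb_roles <- function(x, ...) {
  cat("fnb_roles:\n")
  cat("  mutant_pool:       ", x$mutant_pool, "\n")
  if (!is.null(x$wildtype_like_pool))
    cat("  wildtype_like_pool:", x$wildtype_like_pool, "\n")
  cat("  wildtype_control:  ", x$wildtype_control, "\n")
  if (length(x$irrelevant_mutants))
    cat("  irrelevant_mutants:", paste(x$irrelevant_mutants, collapse = ", "), "\n")
  invisible(x)
}

role_samples <- function(roles) {
  c(roles$mutant_pool, roles$wildtype_like_pool, roles$wildtype_control,
    roles$irrelevant_mutants)
}

#' Validate that roles satisfy a design's requirements
#'
#' Both segregating-population designs require a wild-type-like pool;
#' `INDIVIDUAL` requires only mutant pool and wild-type control. Called by
#' [filter_candidates()] and [run_pipeline()] before any file I/O.
#'
#' @param design an `fnb_design`.
#' @param roles an `fnb_roles`.
#' @return `TRUE`, invisibly; otherwise a configuration error.
#' @export
validate_design <- function(design, roles) {
  stopifnot(inherits(design, "fnb_design"), inherits(roles, "fnb_roles"))
  if (design$mode %in% c("RECESSIVE_BSA", "NONRECESSIVE_F3") &&
      is.null(roles$wildtype_like_pool))
    stop("configuration error: design ", design$mode,
         " requires a wildtype_like_pool sample")
  invisible(TRUE)
}

#' Expected genotype pattern for a study design
#'
#' The causal deletion must be homozygous in the mutant pool in every
#' design. Under `RECESSIVE_BSA` the wild-type-like pool is expected
#' heterozygous; under `NONRECESSIVE_F3` it is expected homozygous wild
#' type; under `INDIVIDUAL` there is no wild-type-like pool. The wild-type
#' control and every irrelevant-mutant cohort sample are expected
#' homozygous wild type in all designs.
#'
#' @param design an `fnb_design`.
#' @return named list of expected genotype classes per role
#'   (`wildtype_like_pool` is `NA` for `INDIVIDUAL`).
#' @export
expected_pattern <- function(design) {
  stopifnot(inherits(design, "fnb_design"))
  wtl <- switch(design$mode,
                RECESSIVE_BSA = "HET",
                NONRECESSIVE_F3 = "HOM_REF",
                INDIVIDUAL = NA_character_)
  list(mutant_pool = "HOM_ALT",
       wildtype_like_pool = wtl,
       wildtype_control = "HOM_REF",
       irrelevant_mutants = "HOM_REF")
}

#' Quality thresholds for site and genotype filtering
#'
#' Raw joint-called variants are filtered by quality before the genotype
#' pattern is applied. A record passes when its site QUAL and, in every
#' role sample, the genotype quality (GQ) and read depth (DP) meet these
#' minima. Missing QUAL/GQ/DP values fail the corresponding check (strict).
#'
#' @param min_site_qual minimum site QUAL (phred-scaled; default 30).
#' @param min_genotype_quality minimum per-sample GQ (default 20).
#' @param min_depth minimum per-sample DP in reads (default 5).
#' @return an object of class `fnb_thresholds`.
#' @export
quality_thresholds <- function(min_site_qual = 30, min_genotype_quality = 20,
                               min_depth = 5) {
  stopifnot(min_site_qual >= 0, min_genotype_quality >= 0, min_depth >= 0)
  structure(list(min_site_qual = min_site_qual,
                 min_genotype_quality = min_genotype_quality,
                 min_depth = min_depth),
            class = "fnb_thresholds")
}

#' @export
print.fnb_thresholds <- function(x, ...) {
  cat("fnb_thresholds: QUAL >=", x$min_site_qual,
      "| GQ >=", x$min_genotype_quality, "| DP >=", x$min_depth, "\n")
  invisible(x)
}
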