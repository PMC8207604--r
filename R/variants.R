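#' @importFrom utils write.table read.table packageVersion head
#' @importFrom stats median rpois runif setNames
NULL

new_fnb_variants <- function(sites, gt, gt_class, gq, dp, samples, meta) {
  structure(list(sites = sites, gt = gt, gt_class = gt_class,
                 gq = gq, dp = dp, samples = samples, meta = meta),
            class = "fnb_variants")
}

#' Number of (decomposed) variant records
#' @param v an `fnb_variants` object.
#' @export
n_variants <- function(v) nrow(v$sites)

#' @export
print.fnb_variants <- function(x, ...) {
  cat("fnb_variants:", n_variants(x), "records,",
      length(x$samples), "samples\n")
  cat("  samples:", paste(x$samples, collapse = ", "), "\n")
  tab <- table(x$sites$variant_class)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.fnb_variants` <- function(x, i, ...) {
  new_fnb_variants(x$sites[i, , drop = FALSE],
                   x$gt[i, , drop = FALSE],
                   x$gt_class[i, , drop = FALSE],
                   x$gq[i, , drop = FALSE],
                   x$dp[i, , drop = FALSE],
                   x$samples, x$meta)
}

# Remap one decomposed ALT allele's genotypes. For allele index `a` of the
# original record: both sample alleles equal to a -> 1/1; exactly one -> 0/1;
# neither, with no missing allele -> 0/0 (other ALT alleles count as
# reference for this decomposed variant); a missing allele with no copy of
# a -> ./.; unparseable -> "."
remap_gt_for_allele <- function(gt, allele_index) {
  vapply(gt, function(g) {
    if (is.na(g) || g == "." || g == "") return("./.")
    a <- strsplit(sub(":.*$", "", g), "[/|]")[[1]]
    if (length(a) != 2L) return(".")
    is_a <- !is.na(suppressWarnings(as.integer(a))) &
      suppressWarnings(as.integer(a)) == allele_index
    n <- sum(is_a)
    if (n == 2L) return("1/1")
    if (n == 1L) return("0/1")
    if (any(a == ".")) return("./.")
    if (all(grepl("^[0-9]+$", a))) return("0/0")
    "."
  }, character(1), USE.NAMES = FALSE)
}

#' Read a multi-sample VCF into a decomposed variant table
#'
#' Reads a VCF v4.x file (plain or gzip-compressed) and returns all records
#' as biallelic variants: multiallelic records are decomposed into one
#' variant per ALT allele, with each sample's genotype re-expressed relative
#' to that allele (homozygous for the allele -> `1/1`, one copy -> `0/1`,
#' no copy and no missing allele -> `0/0`, otherwise missing). Alleles are
#' normalized by shared-prefix/suffix trimming before classification into
#' SNV / insertion / deletion / complex.
#'
#' @param path path to a VCF file with GT in FORMAT (GQ and DP used when
#'   present).
#' @param roles optional [sample_roles()]; when given, every role sample is
#'   checked against the VCF header and a configuration error naming the
#'   missing sample is raised otherwise.
#' @return an `fnb_variants` object: a `sites` data frame (chrom, pos, ref,
#'   alt, qual, variant_class, deletion_length, source record and allele
#'   index) plus per-sample matrices of re-mapped GT strings, genotype
#'   classes, GQ and DP.
#' @export
read_vcf <- function(path, roles = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(vcf@gt)[-1]
  if (!is.null(roles)) {
    need <- role_samples(roles)
    miss <- setdiff(need, samples)
    if (length(miss))
      stop("configuration error: role sample(s) not in VCF header: ",
           paste(miss, collapse = ", "))
  }
  n_rec <- nrow(fix)
  meta <- vcf@meta
  if (n_rec == 0L) {
    empty <- matrix(character(0), 0, length(samples),
                    dimnames = list(NULL, samples))
    return(new_fnb_variants(
      data.frame(chrom = character(0), pos = integer(0), id = character(0),
                 ref = character(0), alt = character(0), qual = numeric(0),
                 variant_class = character(0), deletion_length = integer(0),
                 record = integer(0), allele_index = integer(0),
                 stringsAsFactors = FALSE),
      empty, empty,
      matrix(numeric(0), 0, length(samples), dimnames = list(NULL, samples)),
      matrix(numeric(0), 0, length(samples), dimnames = list(NULL, samples)),
      samples, meta))
  }

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  gq_raw <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  dp_raw <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  if (is.null(gt_raw)) stop("parse error: VCF has no GT in FORMAT")
  fix_mat <- function(m) {
    if (is.null(m)) m <- matrix(NA_real_, n_rec, length(samples))
    if (is.null(dim(m))) m <- matrix(m, nrow = n_rec)
    colnames(m) <- samples
    m
  }
  gt_raw <- fix_mat(gt_raw); gq_raw <- fix_mat(gq_raw); dp_raw <- fix_mat(dp_raw)

  alts <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rec_idx <- rep(seq_len(n_rec), n_alt)
  allele_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)

  ref0 <- as.character(fix[rec_idx, "REF"])
  alt0 <- unlist(alts, use.names = FALSE)
  pos0 <- as.integer(fix[rec_idx, "POS"])
  norm <- normalize_alleles(ref0, alt0, pos0)
  vclass <- classify_variant(norm$ref, norm$alt)
  dlen <- ifelse(vclass == "DELETION", nchar(norm$ref) - nchar(norm$alt), NA_integer_)

  n_out <- length(rec_idx)
  gt <- matrix("", n_out, length(samples), dimnames = list(NULL, samples))
  for (i in seq_len(n_out)) {
    r <- rec_idx[i]
    if (n_alt[r] == 1L) {
      g <- gt_raw[r, ]
      g[is.na(g)] <- "./."
      g <- gsub("|", "/", g, fixed = TRUE)
      gt[i, ] <- g
    } else {
      gt[i, ] <- remap_gt_for_allele(gt_raw[r, ], allele_idx[i])
    }
  }
  gt_class <- matrix(classify_genotype(gt), n_out, length(samples),
                     dimnames = list(NULL, samples))

  qual <- suppressWarnings(as.numeric(fix[rec_idx, "QUAL"]))
  sites <- data.frame(
    chrom = as.character(fix[rec_idx, "CHROM"]),
    pos = norm$pos,
    id = ifelse(is.na(fix[rec_idx, "ID"]), ".", as.character(fix[rec_idx, "ID"])),
    ref = norm$ref, alt = norm$alt, qual = qual,
    variant_class = vclass,
    deletion_length = as.integer(dlen),
    record = rec_idx, allele_index = allele_idx,
    stringsAsFactors = FALSE)

  new_fnb_variants(sites, gt, gt_class,
                   gq_raw[rec_idx, , drop = FALSE],
                   dp_raw[rec_idx, , drop = FALSE],
                   samples, meta)
}

#' Test which variants are deletions
#' @param v an `fnb_variants` object.
#' @return logical vector, one element per record.
#' @export
is_deletion <- function(v) v$sites$variant_class == "DELETION"

#' Deleted genomic interval of deletion records
#'
#' Under the VCF anchor-base convention the bases actually removed by a
#' deletion at anchored position `pos` with length `L` occupy the 1-based
#' inclusive interval `[pos + 1, pos + L]`; the anchor base itself is not
#' deleted.
#'
#' @param v an `fnb_variants` object (non-deletion rows yield NA).
#' @return data frame with chrom, start, end (1-based inclusive).
#' @export
deleted_interval <- function(v) {
  s <- v$sites
  del <- s$variant_class == "DELETION"
  data.frame(chrom = s$chrom,
             start = ifelse(del, s$pos + 1L, NA_integer_),
             end = ifelse(del, s$pos + s$deletion_length, NA_integer_),
             stringsAsFactors = FALSE)
}

format_vcf_number <- function(x) {
  ifelse(is.na(x), ".",
         ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
                format(x, scientific = FALSE, trim = TRUE, digits = 10)))
}

#' Write variants back to a VCF file
#'
#' Emits the (decomposed, normalized) records of an `fnb_variants` object
#' as plain-text VCF v4.2 with a `GT:GQ:DP` FORMAT. Meta header lines
#' carried over from the source file are preserved; output is deterministic
#' (no timestamps, no compression).
#'
#' @param v an `fnb_variants` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(v, path) {
  meta <- v$meta
  if (is.null(meta) || !length(meta)) meta <- "##fileformat=VCFv4.2"
  need <- c(
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">")
  for (ln in need) {
    id <- sub('^##FORMAT=<ID=([A-Z]+),.*$', "\\1", ln)
    if (!any(grepl(paste0("##FORMAT=<ID=", id, ","), meta, fixed = TRUE)))
      meta <- c(meta, ln)
  }
  s <- v$sites
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", v$samples), collapse = "\t"), con)
  if (nrow(s)) {
    fmt_one <- function(i) {
      calls <- paste(v$gt[i, ],
                     format_vcf_number(v$gq[i, ]),
                     format_vcf_number(v$dp[i, ]), sep = ":")
      paste(c(s$chrom[i], s$pos[i], s$id[i], s$ref[i], s$alt[i],
              format_vcf_number(s$qual[i]), "PASS", ".", "GT:GQ:DP", calls),
            collapse = "\t")
    }
    writeLines(vapply(seq_len(nrow(s)), fmt_one, character(1)), con)
  }
  invisible(path)
}
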