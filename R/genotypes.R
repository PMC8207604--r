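#' Classify a VCF GT string into a genotype class
#'
#' Maps raw diploid GT field values onto the five genotype classes the
#' design-pattern filter reasons about: `"0/0"` is `HOM_REF`, `"0/1"` or
#' `"1/0"` is `HET`, `"1/1"` is `HOM_ALT`, and `"./."` or `"."` is
#' `MISSING`. Phased separators (`"|"`) are treated identically to `"/"`.
#' Any genotype carrying an allele index greater than 1 — i.e. referring to
#' a second ALT allele of a multiallelic record that has not been decomposed
#' — is classed `OTHER`, as are haploid, polyploid or unparseable values.
#' A genotype with one missing and one called allele is classed `MISSING`.
#'
#' @param gt character vector of GT field values (trailing FORMAT
#'   subfields, if present, are ignored).
#' @return character vector of the same length with values in
#'   `HOM_REF`, `HET`, `HOM_ALT`, `MISSING`, `OTHER`.
#' @examples
#' classify_genotype(c("0/0", "0/1", "1|0", "1/1", "./.", "2/1"))
#' @export
classify_genotype <- function(gt) {
  gt <- as.character(gt)
  # keep only the GT subfield if a full sample column was passed
  gt <- sub(":.*$", "", gt)
  out <- rep("OTHER", length(gt))
  out[is.na(gt) | gt == "." | gt == "./." | gt == ".|."] <- "MISSING"
  todo <- which(out == "OTHER")
  if (length(todo)) {
    parts <- strsplit(gt[todo], "[/|]")
    out[todo] <- vapply(parts, function(a) {
      if (length(a) != 2L) return("OTHER")
      if (any(a == ".")) return("MISSING")
      if (!all(grepl("^[0-9]+$", a))) return("OTHER")
      ai <- as.integer(a)
      if (any(ai > 1L)) return("OTHER")
      n_alt <- sum(ai == 1L)
      c("HOM_REF", "HET", "HOM_ALT")[n_alt + 1L]
    }, character(1))
  }
  out
}

#' Normalize indel alleles by trimming shared sequence
#'
#' Applies the standard parsimony normalization used before indel
#' classification: shared trailing bases are removed first, then shared
#' leading bases (advancing `pos`), always retaining at least one base in
#' each allele so the VCF anchor-base convention is preserved. Records
#' already written in minimal anchored form are returned unchanged.
#'
#' @param ref,alt character vectors of REF and ALT alleles (equal length).
#' @param pos integer vector of 1-based VCF positions.
#' @return list with components `ref`, `alt`, `pos` after normalization.
#' @export
normalize_alleles <- function(ref, alt, pos) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  pos <- as.integer(pos)
  stopifnot(length(ref) == length(alt), length(ref) == length(pos))
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    if (is.na(r) || is.na(a) || grepl("[^ACGTN]", paste0(r, a))) next
    # trim shared suffix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # trim shared prefix, advancing pos
    while (nchar(r) > 1L && nchar(a) > 1L && substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  list(ref = ref, alt = alt, pos = pos)
}

#' Classify normalized REF/ALT allele pairs
#'
#' A variant is a `DELETION` when, after normalization, ALT is shorter than
#' REF and is a prefix of it (the anchored-deletion form); an `INSERTION`
#' when REF is a prefix of a longer ALT; an `SNV` for two single-base
#' alleles; anything else — equal-length multi-base substitutions, complex
#' indels, symbolic or non-ACGTN alleles — is `MNV_OR_COMPLEX` and is never
#' an eligible deletion candidate.
#'
#' @param ref,alt character vectors of normalized alleles.
#' @return character vector with values in `SNV`, `INSERTION`, `DELETION`,
#'   `MNV_OR_COMPLEX`.
#' @export
classify_variant <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  nr <- nchar(ref); na_ <- nchar(alt)
  out <- rep("MNV_OR_COMPLEX", length(ref))
  ok <- !is.na(ref) & !is.na(alt) &
    grepl("^[ACGTN]+$", ref) & grepl("^[ACGTN]+$", alt)
  out[ok & nr == 1L & na_ == 1L & ref != alt] <- "SNV"
  del <- ok & nr > na_ & substr(ref, 1L, na_) == alt
  out[del] <- "DELETION"
  ins <- ok & na_ > nr & substr(alt, 1L, nr) == ref
  out[ins] <- "INSERTION"
  out
}
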