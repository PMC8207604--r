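# Independent brute-force oracle for the filtering cascade: parses the VCF
# text directly and evaluates the conjunction of conditions record by
# record, sharing no code with the package implementation. Biallelic
# records only (all simulator fixtures are biallelic).
oracle_passed_keys <- function(vcf_path, mode, roles_list, thr_list) {
  lines <- readLines(vcf_path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(body[1], "\t")[[1]]
  samples <- hdr[-(1:9)]
  gt_map <- c("0/0" = "HOM_REF", "0|0" = "HOM_REF",
              "0/1" = "HET", "1/0" = "HET", "0|1" = "HET", "1|0" = "HET",
              "1/1" = "HOM_ALT", "1|1" = "HOM_ALT")
  keys <- character(0)
  for (ln in body[-1]) {
    f <- strsplit(ln, "\t")[[1]]
    chrom <- f[1]; pos <- as.integer(f[2]); ref <- f[4]; alt <- f[5]
    qual <- suppressWarnings(as.numeric(f[6]))
    fmt <- strsplit(f[9], ":")[[1]]
    get <- function(smp, key) {
      v <- strsplit(f[9 + match(smp, samples)], ":")[[1]]
      v[match(key, fmt)]
    }
    role_smps <- c(roles_list$mutant_pool, roles_list$wildtype_like_pool,
                   roles_list$wildtype_control, roles_list$irrelevant_mutants)
    ok <- !is.na(qual) && qual >= thr_list$min_site_qual
    for (s in role_smps) {
      gq <- suppressWarnings(as.numeric(get(s, "GQ")))
      dp <- suppressWarnings(as.numeric(get(s, "DP")))
      if (is.na(gq) || gq < thr_list$min_genotype_quality ||
          is.na(dp) || dp < thr_list$min_depth) ok <- FALSE
    }
    # deletion: ALT strictly shorter and a prefix of REF
    if (!(nchar(ref) > nchar(alt) &&
          substr(ref, 1, nchar(alt)) == alt)) ok <- FALSE
    if (ok) {
      cls <- function(s) {
        g <- gt_map[get(s, "GT")]
        if (is.na(g)) "OTHER_OR_MISSING" else g
      }
      if (cls(roles_list$mutant_pool) != "HOM_ALT") ok <- FALSE
      if (mode == "RECESSIVE_BSA" &&
          cls(roles_list$wildtype_like_pool) != "HET") ok <- FALSE
      if (mode == "NONRECESSIVE_F3" &&
          cls(roles_list$wildtype_like_pool) != "HOM_REF") ok <- FALSE
      if (cls(roles_list$wildtype_control) != "HOM_REF") ok <- FALSE
      for (s in roles_list$irrelevant_mutants)
        if (cls(s) != "HOM_REF") ok <- FALSE
    }
    if (ok) keys <- c(keys, paste(chrom, pos, ref, alt))
  }
  keys
}

candidate_keys <- function(filter_result) {
  s <- filter_result$candidates$sites
  if (!nrow(s)) return(character(0))
  paste(s$chrom, s$pos, s$ref, s$alt)
}
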