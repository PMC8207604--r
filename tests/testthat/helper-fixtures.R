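# In-code fixture builders: small VCF and GFF3 files written to tempdir.

# records: list of lists with chrom, pos, ref, alt, qual, gt (named chr
# vector per sample), and optional gq / dp named vectors.
write_test_vcf <- function(samples, records, path = tempfile(fileext = ".vcf")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  for (r in records) {
    gq <- r$gq %||% setNames(rep(99L, length(samples)), samples)
    dp <- r$dp %||% setNames(rep(30L, length(samples)), samples)
    calls <- paste(r$gt[samples], gq[samples], dp[samples], sep = ":")
    writeLines(paste(c(r$chrom, r$pos, ".", r$ref, r$alt,
                       r$qual %||% 1000, "PASS", ".", "GT:GQ:DP", calls),
                     collapse = "\t"), con)
  }
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

std_roles <- function(n_irr = 2, wtl = TRUE)
  sample_roles(mutant_pool = "mut", wildtype_control = "wt",
               wildtype_like_pool = if (wtl) "wtl",
               irrelevant_mutants = if (n_irr > 0) paste0("irr", seq_len(n_irr))
                                    else character())

std_samples <- function(n_irr = 2, wtl = TRUE)
  c("mut", if (wtl) "wtl", "wt", if (n_irr > 0) paste0("irr", seq_len(n_irr)))

# genotype vector helper: causal pattern for a design over std samples
pattern_gt <- function(mode, samples) {
  g <- setNames(rep("0/0", length(samples)), samples)
  g["mut"] <- "1/1"
  if (mode == "RECESSIVE_BSA") g["wtl"] <- "0/1"
  g
}

# GFF3 writer from a data.frame with chrom,source,type,start,end,strand,attrs
write_test_gff3 <- function(df, path = tempfile(fileext = ".gff3")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(paste(df$chrom, "test", df$type, df$start, df$end, ".",
                   df$strand, ".", df$attrs, sep = "\t"), con)
  path
}

# Toy single-gene annotation used by the consequence tests:
# gene 101..550, exon1 101-250 (UTR 101-150 + CDS 151-250),
# intron 251-350, exon2 351-550 (CDS 351-500 + UTR 501-550).
toy_gene_gff3 <- function(strand = "+", path = tempfile(fileext = ".gff3")) {
  utr_l <- if (strand == "+") "five_prime_UTR" else "three_prime_UTR"
  utr_r <- if (strand == "+") "three_prime_UTR" else "five_prime_UTR"
  df <- data.frame(
    chrom = "chr1", strand = strand,
    type  = c("gene", "mRNA", utr_l, "exon", "CDS", "exon", "CDS", utr_r),
    start = c(101, 101, 101, 101, 151, 351, 351, 501),
    end   = c(550, 550, 150, 250, 250, 550, 500, 550),
    attrs = c("ID=g1", "ID=g1.t1;Parent=g1",
              paste0("ID=u1;Parent=g1.t1"), "ID=e1;Parent=g1.t1",
              "ID=c1;Parent=g1.t1", "ID=e2;Parent=g1.t1",
              "ID=c2;Parent=g1.t1", "ID=u2;Parent=g1.t1"),
    stringsAsFactors = FALSE)
  write_test_gff3(df, path)
}

toy_cds_intervals <- function() rbind(c(151, 250), c(351, 500))

# build an fnb_variants with one anchored deletion at each requested
# (pos, len); ref/alt content is synthetic poly-A (irrelevant to annotation)
deletion_variants <- function(pos, len, chrom = "chr1", mode = "RECESSIVE_BSA",
                              samples = std_samples()) {
  recs <- lapply(seq_along(pos), function(i) list(
    chrom = chrom, pos = pos[i],
    ref = paste(rep("A", len[i] + 1L), collapse = ""), alt = "A",
    gt = pattern_gt(mode, samples)))
  read_vcf(write_test_vcf(samples, recs))
}
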