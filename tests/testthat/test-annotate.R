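# per-base brute-force CDS overlap for the toy gene
brute_cds_overlap <- function(dstart, dend) {
  cds <- toy_cds_intervals()
  sum(vapply(dstart:dend, function(b)
    any(b >= cds[, 1] & b <= cds[, 2]), logical(1)))
}

test_that("annotation index answers point and interval queries", {
  idx <- load_annotation(toy_gene_gff3())
  expect_equal(annotation_query(idx, "chr1", 200), "g1")
  expect_equal(annotation_query(idx, "chr1", 90, 105), "g1")
  expect_equal(annotation_query(idx, "chr1", 600), character(0))
  expect_equal(annotation_query(idx, "chr2", 200), character(0))
})

test_that("overlapping genes on opposite strands are both returned", {
  df <- data.frame(
    chrom = "chr1",
    strand = c("+", "+", "+", "+", "-", "-", "-", "-"),
    type = c("gene", "mRNA", "exon", "CDS", "gene", "mRNA", "exon", "CDS"),
    start = c(100, 100, 100, 100, 250, 250, 250, 250),
    end = c(400, 400, 400, 400, 700, 700, 700, 700),
    attrs = c("ID=gA", "ID=gA.t;Parent=gA", "ID=eA;Parent=gA.t",
              "ID=cA;Parent=gA.t", "ID=gB", "ID=gB.t;Parent=gB",
              "ID=eB;Parent=gB.t", "ID=cB;Parent=gB.t"),
    stringsAsFactors = FALSE)
  idx <- load_annotation(write_test_gff3(df))
  # brute-force interval scan over both gene spans
  spans <- data.frame(id = c("gA", "gB"), start = c(100, 250), end = c(400, 700))
  for (q in list(c(300, 300), c(120, 500), c(450, 460))) {
    brute <- spans$id[spans$start <= q[2] & spans$end >= q[1]]
    expect_setequal(annotation_query(idx, "chr1", q[1], q[2]), brute)
  }
})

test_that("frameshift calls equal the mod-3 oracle at every offset and length", {
  idx <- load_annotation(toy_gene_gff3())
  # deletions of length 1..30 starting at every position across the gene
  cases <- expand.grid(start = seq(95, 560, by = 1), len = 1:30)
  pos <- cases$start - 1L  # VCF anchor
  v <- deletion_variants(pos, cases$len)
  calls <- classify_deletions(v, idx)
  expect_equal(nrow(calls), nrow(cases))
  ov <- mapply(brute_cds_overlap, cases$start, cases$start + cases$len - 1L)
  expect_equal(calls$cds_bases_deleted, unname(as.integer(ov)))
  expect_true(all(calls$cds_bases_deleted <= calls$length))
  whole <- cases$start <= 151 & (cases$start + cases$len - 1L) >= 500
  exp_eff <- ifelse(whole, "WHOLE_OR_PARTIAL_GENE_LOSS",
             ifelse(ov > 0 & ov %% 3 != 0, "FRAMESHIFT",
             ifelse(ov > 0, "IN_FRAME_DELETION", "NONCODING")))
  expect_equal(calls$effect, unname(exp_eff))
})

test_that("worked deletion lengths: 1 and 7 bp shift the frame, 3 bp does not", {
  idx <- load_annotation(toy_gene_gff3())
  # wholly inside the second exon's CDS (351..500)
  v <- deletion_variants(pos = c(399, 399, 399), len = c(1L, 7L, 3L))
  calls <- classify_deletions(v, idx)
  expect_equal(calls$effect,
               c("FRAMESHIFT", "FRAMESHIFT", "IN_FRAME_DELETION"))
  expect_equal(calls$region_class, rep("CDS", 3))
  expect_equal(calls$cds_bases_deleted, c(1L, 7L, 3L))
})

test_that("classification is invariant to gene strand", {
  idx_p <- load_annotation(toy_gene_gff3(strand = "+"))
  idx_m <- load_annotation(toy_gene_gff3(strand = "-"))
  v <- deletion_variants(pos = c(110, 160, 260, 490, 510, 90),
                         len = c(5L, 7L, 10L, 20L, 6L, 600L))
  cp <- classify_deletions(v, idx_p)
  cm <- classify_deletions(v, idx_m)
  expect_equal(cp$cds_bases_deleted, cm$cds_bases_deleted)
  expect_equal(cp$effect, cm$effect)
  expect_equal(cp$region_class, cm$region_class)
})

test_that("region classes follow the deleted interval, anchor excluded", {
  idx <- load_annotation(toy_gene_gff3())
  # anchor at 150 (last UTR base): deleted bases start at 151, inside CDS
  v <- deletion_variants(pos = 150, len = 3L)
  calls <- classify_deletions(v, idx)
  expect_equal(calls$region_class, "CDS")
  expect_equal(calls$cds_bases_deleted, 3L)
  # wholly within the 5' UTR
  v <- deletion_variants(pos = 109, len = 5L)
  calls <- classify_deletions(v, idx)
  expect_equal(calls$region_class, "UTR")
  expect_equal(calls$effect, "NONCODING")
  # intron only
  v <- deletion_variants(pos = 259, len = 10L)
  expect_equal(classify_deletions(v, idx)$region_class, "INTRONIC")
  # intergenic
  v <- deletion_variants(pos = 700, len = 10L)
  calls <- classify_deletions(v, idx)
  expect_equal(calls$region_class, "INTERGENIC")
  expect_equal(calls$gene_ids, "")
  # spanning UTR and CDS: mixed, most severe coding effect retained
  v <- deletion_variants(pos = 145, len = 10L)  # deletes 146..155
  calls <- classify_deletions(v, idx)
  expect_equal(calls$region_class, "MIXED")
  expect_equal(calls$cds_bases_deleted, 5L)
  expect_equal(calls$effect, "FRAMESHIFT")
})

test_that("a deletion containing the entire CDS set is whole-gene loss", {
  idx <- load_annotation(toy_gene_gff3())
  v <- deletion_variants(pos = 100, len = 450L)  # deletes 101..550
  calls <- classify_deletions(v, idx)
  expect_equal(calls$effect, "WHOLE_OR_PARTIAL_GENE_LOSS")
  expect_equal(calls$cds_bases_deleted, 250L)
})

test_that("prioritization ranks coding damage first, ties in genomic order", {
  idx <- load_annotation(toy_gene_gff3())
  # 16 intergenic + 2 UTR + 1 CDS frameshift, mirroring a recessive-BSA run
  pos <- c(seq(600, 900, by = 20), 109, 505, 399)
  len <- c(rep(2L, 16), 3L, 3L, 1L)
  calls <- classify_deletions(deletion_variants(pos, len), idx)
  ranked <- prioritize(calls)
  expect_equal(nrow(ranked), 19L)
  expect_equal(ranked$effect[1], "FRAMESHIFT")
  expect_equal(ranked$region_class[2:3], c("UTR", "UTR"))
  expect_true(all(ranked$region_class[4:19] == "INTERGENIC"))
  # all-intergenic input keeps genomic order
  ig <- prioritize(classify_deletions(
    deletion_variants(c(800, 640, 700), c(2L, 2L, 2L)), idx))
  expect_equal(ig$start, c(641, 701, 801))
  # coding hits on different chromosomes rank above all non-coding,
  # mutual order genomic
  df2 <- data.frame(chrom = "chr7", strand = "+",
                    type = c("gene", "mRNA", "exon", "CDS"),
                    start = 1000, end = 1900,
                    attrs = c("ID=g7", "ID=g7.t;Parent=g7",
                              "ID=e7;Parent=g7.t", "ID=c7;Parent=g7.t"))
  g <- toy_gene_gff3()
  both <- write_test_gff3(rbind(
    read.table(g, sep = "\t", skip = 1,
               col.names = c("chrom", "src", "type", "start", "end", "dot",
                             "strand", "dot2", "attrs"))[,
               c("chrom", "strand", "type", "start", "end", "attrs")], df2))
  idx2 <- load_annotation(both)
  samples <- std_samples()
  recs <- list(
    list(chrom = "chr7", pos = 1099, ref = "AA", alt = "A",
         gt = pattern_gt("RECESSIVE_BSA", samples)),
    list(chrom = "chr1", pos = 399, ref = "AA", alt = "A",
         gt = pattern_gt("RECESSIVE_BSA", samples)),
    list(chrom = "chr1", pos = 700, ref = "AA", alt = "A",
         gt = pattern_gt("RECESSIVE_BSA", samples)))
  ranked2 <- prioritize(classify_deletions(
    read_vcf(write_test_vcf(samples, recs)), idx2))
  expect_equal(ranked2$effect[1:2], c("FRAMESHIFT", "FRAMESHIFT"))
  expect_equal(ranked2$chrom[1:2], c("chr1", "chr7"))
  expect_equal(ranked2$region_class[3], "INTERGENIC")
})

test_that("the longest-CDS transcript represents a multi-mRNA gene", {
  df <- data.frame(
    chrom = "chr1", strand = "+",
    type = c("gene", "mRNA", "exon", "CDS", "mRNA", "exon", "CDS"),
    start = c(100, 100, 100, 100, 100, 100, 100),
    end = c(500, 500, 500, 220, 500, 500, 460),
    attrs = c("ID=g1", "ID=t.short;Parent=g1", "ID=es;Parent=t.short",
              "ID=cs;Parent=t.short", "ID=t.long;Parent=g1",
              "ID=el;Parent=t.long", "ID=cl;Parent=t.long"),
    stringsAsFactors = FALSE)
  idx <- load_annotation(write_test_gff3(df))
  expect_equal(unname(idx$rep_tx["g1"]), "t.long")
  # deletion at 300..305 overlaps only the long transcript's CDS
  calls <- classify_deletions(deletion_variants(299, 6L), idx)
  expect_equal(calls$cds_bases_deleted, 6L)
  expect_equal(calls$effect, "IN_FRAME_DELETION")
})

test_that("an mRNA without CDS warns and is treated as non-coding", {
  df <- data.frame(
    chrom = "chr1", strand = "+",
    type = c("gene", "mRNA", "exon"),
    start = c(100, 100, 100), end = c(300, 300, 300),
    attrs = c("ID=gnc", "ID=gnc.t;Parent=gnc", "ID=enc;Parent=gnc.t"),
    stringsAsFactors = FALSE)
  expect_warning(idx <- load_annotation(write_test_gff3(df)), "non-coding")
  calls <- classify_deletions(deletion_variants(150, 5L), idx)
  expect_equal(calls$effect, "NONCODING")
  expect_equal(calls$cds_bases_deleted, 0L)
})

test_that("a chromosome absent from the annotation classifies intergenic with warning", {
  idx <- load_annotation(toy_gene_gff3())
  v <- deletion_variants(100, 5L, chrom = "chrZ")
  expect_warning(calls <- classify_deletions(v, idx), "absent")
  expect_equal(calls$region_class, "INTERGENIC")
})
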