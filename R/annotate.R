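#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames seqlevels
NULL

REGION_CLASSES <- c("INTERGENIC", "INTRONIC", "UTR", "CDS", "MIXED")
EFFECT_CLASSES <- c("FRAMESHIFT", "IN_FRAME_DELETION", "NONCODING",
                    "WHOLE_OR_PARTIAL_GENE_LOSS")

first_attr <- function(x) vapply(x, function(v) {
  if (length(v)) as.character(v[[1]]) else NA_character_
}, character(1), USE.NAMES = FALSE)

#' Load a GFF3 gene annotation into an interval-queryable index
#'
#' Reads gene / mRNA / exon / CDS features (explicit `five_prime_UTR` /
#' `three_prime_UTR` features are used when present, otherwise UTRs are
#' derived as exonic-minus-CDS regions) and derives introns as within-gene
#' gaps between a transcript's exons. For genes with multiple mRNAs the
#' representative transcript — the one with the longest total CDS — is used
#' for consequence calling. An mRNA without CDS features triggers a warning
#' and its gene is treated as non-coding.
#'
#' @param path path to a GFF3 file (gzip accepted).
#' @return an object of class `fnb_annotation` holding `GRanges` of genes
#'   and, per representative transcript, CDS, exon, UTR and intron
#'   intervals (all 1-based inclusive, as in GFF3).
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in ", path, ": ",
                                          conditionMessage(e)))
  typ <- as.character(gr$type)
  get_id <- function(g) sub("^(gene|transcript|mrna):", "",
                            first_attr(g$ID), ignore.case = TRUE)
  get_parent <- function(g) sub("^(gene|transcript|mrna):", "",
                                first_attr(g$Parent), ignore.case = TRUE)

  genes <- gr[typ == "gene"]
  if (!length(genes)) stop("GFF3 parse error: no gene features in ", path)
  genes$gene_id <- get_id(genes)

  tx <- gr[typ %in% c("mRNA", "transcript")]
  tx_id <- get_id(tx)
  tx_gene <- get_parent(tx)

  pick <- function(types) {
    f <- gr[typ %in% types]
    if (!length(f)) return(f)
    f$tx_id <- get_parent(f)
    f[f$tx_id %in% tx_id]
  }
  cds <- pick("CDS")
  exons <- pick("exon")
  utr <- pick(c("five_prime_UTR", "three_prime_UTR",
                "five_prime_utr", "three_prime_utr"))

  cds_by_tx <- if (length(cds)) split(cds, cds$tx_id) else list()
  cds_len <- setNames(rep(0L, length(tx_id)), tx_id)
  got <- intersect(names(cds_by_tx), tx_id)
  cds_len[got] <- vapply(cds_by_tx[got], function(g) sum(width(g)), integer(1))
  no_cds <- tx_id[cds_len[tx_id] == 0L]
  if (length(no_cds))
    warning("mRNA(s) without CDS treated as non-coding: ",
            paste(no_cds, collapse = ", "))

  # representative transcript per gene: longest total CDS, ties by tx_id
  rep_tx <- character(0)
  for (g in unique(tx_gene)) {
    ids <- tx_id[tx_gene == g]
    ids <- ids[order(-cds_len[ids], ids)]
    rep_tx[g] <- ids[1]
  }

  keep_tx <- unname(rep_tx)
  sub_tx <- function(f) if (length(f)) f[f$tx_id %in% keep_tx] else f
  cds_r <- sub_tx(cds); ex_r <- sub_tx(exons); utr_r <- sub_tx(utr)
  gene_of_tx <- setNames(tx_gene, tx_id)
  add_gene <- function(f) {
    if (length(f)) f$gene_id <- unname(gene_of_tx[f$tx_id])
    f
  }
  cds_r <- add_gene(cds_r); ex_r <- add_gene(ex_r); utr_r <- add_gene(utr_r)

  # derived UTR (exon minus CDS) for transcripts lacking explicit UTR lines
  if (length(ex_r)) {
    for (t in unique(ex_r$tx_id)) {
      if (length(utr_r) && any(utr_r$tx_id == t)) next
      e <- ex_r[ex_r$tx_id == t]
      cc <- if (length(cds_r)) cds_r[cds_r$tx_id == t] else GRanges()
      if (!length(cc)) next  # non-coding: exons stay exonic, no UTR
      d <- GenomicRanges::setdiff(e, cc, ignore.strand = TRUE)
      if (length(d)) {
        d$tx_id <- t
        d$gene_id <- unname(gene_of_tx[t])
        utr_r <- if (length(utr_r)) c(utr_r, d) else d
      }
    }
  }

  # introns: gaps between exons within each representative transcript
  introns <- GRanges()
  if (length(ex_r)) {
    for (t in unique(ex_r$tx_id)) {
      e <- ex_r[ex_r$tx_id == t]
      span <- range(e, ignore.strand = TRUE)
      d <- GenomicRanges::setdiff(span, e, ignore.strand = TRUE)
      if (length(d)) {
        d$tx_id <- t
        d$gene_id <- unname(gene_of_tx[t])
        introns <- if (length(introns)) c(introns, d) else d
      }
    }
  }

  structure(list(genes = genes, cds = cds_r, exons = ex_r, utr = utr_r,
                 introns = introns, rep_tx = rep_tx,
                 all_cds = cds, tx_gene = setNames(tx_gene, tx_id)),
            class = "fnb_annotation")
}

#' @export
print.fnb_annotation <- function(x, ...) {
  cat("fnb_annotation:", length(x$genes), "genes,",
      length(x$rep_tx), "representative transcripts,",
      length(x$cds), "CDS intervals\n")
  invisible(x)
}

#' Genes overlapping a genomic interval
#'
#' @param idx an `fnb_annotation`.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive interval (point query when `end`
#'   omitted). Genes on either strand are returned.
#' @return character vector of gene IDs, in genomic order.
#' @export
annotation_query <- function(idx, chrom, start, end = start) {
  stopifnot(inherits(idx, "fnb_annotation"))
  if (!chrom %in% seqlevels(idx$genes)) return(character(0))
  q <- GRanges(chrom, IRanges(start, end))
  hits <- findOverlaps(q, idx$genes, ignore.strand = TRUE)
  g <- idx$genes[subjectHits(hits)]
  g <- g[order(start(g))]
  g$gene_id
}

severity_rank <- function(effect, region) {
  # WHOLE_OR_PARTIAL_GENE_LOSS and FRAMESHIFT share top rank; noncoding
  # calls are ranked by the best (most gene-proximal) region they touch
  ifelse(effect %in% c("WHOLE_OR_PARTIAL_GENE_LOSS", "FRAMESHIFT"), 1L,
  ifelse(effect == "IN_FRAME_DELETION", 2L,
  ifelse(region == "UTR", 3L,
  ifelse(region == "INTRONIC", 4L, 5L))))
}

# per-query aggregated overlap width between a deletion GRanges and a
# feature GRanges; returns numeric vector indexed by query
agg_overlap <- function(del, feats) {
  out <- numeric(length(del))
  if (!length(feats)) return(out)
  h <- suppressWarnings(findOverlaps(del, feats, ignore.strand = TRUE))
  if (!length(h)) return(out)
  w <- width(pintersect(del[queryHits(h)], feats[subjectHits(h)],
                        ignore.strand = TRUE))
  agg <- tapply(w, queryHits(h), sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Classify candidate deletions' genomic context and coding consequence
#'
#' For each DELETION record, the deleted interval (anchor base excluded)
#' is overlapped with the annotation. The region class follows the
#' precedence CDS > UTR > INTRONIC > INTERGENIC, with `MIXED` when the
#' deletion spans more than one class. `cds_bases_deleted` is the total
#' overlap with the representative transcript's CDS intervals; a deletion
#' removing coding sequence is a `FRAMESHIFT` when that overlap is not a
#' multiple of 3, an `IN_FRAME_DELETION` when it is, and
#' `WHOLE_OR_PARTIAL_GENE_LOSS` when the deletion contains a gene's entire
#' CDS set. Deletions spanning the CDS of several genes report every gene
#' ID, with the most severe effect retained for ranking.
#'
#' @param v an `fnb_variants` object; non-deletion records are skipped.
#' @param idx an `fnb_annotation` from [load_annotation()].
#' @return an object of class `fnb_consequences`: data frame with chrom,
#'   start, end, length, ref, alt, region_class, effect, gene_ids
#'   (comma-separated), cds_bases_deleted.
#' @export
classify_deletions <- function(v, idx) {
  stopifnot(inherits(v, "fnb_variants"), inherits(idx, "fnb_annotation"))
  keep <- which(is_deletion(v))
  iv <- deleted_interval(v)
  n <- length(keep)
  chrom <- v$sites$chrom[keep]
  dstart <- iv$start[keep]; dend <- iv$end[keep]

  region <- rep("INTERGENIC", n)
  effect <- rep("NONCODING", n)
  gene_ids <- rep("", n)
  cds_total <- integer(n)

  known <- chrom %in% seqlevels(idx$genes)
  if (any(!known))
    warning("chromosome(s) absent from annotation, classified INTERGENIC: ",
            paste(unique(chrom[!known]), collapse = ", "))

  if (any(known)) {
    ki <- which(known)
    del <- GRanges(chrom[ki], IRanges(dstart[ki], dend[ki]))

    # gene overlaps, in genomic order per query
    gh <- findOverlaps(del, idx$genes, ignore.strand = TRUE)
    ord <- order(queryHits(gh), start(idx$genes)[subjectHits(gh)])
    gq <- queryHits(gh)[ord]; gs <- subjectHits(gh)[ord]
    gid_by_q <- split(idx$genes$gene_id[gs], gq)
    gene_ids[ki[as.integer(names(gid_by_q))]] <-
      vapply(gid_by_q, paste, character(1), collapse = ",")

    # CDS overlap per (query, gene) and per query
    eff_rank <- rep(3L, length(del))        # per-query best effect rank
    eff_lab <- rep("NONCODING", length(del))
    q_cds <- numeric(length(del))
    if (length(idx$cds)) {
      ch <- findOverlaps(del, idx$cds, ignore.strand = TRUE)
      if (length(ch)) {
        w <- width(pintersect(del[queryHits(ch)], idx$cds[subjectHits(ch)],
                              ignore.strand = TRUE))
        gene_of <- idx$cds$gene_id[subjectHits(ch)]
        pair <- paste(queryHits(ch), gene_of)
        pw <- tapply(w, pair, sum)
        pq <- as.integer(sub(" .*$", "", names(pw)))
        pg <- sub("^[0-9]+ ", "", names(pw))
        agg <- tapply(as.numeric(pw), pq, sum)
        q_cds[as.integer(names(agg))] <- as.numeric(agg)
        # whole-CDS-set loss: deletion contains the gene's CDS span
        span_min <- tapply(start(idx$cds), idx$cds$gene_id, min)
        span_max <- tapply(end(idx$cds), idx$cds$gene_id, max)
        whole <- start(del)[pq] <= span_min[pg] & end(del)[pq] >= span_max[pg]
        pr <- ifelse(whole, 0L, ifelse(pw %% 3 != 0, 1L, 2L))
        plab <- c("WHOLE_OR_PARTIAL_GENE_LOSS", "FRAMESHIFT",
                  "IN_FRAME_DELETION")[pr + 1L]
        for (j in seq_along(pq)) {
          if (pr[j] < eff_rank[pq[j]]) {
            eff_rank[pq[j]] <- pr[j]
            eff_lab[pq[j]] <- plab[j]
          }
        }
      }
    }
    cds_total[ki] <- as.integer(q_cds)
    effect[ki] <- eff_lab

    utr_ov <- agg_overlap(del, idx$utr)
    int_ov <- agg_overlap(del, idx$introns)
    genic_ov <- agg_overlap(del, reduce(idx$genes, ignore.strand = TRUE))
    touched <- (q_cds > 0) + (utr_ov > 0) + (int_ov > 0) +
      (genic_ov < width(del))
    one <- ifelse(q_cds > 0, "CDS",
           ifelse(utr_ov > 0, "UTR",
           ifelse(int_ov > 0, "INTRONIC", "INTERGENIC")))
    region[ki] <- ifelse(touched > 1L, "MIXED", one)
  }

  out <- data.frame(
    chrom = chrom, start = dstart, end = dend,
    length = v$sites$deletion_length[keep],
    pos = v$sites$pos[keep],
    ref = v$sites$ref[keep], alt = v$sites$alt[keep],
    region_class = region, effect = effect, gene_ids = gene_ids,
    cds_bases_deleted = cds_total,
    severity = severity_rank(effect, region),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("fnb_consequences", "data.frame")
  out
}

#' Rank consequence calls by severity
#'
#' Stable sort: whole/partial gene loss and frameshifts first, then
#' in-frame deletions, then UTR, intronic and intergenic deletions; ties
#' broken by genomic order. Coding hits are the reportable candidates.
#'
#' @param calls an `fnb_consequences` data frame.
#' @return the same rows, reordered, with a `rank` column prepended.
#' @export
prioritize <- function(calls) {
  stopifnot(inherits(calls, "fnb_consequences"))
  ord <- order(calls$severity, calls$chrom, calls$start)
  out <- calls[ord, , drop = FALSE]
  rownames(out) <- NULL
  out <- cbind(rank = seq_len(nrow(out)), out)
  class(out) <- c("fnb_consequences", "data.frame")
  out
}
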