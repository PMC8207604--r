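#' Configuration for a synthetic FNB experiment
#'
#' Defines a complete simulated study: a random genome, non-overlapping
#' gene models, implanted causal deletions (small ones emitted as VCF
#' records, large ones as depth dropouts), background variation of the
#' kinds the filter must reject, and per-sample sequencing depth. The
#' defaults mirror a typical FNB mapping experiment: ~30x sequencing
#' depth per pool, one causal coding deletion of a few base pairs, and a
#' background of shared deletions, heterozygous calls, SNVs, insertions,
#' cohort-private deletions and low-quality records.
#'
#' @param seed integer; fully determines every output byte.
#' @param genome named integer vector of chromosome lengths in bp.
#' @param n_genes number of gene models to place.
#' @param design design mode (see [study_design()]).
#' @param n_irrelevant number of irrelevant-mutant cohort samples.
#' @param causal_deletions list of `list(target=, length=)` where target is
#'   one of `"CDS"`, `"UTR"`, `"intron"`, `"intergenic"`.
#' @param large_deletions list of `list(length=, zygosity=)` with zygosity
#'   `"hom"` or `"het"`; reflected only in the depth tracks.
#' @param background named counts:
#'   `shared_deletion` (homozygous in every sample), `het_in_mutant`,
#'   `snv`, `insertion` (both with an otherwise causal-looking pattern),
#'   `cohort_hit` (causal-looking but homozygous in one irrelevant
#'   mutant), `low_quality` (causal-looking deletion with failing QUAL).
#' @param mean_depth mean sequencing depth per sample (default 30).
#' @param window_size depth-track window in bp (default 500).
#' @return an object of class `fnb_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome = c(chr1 = 500000L),
                       n_genes = 20L,
                       design = "RECESSIVE_BSA",
                       n_irrelevant = 2L,
                       causal_deletions = list(list(target = "CDS", length = 7L)),
                       large_deletions = list(),
                       background = c(shared_deletion = 10L, het_in_mutant = 10L,
                                      snv = 15L, insertion = 5L,
                                      cohort_hit = 5L, low_quality = 5L),
                       mean_depth = 30,
                       window_size = 500L) {
  design <- match.arg(design, DESIGN_MODES)
  bg <- c(shared_deletion = 0L, het_in_mutant = 0L, snv = 0L,
          insertion = 0L, cohort_hit = 0L, low_quality = 0L)
  bg[names(background)] <- as.integer(background)
  if (bg["cohort_hit"] > 0 && n_irrelevant < 1)
    stop("cohort_hit background requires at least one irrelevant mutant")
  for (cd in causal_deletions)
    stopifnot(cd$length >= 1,
              cd$target %in% c("CDS", "UTR", "intron", "intergenic"))
  for (ld in large_deletions)
    stopifnot(ld$length >= 1, ld$zygosity %in% c("hom", "het"))
  if (n_genes > 0 && min(genome) / max(1, n_genes) < 5000)
    stop("genome too small for ", n_genes, " genes; need >= 5 kb per gene")
  samples <- c("mut_pool",
               if (design != "INDIVIDUAL") "wtl_pool",
               "wt_A17",
               if (n_irrelevant > 0) paste0("irr_", seq_len(n_irrelevant)))
  structure(list(seed = as.integer(seed), genome = genome,
                 n_genes = as.integer(n_genes), design = design,
                 n_irrelevant = as.integer(n_irrelevant),
                 causal_deletions = causal_deletions,
                 large_deletions = large_deletions,
                 background = bg, mean_depth = mean_depth,
                 window_size = as.integer(window_size),
                 samples = samples),
            class = "fnb_sim_config")
}

#' Roles object matching a simulator configuration
#' @param cfg an `fnb_sim_config`.
#' @return an [sample_roles()] object for the simulated samples.
#' @export
sim_roles <- function(cfg) {
  sample_roles(mutant_pool = "mut_pool",
               wildtype_control = "wt_A17",
               wildtype_like_pool = if (cfg$design != "INDIVIDUAL") "wtl_pool",
               irrelevant_mutants = if (cfg$n_irrelevant > 0)
                 paste0("irr_", seq_len(cfg$n_irrelevant)) else character())
}

# lay out one gene model; returns feature table in genomic coordinates
build_gene <- function(gene_id, chrom, slot_start, slot_end, strand) {
  u5 <- sample(100:200, 1)
  u3 <- sample(150:250, 1)
  k <- sample(2:3, 1)
  cds_lens <- 3L * sample(100:300, k, replace = TRUE)
  intr <- sample(200:400, k - 1, replace = TRUE)
  total <- u5 + sum(cds_lens) + sum(intr) + u3
  gs <- slot_start + sample.int(max(1L, slot_end - slot_start - total - 100L), 1)
  feats <- list(); p <- gs
  add <- function(type, s, e) {
    feats[[length(feats) + 1L]] <<- data.frame(
      type = type, start = s, end = e, stringsAsFactors = FALSE)
  }
  utr_left <- if (strand == "+") "five_prime_UTR" else "three_prime_UTR"
  utr_right <- if (strand == "+") "three_prime_UTR" else "five_prime_UTR"
  ul <- if (strand == "+") u5 else u3
  ur <- if (strand == "+") u3 else u5
  add(utr_left, p, p + ul - 1L)
  add("exon", p, p + ul + cds_lens[1] - 1L)
  add("CDS", p + ul, p + ul + cds_lens[1] - 1L)
  p <- p + ul + cds_lens[1]
  for (j in seq_len(k - 1L)) {
    p <- p + intr[j]
    if (j < k - 1L) {
      add("exon", p, p + cds_lens[j + 1] - 1L)
      add("CDS", p, p + cds_lens[j + 1] - 1L)
      p <- p + cds_lens[j + 1]
    }
  }
  add("exon", p, p + cds_lens[k] + ur - 1L)
  add("CDS", p, p + cds_lens[k] - 1L)
  add(utr_right, p + cds_lens[k], p + cds_lens[k] + ur - 1L)
  ge <- p + cds_lens[k] + ur - 1L
  list(gene_id = gene_id, chrom = chrom, strand = strand,
       start = gs, end = ge, features = do.call(rbind, feats))
}

# shift a deletion interval [s, e] leftwards while reference-equivalent
leftalign_del <- function(seq, s, e) {
  while (s > 2L && substr(seq, e, e) == substr(seq, s - 1L, s - 1L)) {
    s <- s - 1L; e <- e - 1L
  }
  c(s, e)
}

gt_line <- function(gt, gq, dp) paste0(gt, ":", gq, ":", dp)

#' Simulate a complete synthetic FNB experiment
#'
#' Writes, under `out_dir`: `genome.fa` (random uniform-composition
#' genome), `annotation.gff3` (non-overlapping gene models with
#' exon/CDS/UTR structure), `variants.vcf` (every implanted small variant
#' as a left-aligned anchored record with per-sample `GT:GQ:DP`),
#' `depth_<sample>.bed` windowed depth tracks for the mutant pool and
#' wild-type control (large deletions appear only here, as Poisson depth
#' dropouts), and `truth.json` — the machine-readable truth set recording
#' each implanted event with its expected filter stage and consequence.
#' Identical configurations produce byte-identical outputs.
#'
#' @param cfg an [sim_config()] object.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `paths` (named file paths), `truth`
#'   (the truth set as an R list), `roles`, `design`.
#' @export
simulate_experiment <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "fnb_sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  samples <- cfg$samples
  design <- study_design(cfg$design)
  roles <- sim_roles(cfg)

  ## genome
  seqs <- lapply(cfg$genome, function(len)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  names(seqs) <- names(cfg$genome)
  fa_path <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(seqs)), fa_path)

  ## gene models, round-robin over chromosomes proportional to length
  genes <- list()
  if (cfg$n_genes > 0) {
    alloc <- round(cfg$n_genes * cfg$genome / sum(cfg$genome))
    alloc[1] <- cfg$n_genes - sum(alloc[-1])
    gid <- 0L
    for (ci in seq_along(cfg$genome)) {
      ng <- alloc[ci]
      if (ng <= 0) next
      len <- cfg$genome[ci]
      bounds <- floor(seq(1L, len, length.out = ng + 1L))
      for (j in seq_len(ng)) {
        gid <- gid + 1L
        genes[[gid]] <- build_gene(sprintf("SIMG%04d", gid),
                                   names(cfg$genome)[ci],
                                   bounds[j], bounds[j + 1L] - 200L,
                                   sample(c("+", "-"), 1))
      }
    }
  }

  gff_path <- file.path(out_dir, "annotation.gff3")
  con <- file(gff_path, "w")
  writeLines("##gff-version 3", con)
  for (g in genes) {
    ln <- function(type, s, e, attrs)
      writeLines(paste(g$chrom, "fnbfind_sim", type, s, e, ".", g$strand, ".",
                       attrs, sep = "\t"), con)
    ln("gene", g$start, g$end, paste0("ID=", g$gene_id))
    tid <- paste0(g$gene_id, ".1")
    ln("mRNA", g$start, g$end, paste0("ID=", tid, ";Parent=", g$gene_id))
    f <- g$features
    for (i in seq_len(nrow(f)))
      ln(f$type[i], f$start[i], f$end[i],
         paste0("ID=", tid, ".", tolower(f$type[i]), i, ";Parent=", tid))
  }
  close(con)

  ## expected causal genotype pattern as GT strings per design
  pat <- expected_pattern(design)
  gt_of <- c(HOM_REF = "0/0", HET = "0/1", HOM_ALT = "1/1")
  causal_gt <- function() {
    g <- setNames(rep("0/0", length(samples)), samples)
    g["mut_pool"] <- "1/1"
    if (cfg$design != "INDIVIDUAL") g["wtl_pool"] <- gt_of[pat$wildtype_like_pool]
    g
  }

  used <- list()  # occupied intervals per chrom to avoid collisions
  overlaps_used <- function(ch, s, e) {
    u <- used[[ch]]
    !is.null(u) && any(s <= u$end & e >= u$start)
  }
  reserve <- function(ch, s, e) {
    used[[ch]] <<- rbind(used[[ch]],
                         data.frame(start = s - 2L, end = e + 2L))
  }

  intergenic_gap <- function(min_len) {
    # random position in a gap between genes (or gene-free chromosome)
    for (attempt in 1:200) {
      ch <- names(cfg$genome)[sample.int(length(cfg$genome), 1)]
      gs <- Filter(function(g) g$chrom == ch, genes)
      occ <- if (length(gs))
        data.frame(start = vapply(gs, `[[`, 1, "start"),
                   end = vapply(gs, `[[`, 1, "end")) else
        data.frame(start = integer(0), end = integer(0))
      occ <- occ[order(occ$start), , drop = FALSE]
      gap_s <- c(1L, occ$end + 100L)
      gap_e <- c(occ$start - 100L, cfg$genome[[ch]] - 10L)
      ok <- which(gap_e - gap_s >= min_len + 10L)
      if (!length(ok)) next
      k <- ok[sample.int(length(ok), 1)]
      s <- gap_s[k] + sample.int(gap_e[k] - gap_s[k] - min_len - 1L, 1)
      if (s < 3L) next
      if (!overlaps_used(ch, s, s + min_len)) return(list(chrom = ch, start = s))
    }
    stop("infeasible placement: no intergenic gap of ", min_len, " bp found")
  }

  events <- list()
  vcf_rows <- list()
  add_variant <- function(ch, pos, ref, alt, qual, gts, gq, dp,
                          class, expected_stage, extra = list()) {
    calls <- gt_line(gts, gq, dp)
    vcf_rows[[length(vcf_rows) + 1L]] <<- data.frame(
      chrom = ch, pos = pos, ref = ref, alt = alt, qual = qual,
      calls = paste(calls, collapse = "\t"), stringsAsFactors = FALSE)
    events[[length(events) + 1L]] <<- c(
      list(type = "small", class = class, chrom = ch, pos = pos,
           ref = ref, alt = alt,
           length = if (nchar(ref) > nchar(alt)) nchar(ref) - nchar(alt) else 0L,
           expected_stage = expected_stage),
      extra)
  }

  del_record <- function(ch, start, len) {
    # start = first deleted base (1-based); left-align, return anchored rec
    se <- leftalign_del(seqs[[ch]], start, start + len - 1L)
    s <- se[1]
    pos <- s - 1L
    ref <- substr(seqs[[ch]], pos, s + len - 1L)
    alt <- substr(seqs[[ch]], pos, pos)
    list(pos = pos, ref = ref, alt = alt, start = s, end = s + len - 1L)
  }

  dp_draw <- function() pmax(rpois(length(samples), cfg$mean_depth), 10L)

  ## causal small deletions
  feature_target <- function(target, len) {
    cand_genes <- genes[sample.int(length(genes))]
    for (g in cand_genes) {
      f <- g$features
      rows <- switch(target,
        CDS = f[f$type == "CDS", , drop = FALSE],
        UTR = f[f$type %in% c("five_prime_UTR", "three_prime_UTR"), , drop = FALSE],
        intron = NULL)
      if (target == "intron") {
        ex <- f[f$type == "exon", , drop = FALSE]
        ex <- ex[order(ex$start), ]
        if (nrow(ex) < 2) next
        rows <- data.frame(start = ex$end[-nrow(ex)] + 1L,
                           end = ex$start[-1] - 1L)
      }
      rows <- rows[rows$end - rows$start + 1L >= len + 4L, , drop = FALSE]
      if (!nrow(rows)) next
      r <- rows[sample.int(nrow(rows), 1), ]
      s <- r$start + 1L + sample.int(r$end - r$start - len - 1L, 1)
      if (overlaps_used(g$chrom, s, s + len - 1L)) next
      return(list(gene = g, chrom = g$chrom, start = s))
    }
    stop("infeasible placement: no ", target, " of >= ", len + 4L, " bp available")
  }

  for (cd in cfg$causal_deletions) {
    if (cd$target == "intergenic") {
      loc <- intergenic_gap(cd$length)
      gene_id <- ""
      exp_region <- "INTERGENIC"; exp_effect <- "NONCODING"
    } else {
      loc <- feature_target(cd$target, cd$length)
      gene_id <- loc$gene$gene_id
      exp_region <- switch(cd$target, CDS = "CDS", UTR = "UTR",
                           intron = "INTRONIC")
      exp_effect <- if (cd$target == "CDS") {
        if (cd$length %% 3 != 0) "FRAMESHIFT" else "IN_FRAME_DELETION"
      } else "NONCODING"
    }
    rec <- del_record(loc$chrom, loc$start, cd$length)
    reserve(loc$chrom, rec$start, rec$end)
    g <- causal_gt()
    add_variant(loc$chrom, rec$pos, rec$ref, rec$alt,
                qual = sample(500:2000, 1), gts = g,
                gq = rep(99L, length(samples)), dp = dp_draw(),
                class = "causal", expected_stage = "NONE",
                extra = list(start = rec$start, end = rec$end,
                             target = cd$target, gene_id = gene_id,
                             expected_region = exp_region,
                             expected_effect = exp_effect))
  }

  ## background variants
  bg_one <- function(class) {
    if (class %in% c("shared_deletion", "het_in_mutant", "cohort_hit",
                     "low_quality")) {
      len <- sample(1:18, 1)
      loc <- intergenic_gap(len)
      rec <- del_record(loc$chrom, loc$start, len)
      reserve(loc$chrom, rec$start, rec$end)
      g <- setNames(rep("0/0", length(samples)), samples)
      qual <- sample(100:2000, 1)
      stage <- switch(class,
        shared_deletion = { g[] <- "1/1"; "PATTERN" },
        het_in_mutant = { g["mut_pool"] <- "0/1"; "PATTERN" },
        cohort_hit = {
          g[names(causal_gt())] <- causal_gt()
          g[paste0("irr_", sample.int(cfg$n_irrelevant, 1))] <- "1/1"
          "COHORT"
        },
        low_quality = { g[names(causal_gt())] <- causal_gt(); qual <- 10; "QUALITY" })
      add_variant(loc$chrom, rec$pos, rec$ref, rec$alt, qual, g,
                  rep(99L, length(samples)), dp_draw(), class, stage,
                  extra = list(start = rec$start, end = rec$end))
    } else {
      loc <- intergenic_gap(8L)
      ch <- loc$chrom; pos <- loc$start
      reserve(ch, pos, pos + 8L)
      refb <- substr(seqs[[ch]], pos, pos)
      g <- causal_gt()
      if (class == "snv") {
        alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
        add_variant(ch, pos, refb, alt, sample(100:2000, 1), g,
                    rep(99L, length(samples)), dp_draw(), "snv", "CLASS")
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1),
                            replace = TRUE), collapse = "")
        add_variant(ch, pos, refb, paste0(refb, ins), sample(100:2000, 1), g,
                    rep(99L, length(samples)), dp_draw(), "insertion", "CLASS")
      }
    }
  }
  for (class in names(cfg$background))
    for (i in seq_len(cfg$background[[class]])) bg_one(class)

  ## VCF
  vcf_path <- file.path(out_dir, "variants.vcf")
  con <- file(vcf_path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##source=fnbfind_simulator",
               paste0("##contig=<ID=", names(cfg$genome), ",length=",
                      cfg$genome, ">"),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  if (length(vcf_rows)) {
    tab <- do.call(rbind, vcf_rows)
    tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
    writeLines(paste(tab$chrom, tab$pos, ".", tab$ref, tab$alt, tab$qual,
                     "PASS", ".", "GT:GQ:DP", tab$calls, sep = "\t"), con)
  }
  close(con)

  ## large deletions + depth tracks (mutant pool and wild-type control)
  large <- list()
  for (ld in cfg$large_deletions) {
    loc <- intergenic_gap(ld$length)
    reserve(loc$chrom, loc$start, loc$start + ld$length - 1L)
    large[[length(large) + 1L]] <- list(
      type = "large", chrom = loc$chrom,
      start = loc$start - 1L, end = loc$start - 1L + ld$length,  # BED coords
      length = ld$length, zygosity = ld$zygosity)
    events[[length(events) + 1L]] <- large[[length(large)]]
  }

  track_paths <- character(0)
  for (smp in c("mut_pool", "wt_A17")) {
    rows <- list()
    for (ci in seq_along(cfg$genome)) {
      ch <- names(cfg$genome)[ci]; len <- cfg$genome[[ci]]
      starts <- seq(0L, max(0L, len - 1L), by = cfg$window_size)
      ends <- pmin(starts + cfg$window_size, len)
      lam <- rep(cfg$mean_depth, length(starts))
      if (smp == "mut_pool") {
        for (ev in large) {
          if (ev$chrom != ch) next
          ov <- pmax(0L, pmin(ends, ev$end) - pmax(starts, ev$start))
          frac <- ov / (ends - starts)
          loss <- if (ev$zygosity == "hom") 1 else 0.5
          lam <- lam * (1 - frac * loss)
        }
      }
      counts <- rpois(length(starts), lam * (ends - starts))
      rows[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                               mean_depth = counts / (ends - starts))
    }
    d <- do.call(rbind, rows)
    p <- file.path(out_dir, paste0("depth_", smp, ".bed"))
    write.table(format(d, scientific = FALSE, trim = TRUE), p, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    track_paths[smp] <- p
  }

  truth <- list(seed = cfg$seed, design = cfg$design,
                genome = as.list(cfg$genome),
                window_size = cfg$window_size,
                samples = samples, events = events)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(paths = c(fasta = fa_path, gff3 = gff_path, vcf = vcf_path,
                           truth = truth_path, track_paths),
                 truth = truth, roles = roles, design = design))
}

#' Simulate a mutant/control depth-track pair
#'
#' Window-level Poisson depth simulation for the presence-absence channel
#' alone: both samples draw window read counts from Poisson(depth x
#' window), and an optional implanted deletion multiplies the mutant's
#' rate by 0 (homozygous loss) or 0.5 (heterozygous) over its span, with
#' partial windows scaled by their overlap fraction.
#'
#' @param seed integer seed.
#' @param genome_length chromosome length in bp (default 1 Mb).
#' @param window_size window width in bp (default 500).
#' @param mean_depth mean sequencing depth (default 30).
#' @param deletion optional `list(start=, length=, zygosity=)` with
#'   half-open 0-based `start` and zygosity `"hom"` or `"het"`.
#' @param chrom chromosome name.
#' @return list with `mutant` and `control` (`fnb_depth_track`) and
#'   `deletion` (the implanted event, BED coordinates, or NULL).
#' @export
simulate_depth_pair <- function(seed, genome_length = 1000000L,
                                window_size = 500L, mean_depth = 30,
                                deletion = NULL, chrom = "chr1") {
  set.seed(seed)
  starts <- seq(0L, genome_length - 1L, by = window_size)
  ends <- pmin(starts + window_size, genome_length)
  w <- ends - starts
  lam_m <- rep(mean_depth, length(starts))
  if (!is.null(deletion)) {
    dstart <- deletion$start
    dend <- deletion$start + deletion$length
    ov <- pmax(0L, pmin(ends, dend) - pmax(starts, dstart))
    loss <- if (identical(deletion$zygosity, "het")) 0.5 else 1
    lam_m <- lam_m * (1 - (ov / w) * loss)
    deletion <- list(chrom = chrom, start = dstart, end = dend,
                     zygosity = if (loss == 1) "hom" else "het")
  }
  mk <- function(lam, id) new_depth_track(id, data.frame(
    chrom = chrom, start = starts, end = ends,
    mean_depth = rpois(length(starts), lam * w) / w,
    stringsAsFactors = FALSE))
  list(mutant = mk(lam_m, "mutant"), control = mk(rep(mean_depth,
       length(starts)), "control"), deletion = deletion)
}

#' Score pipeline output against a simulation truth set
#'
#' Computes event-level precision and recall for small-deletion candidate
#' identification (exact chrom/pos/ref/alt match against the truth events
#' expected to survive all filters) and, when PAV calls are supplied,
#' window-level boundary error for each implanted large deletion.
#'
#' @param candidates an `fnb_filter_result`, or a data frame with chrom,
#'   pos, ref, alt columns describing called candidates.
#' @param truth the truth list returned by [simulate_experiment()] (or
#'   read from `truth.json`).
#' @param pav_calls optional `fnb_pav_calls` data frame.
#' @return list with `precision`, `recall`, `n_true`, `n_called`, and a
#'   `pav` data frame (one row per implanted large deletion: `recovered`,
#'   `boundary_error_windows`).
#' @export
evaluate_against_truth <- function(candidates, truth, pav_calls = NULL) {
  if (inherits(candidates, "fnb_filter_result"))
    candidates <- candidates$candidates$sites
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(candidates)))
  chroms <- names(truth$genome)
  if (nrow(candidates) && !all(candidates$chrom %in% chroms))
    stop("mismatched genomes: candidate chromosome(s) not in truth set")
  ev <- truth$events
  small <- Filter(function(e) e$type == "small", ev)
  exp_keys <- vapply(Filter(function(e) e$expected_stage == "NONE", small),
                     function(e) paste(e$chrom, e$pos, e$ref, e$alt), character(1))
  obs_keys <- if (nrow(candidates))
    paste(candidates$chrom, candidates$pos, candidates$ref, candidates$alt)
    else character(0)
  tp <- sum(obs_keys %in% exp_keys)
  precision <- if (length(obs_keys)) tp / length(obs_keys) else 1
  recall <- if (length(exp_keys)) tp / length(exp_keys) else 1

  pav <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                    recovered = logical(0), boundary_error_windows = numeric(0))
  large <- Filter(function(e) e$type == "large", ev)
  if (length(large)) {
    ws <- truth$window_size
    for (e in large) {
      be <- NA_real_; rec <- FALSE
      if (!is.null(pav_calls) && nrow(pav_calls)) {
        ov <- pav_calls$chrom == e$chrom & pav_calls$start < e$end &
          pav_calls$end > e$start
        if (any(ov)) {
          rec <- TRUE
          be <- min(pmax(abs(pav_calls$start[ov] - e$start),
                         abs(pav_calls$end[ov] - e$end)) / ws)
        }
      }
      pav <- rbind(pav, data.frame(chrom = e$chrom, start = e$start,
                                   end = e$end, recovered = rec,
                                   boundary_error_windows = be))
    }
  }
  list(precision = precision, recall = recall,
       n_true = length(exp_keys), n_called = length(obs_keys), pav = pav)
}
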