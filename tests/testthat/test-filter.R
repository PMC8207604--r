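test_that("expected genotype pattern is a pure function of the design", {
  p <- expected_pattern(study_design("RECESSIVE_BSA"))
  expect_equal(p[c("mutant_pool", "wildtype_like_pool", "wildtype_control",
                   "irrelevant_mutants")],
               list(mutant_pool = "HOM_ALT", wildtype_like_pool = "HET",
                    wildtype_control = "HOM_REF", irrelevant_mutants = "HOM_REF"))
  expect_equal(expected_pattern(study_design("NONRECESSIVE_F3"))$wildtype_like_pool,
               "HOM_REF")
  expect_true(is.na(expected_pattern(study_design("INDIVIDUAL"))$wildtype_like_pool))
})

test_that("designs with a segregating population require a wild-type-like pool", {
  roles_no_wtl <- std_roles(wtl = FALSE)
  expect_error(validate_design(study_design("RECESSIVE_BSA"), roles_no_wtl),
               "wildtype_like_pool")
  expect_error(validate_design(study_design("NONRECESSIVE_F3"), roles_no_wtl),
               "wildtype_like_pool")
  expect_true(validate_design(study_design("INDIVIDUAL"), roles_no_wtl))
  expect_error(sample_roles("s1", "s1"), "duplicated")
})

test_that("quality filter matches a brute-force predicate on all threshold boundaries", {
  samples <- std_samples(n_irr = 1)
  roles <- std_roles(n_irr = 1)
  thr <- quality_thresholds(30, 20, 5)
  # enumerate QUAL and per-sample GQ/DP around each boundary
  grid <- expand.grid(qual = c(10, 29.99, 30, 100),
                      gq_mut = c(19, 20, 99), dp_mut = c(2, 4, 5, 30),
                      gq_wt = c(19, 99), dp_wt = c(4, 30))
  recs <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    list(chrom = "chr1", pos = 100 + i * 10, ref = "AT", alt = "A",
         qual = g$qual, gt = pattern_gt("RECESSIVE_BSA", samples),
         gq = setNames(c(g$gq_mut, 99, g$gq_wt, 99), samples),
         dp = setNames(c(g$dp_mut, 30, g$dp_wt, 30), samples))
  })
  v <- read_vcf(write_test_vcf(samples, recs))
  got <- quality_filter(v, thr, roles)
  brute <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    g$qual >= 30 && g$gq_mut >= 20 && g$dp_mut >= 5 &&
      g$gq_wt >= 20 && g$dp_wt >= 5
  }, logical(1))
  expect_equal(got, brute)
})

test_that("missing QUAL/GQ/DP values fail the quality filter", {
  samples <- std_samples(n_irr = 0)
  recs <- list(
    list(chrom = "chr1", pos = 100, ref = "AT", alt = "A", qual = ".",
         gt = pattern_gt("RECESSIVE_BSA", samples)),
    list(chrom = "chr1", pos = 200, ref = "AT", alt = "A",
         gt = pattern_gt("RECESSIVE_BSA", samples),
         gq = c(mut = ".", wtl = 99, wt = 99)))
  v <- read_vcf(write_test_vcf(samples, recs))
  expect_equal(quality_filter(v, quality_thresholds(), std_roles(n_irr = 0)),
               c(FALSE, FALSE))
})

test_that("pattern matching accepts the causal pattern and stages failures", {
  samples <- std_samples()
  roles <- std_roles()
  des <- study_design("RECESSIVE_BSA")
  mk <- function(gt) read_vcf(write_test_vcf(samples, list(
    list(chrom = "chr1", pos = 100, ref = "ATT", alt = "A", gt = gt))))
  # wn-style causal site: hom in mutants, het in wild-type-like, ref in A17
  d <- matches_pattern(mk(pattern_gt("RECESSIVE_BSA", samples)), des, roles)
  expect_true(d$passed)
  expect_equal(d$failed_stage, "NONE")
  # shared with the control: present in both pools, not a candidate
  g <- pattern_gt("RECESSIVE_BSA", samples); g["wt"] <- "1/1"
  d <- matches_pattern(mk(g), des, roles)
  expect_equal(d$failed_stage, "PATTERN")
  expect_equal(d$failing_sample, "wt")
  # heterozygous mutant pool cannot be the recessive causal site
  g <- pattern_gt("RECESSIVE_BSA", samples); g["mut"] <- "0/1"
  expect_equal(matches_pattern(mk(g), des, roles)$failed_stage, "PATTERN")
  # homozygous in an irrelevant mutant: cohort background
  g <- pattern_gt("RECESSIVE_BSA", samples); g["irr2"] <- "1/1"
  d <- matches_pattern(mk(g), des, roles)
  expect_equal(d$failed_stage, "COHORT")
  expect_equal(d$failing_sample, "irr2")
})

test_that("missing genotypes never match; lenient mode relaxes cohort only", {
  samples <- std_samples()
  roles <- std_roles()
  des <- study_design("RECESSIVE_BSA")
  g <- pattern_gt("RECESSIVE_BSA", samples); g["irr1"] <- "./."
  v <- read_vcf(write_test_vcf(samples, list(
    list(chrom = "chr1", pos = 100, ref = "AT", alt = "A", gt = g))))
  expect_equal(matches_pattern(v, des, roles)$failed_stage, "COHORT")
  expect_true(matches_pattern(v, des, roles, lenient_missing = TRUE)$passed)
  # missing at a core role is never tolerated
  g2 <- pattern_gt("RECESSIVE_BSA", samples); g2["wtl"] <- "./."
  v2 <- read_vcf(write_test_vcf(samples, list(
    list(chrom = "chr1", pos = 100, ref = "AT", alt = "A", gt = g2))))
  expect_false(matches_pattern(v2, des, roles, lenient_missing = TRUE)$passed)
})

test_that("the cascade keeps exactly the pattern-matching deletions", {
  samples <- std_samples()
  roles <- std_roles()
  causal <- pattern_gt("RECESSIVE_BSA", samples)
  recs <- list(
    # three deletions carrying the causal pattern
    list(chrom = "chr1", pos = 100, ref = "AT", alt = "A", gt = causal),
    list(chrom = "chr2", pos = 500, ref = "ATTTT", alt = "A", gt = causal),
    list(chrom = "chr1", pos = 900, ref = "AGC", alt = "A", gt = causal),
    # seven background records
    list(chrom = "chr1", pos = 150, ref = "AT", alt = "A",
         gt = setNames(rep("1/1", length(samples)), samples)),      # shared
    list(chrom = "chr1", pos = 200, ref = "AT", alt = "A",
         gt = local({g <- causal; g["mut"] <- "0/1"; g})),          # het mutant
    list(chrom = "chr1", pos = 250, ref = "A", alt = "T", gt = causal),   # SNV
    list(chrom = "chr1", pos = 300, ref = "A", alt = "ATG", gt = causal), # ins
    list(chrom = "chr1", pos = 350, ref = "AT", alt = "A", qual = 5,
         gt = causal),                                              # low qual
    list(chrom = "chr1", pos = 400, ref = "AT", alt = "A",
         gt = local({g <- causal; g["irr1"] <- "1/1"; g})),         # cohort
    list(chrom = "chr1", pos = 450, ref = "AT", alt = "A",
         gt = local({g <- causal; g["wt"] <- "0/1"; g})))           # control het
  v <- read_vcf(write_test_vcf(samples, recs))
  fr <- filter_candidates(v, study_design("RECESSIVE_BSA"), roles)
  expect_equal(n_variants(fr$candidates), 3L)
  expect_setequal(candidate_keys(fr),
                  c("chr1 100 AT A", "chr2 500 ATTTT A", "chr1 900 AGC A"))
  # candidates come out in genomic order
  expect_equal(fr$candidates$sites$pos, c(100L, 900L, 500L))
  expect_equal(fr$candidates$sites$chrom, c("chr1", "chr1", "chr2"))
  # stage provenance
  d <- fr$decisions
  stage_of <- function(pos) d$failed_stage[d$pos == pos]
  expect_equal(stage_of(150), "PATTERN")
  expect_equal(stage_of(250), "CLASS")
  expect_equal(stage_of(300), "CLASS")
  expect_equal(stage_of(350), "QUALITY")
  expect_equal(stage_of(400), "COHORT")
  # partition: counts sum to input; passed and failed are disjoint
  expect_equal(sum(fr$stage_counts), n_variants(v))
  expect_equal(sum(d$passed), 3L)
  expect_true(all(d$failed_stage[d$passed] == "NONE"))
  expect_true(all(d$failed_stage[!d$passed] != "NONE"))
})

test_that("filtering is order-independent over input permutations", {
  samples <- std_samples()
  causal <- pattern_gt("RECESSIVE_BSA", samples)
  recs <- list(
    list(chrom = "chr1", pos = 700, ref = "ATG", alt = "A", gt = causal),
    list(chrom = "chr1", pos = 100, ref = "AT", alt = "A",
         gt = setNames(rep("1/1", length(samples)), samples)),
    list(chrom = "chr1", pos = 300, ref = "AC", alt = "A", gt = causal),
    list(chrom = "chr2", pos = 200, ref = "AG", alt = "A", gt = causal))
  des <- study_design("RECESSIVE_BSA")
  k1 <- candidate_keys(filter_candidates(
    read_vcf(write_test_vcf(samples, recs)), des, std_roles()))
  set.seed(4)
  for (i in 1:3) {
    k2 <- candidate_keys(filter_candidates(
      read_vcf(write_test_vcf(samples, sample(recs))), des, std_roles()))
    expect_setequal(k2, k1)
  }
  # ordered output equality, not just set equality
  expect_equal(k1, candidate_keys(filter_candidates(
    read_vcf(write_test_vcf(samples, rev(recs))), des, std_roles())))
})

test_that("a stream with no deletion-class variants yields no candidates", {
  samples <- std_samples()
  causal <- pattern_gt("RECESSIVE_BSA", samples)
  v <- read_vcf(write_test_vcf(samples, list(
    list(chrom = "chr1", pos = 100, ref = "A", alt = "T", gt = causal),
    list(chrom = "chr1", pos = 200, ref = "A", alt = "AT", gt = causal))))
  fr <- filter_candidates(v, study_design("RECESSIVE_BSA"), std_roles())
  expect_equal(n_variants(fr$candidates), 0L)
  expect_equal(unname(fr$stage_counts["CLASS"]), 2L)
})

test_that("the individual design needs only mutant and control", {
  samples <- std_samples(n_irr = 0, wtl = FALSE)
  v <- read_vcf(write_test_vcf(samples, list(
    list(chrom = "chr1", pos = 100, ref = "AT", alt = "A",
         gt = c(mut = "1/1", wt = "0/0")),
    list(chrom = "chr1", pos = 200, ref = "AT", alt = "A",
         gt = c(mut = "1/1", wt = "1/1")))))
  fr <- filter_candidates(v, study_design("INDIVIDUAL"),
                          std_roles(n_irr = 0, wtl = FALSE))
  expect_equal(candidate_keys(fr), "chr1 100 AT A")
  expect_equal(fr$decisions$failed_stage[fr$decisions$pos == 200], "PATTERN")
})
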