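# fnbfind pipeline configuration template
#
# The pipeline consumes a joint multi-sample VCF produced by an upstream
# variant caller. For reference, an upstream GATK4 HaplotypeCaller (GVCF
# mode, then joint genotyping) run compatible with this filtering used:
#   bwa mem: minimum seed length 19, band width 100, off-diagonal
#            X-dropoff 100
#   HaplotypeCaller: --base-quality-score-threshold 19
#                    --assembly-region-padding 100
#                    --max-reads-per-alignment-start 50
#                    --max-assembly-region-size 300
#                    --min-assembly-region-size 50
# fnbfind never invokes the caller itself. Aim for >= 20x sequencing depth
# per pool; ~30x is typical.

design: RECESSIVE_BSA        # RECESSIVE_BSA | NONRECESSIVE_F3 | INDIVIDUAL

roles:
  mutant_pool: mut_pool            # pooled mutant-phenotype plants
  wildtype_like_pool: wtl_pool     # omit under INDIVIDUAL
  wildtype_control: wt_A17         # the wild-type accession
  irrelevant_mutants: [irr_1, irr_2]  # independent FNB lines (may be empty)

vcf: variants.vcf            # joint-called multi-sample VCF (.vcf or .vcf.gz)
gff3: annotation.gff3        # gene annotation (gzip accepted)

thresholds:                  # site/genotype quality filter
  min_site_qual: 30
  min_genotype_quality: 20
  min_depth: 5

# optional: large-deletion (presence-absence) detection from windowed
# depth tracks; omit the section to skip the depth channel
pav:
  mutant_track: depth_mut_pool.bed     # chrom, start, end, mean_depth
  control_track: depth_wt_A17.bed
  window_size: 500
  max_mutant_ratio: 0.1
  min_control_norm_depth: 0.5
  min_windows: 2
  merge_gap_windows: 1

lenient_missing: false       # allow missing genotypes in irrelevant mutants
output_dir: fnbfind_out      # candidates.vcf, report.tsv, decisions.tsv, ...
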