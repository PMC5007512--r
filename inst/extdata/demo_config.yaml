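# Demo pipeline configuration: a small cline-structured simulation with
# planted differentiated loci, run end-to-end in well under a minute.
simulate:
  n_clusters: 3
  provinces_per_cluster: 3
  n_per_province: 15
  n_snps: 1500
  chrom_length_bp: 2.0e7
  cluster_F: 0.02
  province_F: 0.002
  seed: 41
  topology: cline
  planted_daf_loci:
    locus: [400, 1100]
    cluster: CL1
    shift: 0.3
  missing_rate: 0.001
  n_related_pairs: 1
structure:
  n_perm: 99
  seed: 2
selscan:
  cluster1: CL1
  cluster2: CL3
  n_tests: 1500
  min_snps: 5
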