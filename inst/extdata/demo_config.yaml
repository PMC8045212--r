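# Demo pipeline config: 12 case/control pairs on a three-chromosome
# subset of hg19, with planted deletion/duplication events. The chr19
# deletion covers the NLRP4 locus; the chr22 duplication covers GSTT1.
seed: 1
output_dir: cnvcohort_demo
simulate:
  chrom_sizes: hg19
  chromosomes: [chr7, chr19, chr22]
  mean_spacing: 13000
  n_pairs: 12
  noise_sd: 0.15
  events:
    - {chrom: chr19, start: 56300000, end: 56500000, direction: loss,
       shift: -1.0, freq_case: 0.25, freq_control: 0.0}
    - {chrom: chr22, start: 24300000, end: 24450000, direction: gain,
       shift: 0.58, freq_case: 0.5, freq_control: 0.25}
    - {chrom: chr7, start: 54800000, end: 55300000, direction: loss,
       shift: -1.0, freq_case: 0.1, freq_control: 0.05}
caller:
  min_probes: 3
  gain_threshold: 0.25
  loss_threshold: -0.25
cnvr:
  split_mode: false
  include_sex: false
qpcr:
  calibrator_id: CAL
  calibrator_cn: 2
  replicates: 4
  ct_noise_sd: 0.1
  outlier_ct: 0.5
association:
  covariates: [gender, age, bmi_class, bp_class, diabetes]
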