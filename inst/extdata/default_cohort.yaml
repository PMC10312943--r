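# Default synthetic-cohort generator configuration.
#
# The defaults encode the statistical structure of a large published
# pediatric-AML cohort (n = 895): category prevalences, category-conditional
# cooperating-mutation rates, HOXA/HOXB signature structure, MRD positivity,
# and risk-dependent survival. Aggregate expectations under this
# configuration match the cohort-level frequencies the categorization
# framework reports: 91.4% of samples in a defined category, 70.1% with a
# pathogenic fusion/SV, 84.6% with a pathogenic mutation, 37.5% with a
# RAS-pathway mutation (21.1% of those multi-RAS), 67.3% of FLT3-ITD and
# 56.6% of WT1-mutant samples in HOXB categories, KRAS in 22.2% of HOXA vs
# 4.2% of HOXB samples, and 74.0% of FLT3-TKD in KMT2Ar/NPM1/CBF.
# Cooperating-mutation cells not pinned by a printed frequency are
# order-of-magnitude settings (uncalibrated).
n_samples: 895
# Prevalence of each defined molecular category (sums to 0.914 with the
# 0.086 Unclassified fraction). KMT2Ar 20.2% and the CBF/NPM1/CEBPA rates
# are cohort frequencies; small-category rates follow trial-cohort counts.
category_prevalence:
  "KMT2Ar": 0.202
  "RUNX1::RUNX1T1": 0.123
  "CBFB::MYH11": 0.099
  "NUP98r": 0.080
  "NPM1": 0.076
  "CEBPA": 0.055
  "UBTF": 0.040
  "GATA1": 0.033
  "APL": 0.030
  "GLISr": 0.028
  "FET::ETS": 0.017
  "MECOM": 0.017
  "BCL11B": 0.016
  "DEK::NUP214": 0.016
  "RBM15::MRTFA": 0.014
  "KMT2A-PTD": 0.012
  "HOXr": 0.012
  "PICALM::MLLT10": 0.011
  "KAT6Ar": 0.010
  "MNX1": 0.006
  "RUNX1::RUNX1T1-like": 0.006
  "CBFB-GDXY": 0.006
  "BCR::ABL1": 0.005
unclassified_fraction: 0.086
# Unclassified composition: 21/77 rare recurrent drivers, 47/77 with only
# non-defining pathogenic alterations, 9/77 with no pathogenic alteration.
unclassified_split:
  rare: 0.27272727
  nondef: 0.61038961
  none: 0.11688312
# Fraction of rare-driver Unclassified cases whose driver is a fusion
# (remainder carry MLLT1/H3F3A/JAK2-type mutations); solved so the overall
# fusion/SV-positive fraction is 70.1%.
rare_driver_fusion_fraction: 0.4093
# GATA1 category: fraction defined by a fusion (e.g. MYB::GATA1) rather
# than a truncating mutation.
gata1_fusion_fraction: 0.10
# MECOM/BCL11B/MNX1: fraction with no SV evidence, detectable only through
# allele-specific + outlier expression.
ase_only_fraction: 0.10
# Category-conditional cooperating-mutation probabilities. `default`
# applies to every generated group (including Unclassified subgroups other
# than the alteration-free one); `overrides` encode the category
# enrichments. Calibrated rest-rates carry six decimals.
cooperating:
  flt3_itd:
    default: 0.048861
    overrides: {"NPM1": 0.45, "NUP98r": 0.45, "UBTF": 0.45,
                "KMT2A-PTD": 0.45, "DEK::NUP214": 0.45,
                "APL": 0.30, "BCL11B": 0.30}
  flt3_tkd:
    default: 0.035856
    overrides: {"KMT2Ar": 0.10, "NPM1": 0.10,
                "RUNX1::RUNX1T1": 0.10, "CBFB::MYH11": 0.10}
  flt3_other:
    default: 0.02
    overrides: {}
  wt1:
    default: 0.046849
    overrides: {"NUP98r": 0.35, "UBTF": 0.35, "BCL11B": 0.30,
                "KMT2A-PTD": 0.20, "DEK::NUP214": 0.10, "NPM1": 0.08}
  kras:
    default: 0.069688
    overrides: {"KMT2Ar": 0.222, "KAT6Ar": 0.222,
                "NPM1": 0.042, "NUP98r": 0.042, "UBTF": 0.042,
                "KMT2A-PTD": 0.042, "DEK::NUP214": 0.042}
  nras:
    default: 0.19
    overrides: {"KMT2Ar": 0.227, "KAT6Ar": 0.227, "CBFB::MYH11": 0.28,
                "NPM1": 0.193, "NUP98r": 0.193, "UBTF": 0.193,
                "KMT2A-PTD": 0.193, "DEK::NUP214": 0.193}
  ptpn11: {default: 0.07, overrides: {}}
  nf1: {default: 0.03, overrides: {}}
  cbl: {default: 0.025, overrides: {}}
  braf: {default: 0.015, overrides: {}}
  kit:
    default: 0.03
    overrides: {"RUNX1::RUNX1T1": 0.20, "CBFB::MYH11": 0.20}
  other_driver: {default: 0.491498, overrides: {}}
# A sample with exactly one RAS-pathway mutation acquires a second,
# distinct RAS-gene mutation with this probability (cooperating subclonal
# hit); solved so 21.1% of RAS-mutant samples are multi-RAS.
ras_second_hit: 0.061949
# Expression model: negative-binomial counts over the signature gene sets,
# the three ASE genes, and filler genes; full-transcriptome realism is out
# of scope.
expression:
  nb_dispersion: 0.3
  hox_mean_high: 400
  hox_mean_low: 2
  amkl_mean_high: 600
  amkl_mean_low: 3
  immature_mean_high: 500
  immature_mean_low: 5
  ase_mean_outlier: 2000
  ase_mean_base: 20
  n_filler_genes: 70
  filler_meanlog: 5.0
  filler_sdlog: 1.0
  n_silent_genes: 10
  silent_mean: 0.05
# ASE marker emission: heterozygous DNA markers with skewed RNA allele
# fractions for ASE-positive samples.
ase_markers:
  n_markers: 5
  dna_cov_base: 10
  dna_cov_lambda: 25
  rna_cov_base: 5
  rna_cov_lambda: 25
  skew_shape1: 18
  skew_shape2: 2
  negative_control_fraction: 0.05
# MRD positivity probability by risk group, and the fraction of samples
# with unknown MRD.
mrd_prob: {Low: 0.15, Intermediate: 0.30, High: 0.45}
mrd_missing: 0.03
# Exponential overall-survival hazards per stratum (events per year),
# ordered Low/MRD- (best) to High/MRD+ (worst); EFS hazard is a constant
# multiple; censoring is uniform on [0, censor_max] years.
hazards:
  "Low/MRD-": 0.03
  "Low/MRD+": 0.06
  "Intermediate/MRD-": 0.08
  "Intermediate/MRD+": 0.15
  "High/MRD-": 0.20
  "High/MRD+": 0.35
efs_hazard_multiplier: 1.6
censor_max: 7
# Non-response probability by risk group (EFS event at time 0) and the
# share of non-refractory EFS events that are relapses.
non_response_prob: {Low: 0.01, Intermediate: 0.04, High: 0.10}
relapse_share: 0.85
# Clinical covariates.
relapse_timepoint_fraction: 0.122
cnv:
  chr8_gain: 0.072
  chr7_loss: 0.039
  rb1_focal_del: 0.029
complex_karyotype:
  default: 0.08
  overrides: {"MNX1": 0.50, "HOXr": 0.50, "PICALM::MLLT10": 0.50}
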