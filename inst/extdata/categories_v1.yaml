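# Molecular category ruleset for pediatric AML, version 1.
#
# Precedence tiers:
#   tier 1 - fusion/SV-defined categories (including the three categories
#            definable by structural variant OR allele-specific + outlier
#            expression: MECOM, BCL11B, MNX1)
#   tier 2 - mutation/tandem-duplication-defined categories
#   tier 3 - expression-gated categories that apply only without a prior
#            driver and with a consistent expression signature
# Within a tier, two distinct firing categories are a ruleset defect and are
# surfaced as an error rather than silently resolved.
#
# Partner lists are user-extensible without code changes. `partners: any`
# accepts any second gene; `frames` restricts fusion reading-frame classes.
# Entries marked provisional complete the 23-category roster beyond the
# categories that are unambiguous from the primary description.
version: 1
hox_cluster_genes: [HOXA9, HOXA10, HOXA11, HOXA13, HOXB8, HOXB9]
categories:
  - name: "KMT2Ar"
    tier: 1
    fusion: {gene: KMT2A, partners: any, frames: [in_frame]}
    superfamily: HOXA
    risk_group: Intermediate
  - name: "NUP98r"
    tier: 1
    fusion: {gene: NUP98, partners: any, frames: [in_frame]}
    superfamily: HOXB
    risk_group: Intermediate
  - name: "RUNX1::RUNX1T1"
    tier: 1
    fusion_pairs: [[RUNX1, RUNX1T1]]
    superfamily: CBF
    risk_group: Low
  - name: "CBFB::MYH11"
    tier: 1
    fusion_pairs: [[CBFB, MYH11]]
    superfamily: CBF
    risk_group: Low
  - name: "DEK::NUP214"
    tier: 1
    fusion_pairs: [[DEK, NUP214]]
    superfamily: HOXB
    risk_group: Low
  - name: "APL"
    tier: 1
    fusion: {gene: RARA, partners: any, frames: [in_frame]}
    fusion_pairs: [[TBL1XR1, RARB]]
    superfamily: APL
    risk_group: Low
    provisional_risk: true
  - name: "GLISr"
    tier: 1
    fusion: {gene_set: [GLIS2, GLIS3], partners: any, frames: [in_frame, sv_other]}
    superfamily: AMKL_AEL
    risk_group: High
  - name: "FET::ETS"
    tier: 1
    fusion_pairs: [[FUS, ERG], [FUS, FEV], [FUS, FLI1],
                   [EWSR1, ERG], [EWSR1, FEV], [EWSR1, FLI1]]
    superfamily: immature
    risk_group: Intermediate
  - name: "PICALM::MLLT10"
    tier: 1
    fusion_pairs: [[PICALM, MLLT10]]
    superfamily: immature
    risk_group: High
  - name: "KAT6Ar"
    tier: 1
    fusion: {gene: KAT6A, partners: any, frames: [in_frame]}
    superfamily: HOXA
    risk_group: High
  - name: "RUNX1::RUNX1T1-like"
    tier: 1
    fusion_pairs: [[RUNX1, CBFA2T2], [RUNX1, CBFA2T3]]
    superfamily: CBF
    risk_group: Low
  - name: "RBM15::MRTFA"
    tier: 1
    fusion_pairs: [[RBM15, MRTFA]]
    superfamily: AMKL_AEL
    risk_group: Intermediate
    provisional: true
  - name: "BCR::ABL1"
    tier: 1
    fusion_pairs: [[BCR, ABL1]]
    superfamily: other
    risk_group: Intermediate
    provisional: true
  - name: "MECOM"
    tier: 1
    sv_gene: MECOM
    ase_gene: MECOM
    superfamily: other
    risk_group: High
  - name: "BCL11B"
    tier: 1
    sv_gene: BCL11B
    ase_gene: BCL11B
    superfamily: immature
    risk_group: Intermediate
  - name: "MNX1"
    tier: 1
    sv_gene: MNX1
    ase_gene: MNX1
    superfamily: AMKL_AEL
    risk_group: Low
  - name: "NPM1"
    tier: 2
    mutation: {gene: NPM1, classes: [snv, indel]}
    superfamily: HOXB
    risk_group: Low
  - name: "CEBPA"
    tier: 2
    mutation: {gene: CEBPA, classes: [snv, indel]}
    superfamily: CEBPA
    risk_group: Low
  - name: "UBTF"
    tier: 2
    mutation: {gene: UBTF, classes: [itd]}
    superfamily: HOXB
    risk_group: Intermediate
  - name: "CBFB-GDXY"
    tier: 2
    mutation: {gene: CBFB, classes: [snv, indel]}
    superfamily: CBF
    risk_group: Low
  - name: "GATA1"
    tier: 3
    mutation: {gene: GATA1, classes: [snv, indel]}
    fusion: {gene: GATA1, partners: any,
             frames: [in_frame, out_of_frame_Cterm_loss, sv_other]}
    expression_consistency: amkl
    superfamily: AMKL_AEL
    risk_group: Intermediate
  - name: "HOXr"
    tier: 3
    fusion: {gene_set: hox_cluster, partners: any, frames: [in_frame, sv_other]}
    expression_consistency: hox_any
    superfamily: AMKL_AEL
    risk_group: Intermediate
  - name: "KMT2A-PTD"
    tier: 3
    mutation: {gene: KMT2A, classes: [ptd]}
    expression_consistency: hoxb
    superfamily: HOXB
    risk_group: Intermediate
# Rare recurrent drivers: insufficient to define a category, but recognized
# when characterizing Unclassified cases.
rare_drivers:
  fusions: [[RUNX1, USP42], [RUNX1, EVX1], [RUNX1, ZEB2],
            [MLLT10, DDX3X], [MLLT10, TEC], [MLLT10, MAP2K2],
            [SET, NUP214], [SFPQ, ZFP36L2]]
  mutations: [MLLT1, H3F3A, JAK2]
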