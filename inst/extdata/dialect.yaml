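# Default code dialect for coded autopsy/clinical CSV tables.
#
# Each entry under `columns` maps one typed field of the cohort to a coded
# CSV column.  Types:
#   code      categorical; `codes` maps each CSV code to a value, `blank`
#             is the value used for an empty cell (null means NA)
#   flag      0/1 -> FALSE/TRUE, blank -> FALSE
#   numeric   parsed as a number, blank -> NA
#   character kept as text, blank -> NA
#
# Convention: 0 = absent/No, 1 = present/Yes, 8 or blank = not assessed.
# Every mapping here is editable; unrecognized codes fail loudly at parse
# time rather than being silently coerced.
columns:
  participant_id: {column: NACCID, type: character}
  center_id:      {column: NACCADC, type: character}
  year_of_death:  {column: NACCYOD, type: numeric}

  tdp_spinal_cord:
    {column: NPTDPA, type: code, blank: not_assessed,
     codes: {"0": absent, "1": present, "8": not_assessed}}
  tdp_amygdala:
    {column: NPTDPB, type: code, blank: not_assessed,
     codes: {"0": absent, "1": present, "8": not_assessed}}
  tdp_hippocampus:
    {column: NPTDPC, type: code, blank: not_assessed,
     codes: {"0": absent, "1": present, "8": not_assessed}}
  tdp_ec_itc:
    {column: NPTDPD, type: code, blank: not_assessed,
     codes: {"0": absent, "1": present, "8": not_assessed}}
  tdp_neocortex:
    {column: NPTDPE, type: code, blank: not_assessed,
     codes: {"0": absent, "1": present, "8": not_assessed}}

  ftld_tdp:
    {column: NPFTDTDP, type: code, blank: not_assessed,
     codes: {"0": absent, "1": present, "8": not_assessed}}
  mn_inclusion:
    {column: NPALSMND, type: code, blank: not_assessed,
     codes: {"0": none, "1": tdp43, "2": fus, "3": sod1, "4": other,
             "8": not_assessed}}
  hs_a:
    {column: NPHIPSCL, type: code, blank: not_assessed,
     codes: {"0": absent, "1": unilateral, "2": bilateral,
             "3": laterality_unknown, "8": not_assessed}}
  tdp_antibody:
    {column: NPTDPAN, type: code, blank: not_listed,
     codes: {"1": phospho, "2": non_phospho, "3": other, "8": not_listed}}

  ftld_tau:
    {column: NPFTDTAU, type: code, blank: not_assessed,
     codes: {"0": absent, "1": present, "8": not_assessed}}
  adnc:
    {column: NPADNC, type: code, blank: not_assessed,
     codes: {"0": none_low, "1": int_high, "8": not_assessed}}
  caa:
    {column: NPAMY, type: code, blank: not_assessed,
     codes: {"0": none_mild, "1": mod_severe, "8": not_assessed}}
  lewy_any:
    {column: NPLBOD, type: code, blank: not_assessed,
     codes: {"0": absent, "1": present, "8": not_assessed}}
  atherosclerosis:
    {column: NPART, type: code, blank: not_assessed,
     codes: {"0": none_mild, "1": mod_severe, "8": not_assessed}}
  arteriolosclerosis:
    {column: NPARTER, type: code, blank: not_assessed,
     codes: {"0": none_mild, "1": mod_severe, "8": not_assessed}}
  infarcts:
    {column: NPINF, type: code, blank: not_assessed,
     codes: {"0": absent, "1": present, "8": not_assessed}}
  microinfarcts:
    {column: NPMICRO, type: code, blank: not_assessed,
     codes: {"0": absent, "1": present, "8": not_assessed}}
  hemorrhages:
    {column: NPHEM, type: code, blank: not_assessed,
     codes: {"0": absent, "1": present, "8": not_assessed}}
  hipp_atrophy:
    {column: NPHIPATR, type: code, blank: not_assessed,
     codes: {"0": none_mild, "1": mod_severe, "8": not_assessed}}
  cortical_atrophy:
    {column: NPCORTATR, type: code, blank: not_assessed,
     codes: {"0": none_mild, "1": mod_severe, "8": not_assessed}}
  lobar_atrophy:
    {column: NPLOBATR, type: code, blank: not_assessed,
     codes: {"0": absent, "1": present, "8": not_assessed}}

  cbd:         {column: NPCBD,      type: flag}
  cte:         {column: NPCTE,      type: flag}
  tbi_acute:   {column: NPTBIACUTE, type: flag}
  tbi_chronic: {column: NPTBICHRON, type: flag}
  huntington:  {column: NPHUNT,     type: flag}
  guam_kii:    {column: NPGUAM,     type: flag}

  age_at_death: {column: NACCDAGE, type: numeric}
  sex:
    {column: SEX, type: code, blank: null,
     codes: {"1": male, "2": female}}
  education: {column: EDUC, type: numeric}
  interval_visit_death: {column: INTERVAL, type: numeric}
  apoe4:
    {column: APOE4, type: code, blank: missing,
     codes: {"0": absent, "1": present, "8": missing, "9": missing}}
  ftd_mutation:
    {column: FTDMUT, type: code, blank: no_unknown,
     codes: {"0": no_unknown, "1": "yes"}}
  adad_mutation:
    {column: ADADMUT, type: code, blank: no_unknown,
     codes: {"0": no_unknown, "1": "yes"}}
  cognitive_status:
    {column: COGSTAT, type: code, blank: null,
     codes: {"0": normal, "1": mci_impaired, "2": dementia}}
  cdr_sb: {column: CDRSB, type: numeric}
  clinical_ad:
    {column: CLINAD, type: code, blank: null,
     codes: {"0": no_impairment, "1": not_ad, "2": ad}}
  ppa:
    {column: PPA, type: code, blank: missing,
     codes: {"0": absent, "1": present, "8": missing}}
  bvftd:
    {column: BVFTD, type: code, blank: absent,
     codes: {"0": absent, "1": present}}
  etiologic_dx_raw: {column: ETDX, type: character}
  deceased:  {column: DECEASED,  type: flag}
  autopsied: {column: AUTOPSIED, type: flag}

# Raw presumptive-etiologic-diagnosis labels -> eight-way grouping.
# Unrecognized non-missing labels are an error; extend this table to admit
# additional labels.
dx_labels:
  "Alzheimer's disease": AD
  "FTLD other": FTLD
  "FTLD motor neuron disease": FTLD
  "Corticobasal degeneration": CBD_PSP
  "Primary progressive supranuclear palsy": CBD_PSP
  "Lewy body dementia": LB
  "Vascular dementia": VASCULAR
  "Other impairment": OTHER_IMPAIRED
  "No impairment": NOT_IMPAIRED
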