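# In-code fixtures: build decoded cohort tibbles with benign defaults,
# overridable per column (values recycle to n).

make_cohort <- function(n = 1, ...) {
  defaults <- list(
    participant_id = sprintf("P%05d", seq_len(n)),
    center_id = "C001",
    year_of_death = 2020,
    tdp_spinal_cord = "not_assessed",
    tdp_amygdala = "absent",
    tdp_hippocampus = "absent",
    tdp_ec_itc = "absent",
    tdp_neocortex = "absent",
    ftld_tdp = "absent",
    mn_inclusion = "none",
    hs_a = "absent",
    tdp_antibody = "phospho",
    ftld_tau = "absent",
    adnc = "none_low",
    caa = "none_mild",
    lewy_any = "absent",
    atherosclerosis = "none_mild",
    arteriolosclerosis = "none_mild",
    infarcts = "absent",
    microinfarcts = "absent",
    hemorrhages = "absent",
    hipp_atrophy = "none_mild",
    cortical_atrophy = "none_mild",
    lobar_atrophy = "absent",
    cbd = FALSE, cte = FALSE, tbi_acute = FALSE, tbi_chronic = FALSE,
    huntington = FALSE, guam_kii = FALSE,
    age_at_death = 80,
    sex = "female",
    education = 16,
    interval_visit_death = 2,
    apoe4 = "absent",
    ftd_mutation = "no_unknown",
    adad_mutation = "no_unknown",
    cognitive_status = "dementia",
    cdr_sb = 9,
    clinical_ad = "ad",
    ppa = "absent",
    bvftd = "absent",
    etiologic_dx_raw = "Alzheimer's disease",
    deceased = TRUE,
    autopsied = TRUE)
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  out <- lapply(defaults, function(v) rep_len(v, n))
  tibble::as_tibble(out)
}

# stack category-specific blocks into one cohort with fresh unique ids
bind_cohorts <- function(...) {
  out <- dplyr::bind_rows(...)
  out$participant_id <- sprintf("P%05d", seq_len(nrow(out)))
  out
}
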