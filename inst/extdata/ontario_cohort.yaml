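# Reference cohort configuration: an Ontario-style hospital birth cohort
# (births 2009-2011, infant death registrations 2010-2011).  Birthweight and
# gestational-age bin sizes and bin mortality risks reproduce the published
# provincial 2010-2011 surveillance table (counts are per the two-year
# 280,924 live-birth denominator; the generator scales them to n_births).
# Values not available from published tables are stated defaults and are
# documented as such in the methods vignette.
births_per_year: 140462
birth_years: [2009, 2011]
death_years: [2010, 2011]
birthweight_bins:
  - {label: "<500",      lo: 250,  hi: 499,  births: 375,    deaths: 331}
  - {label: "500-999",   lo: 500,  hi: 999,  births: 1150,   deaths: 363}
  - {label: "1000-1499", lo: 1000, hi: 1499, births: 1683,   deaths: 77}
  - {label: "1500-1999", lo: 1500, hi: 1999, births: 3691,   deaths: 71}
  - {label: "2000-2499", lo: 2000, hi: 2499, births: 12153,  deaths: 72}
  - {label: "2500-2999", lo: 2500, hi: 2999, births: 47132,  deaths: 114}
  - {label: "3000-3499", lo: 3000, hi: 3499, births: 104457, deaths: 126}
  - {label: ">=3500",    lo: 3500, hi: 4800, births: 110283, deaths: 109}
gestational_age_bins:
  - {label: "<25",   lo: 20, hi: 24, births: 745}
  - {label: "25-29", lo: 25, hi: 29, births: 1535}
  - {label: "30-31", lo: 30, hi: 31, births: 1324}
  - {label: "32-33", lo: 32, hi: 33, births: 2768}
  - {label: "34-36", lo: 34, hi: 36, births: 16664}
  - {label: "37-39", lo: 37, hi: 39, births: 152124}
  - {label: ">=40",  lo: 40, hi: 42, births: 105706}
# Births below both registration thresholds (< 500 g and < 20 weeks) are
# generated on top of the binned cohort; they are live births with very poor
# prognosis and no hospital birth abstract.
subthreshold_fraction: 0.0001
subthreshold_mortality: 0.93
stillbirth_fraction: 0.006
orphan_fraction: 0.02
# P(age-at-death bucket | birthweight class); buckets: <1 d, 1-6 d, 7-27 d, 28-364 d
age_at_death_model:
  "<1000":     [0.62, 0.18, 0.12, 0.08]
  "1000-2499": [0.45, 0.15, 0.18, 0.22]
  ">=2500":    [0.30, 0.10, 0.15, 0.45]
strata:
  sex_male: 0.512
  maternal_age: {"<20": 0.03, "20-24": 0.12, "25-29": 0.31, "30-34": 0.34, "35-39": 0.16, ">=40": 0.04}
  parity_nulliparous: 0.45
  plurality_multiple: 0.033
  income_quintiles: [0.2, 0.2, 0.2, 0.2, 0.2]
  regions: {East: 0.25, Central: 0.27, Toronto: 0.23, West: 0.25}
  region_letters: {East: "K", Central: "L", Toronto: "M", West: "N"}
  rural: 0.14
  hospitals_per_region: 25
  p_death_same_hospital: 0.8
  p_hospital_death_neonatal: 0.97
  p_hospital_death_postneonatal: 0.85
# Underlying-cause mixture by timing of death, and representative ICD-10
# codes sampled within each group.
cause_mix:
  neonatal:     {immaturity: 0.45, congenital: 0.25, asphyxia: 0.12, infection: 0.06, sids: 0.0, external: 0.0, other: 0.12}
  postneonatal: {immaturity: 0.03, congenital: 0.16, asphyxia: 0.0, infection: 0.15, sids: 0.25, external: 0.12, other: 0.29}
  codes:
    immaturity: [P070, P072, P073, P220, P279, P285]
    congenital: [Q000, Q213, Q249, Q616, Q909]
    asphyxia:   [P210, P219, P240, P035]
    infection:  [P360, P369, A419, B349, J189, P239]
    sids:       [R95]
    external:   [W75, W84, V031, Y07]
    other:      [R99, P969, G809]
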