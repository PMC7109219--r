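#' Cohort configuration for the synthetic registry generator
#'
#' Describes the statistical structure of a simulated provincial birth cohort:
#' how many births, over which years, the joint birthweight / gestational-age
#' distribution (coupled comonotonically so that low birthweight co-occurs
#' with low gestational age), per-bin infant mortality risks, the
#' age-at-death mixture, stillbirth and orphan-record fractions, stratum
#' distributions and the underlying-cause mixture.
#'
#' @param n_births number of true live births to generate (registration
#'   thresholds and corruption are applied later by [corrupt_and_split()]).
#' @param birth_years,death_years inclusive calendar-year ranges (length-2
#'   integer vectors); deaths are registered only if the date of death falls
#'   within `death_years`.
#' @param bw_bins data frame with columns `label`, `lo`, `hi` (grams,
#'   strictly increasing), `prop` (bin proportions summing to 1) and `mort`
#'   (per-1 infant mortality probability per bin).
#' @param ga_bins data frame with columns `label`, `lo`, `hi` (completed
#'   weeks) and `prop` (summing to 1); coupled to `bw_bins` by a shared
#'   latent risk quantile.
#' @param age_at_death_model numeric matrix, one row per birthweight class
#'   (`<1000`, `1000-2499`, `>=2500`), columns the probabilities of death at
#'   `<1 d`, `1-6 d`, `7-27 d`, `28-364 d`; rows sum to 1.
#' @param subthreshold_fraction fraction of live births below both
#'   registration thresholds (< 500 g and < 20 weeks).
#' @param subthreshold_mortality infant mortality probability for those births.
#' @param stillbirth_fraction stillbirth records generated per live birth.
#' @param orphan_fraction fraction of birth records without a linked maternal
#'   abstract (orphan records).
#' @param strata list of stratum distributions (see the shipped
#'   `ontario_cohort.yaml` for the full set of keys).
#' @param cause_mix list with `neonatal` and `postneonatal` named probability
#'   vectors over cause groups, and `codes`, a named list of ICD-10 codes per
#'   group.
#' @param seed integer seed controlling all generator randomness.
#' @return A validated object of class `cohort_config`.
#' @seealso [default_cohort_config()] for the calibrated Ontario-style
#'   defaults, [generate_cohort()].
#' @export
cohort_config <- function(n_births, birth_years, death_years, bw_bins, ga_bins,
                          age_at_death_model, subthreshold_fraction = 0,
                          subthreshold_mortality = 0.9,
                          stillbirth_fraction = 0.006,
                          orphan_fraction = 0.02,
                          strata, cause_mix, seed = 1L) {
  cfg <- structure(list(
    n_births = n_births, birth_years = as.integer(birth_years),
    death_years = as.integer(death_years), bw_bins = bw_bins,
    ga_bins = ga_bins, age_at_death_model = age_at_death_model,
    subthreshold_fraction = subthreshold_fraction,
    subthreshold_mortality = subthreshold_mortality,
    stillbirth_fraction = stillbirth_fraction,
    orphan_fraction = orphan_fraction,
    strata = strata, cause_mix = cause_mix, seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @param cfg object to validate.
#' @export
validate_cohort_config <- function(cfg) {
  if (!is.numeric(cfg$n_births) || length(cfg$n_births) != 1L ||
      is.na(cfg$n_births) || cfg$n_births < 1)
    fail_cfg("n_births", "must be a positive integer count")
  for (nm in c("birth_years", "death_years")) {
    y <- cfg[[nm]]
    if (length(y) != 2L || any(is.na(y)) || y[1] > y[2])
      fail_cfg(nm, "must be an inclusive year range c(first, last)")
  }
  for (nm in c("bw_bins", "ga_bins")) {
    b <- cfg[[nm]]
    if (!is.data.frame(b) || !all(c("label", "lo", "hi", "prop") %in% names(b)))
      fail_cfg(nm, "must be a data frame with label/lo/hi/prop columns")
    if (any(diff(b$lo) <= 0) || any(b$hi < b$lo))
      fail_cfg(nm, "bin edges must be strictly increasing")
    check_prob_vector(b$prop, paste0(nm, "$prop"))
  }
  if (!"mort" %in% names(cfg$bw_bins))
    fail_cfg("bw_bins$mort", "per-bin mortality probabilities are required")
  for (p in cfg$bw_bins$mort) check_prob(p, "bw_bins$mort")
  am <- cfg$age_at_death_model
  if (!is.matrix(am) || ncol(am) != 4L)
    fail_cfg("age_at_death_model", "must be a matrix with 4 age-bucket columns")
  for (i in seq_len(nrow(am)))
    check_prob_vector(am[i, ], sprintf("age_at_death_model[%d,]", i))
  check_prob(cfg$subthreshold_fraction, "subthreshold_fraction")
  check_prob(cfg$subthreshold_mortality, "subthreshold_mortality")
  check_prob(cfg$stillbirth_fraction, "stillbirth_fraction")
  check_prob(cfg$orphan_fraction, "orphan_fraction")
  st <- cfg$strata
  check_prob(st$sex_male, "strata$sex_male")
  check_prob_vector(unlist(st$maternal_age), "strata$maternal_age")
  check_prob(st$parity_nulliparous, "strata$parity_nulliparous")
  check_prob(st$plurality_multiple, "strata$plurality_multiple")
  check_prob_vector(unlist(st$income_quintiles), "strata$income_quintiles")
  check_prob_vector(unlist(st$regions), "strata$regions")
  check_prob(st$rural, "strata$rural")
  cm <- cfg$cause_mix
  check_prob_vector(unlist(cm$neonatal), "cause_mix$neonatal")
  check_prob_vector(unlist(cm$postneonatal), "cause_mix$postneonatal")
  if (!setequal(names(cm$neonatal), names(cm$codes)))
    fail_cfg("cause_mix$codes", "must name a code list for every cause group")
  cfg
}

#' Calibrated default cohort configuration
#'
#' Loads the shipped Ontario-style cohort calibration (births 2009-2011,
#' death registrations 2010-2011; birthweight and gestational-age bin sizes
#' and bin mortality risks from the published two-year provincial
#' surveillance table, with a 280,924 live-birth period denominator at
#' `scale = 1`).
#'
#' @param scale multiplier on the number of births; use small values (for
#'   example `0.1`) for fast runs.
#' @param seed integer generator seed.
#' @param path optional path to an alternative YAML calibration file.
#' @return A `cohort_config` object.
#' @export
default_cohort_config <- function(scale = 1, seed = 1L, path = NULL) {
  path <- path %||% system.file("extdata", "ontario_cohort.yaml",
                                package = "vitalink", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  bw <- do.call(rbind, lapply(y$birthweight_bins, as.data.frame))
  ga <- do.call(rbind, lapply(y$gestational_age_bins, as.data.frame))
  bw$prop <- bw$births / sum(bw$births)
  bw$mort <- bw$deaths / bw$births
  ga$prop <- ga$births / sum(ga$births)
  am <- do.call(rbind, y$age_at_death_model)
  colnames(am) <- c("d0", "d1_6", "d7_27", "d28_364")
  n_years <- y$birth_years[2] - y$birth_years[1] + 1L
  cohort_config(
    n_births = round(y$births_per_year * n_years * scale),
    birth_years = y$birth_years, death_years = y$death_years,
    bw_bins = bw[, c("label", "lo", "hi", "prop", "mort")],
    ga_bins = ga[, c("label", "lo", "hi", "prop")],
    age_at_death_model = am,
    subthreshold_fraction = y$subthreshold_fraction,
    subthreshold_mortality = y$subthreshold_mortality,
    stillbirth_fraction = y$stillbirth_fraction,
    orphan_fraction = y$orphan_fraction,
    strata = y$strata, cause_mix = y$cause_mix, seed = seed
  )
}

#' Field-corruption configuration
#'
#' Controls the recording artifacts that separate the generated truth from
#' the files the linkage engine sees.  Identifier blanking forces deaths into
#' the probabilistic pass; record removal creates structurally unlinkable
#' deaths mirroring the three recognised mechanisms in hospital-based birth
#' reference files: births below both registration thresholds (< 500 g and
#' < 20 weeks), births out of province or outside a hospital, and live births
#' following a late termination of pregnancy.
#'
#' @param p_identifier_missing probability the encoded identifier is absent
#'   from a death registration.
#' @param p_postal_typo probability the death-registration postal code
#'   differs from the birth record's (transcription error or address change);
#'   one character of the six is resampled.
#' @param p_dob_shift probability the recorded date of birth is shifted by
#'   one day (plus or minus one day with equal probability).
#' @param p_sex_missing probability infant sex is unstated on the death
#'   registration.
#' @param p_out_of_hospital probability that an eligible (term, >= 37 weeks)
#'   birth has no hospital birth abstract.
#' @param subthreshold_rule drop reference records with birthweight < 500 g
#'   and gestational age < 20 weeks (the registration-threshold rule).
#' @param p_late_termination probability that a death at 20-24 weeks'
#'   gestation followed a termination with no hospital birth abstract.
#' @param p_stillbirth_misclass probability a borderline-viability death's
#'   (< 1000 g) birth record is carried as a stillbirth in the reference file.
#' @param p_bwga_missing probability birthweight and gestational age are
#'   unrecorded on an otherwise present reference record.
#' @return An object of class `corruption_config`.
#' @export
corruption_config <- function(p_identifier_missing = 0.15,
                              p_postal_typo = 0.02,
                              p_dob_shift = 0.05,
                              p_sex_missing = 0.02,
                              p_out_of_hospital = 0.02,
                              subthreshold_rule = TRUE,
                              p_late_termination = 0.015,
                              p_stillbirth_misclass = 0.01,
                              p_bwga_missing = 2e-4) {
  cc <- structure(list(
    p_identifier_missing = p_identifier_missing,
    p_postal_typo = p_postal_typo, p_dob_shift = p_dob_shift,
    p_sex_missing = p_sex_missing, p_out_of_hospital = p_out_of_hospital,
    subthreshold_rule = isTRUE(subthreshold_rule),
    p_late_termination = p_late_termination,
    p_stillbirth_misclass = p_stillbirth_misclass,
    p_bwga_missing = p_bwga_missing
  ), class = "corruption_config")
  for (nm in setdiff(names(cc), "subthreshold_rule")) check_prob(cc[[nm]], nm)
  cc
}

#' Corruption settings that leave the files clean
#'
#' All corruption probabilities zero and the registration-threshold rule off:
#' every death keeps its identifier and the deterministic pass alone can
#' recover the full truth map.
#' @return A `corruption_config` with every probability 0.
#' @export
no_corruption <- function() {
  corruption_config(0, 0, 0, 0, 0, subthreshold_rule = FALSE,
                    p_late_termination = 0, p_stillbirth_misclass = 0,
                    p_bwga_missing = 0)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  births: %d (%d-%d); death registrations %d-%d\n",
              x$n_births, x$birth_years[1], x$birth_years[2],
              x$death_years[1], x$death_years[2]))
  cat(sprintf("  expected deaths per live birth: %.4f\n",
              sum(x$bw_bins$prop * x$bw_bins$mort)))
  cat(sprintf("  birthweight bins: %s\n", paste(x$bw_bins$label, collapse = ", ")))
  invisible(x)
}
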