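# Synthetic registry generator: a birth reference file, an infant death
# registration file and a ground-truth match map with the statistical
# structure the linkage and rates stages assume.

POSTAL_LETTERS <- c("A", "B", "C", "E", "G", "H", "J", "K", "L", "M",
                    "N", "P", "R", "S", "T", "V", "W", "X", "Y", "Z")

# Canadian-format postal codes (A1A 1A1) with a region-dependent first
# letter, so the forward sortation area (first three characters) is a
# meaningful partial comparator.
gen_postal <- function(first_letter, n) {
  paste0(first_letter,
         sample(0:9, n, replace = TRUE),
         sample(POSTAL_LETTERS, n, replace = TRUE), " ",
         sample(0:9, n, replace = TRUE),
         sample(POSTAL_LETTERS, n, replace = TRUE),
         sample(0:9, n, replace = TRUE))
}

sample_levels <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = unlist(probs))
}

weight_class <- function(bw) {
  ifelse(bw < 1000, "<1000", ifelse(bw < 2500, "1000-2499", ">=2500"))
}

#' Generate a synthetic birth cohort with deaths and ground truth
#'
#' Simulates `n_births` live births (plus subthreshold births and stillbirth
#' records), assigns each live birth an infant death with its birthweight
#' bin's mortality probability, gives each death an age at death from the
#' age-at-death mixture and an ICD-10 underlying cause from the cause
#' mixture, and registers deaths whose date of death falls inside the
#' configured death-registration years.  Birthweight and gestational-age
#' bins are coupled through a shared latent risk quantile, so low
#' birthweight co-occurs with short gestation and gestational-age-specific
#' mortality falls as gestation lengthens.
#'
#' @param config a [cohort_config()].
#' @return A list of class `cohort` with elements `births` (one row per
#'   birth record, including stillbirth records), `deaths` (registered infant
#'   deaths) and `truth` (data frame `death_id`, `birth_id`, `reason`).
#'   Output is deterministic given `config$seed`.
#' @export
generate_cohort <- function(config) {
  config <- validate_cohort_config(config)
  set.seed(stage_seed(config$seed, "generate_cohort"))
  n <- as.integer(config$n_births)
  st <- config$strata

  n_sub <- round(config$subthreshold_fraction * n)
  n_main <- n - n_sub

  # --- joint birthweight / gestational age via a common latent quantile ---
  u <- stats::runif(n_main)
  bw_breaks <- c(0, cumsum(config$bw_bins$prop)); bw_breaks[length(bw_breaks)] <- 1
  ga_breaks <- c(0, cumsum(config$ga_bins$prop)); ga_breaks[length(ga_breaks)] <- 1
  bw_bin <- cut(u, bw_breaks, labels = config$bw_bins$label, include.lowest = TRUE)
  ga_bin <- cut(u, ga_breaks, labels = config$ga_bins$label, include.lowest = TRUE)
  bwi <- as.integer(bw_bin); gai <- as.integer(ga_bin)
  bw <- round(config$bw_bins$lo[bwi] +
                stats::runif(n_main) * (config$bw_bins$hi[bwi] - config$bw_bins$lo[bwi]))
  ga <- config$ga_bins$lo[gai] +
    floor(stats::runif(n_main) * (config$ga_bins$hi[gai] - config$ga_bins$lo[gai] + 1))

  subthreshold <- rep(c(FALSE, TRUE), c(n_main, n_sub))
  if (n_sub > 0) {
    bw <- c(bw, round(stats::runif(n_sub, 100, 499)))
    ga <- c(ga, sample(16:19, n_sub, replace = TRUE))
  }

  # --- demographics and identifiers ---
  day0 <- as.Date(sprintf("%d-01-01", config$birth_years[1]))
  day1 <- as.Date(sprintf("%d-12-31", config$birth_years[2]))
  dob <- day0 + sample.int(as.integer(day1 - day0) + 1L, n, replace = TRUE) - 1L
  sex <- ifelse(stats::runif(n) < st$sex_male, "M", "F")
  region <- sample_levels(n, st$regions)
  first_letter <- unlist(st$region_letters)[region]
  postal <- gen_postal(first_letter, n)
  region_idx <- match(region, names(st$regions))
  hosp_per <- st$hospitals_per_region %||% 25
  hospital <- sprintf("H%03d", (region_idx - 1L) * hosp_per +
                        sample.int(hosp_per, n, replace = TRUE))
  quint <- sample(1:5, n, replace = TRUE, prob = unlist(st$income_quintiles))

  births <- data.frame(
    birth_id = sprintf("B%07d", seq_len(n)),
    encoded_id = sprintf("ENC%08d", seq_len(n)),
    dob = dob, sex = sex, place_code = hospital, postal_code = postal,
    birthweight_g = bw, ga_weeks = ga,
    maternal_age = sample_levels(n, st$maternal_age),
    parity = ifelse(stats::runif(n) < st$parity_nulliparous, "0", "1+"),
    plurality = ifelse(stats::runif(n) < st$plurality_multiple,
                       "multiple", "singleton"),
    income_quintile = quint,
    region = region,
    rural = stats::runif(n) < st$rural,
    stillbirth_flag = FALSE,
    orphan_flag = stats::runif(n) < config$orphan_fraction,
    subthreshold = subthreshold,
    stringsAsFactors = FALSE
  )

  # --- deaths: bin mortality, age-at-death mixture, place and cause ---
  p_death <- ifelse(subthreshold, config$subthreshold_mortality,
                    config$bw_bins$mort[c(bwi, rep(1L, n_sub))])
  if (n_sub > 0) p_death[(n_main + 1):n] <- config$subthreshold_mortality
  died <- stats::runif(n) < p_death

  deaths <- data.frame(); truth <- data.frame(
    death_id = character(0), birth_id = character(0), reason = character(0),
    stringsAsFactors = FALSE)
  if (any(died)) {
    db <- births[died, , drop = FALSE]
    nd <- nrow(db)
    wc <- weight_class(db$birthweight_g)
    am <- config$age_at_death_model
    bucket <- vapply(seq_len(nd), function(i)
      sample.int(4L, 1L, prob = am[wc[i], ]), integer(1))
    age <- integer(nd)
    age[bucket == 1L] <- 0L
    age[bucket == 2L] <- sample(1:6, sum(bucket == 2L), replace = TRUE)
    age[bucket == 3L] <- sample(7:27, sum(bucket == 3L), replace = TRUE)
    age[bucket == 4L] <- sample(28:364, sum(bucket == 4L), replace = TRUE)
    dod <- db$dob + age

    p_hosp <- ifelse(age < 28,
                     st$p_hospital_death_neonatal %||% 0.97,
                     st$p_hospital_death_postneonatal %||% 0.85)
    in_hosp <- stats::runif(nd) < p_hosp
    same <- stats::runif(nd) < (st$p_death_same_hospital %||% 0.8)
    ridx <- match(db$region, names(st$regions))
    other_hosp <- sprintf("H%03d", (ridx - 1L) * hosp_per +
                            sample.int(hosp_per, nd, replace = TRUE))
    place_of_death <- ifelse(in_hosp,
                             ifelse(same, db$place_code, other_hosp), "OTH")

    cm <- config$cause_mix
    grp <- character(nd)
    neo <- age < 28
    if (any(neo)) grp[neo] <- sample_levels(sum(neo), cm$neonatal)
    if (any(!neo)) grp[!neo] <- sample_levels(sum(!neo), cm$postneonatal)
    icd <- vapply(grp, function(g) {
      codes <- cm$codes[[g]]
      codes[sample.int(length(codes), 1L)]
    }, character(1))

    registered <- as.integer(format(dod, "%Y")) >= config$death_years[1] &
      as.integer(format(dod, "%Y")) <= config$death_years[2]
    keep <- which(registered)
    if (length(keep)) {
      ord <- keep[order(dod[keep], db$birth_id[keep])]
      deaths <- data.frame(
        death_id = sprintf("D%06d", seq_along(ord)),
        encoded_id = db$encoded_id[ord],
        dob = db$dob[ord], dod = dod[ord],
        place_of_death = place_of_death[ord],
        sex = db$sex[ord], postal_code = db$postal_code[ord],
        icd10_cause = unname(icd[ord]), age_days = age[ord],
        stringsAsFactors = FALSE
      )
      truth <- data.frame(death_id = deaths$death_id,
                          birth_id = db$birth_id[ord],
                          reason = NA_character_, stringsAsFactors = FALSE)
    }
  }

  # --- stillbirth records (reference-file distractors) ---
  n_still <- round(config$stillbirth_fraction * n)
  if (n_still > 0) {
    us <- stats::runif(n_still)
    sbwi <- as.integer(cut(us, bw_breaks, include.lowest = TRUE))
    sgai <- as.integer(cut(us, ga_breaks, include.lowest = TRUE))
    sregion <- sample_levels(n_still, st$regions)
    sridx <- match(sregion, names(st$regions))
    stills <- data.frame(
      birth_id = sprintf("S%07d", seq_len(n_still)),
      encoded_id = sprintf("ENS%08d", seq_len(n_still)),
      dob = day0 + sample.int(as.integer(day1 - day0) + 1L, n_still,
                              replace = TRUE) - 1L,
      sex = ifelse(stats::runif(n_still) < st$sex_male, "M", "F"),
      place_code = sprintf("H%03d", (sridx - 1L) * hosp_per +
                             sample.int(hosp_per, n_still, replace = TRUE)),
      postal_code = gen_postal(unlist(st$region_letters)[sregion], n_still),
      birthweight_g = round(config$bw_bins$lo[sbwi] +
                              stats::runif(n_still) *
                              (config$bw_bins$hi[sbwi] - config$bw_bins$lo[sbwi])),
      ga_weeks = config$ga_bins$lo[sgai] +
        floor(stats::runif(n_still) *
                (config$ga_bins$hi[sgai] - config$ga_bins$lo[sgai] + 1)),
      maternal_age = sample_levels(n_still, st$maternal_age),
      parity = ifelse(stats::runif(n_still) < st$parity_nulliparous, "0", "1+"),
      plurality = ifelse(stats::runif(n_still) < st$plurality_multiple,
                         "multiple", "singleton"),
      income_quintile = sample(1:5, n_still, replace = TRUE,
                               prob = unlist(st$income_quintiles)),
      region = sregion,
      rural = stats::runif(n_still) < st$rural,
      stillbirth_flag = TRUE, orphan_flag = FALSE, subthreshold = FALSE,
      stringsAsFactors = FALSE
    )
    births <- rbind(births, stills)
  }

  structure(list(births = births, deaths = deaths, truth = truth,
                 config = config), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>\n")
  cat(sprintf("  birth records: %d (%d stillbirth)\n", nrow(x$births),
              sum(x$births$stillbirth_flag)))
  cat(sprintf("  registered infant deaths: %d\n", nrow(x$deaths)))
  invisible(x)
}

# Resample one character of a postal code (letter -> different letter,
# digit -> different digit), preserving the format.
postal_typo <- function(codes) {
  pos <- sample(c(1:3, 5:7), length(codes), replace = TRUE)
  vapply(seq_along(codes), function(i) {
    ch <- strsplit(codes[i], "")[[1]]
    old <- ch[pos[i]]
    pool <- if (grepl("[0-9]", old)) as.character(0:9) else POSTAL_LETTERS
    ch[pos[i]] <- sample(setdiff(pool, old), 1L)
    paste(ch, collapse = "")
  }, character(1))
}

#' Apply recording artifacts and split the cohort into linkage input files
#'
#' Produces the two files the linkage engine sees.  The reference file
#' excludes sub-threshold births (< 500 g and < 20 weeks), out-of-hospital /
#' out-of-province births and late-termination births, and carries stillbirth
#' and orphan records; a small fraction of borderline-viability deaths have
#' their birth record reclassified as a stillbirth.  The death file has
#' encoded identifiers blanked and dates / postal codes / sex perturbed per
#' the corruption configuration.  The truth map is updated with `NA` plus a
#' reason code for deaths whose birth record was removed.
#'
#' @param cohort a `cohort` from [generate_cohort()], or its `births`
#'   component (in which case `deaths` and `truth` must be supplied).
#' @param corruption a [corruption_config()].
#' @param seed integer seed for the corruption randomness.
#' @param deaths,truth override components when `cohort` is a plain data frame.
#' @return A list of class `linkage_input` with `reference` (birth reference
#'   file), `deaths` (death registration file) and `truth` (with removal
#'   reasons filled in).
#' @export
corrupt_and_split <- function(cohort, corruption = corruption_config(),
                              seed = 1L, deaths = NULL, truth = NULL) {
  if (inherits(cohort, "cohort")) {
    births <- cohort$births; deaths <- cohort$deaths; truth <- cohort$truth
  } else {
    births <- cohort
    if (is.null(deaths) || is.null(truth))
      stop("supply `deaths` and `truth` when `cohort` is a data frame")
  }
  stopifnot(inherits(corruption, "corruption_config"))
  set.seed(stage_seed(seed, "corrupt_and_split"))

  removal <- rep(NA_character_, nrow(births))
  names(removal) <- births$birth_id

  if (corruption$subthreshold_rule) {
    idx <- births$birthweight_g < 500 & births$ga_weeks < 20 &
      !births$stillbirth_flag
    removal[idx] <- "subthreshold"
  }
  eligible <- is.na(removal) & !births$stillbirth_flag & births$ga_weeks >= 37
  ooh <- eligible & stats::runif(nrow(births)) < corruption$p_out_of_hospital
  removal[ooh] <- "out_of_hospital"

  # late terminations: deaths at 20-24 weeks whose birth abstract was never filed
  if (corruption$p_late_termination > 0 && nrow(truth) > 0) {
    bidx <- match(truth$birth_id, births$birth_id)
    cand <- which(!is.na(bidx) & is.na(removal[bidx]) &
                    births$ga_weeks[bidx] >= 20 & births$ga_weeks[bidx] < 25 &
                    !births$subthreshold[bidx])
    hit <- cand[stats::runif(length(cand)) < corruption$p_late_termination]
    removal[bidx[hit]] <- "late_termination"
  }

  # borderline-viability deaths carried as stillbirths in the reference file
  if (corruption$p_stillbirth_misclass > 0 && nrow(truth) > 0) {
    bidx <- match(truth$birth_id, births$birth_id)
    cand <- which(!is.na(bidx) & is.na(removal[bidx]) &
                    births$birthweight_g[bidx] < 1000)
    hit <- cand[stats::runif(length(cand)) < corruption$p_stillbirth_misclass]
    births$stillbirth_flag[bidx[hit]] <- TRUE
    truth$reason[hit] <- "stillbirth_misclassified"
  }

  reference <- births[is.na(removal), , drop = FALSE]
  reference$subthreshold <- NULL
  rownames(reference) <- NULL

  # masked birthweight / gestational age on otherwise present records
  if (corruption$p_bwga_missing > 0 && nrow(reference) > 0) {
    mask <- stats::runif(nrow(reference)) < corruption$p_bwga_missing
    reference$birthweight_g[mask] <- NA_real_
    reference$ga_weeks[mask] <- NA_real_
  }

  dth <- deaths
  if (nrow(dth) > 0) {
    blank <- stats::runif(nrow(dth)) < corruption$p_identifier_missing
    dth$encoded_id[blank] <- NA_character_
    typo <- stats::runif(nrow(dth)) < corruption$p_postal_typo
    if (any(typo)) dth$postal_code[typo] <- postal_typo(dth$postal_code[typo])
    shift <- stats::runif(nrow(dth)) < corruption$p_dob_shift
    if (any(shift))
      dth$dob[shift] <- dth$dob[shift] +
        sample(c(-1L, 1L), sum(shift), replace = TRUE)
    sexna <- stats::runif(nrow(dth)) < corruption$p_sex_missing
    dth$sex[sexna] <- "U"
  }

  if (nrow(truth) > 0) {
    gone <- removal[truth$birth_id]
    truth$reason[!is.na(gone)] <- gone[!is.na(gone)]
    truth$birth_id[!is.na(gone)] <- NA_character_
  }

  structure(list(reference = reference, deaths = dth, truth = truth),
            class = "linkage_input")
}
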