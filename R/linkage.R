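# Deterministic + Fellegi-Sunter probabilistic linkage of infant death
# registrations to a birth reference file.

# Agreement-level sets for the four linkage fields.  "missing" is a distinct
# level on any field; by convention it contributes zero weight.
FIELD_LEVELS <- list(
  dob    = c("exact", "pm1", "disagree"),
  place  = c("agree", "disagree"),
  sex    = c("agree", "disagree"),
  postal = c("exact", "fsa", "disagree")
)
LINK_FIELDS <- names(FIELD_LEVELS)

norm_postal <- function(x) toupper(gsub("[[:space:]-]", "", x))

#' Field-by-field comparison of death registrations against birth records
#'
#' Computes the agreement pattern on the four linkage fields: infant date of
#' birth (`exact` / `pm1`, one day apart / `disagree`), place of death
#' against birth place code (`agree` / `disagree`), infant sex (`agree` /
#' `disagree`) and residential postal code (`exact` / `fsa`, first three
#' characters agree / `disagree`).  A field unstated on either side yields
#' the distinct level `missing`.
#'
#' `compare_pairs()` is vectorised over aligned rows (row i of `deaths`
#' against row i of `births`); `compare_records()` compares one death to one
#' birth.
#'
#' @param deaths,births data frames with the registry columns (`dob`, `sex`,
#'   `postal_code`, and `place_of_death` / `place_code`), row-aligned.
#' @return A data frame with character columns `dob`, `place`, `sex`,
#'   `postal`, one row per pair.
#' @export
compare_pairs <- function(deaths, births) {
  n <- nrow(deaths)
  stopifnot(nrow(births) == n)
  d_dob <- as.Date(deaths$dob); b_dob <- as.Date(births$dob)
  dd <- abs(as.integer(d_dob - b_dob))
  dob <- ifelse(is.na(dd), "missing",
                ifelse(dd == 0L, "exact", ifelse(dd == 1L, "pm1", "disagree")))

  dp <- deaths$place_of_death; bp <- births$place_code
  place <- ifelse(is.na(dp) | is.na(bp), "missing",
                  ifelse(dp == bp, "agree", "disagree"))

  ds <- deaths$sex; bs <- births$sex
  ds[ds %in% "U"] <- NA; bs[bs %in% "U"] <- NA
  sex <- ifelse(is.na(ds) | is.na(bs), "missing",
                ifelse(ds == bs, "agree", "disagree"))

  dpc <- norm_postal(deaths$postal_code); bpc <- norm_postal(births$postal_code)
  dpc[!nzchar(dpc)] <- NA; bpc[!nzchar(bpc)] <- NA
  postal <- ifelse(is.na(dpc) | is.na(bpc), "missing",
                   ifelse(dpc == bpc, "exact",
                          ifelse(substr(dpc, 1, 3) == substr(bpc, 1, 3),
                                 "fsa", "disagree")))
  data.frame(dob = dob, place = place, sex = sex, postal = postal,
             stringsAsFactors = FALSE)
}

#' @rdname compare_pairs
#' @param death,birth single-row data frames (or lists) with the registry fields.
#' @export
compare_records <- function(death, birth) {
  compare_pairs(as.data.frame(death, stringsAsFactors = FALSE)[1, , drop = FALSE],
                as.data.frame(birth, stringsAsFactors = FALSE)[1, , drop = FALSE])
}

#' Deterministic identifier linkage pass
#'
#' Links each death registration to a birth record when the encoded
#' identifier is present on both sides, equal, and unique on each side.
#' Duplicate identifiers (within either file) are demoted to the residual
#' set with a warning.
#'
#' @param deaths death registration data frame.
#' @param reference birth reference data frame (may include stillbirth and
#'   orphan records).
#' @return List with `matches` (data frame `death_id`, `birth_id`, `weight`
#'   (`NA` for the deterministic stage), `stage`, `decision`) and
#'   `residual_deaths` (rows of `deaths` not linked).
#' @export
deterministic_link <- function(deaths, reference) {
  matches <- data.frame(death_id = character(0), birth_id = character(0),
                        weight = numeric(0), stage = character(0),
                        decision = character(0), stringsAsFactors = FALSE)
  if (nrow(deaths) == 0)
    return(list(matches = matches, residual_deaths = deaths))

  d_id <- deaths$encoded_id
  r_id <- reference$encoded_id
  dup_d <- unique(d_id[!is.na(d_id) & duplicated(d_id)])
  dup_r <- unique(r_id[!is.na(r_id) & duplicated(r_id)])
  if (length(dup_d))
    warning(sprintf("%d duplicate identifier(s) in the death file; affected deaths demoted to the residual set", length(dup_d)))
  if (length(dup_r))
    warning(sprintf("%d ambiguous identifier(s) in the reference file; affected deaths demoted to the residual set", length(dup_r)))

  usable <- !is.na(d_id) & !(d_id %in% c(dup_d, dup_r))
  hit <- match(d_id, r_id)
  linked <- usable & !is.na(hit)
  if (any(linked)) {
    matches <- data.frame(
      death_id = deaths$death_id[linked],
      birth_id = reference$birth_id[hit[linked]],
      weight = NA_real_, stage = "deterministic", decision = "link",
      stringsAsFactors = FALSE)
  }
  list(matches = matches,
       residual_deaths = deaths[!linked, , drop = FALSE])
}

# Candidate-pair construction for a set of residual deaths under a blocking
# scheme.  Returns a data frame of row indices into `deaths` / `reference`.
candidate_pairs <- function(deaths, reference, scheme = "dob_pm1") {
  scheme <- match.arg(scheme, c("dob_pm1", "dobyear_fsa", "none"))
  nd <- nrow(deaths); nr <- nrow(reference)
  if (nd == 0 || nr == 0)
    return(data.frame(death_idx = integer(0), birth_idx = integer(0)))
  if (scheme == "none") {
    return(data.frame(death_idx = rep(seq_len(nd), each = nr),
                      birth_idx = rep(seq_len(nr), times = nd)))
  }
  if (scheme == "dob_pm1") {
    key <- split(seq_len(nr), as.integer(as.Date(reference$dob)))
    dk <- as.integer(as.Date(deaths$dob))
    cand <- lapply(seq_len(nd), function(i)
      unlist(key[as.character((dk[i] - 1L):(dk[i] + 1L))], use.names = FALSE))
  } else {
    yr_key <- split(seq_len(nr), format(as.Date(reference$dob), "%Y"))
    fsa_key <- split(seq_len(nr), substr(norm_postal(reference$postal_code), 1, 3))
    dy <- format(as.Date(deaths$dob), "%Y")
    dfsa <- substr(norm_postal(deaths$postal_code), 1, 3)
    cand <- lapply(seq_len(nd), function(i)
      unique(c(yr_key[[dy[i]]], fsa_key[[dfsa[i]]])))
  }
  len <- lengths(cand)
  data.frame(death_idx = rep(seq_len(nd), len),
             birth_idx = unlist(cand, use.names = FALSE))
}

#' Candidate birth records for one death under a blocking scheme
#'
#' Blocking restricts the candidate pairs scored by the probabilistic pass to
#' those sharing a key.  `"dob_pm1"` blocks on date of birth within one day;
#' `"dobyear_fsa"` takes the union of same birth year and same forward
#' sortation area (first three postal characters); `"none"` returns the full
#' reference file.
#'
#' @param death single-row death data frame.
#' @param reference birth reference data frame.
#' @param scheme one of `"dob_pm1"`, `"dobyear_fsa"`, `"none"`.
#' @return The candidate rows of `reference`.
#' @export
block_candidates <- function(death, reference, scheme = "dob_pm1") {
  pr <- candidate_pairs(death[1, , drop = FALSE], reference, scheme)
  reference[pr$birth_idx, , drop = FALSE]
}

#' Fellegi-Sunter match parameters
#'
#' Container for the per-field, per-agreement-level m-probabilities
#' (probability of the level given a true match) and u-probabilities
#' (probability given a non-match), plus the prior match probability
#' `lambda` for a candidate pair.  Within each field the probabilities over
#' the informative levels sum to 1; the `missing` level is treated as
#' uninformative (identical under both classes), so it carries no parameters
#' and contributes zero weight.
#'
#' @param m,u named lists with one named numeric vector per field (`dob`,
#'   `place`, `sex`, `postal`), each over that field's levels.
#' @param lambda prior match probability in (0, 1).
#' @return Object of class `fs_params`.
#' @export
fs_params <- function(m, u, lambda) {
  for (f in LINK_FIELDS) {
    for (nm in c("m", "u")) {
      v <- (if (nm == "m") m else u)[[f]]
      if (is.null(v) || !setequal(names(v), FIELD_LEVELS[[f]]))
        fail_cfg(sprintf("%s$%s", nm, f),
                 sprintf("must be a named vector over levels {%s}",
                         paste(FIELD_LEVELS[[f]], collapse = ", ")))
      check_prob_vector(v[FIELD_LEVELS[[f]]], sprintf("%s$%s", nm, f))
    }
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda <= 0 || lambda >= 1)
    fail_cfg("lambda", "must lie strictly inside (0, 1)")
  m <- mapply(function(v, lv) v[lv], m[LINK_FIELDS], FIELD_LEVELS,
              SIMPLIFY = FALSE)
  u <- mapply(function(v, lv) v[lv], u[LINK_FIELDS], FIELD_LEVELS,
              SIMPLIFY = FALSE)
  structure(list(m = m, u = u, lambda = lambda), class = "fs_params")
}

#' @export
print.fs_params <- function(x, ...) {
  cat("<fs_params>  lambda =", signif(x$lambda, 4), "\n")
  for (f in LINK_FIELDS) {
    cat(sprintf("  %-6s m: %s\n", f,
                paste(sprintf("%s=%.4f", names(x$m[[f]]), x$m[[f]]), collapse = " ")))
    cat(sprintf("  %-6s u: %s\n", "",
                paste(sprintf("%s=%.4f", names(x$u[[f]]), x$u[[f]]), collapse = " ")))
  }
  if (!is.null(attr(x, "loglik")))
    cat(sprintf("  EM: %d iteration(s), final log-likelihood %.4f\n",
                length(attr(x, "loglik")), utils::tail(attr(x, "loglik"), 1)))
  invisible(x)
}

clamp_norm <- function(v, eps = 1e-6) {
  v <- pmin(pmax(v, eps), 1 - eps)
  v / sum(v)
}

default_init_params <- function(vectors, lambda = 0.01) {
  m <- list(); u <- list()
  for (f in LINK_FIELDS) {
    lv <- FIELD_LEVELS[[f]]
    # m: 0.9 mass on the top agreement level, remainder spread uniformly
    mv <- stats::setNames(rep(0.1 / (length(lv) - 1), length(lv)), lv)
    mv[1] <- 0.9
    obs <- vectors[[f]][vectors[[f]] != "missing"]
    uv <- if (length(obs)) table(factor(obs, levels = lv)) / length(obs)
          else rep(1 / length(lv), length(lv))
    m[[f]] <- mv
    u[[f]] <- clamp_norm(stats::setNames(as.numeric(uv), lv))
  }
  fs_params(m, u, lambda)
}

# Per-pattern class likelihoods under conditional independence; `missing`
# contributes a factor of 1 to both classes.
pattern_lik <- function(patterns, probs) {
  lik <- rep(1, nrow(patterns))
  for (f in LINK_FIELDS) {
    lv <- patterns[[f]]
    obs <- lv != "missing"
    lik[obs] <- lik[obs] * probs[[f]][lv[obs]]
  }
  lik
}

#' Estimate Fellegi-Sunter parameters by EM
#'
#' Fits the two-class latent mixture over comparison vectors under
#' conditional independence of fields given class.  The E-step computes the
#' posterior match probability of each distinct agreement pattern; the
#' M-step re-estimates the m- and u-probabilities (over informative levels)
#' and the class prior `lambda`.  Iteration stops when the largest absolute
#' parameter change falls below `tol` or after `max_iter` iterations.  The
#' observed-data log-likelihood is non-decreasing across iterations and is
#' returned as attribute `"loglik"`.  Estimates that reach 0 or 1 are
#' clamped to `[1e-6, 1 - 1e-6]` (and renormalised) with a warning, as is a
#' degenerate `lambda`.
#'
#' @param vectors comparison-vector data frame from [compare_pairs()].
#' @param init optional starting `fs_params`; by default m puts 0.9 on the
#'   top agreement level, u is the empirical level frequency over all pairs,
#'   and `lambda = init_lambda`.
#' @param tol convergence tolerance on the parameters.
#' @param max_iter iteration cap.
#' @param init_lambda starting prior used when `init` is `NULL`.
#' @return An `fs_params` object with attributes `loglik` (per-iteration
#'   trace), `n_iter` and `converged`.
#' @export
estimate_fs_params <- function(vectors, init = NULL, tol = 1e-6,
                               max_iter = 500, init_lambda = 0.01) {
  stopifnot(nrow(vectors) >= 1)
  if (is.null(init)) init <- default_init_params(vectors, init_lambda)
  stopifnot(inherits(init, "fs_params"))

  pat_key <- do.call(paste, c(vectors[LINK_FIELDS], sep = "|"))
  tab <- table(pat_key)
  counts <- as.numeric(tab)
  patterns <- utils::read.table(text = names(tab), sep = "|",
                                col.names = LINK_FIELDS,
                                colClasses = "character")
  m <- init$m; u <- init$u; lambda <- init$lambda
  loglik <- numeric(0); clamped <- FALSE

  for (it in seq_len(max_iter)) {
    pm <- pattern_lik(patterns, m)
    pu <- pattern_lik(patterns, u)
    denom <- lambda * pm + (1 - lambda) * pu
    g <- lambda * pm / denom
    loglik <- c(loglik, sum(counts * log(denom)))

    old <- c(unlist(m), unlist(u), lambda)
    nm <- m; nu <- u
    for (f in LINK_FIELDS) {
      lv <- FIELD_LEVELS[[f]]
      obs <- patterns[[f]] != "missing"
      lvf <- factor(patterns[[f]][obs], levels = lv)
      wm <- g[obs] * counts[obs]; wu <- (1 - g[obs]) * counts[obs]
      m_new <- tapply(wm, lvf, sum, default = 0) / max(sum(wm), 1e-300)
      u_new <- tapply(wu, lvf, sum, default = 0) / max(sum(wu), 1e-300)
      if (any(m_new <= 0 | m_new >= 1) || any(u_new <= 0 | u_new >= 1))
        clamped <- TRUE
      nm[[f]] <- clamp_norm(stats::setNames(as.numeric(m_new), lv))
      nu[[f]] <- clamp_norm(stats::setNames(as.numeric(u_new), lv))
    }
    lambda_new <- sum(g * counts) / sum(counts)
    if (lambda_new <= 1e-6 || lambda_new >= 1 - 1e-6) {
      clamped <- TRUE
      lambda_new <- min(max(lambda_new, 1e-6), 1 - 1e-6)
    }
    m <- nm; u <- nu; lambda <- lambda_new
    if (max(abs(c(unlist(m), unlist(u), lambda) - old)) < tol) break
  }
  if (clamped)
    warning("EM reached a parameter boundary; estimates clamped to [1e-6, 1-1e-6]")

  # Orientation guard: the match class is the one favouring full agreement.
  top_w <- sum(vapply(LINK_FIELDS, function(f)
    log2(m[[f]][1] / u[[f]][1]), numeric(1)))
  if (top_w < 0) {
    tmp <- m; m <- u; u <- tmp; lambda <- 1 - lambda
  }

  out <- fs_params(m, u, lambda)
  attr(out, "loglik") <- loglik
  attr(out, "n_iter") <- length(loglik)
  attr(out, "converged") <- length(loglik) < max_iter
  out
}

#' Fellegi-Sunter agreement weight of comparison vectors
#'
#' The total weight of a pair is the sum over the four fields of
#' `log2(m / u)` at the observed agreement level; a `missing` field
#' contributes 0 (the m = u convention for uninformative fields).
#'
#' @param vectors comparison-vector data frame from [compare_pairs()].
#' @param params an `fs_params` object.
#' @return Numeric vector of log2 weights, one per row.
#' @export
score_pairs <- function(vectors, params) {
  stopifnot(inherits(params, "fs_params"))
  w <- rep(0, nrow(vectors))
  for (f in LINK_FIELDS) {
    lv <- vectors[[f]]
    obs <- lv != "missing"
    w[obs] <- w[obs] + log2(params$m[[f]][lv[obs]] / params$u[[f]][lv[obs]])
  }
  unname(w)
}

#' Weight threshold attaining a target posterior match probability
#'
#' Under the fitted model the posterior match probability of a pair with
#' weight `w` is `lambda * 2^w / (lambda * 2^w + 1 - lambda)`; inverting
#' gives the weight at which the posterior equals `posterior`.
#'
#' @param params an `fs_params` object.
#' @param posterior target posterior match probability in (0, 1).
#' @return The log2 weight threshold.
#' @export
weight_threshold <- function(params, posterior) {
  stopifnot(posterior > 0, posterior < 1)
  log2(posterior / (1 - posterior)) +
    log2((1 - params$lambda) / params$lambda)
}

#' Classify scored pairs and enforce one-to-one assignment
#'
#' Pairs with weight at or above `upper` are candidate links; below `lower`,
#' non-links; in between, `possible` (reported but not linked).  Candidate
#' links are assigned greedily in order of descending weight (ties broken by
#' death then birth identifier), skipping any death or birth already
#' assigned, so no identifier appears in two links; displaced candidates
#' are demoted to `possible`.
#'
#' @param pairs data frame with `death_id`, `birth_id`, `weight`.
#' @param upper,lower weight thresholds, `lower <= upper`.
#' @return The pairs with added `stage = "probabilistic"` and `decision`
#'   (`link` / `possible` / `non-link`).
#' @export
classify_and_assign <- function(pairs, upper, lower) {
  stopifnot(lower <= upper)
  pairs <- pairs[, c("death_id", "birth_id", "weight")]
  pairs$stage <- "probabilistic"
  pairs$decision <- ifelse(pairs$weight >= upper, "link",
                           ifelse(pairs$weight < lower, "non-link", "possible"))
  cand <- which(pairs$decision == "link")
  if (length(cand) > 1) {
    ord <- cand[order(-pairs$weight[cand], pairs$death_id[cand],
                      pairs$birth_id[cand])]
    seen_d <- character(0); seen_b <- character(0)
    for (i in ord) {
      if (pairs$death_id[i] %in% seen_d || pairs$birth_id[i] %in% seen_b) {
        pairs$decision[i] <- "possible"
      } else {
        seen_d <- c(seen_d, pairs$death_id[i])
        seen_b <- c(seen_b, pairs$birth_id[i])
      }
    }
  }
  pairs
}

#' Linkage engine settings
#'
#' @param blocking candidate blocking scheme (see [block_candidates()]).
#' @param upper_posterior,lower_posterior posterior match probabilities
#'   defining the link / possible / non-link weight thresholds.
#' @param em_tol,em_max_iter EM convergence controls.
#' @param probabilistic run the probabilistic pass after the deterministic
#'   pass (set `FALSE` for an identifier-only linkage).
#' @return Object of class `linkage_config`.
#' @export
linkage_config <- function(blocking = c("dob_pm1", "dobyear_fsa", "none"),
                           upper_posterior = 0.9, lower_posterior = 0.1,
                           em_tol = 1e-6, em_max_iter = 500,
                           probabilistic = TRUE) {
  blocking <- match.arg(blocking)
  check_prob(upper_posterior, "upper_posterior")
  check_prob(lower_posterior, "lower_posterior")
  if (lower_posterior > upper_posterior)
    fail_cfg("lower_posterior", "must not exceed upper_posterior")
  structure(list(blocking = blocking, upper_posterior = upper_posterior,
                 lower_posterior = lower_posterior, em_tol = em_tol,
                 em_max_iter = em_max_iter,
                 probabilistic = isTRUE(probabilistic)),
            class = "linkage_config")
}

#' Run the full period linkage
#'
#' Builds the period linked file: a deterministic identifier pass over all
#' registered deaths, then Fellegi-Sunter probabilistic linkage of the
#' residual deaths on date of birth, place of death, sex and postal code
#' (EM-fitted parameters; thresholds set by posterior match probability).
#' Deaths registered outside the configured period are excluded with a
#' warning.  Links onto stillbirth reference records are reported in a
#' reclassification table rather than counted as live-birth links; the
#' denominator set comprises live births whose birth date falls inside the
#' death-registration window.
#'
#' @param deaths death registration file.
#' @param reference birth reference file (live births, orphan records and
#'   stillbirth records).
#' @param config a [linkage_config()].
#' @param death_years inclusive death-registration year range; defaults to
#'   the years observed in `deaths`.
#' @return Object of class `period_linked_file` with elements `pairs` (all
#'   emitted match pairs incl. possibles), `linked` (linked deaths joined to
#'   live-birth attributes), `unlinked` (death rows not linked),
#'   `reclassified` (links onto stillbirth records), `denominator` (live
#'   births in the period), `params`, `thresholds` and `summary`.
#' @export
run_period_linkage <- function(deaths, reference, config = linkage_config(),
                               death_years = NULL) {
  stopifnot(inherits(config, "linkage_config"))
  if (nrow(reference) == 0) stop("empty reference file")
  deaths$dob <- as.Date(deaths$dob); deaths$dod <- as.Date(deaths$dod)
  reference$dob <- as.Date(reference$dob)

  dod_year <- as.integer(format(deaths$dod, "%Y"))
  if (is.null(death_years)) death_years <- range(dod_year)
  ref_years <- range(as.integer(format(reference$dob, "%Y")))
  if (ref_years[1] > death_years[1] - 1L || ref_years[2] < death_years[2])
    warning(sprintf(
      "reference birth years %d-%d do not cover [%d, %d]; linkage may be incomplete",
      ref_years[1], ref_years[2], death_years[1] - 1L, death_years[2]))
  out_of_period <- dod_year < death_years[1] | dod_year > death_years[2]
  if (any(out_of_period)) {
    warning(sprintf("%d death(s) outside the %d-%d registration period excluded",
                    sum(out_of_period), death_years[1], death_years[2]))
    deaths <- deaths[!out_of_period, , drop = FALSE]
  }

  det <- deterministic_link(deaths, reference)
  pairs <- det$matches
  residual <- det$residual_deaths

  params <- NULL; thresholds <- c(upper = NA_real_, lower = NA_real_)
  if (config$probabilistic && nrow(residual) > 0) {
    cp <- candidate_pairs(residual, reference, config$blocking)
    if (nrow(cp) > 0) {
      vec <- compare_pairs(residual[cp$death_idx, , drop = FALSE],
                           reference[cp$birth_idx, , drop = FALSE])
      init_lambda <- min(max(nrow(residual) / nrow(cp), 1e-6), 0.5)
      params <- estimate_fs_params(vec, tol = config$em_tol,
                                   max_iter = config$em_max_iter,
                                   init_lambda = init_lambda)
      w <- score_pairs(vec, params)
      thresholds <- c(upper = weight_threshold(params, config$upper_posterior),
                      lower = weight_threshold(params, config$lower_posterior))
      scored <- data.frame(death_id = residual$death_id[cp$death_idx],
                           birth_id = reference$birth_id[cp$birth_idx],
                           weight = w, stringsAsFactors = FALSE)
      prob <- classify_and_assign(scored, thresholds["upper"], thresholds["lower"])
      pairs <- rbind(pairs, prob[prob$decision != "non-link", , drop = FALSE])
    }
  }

  links <- pairs[pairs$decision == "link", , drop = FALSE]
  still <- reference$birth_id[reference$stillbirth_flag]
  reclassified <- links[links$birth_id %in% still, , drop = FALSE]
  live_links <- links[!links$birth_id %in% still, , drop = FALSE]

  linked <- merge(deaths[deaths$death_id %in% links$death_id, , drop = FALSE],
                  links[, c("death_id", "birth_id", "weight", "stage")],
                  by = "death_id")
  battr <- reference[, setdiff(names(reference), c("encoded_id", "dob",
                                                   "postal_code")), drop = FALSE]
  names(battr)[names(battr) == "sex"] <- "sex_birth"
  linked <- merge(linked, battr, by = "birth_id", all.x = TRUE,
                  suffixes = c("", ".birth"))
  linked <- linked[order(linked$death_id), , drop = FALSE]
  rownames(linked) <- NULL

  unlinked <- deaths[!deaths$death_id %in% links$death_id, , drop = FALSE]
  rownames(unlinked) <- NULL

  birth_year <- as.integer(format(reference$dob, "%Y"))
  denominator <- reference[!reference$stillbirth_flag &
                             birth_year >= death_years[1] &
                             birth_year <= death_years[2], , drop = FALSE]
  rownames(denominator) <- NULL

  n_deaths <- nrow(deaths)
  summary <- list(
    n_deaths = n_deaths,
    n_linked = nrow(links),
    n_deterministic = sum(links$stage == "deterministic"),
    n_probabilistic = sum(links$stage == "probabilistic"),
    n_possible = sum(pairs$decision == "possible"),
    n_unlinked = nrow(unlinked),
    n_reclassified = nrow(reclassified),
    prop_linked = if (n_deaths) nrow(links) / n_deaths else NA_real_,
    prop_unlinked = if (n_deaths) nrow(unlinked) / n_deaths else NA_real_,
    n_denominator = nrow(denominator)
  )
  structure(list(pairs = pairs, linked = linked, unlinked = unlinked,
                 reclassified = reclassified, denominator = denominator,
                 params = params, thresholds = thresholds, summary = summary,
                 meta = list(death_years = death_years,
                             reference_years = ref_years,
                             blocking = config$blocking)),
            class = "period_linked_file")
}

#' @export
print.period_linked_file <- function(x, ...) {
  s <- x$summary
  cat("<period_linked_file>\n")
  cat(sprintf("  death registrations %d-%d: %d\n", x$meta$death_years[1],
              x$meta$death_years[2], s$n_deaths))
  cat(sprintf("  linked: %d (%.1f%%)  [deterministic %d, probabilistic %d]\n",
              s$n_linked, 100 * s$prop_linked, s$n_deterministic,
              s$n_probabilistic))
  cat(sprintf("  unlinked: %d (%.1f%%); possible pairs: %d; stillbirth reclassifications: %d\n",
              s$n_unlinked, 100 * s$prop_unlinked, s$n_possible,
              s$n_reclassified))
  cat(sprintf("  live-birth denominator: %d\n", s$n_denominator))
  invisible(x)
}

#' Evaluate a linkage run against the ground-truth map
#'
#' Precision is the share of emitted links whose birth record matches the
#' truth map; recall is the share of linkable deaths (truth map gives a
#' birth record present in the reference file) that were linked correctly.
#' Stage-specific values restrict both to deaths handled by that stage.
#'
#' @param plf a `period_linked_file`.
#' @param truth truth data frame (`death_id`, `birth_id`, `reason`).
#' @return List with `overall`, `deterministic` and `probabilistic`
#'   precision/recall, and the count of linkable deaths.
#' @export
linkage_accuracy <- function(plf, truth) {
  links <- plf$pairs[plf$pairs$decision == "link", , drop = FALSE]
  tmap <- stats::setNames(truth$birth_id, truth$death_id)
  eval_stage <- function(lk, deaths_in_scope) {
    linkable <- deaths_in_scope[!is.na(tmap[deaths_in_scope])]
    correct <- sum(lk$birth_id == tmap[lk$death_id], na.rm = TRUE)
    list(precision = if (nrow(lk)) correct / nrow(lk) else NA_real_,
         recall = if (length(linkable)) correct / length(linkable) else NA_real_,
         n_links = nrow(lk), n_linkable = length(linkable))
  }
  all_deaths <- c(links$death_id, plf$unlinked$death_id)
  det <- links[links$stage == "deterministic", , drop = FALSE]
  prob <- links[links$stage == "probabilistic", , drop = FALSE]
  prob_scope <- setdiff(all_deaths, det$death_id)
  list(overall = eval_stage(links, all_deaths),
       deterministic = eval_stage(det, det$death_id),
       probabilistic = eval_stage(prob, prob_scope))
}
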