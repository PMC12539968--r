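# Synthetic focal-sampling generator. Two generation paths: a mechanistic
# simulator that emits demography, dominance bouts and interval-scored focal
# records with configurable developmental trends, homophily and
# cross-behaviour coupling (exercising the entire pipeline), and a
# likelihood-exact shortcut that draws responses directly from the fitted
# model's families for clean parameter recovery.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: a ~130-animal mixed-sex group
#' (F:M about 2:1), two ego birth cohorts of 25 and 24 infants, 10-minute
#' focals 8 times per monthly bin (observed monthly in year one, bimonthly
#' after), five behaviours with developmental trends (play declining,
#' grooming and aggression increasing), kin/rank/sex/age homophily and a
#' cross-behaviour lag coupling matrix dominated by proximity.
#'
#' @param n_egos named integer vector: egos per cohort.
#' @param group_size total group size target.
#' @param sex_ratio_f probability a generated animal is female.
#' @param n_matrilines number of matrilines.
#' @param rank_steepness logistic steepness of bout outcomes on the latent
#'   rank scale.
#' @param n_bouts_per_year decided dominance bouts sampled per study year.
#' @param sessions_per_month focal sessions per ego per observed month.
#' @param months months of life tracked per ego.
#' @param observed_months month-of-life bins with observation effort.
#' @param base_rate named per-interval event probabilities at month 1.
#' @param slope named monthly trends on the logit scale.
#' @param give_base,give_slope logit intercept/trend of the probability a
#'   directed event is given (vs received) by the focal.
#' @param homophily named list per behaviour with elements `kin`, `rank`,
#'   `sex`, `age`: log-weight coefficients (rank and age multiply negative
#'   absolute differences, so positive values mean homophily).
#' @param coupling 5x5 matrix, `coupling[b1, b2]` = log-weight added to a
#'   partner's odds of behaviour `b2` when the dyad interacted in `b1`
#'   during the previous partition.
#' @param re_sd_ego,re_sd_alter sd of per-animal log-rate intercepts.
#' @param removal_hazard yearly removal probability for non-ego juveniles.
#' @param max_alter_age age cutoff defining the peer pool.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_egos = c(`2016` = 25, `2017` = 24),
                       group_size = 130,
                       sex_ratio_f = 0.67,
                       n_matrilines = 12,
                       rank_steepness = 1.5,
                       n_bouts_per_year = 1500,
                       sessions_per_month = 8,
                       months = 36,
                       observed_months = c(1:12, seq(13, 36, by = 2)),
                       base_rate = c(aggression = 0.015, contact = 0.06,
                                     groom = 0.008, play = 0.05,
                                     proximity = 0.25),
                       slope = c(aggression = 0.02, contact = -0.02,
                                 groom = 0.05, play = -0.04,
                                 proximity = -0.02),
                       give_base = c(aggression = -0.6, groom = -1.2,
                                     play = 0),
                       give_slope = c(aggression = 0.04, groom = 0.08,
                                      play = 0),
                       homophily = NULL,
                       coupling = NULL,
                       re_sd_ego = 0.3,
                       re_sd_alter = 0.8,
                       removal_hazard = 0.03,
                       max_alter_age = 3) {
  if (is.null(homophily)) {
    homophily <- setNames(rep(list(list(kin = 1, rank = 0.5, sex = 0.5,
                                        age = 0.5)), 5), BEHAVIOURS)
  }
  if (is.null(coupling)) {
    coupling <- matrix(0, 5, 5, dimnames = list(BEHAVIOURS, BEHAVIOURS))
    diag(coupling) <- 0.8
    coupling["proximity", ] <- coupling["proximity", ] + 0.6
    coupling["contact", c("contact", "groom", "play", "proximity")] <-
      coupling["contact", c("contact", "groom", "play", "proximity")] + 0.4
  }
  stopifnot(all(base_rate > 0 & base_rate < 1), all(is.finite(coupling)),
            nrow(coupling) == 5, sum(n_egos) >= 1)
  structure(list(n_egos = n_egos, group_size = group_size,
                 sex_ratio_f = sex_ratio_f, n_matrilines = n_matrilines,
                 rank_steepness = rank_steepness,
                 n_bouts_per_year = n_bouts_per_year,
                 sessions_per_month = sessions_per_month, months = months,
                 observed_months = observed_months, base_rate = base_rate,
                 slope = slope, give_base = give_base,
                 give_slope = give_slope, homophily = homophily,
                 coupling = coupling, re_sd_ego = re_sd_ego,
                 re_sd_alter = re_sd_alter,
                 removal_hazard = removal_hazard,
                 max_alter_age = max_alter_age),
            class = "sim_config")
}

#' Simulate group demography and dominance bouts
#'
#' Generates matrilines of adult females, infants in the configured ego
#' cohorts (each with a distinct mother within a cohort, so across-cohort
#' siblings arise naturally), non-ego juvenile peers, adult males, removal
#' dates drawn from a yearly hazard, and decided dominance bouts consistent
#' with a planted matriline-structured linear hierarchy.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `demography`, `bouts` and `latent` (data.frame
#'   `animal_id`, `latent_rank`: the planted hierarchy, maternally
#'   inherited).
#' @export
simulate_group <- function(config, seed = 1) {
  set.seed(seed)
  cohort_years <- as.integer(names(config$n_egos))
  first_year <- min(cohort_years)
  study_years <- first_year:(first_year + ceiling(config$months / 12))

  n_mothers <- max(35, max(config$n_egos) + 5)
  if (max(config$n_egos) > n_mothers) {
    stop("more egos in a cohort than available mothers", call. = FALSE)
  }
  mat <- sprintf("M%02d", seq_len(config$n_matrilines))
  mat_base <- seq(1.5, -1.5, length.out = config$n_matrilines)

  mothers <- data.frame(
    animal_id = sprintf("F%03d", seq_len(n_mothers)),
    sex = "F",
    birth_date = as.Date(sprintf("%d-%02d-01",
                                 sample((first_year - 16):(first_year - 4),
                                        n_mothers, TRUE),
                                 sample(1:12, n_mothers, TRUE))),
    matriline_id = sample(mat, n_mothers, TRUE),
    mother_id = NA_character_,
    removal_date = as.Date(NA),
    cohort = "other", stringsAsFactors = FALSE)

  # ego infants: distinct mothers within a cohort
  egos <- list()
  for (cy in cohort_years) {
    n <- config$n_egos[[as.character(cy)]]
    ms <- sample(mothers$animal_id, n)
    egos[[as.character(cy)]] <- data.frame(
      animal_id = sprintf("E%d%03d", cy %% 100, seq_len(n)),
      sex = ifelse(runif(n) < config$sex_ratio_f, "F", "M"),
      birth_date = as.Date(sprintf("%d-%02d-%02d", cy, sample(4:6, n, TRUE),
                                   sample(1:28, n, TRUE))),
      matriline_id = mothers$matriline_id[match(ms, mothers$animal_id)],
      mother_id = ms,
      removal_date = as.Date(NA),
      cohort = as.character(cy), stringsAsFactors = FALSE)
  }
  egos <- do.call(rbind, egos)

  # non-ego juvenile peers born around the cohorts (alters 0-6 years old)
  n_filled <- n_mothers + nrow(egos)
  n_males <- max(5, round(config$group_size * 0.15))
  n_peers <- max(0, config$group_size - n_filled - n_males)
  peer_years <- (first_year - 3):(first_year + 2)
  if (n_peers > 0) {
    pm <- sample(mothers$animal_id, n_peers, TRUE)
    peers <- data.frame(
      animal_id = sprintf("J%03d", seq_len(n_peers)),
      sex = ifelse(runif(n_peers) < config$sex_ratio_f, "F", "M"),
      birth_date = as.Date(sprintf("%d-%02d-%02d",
                                   sample(peer_years, n_peers, TRUE),
                                   sample(3:7, n_peers, TRUE),
                                   sample(1:28, n_peers, TRUE))),
      matriline_id = mothers$matriline_id[match(pm, mothers$animal_id)],
      mother_id = pm,
      removal_date = as.Date(NA), cohort = "other", stringsAsFactors = FALSE)
  } else {
    peers <- mothers[0, ]
  }

  males <- data.frame(
    animal_id = sprintf("A%03d", seq_len(n_males)),
    sex = "M",
    birth_date = as.Date(sprintf("%d-%02d-01",
                                 sample((first_year - 12):(first_year - 4),
                                        n_males, TRUE),
                                 sample(1:12, n_males, TRUE))),
    matriline_id = sample(mat, n_males, TRUE),
    mother_id = NA_character_,
    removal_date = as.Date(NA), cohort = "other", stringsAsFactors = FALSE)

  demography <- rbind(mothers, egos, peers, males)

  # removals among non-ego juveniles (yearly hazard)
  if (config$removal_hazard > 0 && n_peers > 0) {
    for (k in which(demography$animal_id %in% peers$animal_id)) {
      for (yr in study_years) {
        if (yr <= as.integer(format(demography$birth_date[k], "%Y"))) next
        if (runif(1) < config$removal_hazard) {
          demography$removal_date[k] <-
            as.Date(sprintf("%d-%02d-%02d", yr, sample(1:12, 1),
                            sample(1:28, 1)))
          break
        }
      }
    }
    bad <- !is.na(demography$removal_date) &
      demography$removal_date < demography$birth_date
    demography$removal_date[bad] <- NA
  }

  # planted hierarchy: matriline base + individual noise, maternally
  # inherited by juveniles
  latent <- setNames(numeric(nrow(demography)), demography$animal_id)
  adults_mask <- is.na(demography$mother_id)
  mb <- mat_base[match(demography$matriline_id, mat)]
  mb[is.na(mb)] <- 0
  latent[adults_mask] <- mb[adults_mask] + rnorm(sum(adults_mask), 0, 0.3)
  kids <- which(!adults_mask)
  latent[kids] <- latent[demography$mother_id[kids]] +
    rnorm(length(kids), 0, 0.1)

  # decided bouts among adults per study year
  bouts <- list()
  for (yr in study_years) {
    birth_year <- as.integer(format(demography$birth_date, "%Y"))
    adults <- demography$animal_id[(yr - birth_year) >= 3 &
                                     (is.na(demography$removal_date) |
                                        as.integer(format(demography$removal_date,
                                                          "%Y")) >= yr)]
    if (length(adults) < 2) next
    i <- sample(adults, config$n_bouts_per_year, TRUE)
    j <- vapply(i, function(a) sample(setdiff(adults, a), 1), character(1))
    p_win <- plogis(config$rank_steepness * (latent[i] - latent[j]))
    w <- runif(length(i)) < p_win
    bouts[[length(bouts) + 1L]] <- data.frame(
      winner_id = ifelse(w, i, j), loser_id = ifelse(w, j, i),
      date = as.Date(sprintf("%d-%02d-%02d", yr,
                             sample(1:12, length(i), TRUE),
                             sample(1:28, length(i), TRUE))),
      stringsAsFactors = FALSE)
  }
  bouts <- do.call(rbind, bouts)
  rownames(bouts) <- NULL

  list(demography = validate_demography(demography),
       bouts = validate_bouts(bouts),
       latent = data.frame(animal_id = demography$animal_id,
                           latent_rank = as.numeric(latent),
                           row.names = NULL))
}

#' Simulate interval-scored focal records
#'
#' For each ego, observed month and behaviour, the number of scored
#' intervals is binomial over the month's session-interval slots with a
#' logistic month trend; each event picks a partner with probability
#' proportional to `exp(homophily terms + alter intercept + coupling from
#' the previous partition's interaction history)`. Directed events draw a
#' given/received direction from a logistic month trend. Interval events
#' are independent given rates (no within-session autocorrelation).
#'
#' @param demography validated demography (from [simulate_group()]).
#' @param ranks data.frame `animal_id`, `rank_score` used for the rank
#'   homophily term (the planted latent hierarchy or an estimated one).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param scheme `partition_scheme` used for the coupling history.
#' @return validated focal records data.frame.
#' @export
simulate_focals <- function(demography, ranks, config, seed = 1,
                            scheme = partition_scheme()) {
  set.seed(seed)
  egos <- focal_subjects(demography)
  rank_of <- setNames(ranks$rank_score, ranks$animal_id)
  out <- vector("list", 5000); n_out <- 0L
  ego_re <- setNames(rnorm(length(egos), 0, config$re_sd_ego), egos)
  alter_re <- setNames(rnorm(nrow(demography), 0, config$re_sd_alter),
                       demography$animal_id)
  birth_year <- as.integer(format(demography$birth_date, "%Y"))

  for (ego in egos) {
    ei <- match(ego, demography$animal_id)
    cohort_year <- as.integer(demography$cohort[ei])
    # peer pool: age cutoff in the cohort's birth year
    pool <- demography$animal_id[
      (cohort_year - birth_year) <= config$max_alter_age &
        demography$animal_id != ego]
    if (!length(pool)) next
    pi_dem <- match(pool, demography$animal_id)
    kin <- .kinship(rep(ei, length(pool)), pi_dem, demography)
    kin_num <- ifelse(kin == "sibling", 1.5, ifelse(kin == "comatriline", 1, 0))
    same_sex <- demography$sex[pi_dem] == demography$sex[ei]
    rank_d <- abs(rank_of[ego] - rank_of[pool])
    rank_d[is.na(rank_d)] <- median(rank_d, na.rm = TRUE)
    hist_prev <- matrix(FALSE, length(pool), 5,
                        dimnames = list(pool, BEHAVIOURS))
    hist_cur <- hist_prev
    cur_part <- partition_of(scheme, min(config$observed_months))

    for (m in sort(intersect(config$observed_months,
                             seq_len(config$months)))) {
      p_m <- partition_of(scheme, m)
      if (!is.na(p_m) && !identical(p_m, cur_part)) {
        hist_prev <- hist_cur
        hist_cur[] <- FALSE
        cur_part <- p_m
      }
      win <- partition_window(partition_scheme(setNames(list(m), "1")), 1,
                              demography$birth_date[ei])
      alive <- demography$birth_date[pi_dem] <= win[2] &
        (is.na(demography$removal_date[pi_dem]) |
           demography$removal_date[pi_dem] >= win[1])
      if (!any(alive)) next
      age_d <- abs(as.numeric(win[1] - demography$birth_date[ei]) -
                     as.numeric(win[1] - demography$birth_date[pi_dem])) /
        365.25
      n_slots <- config$sessions_per_month * INTERVALS_PER_SESSION
      session_dates <- sort(win[1] + sample(as.numeric(win[2] - win[1]),
                                            config$sessions_per_month,
                                            replace = TRUE))
      for (b in BEHAVIOURS) {
        h <- config$homophily[[b]]
        lw <- h$kin * kin_num + h$sex * same_sex - h$rank * rank_d -
          h$age * age_d + alter_re[pool] +
          as.numeric(hist_prev %*% config$coupling[, b])
        w <- exp(lw) * alive
        if (sum(w) == 0) next
        p_b <- plogis(qlogis(config$base_rate[[b]]) +
                        config$slope[[b]] * (m - 1) + ego_re[ego])
        n_ev <- rbinom(1, n_slots, p_b)
        if (n_ev == 0) next
        slots <- sample.int(n_slots, n_ev, replace = TRUE)
        partners <- pool[sample.int(length(pool), n_ev, replace = TRUE,
                                    prob = w)]
        hist_cur[unique(partners), b] <- TRUE
        if (b %in% DIRECTED_BEHAVIOURS) {
          p_give <- plogis(config$give_base[[b]] +
                             config$give_slope[[b]] * (m - 1))
          dir <- ifelse(runif(n_ev) < p_give, "given", "received")
        } else dir <- "undirected"
        sess <- (slots - 1L) %/% INTERVALS_PER_SESSION
        rec <- data.frame(
          focal_id = ego,
          session_date = session_dates[sess + 1L],
          session_index = sess,
          interval_index = (slots - 1L) %% INTERVALS_PER_SESSION,
          behaviour = b, partner_id = partners, direction = dir,
          stringsAsFactors = FALSE)
        n_out <- n_out + 1L
        out[[n_out]] <- rec
      }
    }
  }
  f <- do.call(rbind, out[seq_len(n_out)])
  if (is.null(f)) stop("simulation produced no focal records", call. = FALSE)
  key <- paste(f$focal_id, f$session_date, f$session_index,
               f$interval_index, f$behaviour, f$partner_id, f$direction)
  f <- f[!duplicated(key), , drop = FALSE]
  rownames(f) <- NULL
  validate_focals(f)
}

#' Simulate a full observation database
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param scheme `partition_scheme` for the coupling history.
#' @return list with `db` (an `observation_db`) and `truth` (latent ranks
#'   and the generating config).
#' @export
simulate_observations <- function(config = sim_config(), seed = 1,
                                  scheme = partition_scheme()) {
  grp <- simulate_group(config, seed)
  lat <- grp$latent
  lat$rank_score <- (lat$latent_rank - mean(lat$latent_rank)) /
    sd(lat$latent_rank)
  focals <- simulate_focals(grp$demography, lat, config,
                            seed = seed + 1L, scheme = scheme)
  db <- observation_db(focals, grp$demography, grp$bouts)
  list(db = db, truth = list(latent = grp$latent, config = config))
}

#' Random generative truth for recovery studies
#'
#' @param predictor_names design-matrix column names (including
#'   `(Intercept)`).
#' @param seed integer seed.
#' @param beta_range fixed effects drawn uniformly from this range
#'   (intercepts from a narrower centred range).
#' @param re_sd random-effect sd (all 7 components).
#' @param re_cor_ego,re_cor_alter 7x7 correlation targets (default: 0.7
#'   between the first two components for the ego, identity otherwise).
#' @param sigma_contact,sigma_proximity lognormal residual scales.
#' @return list of class `sim_truth` keyed to the model's coefficients.
#' @export
random_truth <- function(predictor_names, seed = 1, beta_range = c(-1, 1),
                         re_sd = 0.5, re_cor_ego = NULL,
                         re_cor_alter = NULL, sigma_contact = 0.6,
                         sigma_proximity = 0.5) {
  set.seed(seed)
  P <- length(predictor_names)
  beta <- matrix(runif(P * 7, beta_range[1], beta_range[2]), P, 7,
                 dimnames = list(predictor_names, MODEL_COMPONENTS))
  beta["(Intercept)", ] <- runif(7, -0.5, 0.5)
  if (is.null(re_cor_ego)) {
    re_cor_ego <- diag(7)
    re_cor_ego[1, 2] <- re_cor_ego[2, 1] <- 0.7
  }
  if (is.null(re_cor_alter)) re_cor_alter <- diag(7)
  structure(list(beta = beta, sd_u = rep(re_sd, 7), cor_u = re_cor_ego,
                 sd_v = rep(re_sd, 7), cor_v = re_cor_alter,
                 sigma_contact = sigma_contact,
                 sigma_proximity = sigma_proximity),
            class = "sim_truth")
}

#' Synthetic model-table skeleton (predictors only)
#'
#' Pre-scaled continuous predictors, factor covariates and ego/alter
#' assignments without responses, for use with [simulate_from_model()].
#'
#' @param n_ego,n_alter numbers of egos and alters.
#' @param alters_per_ego partners sampled per ego.
#' @param seed integer seed.
#' @return model-table data.frame lacking the response columns.
#' @export
model_table_skeleton <- function(n_ego = 40, n_alter = 120,
                                 alters_per_ego = 34, seed = 1) {
  set.seed(seed)
  rows <- list()
  egos <- sprintf("E%03d", seq_len(n_ego))
  alters <- sprintf("A%03d", seq_len(n_alter))
  ego_sex <- sample(c("F", "M"), n_ego, TRUE)
  ego_cohort <- sample(c("2016", "2017"), n_ego, TRUE)
  ego_rank <- rnorm(n_ego, 0, 0.5)
  for (e in seq_len(n_ego)) {
    als <- sample(alters, min(alters_per_ego, n_alter))
    for (p in 2:4) {
      n <- length(als)
      rows[[length(rows) + 1L]] <- data.frame(
        ego_id = egos[e], alter_id = als, partition_index = p,
        lag_aggression = rnorm(n, 0, 0.5), lag_contact = rnorm(n, 0, 0.5),
        lag_groom = rnorm(n, 0, 0.5), lag_play = rnorm(n, 0, 0.5),
        lag_proximity = rnorm(n, 0, 0.5),
        ego_cohort = ego_cohort[e], ego_sex = ego_sex[e],
        ego_maternal_rank = ego_rank[e],
        rank_diff = abs(rnorm(n, 0, 0.5)) - 0.4,
        age_diff_years = abs(rnorm(n, 0, 0.5)) - 0.4,
        same_sex = runif(n) < 0.5,
        kinship = sample(c("unrelated", "comatriline", "sibling"), n, TRUE,
                         prob = c(0.75, 0.15, 0.10)),
        alter_born_flag = runif(n) < 0.08,
        alter_removed_flag = runif(n) < 0.05,
        partition_linear = (p - 3) / 2,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# multivariate normal draws given sd vector and correlation matrix
.rmvn <- function(n, sd, cor_mat) {
  L <- chol(cor_mat)
  z <- matrix(rnorm(n * length(sd)), n)
  sweep(z %*% L, 2, sd, `*`)
}

#' Draw responses exactly from the model's likelihood
#'
#' Given a predictor skeleton and generative truth, draws correlated ego
#' and alter random effects and then each response from its family:
#' Bernoulli for aggression/groom/play, hurdle-lognormal for contact and
#' proximity versatility.
#'
#' @param skeleton from [model_table_skeleton()] (or a real scaled table
#'   stripped of responses).
#' @param truth a [random_truth()] (or compatible list); its `beta`
#'   rownames must match the design columns implied by `spec`.
#' @param seed integer seed.
#' @param spec a [model_spec()].
#' @return the skeleton with response columns appended; attributes
#'   `u`, `v` hold the realized random effects, `truth` the generator.
#' @export
simulate_from_model <- function(skeleton, truth, seed = 1,
                                spec = model_spec()) {
  set.seed(seed)
  X <- build_design(skeleton, spec)
  if (!identical(sort(colnames(X)), sort(rownames(truth$beta)))) {
    stop(sprintf("truth coefficients do not match predictors; missing: %s; extra: %s",
                 paste(setdiff(colnames(X), rownames(truth$beta)),
                       collapse = ", "),
                 paste(setdiff(rownames(truth$beta), colnames(X)),
                       collapse = ", ")), call. = FALSE)
  }
  beta <- truth$beta[colnames(X), , drop = FALSE]
  ego_f <- factor(skeleton$ego_id)
  alter_f <- factor(skeleton$alter_id)
  u <- .rmvn(nlevels(ego_f), truth$sd_u, truth$cor_u)
  v <- .rmvn(nlevels(alter_f), truth$sd_v, truth$cor_v)
  rownames(u) <- levels(ego_f); rownames(v) <- levels(alter_f)
  eta <- X %*% beta + u[as.integer(ego_f), ] + v[as.integer(alter_f), ]
  colnames(eta) <- MODEL_COMPONENTS
  n <- nrow(skeleton)
  out <- skeleton
  out$aggr_bin <- rbinom(n, 1, plogis(eta[, "aggression"]))
  out$groom_bin <- rbinom(n, 1, plogis(eta[, "groom"]))
  out$play_bin <- rbinom(n, 1, plogis(eta[, "play"]))
  zc <- rbinom(n, 1, plogis(eta[, "contact_hu"]))
  zp <- rbinom(n, 1, plogis(eta[, "proximity_hu"]))
  out$contact_vers <- ifelse(zc == 1, 0,
                             rlnorm(n, eta[, "contact_mu"],
                                    truth$sigma_contact))
  out$proximity_vers <- ifelse(zp == 1, 0,
                               rlnorm(n, eta[, "proximity_mu"],
                                      truth$sigma_proximity))
  attr(out, "u") <- u
  attr(out, "v") <- v
  attr(out, "truth") <- truth
  out
}
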