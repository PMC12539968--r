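# Dominance ranks, dyadic assortativity covariates, temporal lags and the
# assembly of the wide model table (one row per ego-alter-partition).

#' Estimate yearly dominance ranks (David's score)
#'
#' Linear-hierarchy score from decided dyadic bouts within one calendar
#' year. David's score uses dyadic winning proportions `P_ij = w_ij / n_ij`:
#' `DS_i = w + w2 - l - l2` where `w` sums `P_ij`, `w2` weights opponents'
#' `w`, and `l`, `l2` are the losing analogues. Scores are z-standardized
#' within the year so that they act as a comparable covariate; higher means
#' more dominant. The estimator is pluggable: any function returning a
#' standardized score per animal can substitute via the `estimator`
#' argument.
#'
#' @param bouts validated bout records ([read_bouts()]).
#' @param year calendar year to use.
#' @param demography optional; when given, only animals at least
#'   `min_age` years old in `year` are ranked (hierarchies are estimated
#'   among adults).
#' @param min_age adult age threshold in years (default 3).
#' @param estimator function(win_matrix) -> named numeric scores; default
#'   [davids_score()].
#' @return data.frame (`animal_id`, `year`, `rank_score`), one row per
#'   ranked animal; animals with no bouts that year are absent.
#' @export
estimate_ranks <- function(bouts, year, demography = NULL, min_age = 3,
                           estimator = davids_score) {
  yr <- as.integer(format(bouts$date, "%Y"))
  b <- bouts[yr == year, , drop = FALSE]
  if (!nrow(b)) stop(sprintf("no bouts in year %d", year), call. = FALSE)
  if (!is.null(demography)) {
    birth_year <- as.integer(format(demography$birth_date, "%Y"))
    adults <- demography$animal_id[(year - birth_year) >= min_age]
    b <- b[b$winner_id %in% adults & b$loser_id %in% adults, , drop = FALSE]
    if (!nrow(b)) stop(sprintf("no adult bouts in year %d", year),
                       call. = FALSE)
  }
  ids <- sort(unique(c(b$winner_id, b$loser_id)))
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  tab <- table(factor(b$winner_id, ids), factor(b$loser_id, ids))
  W[] <- as.numeric(tab)
  ds <- estimator(W)
  z <- if (sd(ds) > 0) (ds - mean(ds)) / sd(ds) else ds * 0
  data.frame(animal_id = names(z), year = year, rank_score = as.numeric(z),
             row.names = NULL)
}

#' David's score from a win matrix
#'
#' @param W square matrix, `W[i, j]` = number of times `i` beat `j`.
#' @return named numeric vector of scores.
#' @export
davids_score <- function(W) {
  n <- W + t(W)
  P <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  nz <- n > 0
  P[nz] <- W[nz] / n[nz]
  w <- rowSums(P)
  l <- colSums(P)
  w2 <- as.numeric(P %*% w)
  l2 <- as.numeric(t(P) %*% l)
  setNames(w + w2 - l - l2, rownames(W))
}

#' Assigned rank of an animal in a year
#'
#' Egos (focal subjects) carry their mother's dominance score. Alters old
#' enough to be ranked themselves use their own score; younger alters fall
#' back to their mother's score, then up the maternal line, then to the
#' mean score of ranked members of their matriline.
#'
#' @param animal_id animal to look up.
#' @param year calendar year.
#' @param demography validated demography.
#' @param ranks rank table from [estimate_ranks()] (may span years).
#' @param adult_age own-rank age threshold in years (default 3).
#' @return single numeric score.
#' @export
assign_rank <- function(animal_id, year, demography, ranks, adult_age = 3) {
  ry <- ranks[ranks$year == year, , drop = FALSE]
  score <- setNames(ry$rank_score, ry$animal_id)
  i <- match(animal_id, demography$animal_id)
  if (is.na(i)) stop(sprintf("'%s' not in demography", animal_id),
                     call. = FALSE)
  is_ego <- demography$cohort[i] %in% c("2016", "2017")
  age <- year - as.integer(format(demography$birth_date[i], "%Y"))
  if (!is_ego && age >= adult_age && animal_id %in% names(score)) {
    return(unname(score[animal_id]))
  }
  # maternal line (for egos this starts at the mother: maternal rank)
  cur <- demography$mother_id[i]
  seen <- character()
  while (!is.na(cur) && !cur %in% seen) {
    if (cur %in% names(score)) return(unname(score[cur]))
    seen <- c(seen, cur)
    j <- match(cur, demography$animal_id)
    cur <- if (is.na(j)) NA_character_ else demography$mother_id[j]
  }
  if (!is_ego && animal_id %in% names(score)) {
    return(unname(score[animal_id]))  # young but ranked in its own right
  }
  kin <- demography$animal_id[demography$matriline_id ==
                                demography$matriline_id[i]]
  kin_scores <- score[intersect(kin, names(score))]
  if (length(kin_scores)) return(mean(kin_scores))
  stop(sprintf("no rankable maternal relative for '%s' in %d",
               animal_id, year), call. = FALSE)
}

.kinship <- function(ego_i, alter_i, demography) {
  m_e <- demography$mother_id[ego_i]
  m_a <- demography$mother_id[alter_i]
  sib <- !is.na(m_e) & !is.na(m_a) & m_e == m_a
  com <- demography$matriline_id[ego_i] == demography$matriline_id[alter_i]
  ifelse(sib, "sibling", ifelse(com, "comatriline", "unrelated"))
}

#' Dyadic covariates for one ego-alter-partition row
#'
#' Rank and age differences are absolute values computed at the partition's
#' midpoint (egos carry maternal rank; alters their own or maternal-kin
#' rank, see [assign_rank()]). `alter_born_flag` marks alters born during
#' the previous partition (i.e. the partition after the first lag the alter
#' was present for); `alter_removed_flag` marks removal during the focal
#' partition.
#'
#' @param ego,alter animal ids.
#' @param partition partition index.
#' @param demography validated demography.
#' @param ranks rank table covering the relevant years.
#' @param scheme `partition_scheme`.
#' @param adult_age own-rank age threshold passed to [assign_rank()].
#' @return one-row data.frame of covariates.
#' @export
dyad_covariates <- function(ego, alter, partition, demography, ranks,
                            scheme = partition_scheme(), adult_age = 3) {
  ei <- match(ego, demography$animal_id)
  ai <- match(alter, demography$animal_id)
  stopifnot(!is.na(ei), !is.na(ai))
  win <- partition_window(scheme, partition, demography$birth_date[ei])
  mid <- win[1] + as.numeric(win[2] - win[1]) / 2
  year <- as.integer(format(mid, "%Y"))
  ego_rank <- assign_rank(ego, year, demography, ranks, adult_age)
  alter_rank <- assign_rank(alter, year, demography, ranks, adult_age)
  ego_age <- as.numeric(mid - demography$birth_date[ei]) / 365.25
  alter_age <- as.numeric(mid - demography$birth_date[ai]) / 365.25
  prev_win <- if (partition > min(as.integer(names(scheme$partitions)))) {
    partition_window(scheme, partition - 1, demography$birth_date[ei])
  } else NULL
  removal <- demography$removal_date[ai]
  data.frame(
    ego_id = ego, alter_id = alter, partition_index = partition,
    rank_diff = abs(ego_rank - alter_rank),
    age_diff_years = abs(ego_age - alter_age),
    same_sex = demography$sex[ei] == demography$sex[ai],
    kinship = .kinship(ei, ai, demography),
    alter_born_flag = !is.null(prev_win) &&
      demography$birth_date[ai] >= prev_win[1] &&
      demography$birth_date[ai] <= prev_win[2],
    alter_removed_flag = !is.na(removal) &&
      removal >= win[1] && removal <= win[2],
    ego_cohort = demography$cohort[ei],
    ego_sex = demography$sex[ei],
    ego_maternal_rank = ego_rank,
    stringsAsFactors = FALSE)
}

#' Lagged behaviour predictors from a versatility table
#'
#' The versatility of every behaviour at partition `t - 1` becomes the lag
#' predictor on the partition-`t` row, so lag values retain both
#' connectivity (non-zero) and quality (magnitude) information. Pairs
#' infeasible at `t - 1` (e.g. alters born during partition `t - 1` is fine,
#' but born during `t` is not present at `t - 1`) have no lag and are
#' excluded. First-partition rows never appear as responses.
#'
#' @param vers zero-populated versatility table ([zero_populate()]).
#' @return data.frame (`ego_id`, `alter_id`, `partition_index` >= 2,
#'   `lag_aggression`, `lag_contact`, `lag_groom`, `lag_play`,
#'   `lag_proximity`).
#' @export
build_lags <- function(vers) {
  wide <- versatility_wide(vers)
  lag <- wide
  lag$partition_index <- lag$partition_index + 1L
  names(lag)[match(BEHAVIOURS, names(lag))] <- paste0("lag_", BEHAVIOURS)
  lag
}

# pivot a versatility table to one row per (ego, alter, partition) with a
# column per behaviour
versatility_wide <- function(vers) {
  key <- paste(vers$ego_id, vers$alter_id, vers$partition_index, sep = "\r")
  ukey <- !duplicated(key)
  wide <- data.frame(ego_id = vers$ego_id[ukey],
                     alter_id = vers$alter_id[ukey],
                     partition_index = vers$partition_index[ukey],
                     stringsAsFactors = FALSE)
  rownames(wide) <- key[ukey]
  for (b in BEHAVIOURS) wide[[b]] <- NA_real_
  for (b in BEHAVIOURS) {
    vb <- vers[vers$behaviour == b, , drop = FALSE]
    kb <- paste(vb$ego_id, vb$alter_id, vb$partition_index, sep = "\r")
    if (anyDuplicated(kb)) {
      stop(sprintf("duplicate versatility rows for behaviour %s", b),
           call. = FALSE)
    }
    wide[kb, b] <- vb$versatility
  }
  rownames(wide) <- NULL
  wide
}

#' Binarize a directed-behaviour response
#'
#' Grooming, aggression and play versatilities exceeding 0 become 1 (few
#' samples fall strictly between 0 and 1, so the directed responses reduce
#' to connectivity); contact and proximity pass through unchanged and keep
#' quality information.
#'
#' @param x nonnegative versatility values.
#' @param behaviour one of [BEHAVIOURS].
#' @return numeric vector.
#' @export
binarize_directed <- function(x, behaviour) {
  stopifnot(behaviour %in% BEHAVIOURS)
  if (any(x < 0)) stop("versatility values must be nonnegative",
                       call. = FALSE)
  if (behaviour %in% DIRECTED_BEHAVIOURS) as.numeric(x > 0) else x
}

#' Assemble the wide model table
#'
#' Inner-joins the partition-`t` responses (contact and proximity
#' versatility; binarized aggression, groom, play) with partition-`t-1`
#' lags and the dyadic covariates, for partitions 2-4. Errors on duplicate
#' (ego, alter, partition) rows.
#'
#' @param vers zero-populated versatility table.
#' @param demography validated demography.
#' @param ranks rank table covering the study years.
#' @param scheme `partition_scheme`.
#' @param adult_age own-rank age threshold.
#' @return data.frame, one row per ego-alter-partition with responses,
#'   lags, covariates and `partition_linear`.
#' @export
assemble_model_table <- function(vers, demography, ranks,
                                 scheme = partition_scheme(),
                                 adult_age = 3) {
  wide <- versatility_wide(vers)
  lags <- build_lags(vers)
  cur <- wide[wide$partition_index >= 2, , drop = FALSE]
  tab <- merge(cur, lags,
               by = c("ego_id", "alter_id", "partition_index"))
  key <- paste(tab$ego_id, tab$alter_id, tab$partition_index)
  if (anyDuplicated(key)) {
    stop("duplicate (ego, alter, partition) rows in model table",
         call. = FALSE)
  }
  if (!nrow(tab)) stop("model table is empty", call. = FALSE)

  # responses
  tab$contact_vers <- binarize_directed(tab$contact, "contact")
  tab$proximity_vers <- binarize_directed(tab$proximity, "proximity")
  tab$aggr_bin <- binarize_directed(tab$aggression, "aggression")
  tab$groom_bin <- binarize_directed(tab$groom, "groom")
  tab$play_bin <- binarize_directed(tab$play, "play")
  tab[BEHAVIOURS] <- NULL

  cov <- dyad_covariates_table(tab[, c("ego_id", "alter_id",
                                       "partition_index")],
                               demography, ranks, scheme, adult_age)
  tab <- cbind(tab, cov[, setdiff(names(cov), c("ego_id", "alter_id",
                                                "partition_index")),
                        drop = FALSE])
  tab$partition_linear <- as.numeric(tab$partition_index)
  stopifnot(!anyNA(tab))
  rownames(tab) <- NULL
  tab
}

# vectorized dyad_covariates over many rows (memoized rank lookups)
dyad_covariates_table <- function(pairs, demography, ranks,
                                  scheme = partition_scheme(),
                                  adult_age = 3) {
  ei <- match(pairs$ego_id, demography$animal_id)
  ai <- match(pairs$alter_id, demography$animal_id)
  stopifnot(!anyNA(ei), !anyNA(ai))
  # per (ego birth month, partition) midpoint
  ego_birth <- demography$birth_date[ei]
  mids <- as.Date(vapply(seq_len(nrow(pairs)), function(k) {
    win <- partition_window(scheme, pairs$partition_index[k], ego_birth[k])
    as.character(win[1] + as.numeric(win[2] - win[1]) / 2)
  }, character(1)))
  years <- as.integer(format(mids, "%Y"))
  memo <- new.env(parent = emptyenv())
  rank_of <- function(id, year) {
    kk <- paste0(id, "@", year)
    val <- memo[[kk]]
    if (is.null(val)) {
      val <- assign_rank(id, year, demography, ranks, adult_age)
      memo[[kk]] <- val
    }
    val
  }
  ego_rank <- vapply(seq_len(nrow(pairs)),
                     function(k) rank_of(pairs$ego_id[k], years[k]),
                     numeric(1))
  alter_rank <- vapply(seq_len(nrow(pairs)),
                       function(k) rank_of(pairs$alter_id[k], years[k]),
                       numeric(1))
  ego_age <- as.numeric(mids - ego_birth) / 365.25
  alter_age <- as.numeric(mids - demography$birth_date[ai]) / 365.25
  removal <- demography$removal_date[ai]
  min_part <- min(as.integer(names(scheme$partitions)))
  born_flag <- logical(nrow(pairs))
  removed_flag <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    win <- partition_window(scheme, pairs$partition_index[k], ego_birth[k])
    removed_flag[k] <- !is.na(removal[k]) && removal[k] >= win[1] &&
      removal[k] <= win[2]
    if (pairs$partition_index[k] > min_part) {
      pw <- partition_window(scheme, pairs$partition_index[k] - 1,
                             ego_birth[k])
      ab <- demography$birth_date[ai[k]]
      born_flag[k] <- ab >= pw[1] && ab <= pw[2]
    }
  }
  data.frame(
    ego_id = pairs$ego_id, alter_id = pairs$alter_id,
    partition_index = pairs$partition_index,
    rank_diff = abs(ego_rank - alter_rank),
    age_diff_years = abs(ego_age - alter_age),
    same_sex = demography$sex[ei] == demography$sex[ai],
    kinship = .kinship(ei, ai, demography),
    alter_born_flag = born_flag,
    alter_removed_flag = removed_flag,
    ego_cohort = demography$cohort[ei],
    ego_sex = demography$sex[ei],
    ego_maternal_rank = ego_rank,
    stringsAsFactors = FALSE)
}

#' Continuous model predictors
#'
#' The predictors centred and scaled by two standard deviations before
#' fitting; binary and factor predictors are left on their natural scale.
#' @return character vector of column names.
#' @export
continuous_predictors <- function() {
  c("ego_maternal_rank", "rank_diff", "age_diff_years", "partition_linear",
    paste0("lag_", BEHAVIOURS))
}

#' Centre and scale continuous predictors by two standard deviations
#'
#' Scaling by `2 * sd` puts continuous coefficients on a scale comparable
#' with untouched binary predictors.
#'
#' @param table model table from [assemble_model_table()].
#' @param predictors columns to scale (default [continuous_predictors()]).
#' @return list with `table` (scaled) and `scaling` (data.frame
#'   `predictor`, `mean`, `sd` for the inverse transform).
#' @export
scale_predictors <- function(table, predictors = continuous_predictors()) {
  miss <- setdiff(predictors, names(table))
  if (length(miss)) stop(sprintf("missing predictor column(s): %s",
                                 paste(miss, collapse = ", ")),
                         call. = FALSE)
  sc <- data.frame(predictor = predictors,
                   mean = vapply(predictors, function(p) mean(table[[p]]),
                                 numeric(1)),
                   sd = vapply(predictors, function(p) sd(table[[p]]),
                               numeric(1)),
                   row.names = NULL)
  zero <- sc$predictor[sc$sd == 0]
  if (length(zero)) {
    stop(sprintf("zero-variance predictor(s): %s",
                 paste(zero, collapse = ", ")), call. = FALSE)
  }
  for (k in seq_len(nrow(sc))) {
    p <- sc$predictor[k]
    table[[p]] <- (table[[p]] - sc$mean[k]) / (2 * sc$sd[k])
  }
  list(table = table, scaling = sc)
}
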