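# Descriptive monthly aggregates of the five behaviours and a delegated
# GAMM-style smoother for visualising developmental trends.

#' Monthly behavioural aggregates per ego
#'
#' For every (ego, month-of-life, behaviour):
#' `rate_by_focal` = scored intervals per session; `rate_by_dyad` = mean
#' per-dyad intervals per session; `partner_count` = distinct alters;
#' `given_total_ratio` = given / (given + received), defined only for
#' directed behaviours with at least one event (otherwise `NA`). Months
#' with sessions but no events of a behaviour report zero rates. Rates are
#' per session rather than per hour: sessions are fixed 10-minute follows,
#' so the two scales are proportional.
#'
#' @param db an `observation_db`.
#' @return data.frame of class `monthly_aggregates` with columns `ego_id`,
#'   `month_bin`, `behaviour`, `n_sessions`, `n_events`, `given`,
#'   `received`, `rate_by_focal`, `rate_by_dyad`, `partner_count`,
#'   `given_total_ratio`.
#' @export
monthly_aggregates <- function(db) {
  stopifnot(inherits(db, "observation_db"))
  egos <- focal_subjects(db$demography)
  f <- db$focals[db$focals$focal_id %in% egos, , drop = FALSE]
  if (!nrow(f)) stop("no focal records for focal subjects", call. = FALSE)
  birth <- db$demography$birth_date[match(f$focal_id,
                                          db$demography$animal_id)]
  f$month_bin <- month_of_life(f$session_date, birth)

  skey <- unique(f[, c("focal_id", "month_bin", "session_date",
                       "session_index")])
  sess <- aggregate(list(n_sessions = skey$session_date),
                    by = list(ego_id = skey$focal_id,
                              month_bin = skey$month_bin), FUN = length)

  rows <- list()
  for (b in BEHAVIOURS) {
    fb <- f[f$behaviour == b, , drop = FALSE]
    base <- sess
    base$behaviour <- b
    if (nrow(fb)) {
      ev <- aggregate(list(n_events = fb$interval_index),
                      by = list(ego_id = fb$focal_id,
                                month_bin = fb$month_bin), FUN = length)
      pc <- aggregate(list(partner_count = fb$partner_id),
                      by = list(ego_id = fb$focal_id,
                                month_bin = fb$month_bin),
                      FUN = function(x) length(unique(x)))
      gv <- aggregate(list(given = fb$direction == "given",
                           received = fb$direction == "received"),
                      by = list(ego_id = fb$focal_id,
                                month_bin = fb$month_bin), FUN = sum)
      base <- Reduce(function(a, b2) merge(a, b2, all.x = TRUE),
                     list(base, ev, pc, gv))
    } else {
      base$n_events <- 0L; base$partner_count <- 0L
      base$given <- 0L; base$received <- 0L
    }
    base$n_events[is.na(base$n_events)] <- 0L
    base$partner_count[is.na(base$partner_count)] <- 0L
    base$given[is.na(base$given)] <- 0L
    base$received[is.na(base$received)] <- 0L
    rows[[b]] <- base
  }
  out <- do.call(rbind, rows)
  out$rate_by_focal <- out$n_events / out$n_sessions
  out$rate_by_dyad <- ifelse(out$partner_count > 0,
                             out$n_events / (out$partner_count *
                                               out$n_sessions), 0)
  directed <- out$behaviour %in% DIRECTED_BEHAVIOURS
  tot <- out$given + out$received
  out$given_total_ratio <- ifelse(directed & tot > 0, out$given / tot,
                                  NA_real_)
  rownames(out) <- NULL
  class(out) <- c("monthly_aggregates", class(out))
  out
}

#' Smoothed developmental trend of an aggregate measure
#'
#' Penalized-spline smooth of month-of-life with ego as a random effect
#' (a GAMM in the `mgcv` sense, fitted by REML); only the aggregation
#' feeding the smoother is bespoke. With a single ego, or too few months
#' for a random effect, the model reduces to the fixed smooth.
#'
#' @param aggregates from [monthly_aggregates()].
#' @param behaviour one of [BEHAVIOURS].
#' @param measure column to smooth (e.g. `"rate_by_focal"`).
#' @return data.frame (`month_bin`, `fit`, `se`) over the observed months.
#' @export
smooth_trend <- function(aggregates, behaviour,
                         measure = c("rate_by_focal", "rate_by_dyad",
                                     "partner_count", "given_total_ratio")) {
  measure <- match.arg(measure)
  a <- aggregates[aggregates$behaviour == behaviour, , drop = FALSE]
  a <- a[!is.na(a[[measure]]), , drop = FALSE]
  if (length(unique(a$month_bin)) < 2) {
    stop("need at least 2 months of data to smooth", call. = FALSE)
  }
  a$y <- a[[measure]]
  a$ego <- factor(a$ego_id)
  months <- sort(unique(a$month_bin))
  if (sd(a$y) == 0) { # degenerate constant input: flat curve, no smoothing
    return(data.frame(month_bin = months, fit = a$y[1], se = 0))
  }
  k_s <- max(3, min(10, length(months) - 1))
  if (nlevels(a$ego) > 1) {
    m <- mgcv::gam(y ~ s(month_bin, k = k_s) + s(ego, bs = "re"), data = a,
                   method = "REML")
    new <- data.frame(month_bin = months, ego = a$ego[1])
    pr <- mgcv::predict.gam(m, new, se.fit = TRUE,
                            exclude = "s(ego)", newdata.guaranteed = TRUE)
  } else {
    m <- mgcv::gam(y ~ s(month_bin, k = k_s), data = a, method = "REML")
    new <- data.frame(month_bin = months)
    pr <- mgcv::predict.gam(m, new, se.fit = TRUE)
  }
  data.frame(month_bin = months, fit = as.numeric(pr$fit),
             se = as.numeric(pr$se.fit))
}
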