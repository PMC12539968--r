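# Monthly unilayer ego star networks and their aggregation into temporal
# multilayer (multiplex) networks per developmental partition.

#' Construct a unilayer ego network
#'
#' @param ego_id focal subject id.
#' @param behaviour one of [BEHAVIOURS].
#' @param month_bin month-of-life index (1 = first calendar month of life).
#' @param edges data.frame with columns `alter_id`, `direction`, `weight`
#'   (positive integer interval counts). For undirected behaviours
#'   `direction` is `"undirected"`; directed behaviours keep `"given"` /
#'   `"received"` weights separately.
#' @return object of class `unilayer_ego_network`.
#' @export
unilayer_ego_network <- function(ego_id, behaviour, month_bin, edges) {
  stopifnot(behaviour %in% BEHAVIOURS)
  directed <- behaviour %in% DIRECTED_BEHAVIOURS
  if (nrow(edges)) {
    stopifnot(all(c("alter_id", "direction", "weight") %in% names(edges)),
              all(edges$weight > 0),
              all(edges$alter_id != ego_id))
    if (directed) stopifnot(all(edges$direction %in% c("given", "received")))
    else stopifnot(all(edges$direction == "undirected"))
  } else {
    edges <- data.frame(alter_id = character(), direction = character(),
                        weight = numeric())
  }
  structure(list(ego_id = ego_id, behaviour = behaviour,
                 month_bin = as.integer(month_bin), directed = directed,
                 edges = edges),
            class = "unilayer_ego_network")
}

#' @export
print.unilayer_ego_network <- function(x, ...) {
  cat(sprintf("unilayer_ego_network: ego %s, %s, month %d, %d alter(s), total weight %g\n",
              x$ego_id, x$behaviour, x$month_bin,
              length(unique(x$edges$alter_id)), sum(x$edges$weight)))
  invisible(x)
}

#' Bin one ego's focal records into monthly unilayer networks
#'
#' One network per month-of-life with at least one focal session (a session
#' is a unique `(date, session_index)` pair, any behaviour). Edge weight is
#' the number of scored intervals for that dyad (and direction, for directed
#' behaviours) in the month. Months with sessions but no records of the
#' requested behaviour yield networks with empty edge sets, so downstream
#' layer counts reflect observation effort.
#'
#' @param db an `observation_db`.
#' @param ego ego id (must be a focal subject).
#' @param behaviour one of [BEHAVIOURS].
#' @return list of `unilayer_ego_network`, ordered by month.
#' @export
bin_focals_to_monthly <- function(db, ego, behaviour) {
  stopifnot(inherits(db, "observation_db"), behaviour %in% BEHAVIOURS)
  if (!ego %in% focal_subjects(db$demography)) {
    stop(sprintf("'%s' is not a focal subject", ego), call. = FALSE)
  }
  birth <- db$demography$birth_date[db$demography$animal_id == ego]
  f <- db$focals[db$focals$focal_id == ego, , drop = FALSE]
  if (!nrow(f)) return(list())
  f$month_bin <- month_of_life(f$session_date, birth)
  months <- sort(unique(f$month_bin))
  fb <- f[f$behaviour == behaviour, , drop = FALSE]
  lapply(months, function(m) {
    fm <- fb[fb$month_bin == m, , drop = FALSE]
    if (nrow(fm)) {
      agg <- aggregate(list(weight = fm$interval_index),
                       by = list(alter_id = fm$partner_id,
                                 direction = fm$direction),
                       FUN = length)
      agg <- agg[order(agg$alter_id, agg$direction), , drop = FALSE]
      rownames(agg) <- NULL
    } else {
      agg <- data.frame(alter_id = character(), direction = character(),
                        weight = numeric())
    }
    unilayer_ego_network(ego, behaviour, m, agg)
  })
}

#' Remove over-age alters from a unilayer network
#'
#' Alters more than `max_age` years old in the ego cohort's birth year are
#' excluded, so retained alters are age peers (0-6 years old across a
#' three-year study). Age in the birth year is `cohort_birth_year` minus the
#' alter's birth year; the boundary is strict exceedance (an alter aged
#' exactly `max_age` is retained).
#'
#' @param net a `unilayer_ego_network`.
#' @param demography validated demography table.
#' @param cohort_birth_year integer, e.g. 2016.
#' @param max_age age cutoff in years (default 3).
#' @return the filtered network.
#' @export
filter_alters <- function(net, demography, cohort_birth_year, max_age = 3) {
  if (!nrow(net$edges)) return(net)
  idx <- match(net$edges$alter_id, demography$animal_id)
  if (anyNA(idx)) {
    stop(sprintf("alter(s) not in demography: %s",
                 paste(unique(net$edges$alter_id[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  birth_year <- as.integer(format(demography$birth_date[idx], "%Y"))
  keep <- (cohort_birth_year - birth_year) <= max_age
  net$edges <- net$edges[keep, , drop = FALSE]
  rownames(net$edges) <- NULL
  net
}

#' Developmental partition scheme
#'
#' Maps month-of-life bins to four ordered developmental partitions. The
#' default follows the study design: months 1-6, months 7-12, the second
#' year and the third year (observation is bimonthly after the first year,
#' so the two later partitions also realise about six monthly bins each).
#'
#' @param partitions named list: partition index -> integer month bins.
#' @return object of class `partition_scheme`.
#' @export
partition_scheme <- function(partitions = list(`1` = 1:6, `2` = 7:12,
                                               `3` = 13:24, `4` = 25:36)) {
  bins <- unlist(partitions, use.names = FALSE)
  if (anyDuplicated(bins)) {
    stop("partitions overlap: each month bin may appear in one partition only",
         call. = FALSE)
  }
  if (is.null(names(partitions))) names(partitions) <- seq_along(partitions)
  idx <- as.integer(names(partitions))
  stopifnot(!anyNA(idx), all(diff(idx) > 0))
  structure(list(partitions = partitions), class = "partition_scheme")
}

#' Partition index of a month bin
#' @param scheme a `partition_scheme`.
#' @param month_bin integer vector.
#' @return integer partition indices (NA if uncovered).
#' @export
partition_of <- function(scheme, month_bin) {
  out <- rep(NA_integer_, length(month_bin))
  for (p in names(scheme$partitions)) {
    out[month_bin %in% scheme$partitions[[p]]] <- as.integer(p)
  }
  out
}

#' Calendar window of a partition for one ego
#'
#' First and last calendar date of the partition's month-of-life bins,
#' relative to the ego's birth month.
#' @param scheme a `partition_scheme`.
#' @param partition_index integer.
#' @param birth_date the ego's birth date.
#' @return `Date` vector `c(start, end)`.
#' @export
partition_window <- function(scheme, partition_index, birth_date) {
  bins <- scheme$partitions[[as.character(partition_index)]]
  b <- as.POSIXlt(birth_date)
  start <- as.Date(sprintf("%04d-%02d-01",
                           1900 + b$year + (b$mon + min(bins) - 1) %/% 12,
                           (b$mon + min(bins) - 1) %% 12 + 1))
  endm <- as.Date(sprintf("%04d-%02d-01",
                          1900 + b$year + (b$mon + max(bins)) %/% 12,
                          (b$mon + max(bins)) %% 12 + 1))
  c(start, endm - 1)
}

#' Assemble monthly networks into multilayer ego networks
#'
#' One `multilayer_ego_network` per (ego, behaviour, partition) with at
#' least one realised monthly layer; partitions with no observed months are
#' absent, so realised networks can number fewer than the potential
#' `egos x behaviours x partitions`.
#'
#' @param monthly_nets list of `unilayer_ego_network` for one ego and
#'   behaviour (as from [bin_focals_to_monthly()]).
#' @param scheme a `partition_scheme`.
#' @return named list of `multilayer_ego_network` keyed by partition index.
#' @export
assemble_partitions <- function(monthly_nets, scheme) {
  if (!length(monthly_nets)) return(list())
  months <- vapply(monthly_nets, `[[`, integer(1), "month_bin")
  parts <- partition_of(scheme, months)
  if (anyNA(parts)) {
    stop(sprintf("month bin(s) %s not covered by the partition scheme",
                 paste(unique(months[is.na(parts)]), collapse = ", ")),
         call. = FALSE)
  }
  ego_id <- monthly_nets[[1]]$ego_id
  behaviour <- monthly_nets[[1]]$behaviour
  out <- list()
  for (p in sort(unique(parts))) {
    layers <- monthly_nets[parts == p]
    layers <- layers[order(vapply(layers, `[[`, integer(1), "month_bin"))]
    alters <- unique(unlist(lapply(layers, function(l) l$edges$alter_id)))
    net <- structure(list(ego_id = ego_id, behaviour = behaviour,
                          partition_index = p, layers = layers,
                          node_set = c(ego_id, sort(alters))),
                     class = "multilayer_ego_network")
    out[[as.character(p)]] <- net
  }
  out
}

#' @export
print.multilayer_ego_network <- function(x, ...) {
  cat(sprintf("multilayer_ego_network: ego %s, %s, partition %d, %d layer(s), %d node(s)\n",
              x$ego_id, x$behaviour, x$partition_index, length(x$layers),
              length(x$node_set)))
  invisible(x)
}

#' Build all multilayer ego networks in a database
#'
#' Convenience driver: bins, filters over-age alters per the ego's cohort
#' and assembles partitions for every (focal subject, behaviour).
#'
#' @param db an `observation_db`.
#' @param scheme a `partition_scheme`.
#' @param max_alter_age alter age cutoff passed to [filter_alters()].
#' @return list of `multilayer_ego_network`.
#' @export
build_ego_networks <- function(db, scheme = partition_scheme(),
                               max_alter_age = 3) {
  egos <- focal_subjects(db$demography)
  out <- list()
  for (ego in egos) {
    cohort <- db$demography$cohort[db$demography$animal_id == ego]
    cohort_year <- as.integer(cohort)
    for (b in BEHAVIOURS) {
      nets <- bin_focals_to_monthly(db, ego, b)
      nets <- lapply(nets, filter_alters, demography = db$demography,
                     cohort_birth_year = cohort_year, max_age = max_alter_age)
      out <- c(out, unname(assemble_partitions(nets, scheme)))
    }
  }
  out
}

#' Serialize networks to an edge-list data.frame
#'
#' @param nets list of `multilayer_ego_network`.
#' @return data.frame with one row per (layer, edge): `ego_id`, `behaviour`,
#'   `partition_index`, `month_bin`, `alter_id`, `direction`, `weight`.
#' @export
networks_edge_list <- function(nets) {
  rows <- lapply(nets, function(mn) {
    do.call(rbind, lapply(mn$layers, function(l) {
      if (!nrow(l$edges)) return(NULL)
      data.frame(ego_id = mn$ego_id, behaviour = mn$behaviour,
                 partition_index = mn$partition_index,
                 month_bin = l$month_bin, l$edges)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(ego_id = character(), behaviour = character(),
                      partition_index = integer(), month_bin = integer(),
                      alter_id = character(), direction = character(),
                      weight = numeric())
  }
  rownames(out) <- NULL
  out
}
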