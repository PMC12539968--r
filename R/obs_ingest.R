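# Ingestion and validation of the three observation tables: interval-scored
# focal records, demography, and dyadic dominance bouts. All files are plain
# CSV with a header row, ISO-8601 dates, UTF-8.

.parse_date <- function(x, what, allow_na = FALSE) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- is.na(d) & !(allow_na & (is.na(x) | !nzchar(as.character(x))))
  if (any(bad)) {
    stop(sprintf("invalid %s date(s) at row(s) %s (expected YYYY-MM-DD)",
                 what, paste(utils::head(which(bad), 5), collapse = ", ")),
         call. = FALSE)
  }
  d
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}

#' Read interval-scored focal observation records
#'
#' One row per scored 30 s interval mark: state behaviours (`contact`,
#' `proximity`) are sampled on the mark, directed behaviours (`aggression`,
#' `groom`, `play`) are scored per unique dyad interacting during the
#' interval, with direction recorded from the focal's perspective.
#'
#' @param path CSV file with columns `focal_id`, `session_date`,
#'   `session_index`, `interval_index`, `behaviour`, `partner_id`,
#'   `direction`.
#' @return A `data.frame` of validated focal records with `session_date` as
#'   `Date` and integer indices.
#' @export
read_focals <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_focals(df)
}

#' @rdname read_focals
#' @param focals data.frame of raw focal records to validate in place.
#' @export
validate_focals <- function(focals) {
  df <- focals
  .require_cols(df, c("focal_id", "session_date", "session_index",
                      "interval_index", "behaviour", "partner_id",
                      "direction"), "focal table")
  df$focal_id <- as.character(df$focal_id)
  df$partner_id <- as.character(df$partner_id)
  df$session_date <- .parse_date(df$session_date, "session")
  df$session_index <- as.integer(df$session_index)
  df$interval_index <- as.integer(df$interval_index)
  df$behaviour <- as.character(df$behaviour)
  df$direction <- as.character(df$direction)

  bad <- which(!df$behaviour %in% BEHAVIOURS)
  if (length(bad)) {
    stop(sprintf("unknown behaviour code '%s' at row %d; valid codes: %s",
                 df$behaviour[bad[1]], bad[1],
                 paste(BEHAVIOURS, collapse = ", ")), call. = FALSE)
  }
  bad <- which(df$interval_index < 0L |
                 df$interval_index >= INTERVALS_PER_SESSION)
  if (length(bad)) {
    stop(sprintf("interval_index outside 0..%d at row %d",
                 INTERVALS_PER_SESSION - 1L, bad[1]), call. = FALSE)
  }
  bad <- which(df$session_index < 0L)
  if (length(bad)) {
    stop(sprintf("negative session_index at row %d", bad[1]), call. = FALSE)
  }
  und <- df$behaviour %in% UNDIRECTED_BEHAVIOURS
  bad <- which(und & df$direction != "undirected")
  if (length(bad)) {
    stop(sprintf("state behaviour with direction '%s' at row %d (must be 'undirected')",
                 df$direction[bad[1]], bad[1]), call. = FALSE)
  }
  bad <- which(!und & !df$direction %in% c("given", "received"))
  if (length(bad)) {
    stop(sprintf("directed behaviour with direction '%s' at row %d (must be 'given' or 'received')",
                 df$direction[bad[1]], bad[1]), call. = FALSE)
  }
  key <- paste(df$focal_id, df$session_date, df$session_index,
               df$interval_index, df$behaviour, df$partner_id, df$direction)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate focal record at row %d", which(duplicated(key))[1]),
         call. = FALSE)
  }
  df
}

#' Write focal records to CSV
#' @param focals validated focal records.
#' @param path output file.
#' @export
write_focals <- function(focals, path) {
  out <- focals
  out$session_date <- format(out$session_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the demography table
#'
#' @param path CSV with columns `animal_id`, `sex` (F/M), `birth_date`,
#'   `matriline_id`, `mother_id` (may be empty), `removal_date` (may be
#'   empty), `cohort` (`2016`, `2017` for focal subjects, `other` otherwise).
#' @return validated `data.frame`, one row per animal.
#' @export
read_demography <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_demography(df)
}

#' @rdname read_demography
#' @param demography data.frame of raw demography rows.
#' @export
validate_demography <- function(demography) {
  df <- demography
  .require_cols(df, c("animal_id", "sex", "birth_date", "matriline_id",
                      "mother_id", "removal_date", "cohort"),
                "demography table")
  df$animal_id <- as.character(df$animal_id)
  if (anyDuplicated(df$animal_id)) {
    stop(sprintf("duplicate animal_id '%s' in demography",
                 df$animal_id[duplicated(df$animal_id)][1]), call. = FALSE)
  }
  df$sex <- as.character(df$sex)
  if (any(!df$sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M'", call. = FALSE)
  }
  df$birth_date <- .parse_date(df$birth_date, "birth")
  df$matriline_id <- as.character(df$matriline_id)
  df$mother_id <- as.character(df$mother_id)
  df$mother_id[!nzchar(df$mother_id) | is.na(df$mother_id)] <- NA_character_
  rd <- as.character(df$removal_date)
  rd[is.na(rd) | !nzchar(rd)] <- NA
  df$removal_date <- as.Date(rd, format = "%Y-%m-%d")
  bad <- which(!is.na(df$removal_date) & df$removal_date < df$birth_date)
  if (length(bad)) {
    stop(sprintf("removal_date before birth_date for animal '%s'",
                 df$animal_id[bad[1]]), call. = FALSE)
  }
  df$cohort <- as.character(df$cohort)
  if (any(!df$cohort %in% c("2016", "2017", "other"))) {
    stop("cohort must be one of '2016', '2017', 'other'", call. = FALSE)
  }
  df
}

#' Read dyadic dominance bout records
#'
#' Event-sampled decided dominance interactions (status signalling and
#' dyadic aggression) used to estimate yearly hierarchies.
#' @param path CSV with columns `winner_id`, `loser_id`, `date`.
#' @return validated `data.frame`.
#' @export
read_bouts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_bouts(df)
}

#' @rdname read_bouts
#' @param bouts data.frame of raw bout rows.
#' @export
validate_bouts <- function(bouts) {
  df <- bouts
  .require_cols(df, c("winner_id", "loser_id", "date"), "bout table")
  df$winner_id <- as.character(df$winner_id)
  df$loser_id <- as.character(df$loser_id)
  df$date <- .parse_date(df$date, "bout")
  bad <- which(df$winner_id == df$loser_id)
  if (length(bad)) {
    stop(sprintf("bout with winner == loser at row %d", bad[1]), call. = FALSE)
  }
  df
}

#' Assemble an observation database
#'
#' Bundles the three validated tables. Referential integrity (every id in
#' focals/bouts present in demography) is checked by [validate_db()], which
#' reports rather than errors, so partially dirty data can be inspected.
#'
#' @param focals validated focal records ([read_focals()]).
#' @param demography validated demography ([read_demography()]).
#' @param bouts validated bouts ([read_bouts()]); may be empty.
#' @return an object of class `observation_db`.
#' @export
observation_db <- function(focals, demography,
                           bouts = data.frame(winner_id = character(),
                                              loser_id = character(),
                                              date = as.Date(character()))) {
  db <- list(focals = validate_focals(focals),
             demography = validate_demography(demography),
             bouts = validate_bouts(bouts))
  class(db) <- "observation_db"
  db
}

#' @export
print.observation_db <- function(x, ...) {
  egos <- focal_subjects(x$demography)
  cat(sprintf("observation_db: %d focal records, %d animals (%d focal subjects), %d bouts\n",
              nrow(x$focals), nrow(x$demography), length(egos),
              nrow(x$bouts)))
  invisible(x)
}

#' Focal subject (ego) identifiers
#'
#' Egos are exactly the animals in the two study birth cohorts.
#' @param demography validated demography table.
#' @return character vector of ids.
#' @export
focal_subjects <- function(demography) {
  demography$animal_id[demography$cohort %in% c("2016", "2017")]
}

#' Month-of-life bin of a date
#'
#' Bin 1 is the calendar month containing the birth date; bins advance with
#' calendar months, so developmental partitions line up with relative age.
#' @param date,birth_date `Date` vectors (recycled).
#' @return integer bins.
#' @export
month_of_life <- function(date, birth_date) {
  d <- as.POSIXlt(date); b <- as.POSIXlt(birth_date)
  12L * (d$year - b$year) + (d$mon - b$mon) + 1L
}

#' Validate an observation database
#'
#' Report-only integrity check: lists referential violations (ids in focals
#' or bouts absent from demography, focal partners equal to the focal) and
#' tabulates focal sessions per ego per month-of-life, flagging sessions
#' shorter than the full 20 intervals is not possible from interval-scored
#' records alone, so short sessions are inferred where a session has fewer
#' than one scored state mark (informational only).
#'
#' @param db an `observation_db`.
#' @return list of class `db_validation` with `violations` (data.frame:
#'   `type`, `detail`) and `session_counts` (data.frame: `ego_id`,
#'   `month_bin`, `n_sessions`).
#' @export
validate_db <- function(db) {
  stopifnot(inherits(db, "observation_db"))
  f <- db$focals; dem <- db$demography; bt <- db$bouts
  viol <- list()
  known <- dem$animal_id
  miss_f <- setdiff(unique(c(f$focal_id, f$partner_id)), known)
  if (length(miss_f)) {
    viol[[length(viol) + 1L]] <- data.frame(
      type = "unknown_id_in_focals", detail = miss_f)
  }
  miss_b <- setdiff(unique(c(bt$winner_id, bt$loser_id)), known)
  if (length(miss_b)) {
    viol[[length(viol) + 1L]] <- data.frame(
      type = "unknown_id_in_bouts", detail = miss_b)
  }
  self <- unique(f$focal_id[f$focal_id == f$partner_id])
  if (length(self)) {
    viol[[length(viol) + 1L]] <- data.frame(
      type = "self_partner", detail = self)
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(type = character(), detail = character())

  egos <- focal_subjects(dem)
  fe <- f[f$focal_id %in% egos, , drop = FALSE]
  if (nrow(fe)) {
    birth <- dem$birth_date[match(fe$focal_id, dem$animal_id)]
    fe$month_bin <- month_of_life(fe$session_date, birth)
    key <- unique(fe[, c("focal_id", "month_bin", "session_date",
                         "session_index")])
    session_counts <- aggregate(
      list(n_sessions = key$session_date),
      by = list(ego_id = key$focal_id, month_bin = key$month_bin),
      FUN = length)
  } else {
    session_counts <- data.frame(ego_id = character(),
                                 month_bin = integer(),
                                 n_sessions = integer())
  }
  out <- list(violations = violations, session_counts = session_counts)
  class(out) <- "db_validation"
  out
}

#' @export
print.db_validation <- function(x, ...) {
  cat(sprintf("db_validation: %d violation(s), session counts for %d ego-months\n",
              nrow(x$violations), nrow(x$session_counts)))
  if (nrow(x$violations)) print(utils::head(x$violations, 10))
  invisible(x)
}
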