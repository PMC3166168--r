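#' Scan-sampled group observations
#'
#' An `observation_set` holds repeated scan samples of group membership for a
#' closed population of individually recognisable animals: in each sampling
#' period (identified by study day and within-day minute) every observed
#' group is recorded as a set of individual ids. Singleton "groups" are
#' legitimate observations of a lone individual and are retained; they
#' contribute to the denominator of association indices and to
#' gregariousness (with experienced group size 1).
#'
#' @param records data.frame with columns `day` (integer), `minute`
#'   (integer), `group_id` (label, unique within a period), `individual_id`
#'   (label); one row per (group, member).
#' @param individuals optional character vector of all individual ids in the
#'   population. Defaults to the ids appearing in `records`. Individuals
#'   never observed are allowed (they are simply absent from every period).
#'
#' @return An object of class `observation_set` with components:
#'   `individuals` (character), `periods` (data.frame `index`, `day`,
#'   `minute`, ordered by (day, minute)), `records` (data.frame `period`,
#'   `group_id`, `individual_id`), and `N` (population size).
#' @export
observation_set <- function(records, individuals = NULL) {
  stopifnot(is.data.frame(records))
  needed <- c("day", "minute", "group_id", "individual_id")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("observation records lack column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  records$day <- as.integer(records$day)
  records$minute <- as.integer(records$minute)
  records$group_id <- as.character(records$group_id)
  records$individual_id <- as.character(records$individual_id)

  if (is.null(individuals)) {
    individuals <- sort(unique(records$individual_id))
  } else {
    individuals <- as.character(individuals)
    if (anyDuplicated(individuals)) stop("duplicate individual ids")
    unknown <- setdiff(records$individual_id, individuals)
    if (length(unknown) > 0) {
      stop("record member(s) not in population: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (length(individuals) < 2) stop("need at least 2 individuals")

  per_key <- paste(records$day, records$minute, sep = "\r")
  uk <- unique(per_key[order(records$day, records$minute)])
  periods <- data.frame(
    index = seq_along(uk),
    day = as.integer(sub("\r.*", "", uk)),
    minute = as.integer(sub(".*\r", "", uk))
  )
  period_of <- match(per_key, uk)

  # within one period each individual may appear in at most one group
  pi_key <- paste(period_of, records$individual_id)
  if (anyDuplicated(pi_key)) {
    bad <- which(duplicated(pi_key))[1]
    stop(sprintf(
      "individual '%s' appears more than once in period day=%d minute=%d (row %d)",
      records$individual_id[bad], records$day[bad], records$minute[bad], bad))
  }

  out <- list(
    individuals = individuals,
    periods = periods,
    records = data.frame(
      period = period_of,
      group_id = records$group_id,
      individual_id = records$individual_id,
      stringsAsFactors = FALSE
    ),
    N = length(individuals)
  )
  class(out) <- "observation_set"
  out
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf(
    "observation_set: %d individuals, %d sampling periods over %d day(s), %d group-membership rows\n",
    x$N, nrow(x$periods), length(unique(x$periods$day)), nrow(x$records)))
  invisible(x)
}

#' Number of sampling periods
#' @param obs an [observation_set()]
#' @return integer count of sampling periods
#' @export
n_periods <- function(obs) nrow(obs$periods)

#' Read scan-sample observations from CSV
#'
#' Expects a UTF-8 CSV with header `day,minute,group_id,individual_id`, one
#' row per (group, member). Validation errors name the offending row.
#'
#' @param path file path
#' @param individuals optional full population id vector (see
#'   [observation_set()])
#' @return an [observation_set()]
#' @export
read_observations <- function(path, individuals = NULL) {
  if (!file.exists(path)) stop("observation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  observation_set(df, individuals = individuals)
}

#' Write observations to CSV
#'
#' Rows are emitted sorted by (day, minute, group_id) so that
#' `read_observations(write_observations(obs))` round-trips.
#'
#' @param obs an [observation_set()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_observations <- function(obs, path) {
  df <- data.frame(
    day = obs$periods$day[obs$records$period],
    minute = obs$periods$minute[obs$records$period],
    group_id = obs$records$group_id,
    individual_id = obs$records$individual_id
  )
  df <- df[order(df$day, df$minute, df$group_id, df$individual_id), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Group-by-individual (GBI) matrix
#'
#' Converts an observation set to the binary group-by-individual matrix used
#' by the swap permutation null models: one row per observed group, one
#' column per individual, 1 when the individual was a member. Row names are
#' `d<day>_m<minute>_<group_id>`; the sampling period and study day of each
#' row are attached as attributes `period` and `day`.
#'
#' @param obs an [observation_set()]
#' @return integer matrix with attributes `period` and `day` (one entry per
#'   row)
#' @export
to_gbi <- function(obs) {
  rec <- obs$records
  gkey <- paste(rec$period, rec$group_id, sep = "\r")
  ord <- order(rec$period, rec$group_id)
  ug <- unique(gkey[ord])
  gi <- match(gkey, ug)
  m <- matrix(0L, nrow = length(ug), ncol = obs$N,
              dimnames = list(NULL, obs$individuals))
  m[cbind(gi, match(rec$individual_id, obs$individuals))] <- 1L
  g_period <- as.integer(sub("\r.*", "", ug))
  g_id <- sub(".*\r", "", ug)
  rownames(m) <- sprintf("d%d_m%d_%s",
                         obs$periods$day[g_period],
                         obs$periods$minute[g_period], g_id)
  attr(m, "period") <- g_period
  attr(m, "day") <- obs$periods$day[g_period]
  m
}

#' Per-period group membership matrix
#'
#' Internal canonical layout for fast dyadic computations: an integer matrix
#' with one row per sampling period and one column per individual, holding
#' the within-period group code (NA when the individual was not observed in
#' that period).
#'
#' @param obs an [observation_set()]
#' @return integer matrix (periods x individuals) of group codes, NA = not
#'   observed
#' @export
membership_matrix <- function(obs) {
  rec <- obs$records
  m <- matrix(NA_integer_, nrow = nrow(obs$periods), ncol = obs$N,
              dimnames = list(NULL, obs$individuals))
  gcode <- as.integer(factor(paste(rec$period, rec$group_id, sep = "\r")))
  m[cbind(rec$period, match(rec$individual_id, obs$individuals))] <- gcode
  m
}

#' Dyadic count data for an association index
#'
#' For a dyad (i, j): `x` = periods in which i and j were in the same group;
#' `y_AB` = periods both were observed but in different groups; `y_A`
#' (`y_B`) = periods in which only i (only j) was observed. Under complete
#' detection `x + y_AB` equals the number of sampling periods.
#'
#' @param obs an [observation_set()]
#' @param i,j individual ids (distinct)
#' @return named integer vector `c(x, y_AB, y_A, y_B)`
#' @export
dyad_counts <- function(obs, i, j) {
  if (identical(i, j)) stop("dyad requires two distinct individuals")
  if (!all(c(i, j) %in% obs$individuals)) {
    stop("unknown individual id(s): ",
         paste(setdiff(c(i, j), obs$individuals), collapse = ", "))
  }
  m <- membership_matrix(obs)
  gi <- m[, i]
  gj <- m[, j]
  both <- !is.na(gi) & !is.na(gj)
  x <- sum(both & gi == gj)
  y_ab <- sum(both) - x
  y_a <- sum(!is.na(gi) & is.na(gj))
  y_b <- sum(is.na(gi) & !is.na(gj))
  c(x = x, y_AB = y_ab, y_A = y_a, y_B = y_b)
}
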