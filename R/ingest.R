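#' Define an age-group scheme from bin boundaries
#'
#' Age groups are closed-open intervals `[lower, upper)`; the last bin is
#' always open-ended. Boundaries follow the demographic bracket convention,
#' so breaks `c(35, 45, 55)` produce groups labelled `"35-44"`, `"45-54"`
#' and `"55+"`.
#'
#' @param breaks Integer vector of strictly increasing lower bin boundaries,
#'   in years. The first element is the lowest age covered by the scheme;
#'   each subsequent element opens a new bin. At least two breaks are
#'   required (two bins: `[b1, b2)` and `[b2, Inf)`).
#' @return An object of class `age_scheme`: a list with integer vectors
#'   `lower` and `upper` (last upper is `Inf`) and character `labels`.
#' @examples
#' parse_age_scheme(c(0, 35, 45, 65))   # 0-34, 35-44, 45-64, 65+
#' @export
parse_age_scheme <- function(breaks) {
  breaks <- as.numeric(breaks)
  if (length(breaks) < 2)
    stop("age scheme needs at least 2 breaks (2 bins)", call. = FALSE)
  if (anyNA(breaks) || any(breaks < 0))
    stop("age breaks must be nonnegative numbers", call. = FALSE)
  d <- diff(breaks)
  if (any(d <= 0)) {
    k <- which(d <= 0)[1]
    stop(sprintf("age breaks must be strictly increasing: %g >= %g at positions %d,%d",
                 breaks[k], breaks[k + 1], k, k + 1), call. = FALSE)
  }
  lower <- breaks
  upper <- c(breaks[-1], Inf)
  labels <- ifelse(is.finite(upper),
                   paste0(lower, "-", upper - 1),
                   paste0(lower, "+"))
  structure(list(lower = lower, upper = upper, labels = labels),
            class = "age_scheme")
}

#' @export
print.age_scheme <- function(x, ...) {
  cat("Age-group scheme:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.age_scheme <- function(x) length(x$lower)

#' Assign ages to age-group indices
#'
#' @param age Integer vector of ages in years.
#' @param scheme An [parse_age_scheme()] object.
#' @return Integer vector of 1-based age-group indices.
#' @export
bin_age <- function(age, scheme) {
  stopifnot(inherits(scheme, "age_scheme"))
  if (any(age < scheme$lower[1]))
    stop(sprintf("age %s below the scheme's lowest bound %g",
                 paste(unique(age[age < scheme$lower[1]]), collapse = ","),
                 scheme$lower[1]), call. = FALSE)
  # findInterval implements the closed-open convention directly
  findInterval(age, scheme$lower)
}

#' Parse age-group labels of the form "35-44" or "85+" against a scheme
#'
#' @param labels Character vector of bin labels.
#' @param scheme An `age_scheme`.
#' @return Integer vector of age-group indices.
#' @keywords internal
match_age_labels <- function(labels, scheme) {
  idx <- match(trimws(labels), scheme$labels)
  if (anyNA(idx))
    stop(sprintf("age-group label(s) not in scheme [%s]: %s",
                 paste(scheme$labels, collapse = ", "),
                 paste(unique(labels[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  idx
}

#' Normalize a standard population into age weights
#'
#' Direct age-standardization weights each age-specific rate by the share of
#' a standard population (e.g. the 2010 US standard) in that age group.
#'
#' @param counts Nonnegative numeric vector, one count (or weight) per age
#'   group, at least one positive.
#' @return Numeric vector of weights summing to 1.
#' @export
normalize_standard <- function(counts) {
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0))
    stop("standard-population counts must be nonnegative", call. = FALSE)
  s <- sum(counts)
  if (s <= 0)
    stop("standard-population counts are all zero", call. = FALSE)
  counts / s
}

#' Aggregate record-level events into a region x age-group count cube
#'
#' Builds the sufficient statistics of the Poisson rate model: event counts
#' `y[i, j]` and person-years `n[i, j]` for every region `i` and age group
#' `j`. Regions appearing in the population table with zero events are kept
#' with `y = 0`; events in a region absent from the population table are an
#' error.
#'
#' @param events Data frame with columns `region_id` (character) and `age`
#'   (integer years), one row per event. May have zero rows.
#' @param pop Data frame with columns `region_id`, `age_group` (bin label
#'   matching the scheme, e.g. `"35-44"`, `"85+"`) and `population`
#'   (positive person-years). Must be rectangular: every region x age-group
#'   combination exactly once.
#' @param scheme An [parse_age_scheme()] object.
#' @param observation_years Multiplier converting population counts into
#'   person-years (number of years the events span). Default 1.
#' @return An object of class `count_cube`: list with integer matrix `y`,
#'   numeric matrix `n` (regions x age groups, dimnames set), `region_ids`,
#'   and `scheme`.
#' @export
aggregate_events <- function(events, pop, scheme, observation_years = 1) {
  stopifnot(inherits(scheme, "age_scheme"))
  if (!all(c("region_id", "age_group", "population") %in% names(pop)))
    stop("population table needs columns region_id, age_group, population",
         call. = FALSE)
  if (!is.numeric(observation_years) || observation_years <= 0)
    stop("observation_years must be positive", call. = FALSE)

  pop$region_id <- as.character(pop$region_id)
  regions <- sort(unique(pop$region_id))
  J <- length(scheme)
  jdx <- match_age_labels(pop$age_group, scheme)
  key <- paste(pop$region_id, jdx, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- pop[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate population row for region %s, age group %s",
                 dup$region_id, dup$age_group), call. = FALSE)
  }
  if (length(key) != length(regions) * J)
    stop(sprintf("population table is not rectangular: %d rows for %d regions x %d age groups",
                 length(key), length(regions), J), call. = FALSE)
  if (anyNA(pop$population) || any(pop$population <= 0))
    stop("population must be positive in every region x age-group cell",
         call. = FALSE)

  n <- matrix(NA_real_, length(regions), J,
              dimnames = list(regions, scheme$labels))
  n[cbind(match(pop$region_id, regions), jdx)] <-
    pop$population * observation_years

  y <- matrix(0L, length(regions), J, dimnames = dimnames(n))
  if (nrow(events) > 0) {
    if (!all(c("region_id", "age") %in% names(events)))
      stop("event table needs columns region_id, age", call. = FALSE)
    ev_region <- as.character(events$region_id)
    if (any(!nzchar(ev_region)) || anyNA(ev_region))
      stop("event region_id must be non-empty", call. = FALSE)
    unknown <- setdiff(unique(ev_region), regions)
    if (length(unknown) > 0)
      stop(sprintf("event region_id(s) missing from population table: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    bad_age <- which(is.na(events$age) | events$age < scheme$lower[1])
    if (length(bad_age) > 0)
      stop(sprintf("event age out of scheme range at row(s) %s",
                   paste(utils::head(bad_age, 5), collapse = ", ")),
           call. = FALSE)
    jev <- bin_age(events$age, scheme)
    tab <- table(factor(ev_region, levels = regions),
                 factor(jev, levels = seq_len(J)))
    y[] <- as.integer(tab)
  }

  structure(list(y = y, n = n, region_ids = regions, scheme = scheme),
            class = "count_cube")
}

#' @export
print.count_cube <- function(x, ...) {
  cat(sprintf("count_cube: %d regions x %d age groups, %d events, %s person-years\n",
              nrow(x$y), ncol(x$y), sum(x$y), format(sum(x$n), big.mark = ",")))
  invisible(x)
}

#' Read a record-level events CSV
#'
#' Required columns `region_id,age`; extra columns are ignored with a
#' warning.
#' @param path Path to the CSV file.
#' @return Data frame with columns `region_id`, `age`.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, colClasses = c(region_id = "character"))
  if (!all(c("region_id", "age") %in% names(df)))
    stop(sprintf("%s: events CSV needs columns region_id, age", path),
         call. = FALSE)
  extra <- setdiff(names(df), c("region_id", "age"))
  if (length(extra) > 0)
    warning(sprintf("ignoring extra event columns: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  df[c("region_id", "age")]
}

#' Read a region x age-group population CSV
#'
#' Columns `region_id,age_group,population`; `age_group` is the bin label
#' `"lower-upper"` or `"lower+"`.
#' @param path Path to the CSV file.
#' @return Data frame with the three required columns.
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path, colClasses = c(region_id = "character"))
  need <- c("region_id", "age_group", "population")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: population CSV needs columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  df[need]
}

#' Read a standard-population CSV and derive age weights
#'
#' Columns `age_group,population`. Rows are matched to the scheme's bins by
#' label and the counts normalized to weights.
#' @param path Path to the CSV file.
#' @param scheme An `age_scheme` the labels must match.
#' @return Numeric weight vector (one per age group, sums to 1).
#' @export
read_standard <- function(path, scheme) {
  df <- utils::read.csv(path)
  if (!all(c("age_group", "population") %in% names(df)))
    stop(sprintf("%s: standard-population CSV needs columns age_group, population",
                 path), call. = FALSE)
  idx <- match_age_labels(df$age_group, scheme)
  if (anyDuplicated(idx))
    stop(sprintf("%s: duplicate age-group rows in standard population", path),
         call. = FALSE)
  if (length(idx) != length(scheme))
    stop(sprintf("%s: standard population covers %d of %d age groups",
                 path, length(idx), length(scheme)), call. = FALSE)
  counts <- numeric(length(scheme))
  counts[idx] <- df$population
  normalize_standard(counts)
}
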