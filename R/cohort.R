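#' Cause maps: named sets of ICD-9-CM code patterns
#'
#' A cause map associates each cause name (e.g. "alcohol") with a set of
#' ICD-9-CM patterns. A pattern is either a full code ("304.30") or a
#' prefix at any dot-free granularity: "304.3" matches 304.30-304.39,
#' "304" matches the whole 304.xx block. Matching ignores the decimal
#' point, mirroring how grouper software specifies code blocks at mixed
#' granularity.
#'
#' @param x Named list; each element a character vector of patterns.
#' @return Object of class `cause_map`.
#' @export
cause_map <- function(x) {
  if (!is.list(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("cause map must be a named list of pattern vectors", call. = FALSE)
  }
  if (any(lengths(x) == 0L)) {
    stop("cause map contains an empty pattern set", call. = FALSE)
  }
  pats <- unlist(x, use.names = FALSE)
  ok <- grepl("^[EV]?[0-9]{2,3}(\\.[0-9]{1,2})?$", pats)
  if (any(!ok)) {
    stop("invalid ICD-9-CM pattern(s): ", paste(pats[!ok], collapse = ", "),
         call. = FALSE)
  }
  structure(lapply(x, as.character), class = "cause_map")
}

#' @rdname cause_map
#' @param path YAML file with a top-level `causes:` mapping of
#'   cause name to pattern list.
#' @export
read_cause_map <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$causes)) y <- y$causes
  cause_map(y)
}

#' Read an admissions table from delimited text
#'
#' Columns `record_id,admission_date,unit_id,dx1,dx2,dx3,dx4,age,sex,
#' admission_type`; diagnosis codes and unit ids are read as character so
#' ICD codes like "305.00" are never numerically coerced.
#'
#' @param path CSV file path.
#' @return Data frame of raw admission records.
#' @export
read_admissions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(record_id = "character",
                                 admission_date = "character",
                                 unit_id = "character",
                                 dx1 = "character", dx2 = "character",
                                 dx3 = "character", dx4 = "character",
                                 sex = "character",
                                 admission_type = "character"))
}

# dot-insensitive prefix match of codes against one pattern set
icd_matches <- function(codes, patterns) {
  codes <- gsub(".", "", codes, fixed = TRUE)
  patterns <- gsub(".", "", patterns, fixed = TRUE)
  hit <- rep(FALSE, length(codes))
  for (p in patterns) hit <- hit | startsWith(codes, p)
  hit & nzchar(codes)
}

#' Classify admissions into causes from the first four diagnosis codes
#'
#' A record is attributed to a cause when at least one of its diagnosis
#' codes in positions 1-4 matches that cause's pattern set; a single
#' admission may be attributed to several causes. Codes beyond position 4
#' are never ingested.
#'
#' @param records Admissions data frame with columns `record_id` and
#'   `dx1`..`dx4` (character; `NA`/empty allowed).
#' @param causes A [cause_map()].
#' @return Data frame `record_id`, `cause` in long format (zero rows for
#'   a record matching no cause).
#' @export
classify_admissions <- function(records, causes) {
  stopifnot(inherits(causes, "cause_map"))
  dxc <- paste0("dx", 1:4)
  miss <- setdiff(dxc, names(records))
  if (length(miss)) {
    stop("records missing diagnosis columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(records)
  codes <- as.character(unlist(records[dxc], use.names = FALSE))
  codes[is.na(codes)] <- ""
  out <- vector("list", length(causes))
  for (k in seq_along(causes)) {
    hit <- matrix(icd_matches(codes, causes[[k]]), nrow = n)
    idx <- which(rowSums(hit) > 0)
    out[[k]] <- data.frame(record_id = records$record_id[idx],
                           cause = rep(names(causes)[k], length(idx)),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(record_id = character(), cause = character())
  }
  rownames(res) <- NULL
  res
}

#' Exclusion percentage from record counts
#'
#' `100 * (n_in - n_out) / n_in`, rounded to one decimal, as quoted in
#' cohort flow reports.
#'
#' @param n_in,n_out Record counts before and after exclusion.
#' @return Percentage excluded, one decimal.
#' @export
exclusion_percent <- function(n_in, n_out) {
  round(100 * (n_in - n_out) / n_in, 1)
}

#' Apply completeness exclusions to admission records
#'
#' Drops records with missing or unparseable sex, age, admission date or
#' residential ZIP, and (optionally) dates outside the study period
#' ("inaccurate" dates). Returns the retained records together with an
#' exclusion report. Applying the function twice gives the same result
#' (idempotence).
#'
#' @param records Data frame with at least `record_id`, `admission_date`,
#'   `unit_id`, `age`, `sex`.
#' @param period Optional length-2 date range; dates outside it are
#'   treated as inaccurate and excluded.
#' @return List with `records` (retained, `admission_date` parsed to
#'   `Date`) and `report` (`n_in`, `n_retained`, `n_excluded`,
#'   `percent_excluded`, and per-field failure counts in `reasons`).
#' @export
apply_exclusions <- function(records, period = NULL) {
  n_in <- nrow(records)
  sex <- as.character(records$sex)
  bad_sex <- is.na(sex) | !(sex %in% c("female", "male"))
  age <- suppressWarnings(as.numeric(records$age))
  bad_age <- is.na(age) | !is.finite(age) | age < 0 | age > 120
  date <- suppressWarnings(as_date_strict(records$admission_date))
  bad_date <- is.na(date)
  if (!is.null(period)) {
    period <- as_date_strict(period)
    bad_date <- bad_date | date < period[1L] | date > period[2L]
    bad_date[is.na(bad_date)] <- TRUE
  }
  zip <- as.character(records$unit_id)
  bad_zip <- is.na(zip) | !nzchar(trimws(zip))

  drop <- bad_sex | bad_age | bad_date | bad_zip
  kept <- records[!drop, , drop = FALSE]
  kept$admission_date <- date[!drop]
  kept$age <- age[!drop]
  rownames(kept) <- NULL
  list(
    records = kept,
    report = list(
      n_in = n_in,
      n_retained = nrow(kept),
      n_excluded = sum(drop),
      percent_excluded = exclusion_percent(n_in, nrow(kept)),
      reasons = c(sex = sum(bad_sex), age = sum(bad_age),
                  date = sum(bad_date), zip = sum(bad_zip))
    )
  )
}

# group sizes differing by at most one, lowest group gets the remainder
tertile_sizes <- function(n) {
  base <- n %/% 3L
  extra <- n %% 3L
  base + (seq_len(3L) <= extra)
}

#' Area-weight tract-level social vulnerability to units and cut tertiles
#'
#' Unit-level SVI is the area-share-weighted mean of contributing tract
#' values; units are then ranked (ties broken by unit id, lexically) and
#' split into three groups of as-equal-as-possible size, 1 = least to
#' 3 = most vulnerable.
#'
#' @param tract_svi Data frame `tract_id`, `svi_value` (values in [0, 1]).
#' @param area_weights Data frame `tract_id`, `unit_id`, `weight`; shares
#'   must sum to 1 per unit within 1e-9.
#' @return Data frame `unit_id`, `svi_value`, `tertile`.
#' @export
assign_svi_tertiles <- function(tract_svi, area_weights) {
  sums <- rowsum(area_weights$weight, area_weights$unit_id)
  off <- abs(sums - 1) > 1e-9
  if (any(off)) {
    stop("area weights do not sum to 1 for unit(s): ",
         paste(rownames(sums)[off], collapse = ", "), call. = FALSE)
  }
  v <- tract_svi$svi_value[match(area_weights$tract_id, tract_svi$tract_id)]
  if (anyNA(v)) {
    stop("area weights reference unknown tract(s): ",
         paste(unique(area_weights$tract_id[is.na(v)]), collapse = ", "),
         call. = FALSE)
  }
  agg <- rowsum(area_weights$weight * v, area_weights$unit_id)
  unit_id <- rownames(agg)
  svi <- drop(agg)
  ord <- order(svi, unit_id)
  n <- length(svi)
  tert <- integer(n)
  tert[ord] <- rep.int(1:3, tertile_sizes(n))
  data.frame(unit_id = unit_id, svi_value = svi, tertile = tert,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Age groups used for stratified analyses
#'
#' Bins closed on the left: [0,25) -> "0-24", [25,45) -> "25-44",
#' [45,65) -> "45-64", [65,Inf) -> "65+".
#'
#' @param age Numeric ages in years.
#' @return Factor with the four group labels.
#' @export
age_group <- function(age) {
  cut(age, breaks = c(0, 25, 45, 65, Inf), right = FALSE,
      labels = c("0-24", "25-44", "45-64", "65+"))
}

#' Extract per-cause case events with stratification attributes
#'
#' Joins classified, exclusion-complete admission records for one cause
#' with SVI tertiles and city membership, yielding one case event per
#' (record, cause) with the four stratification attributes attached.
#'
#' @param records Retained records from [apply_exclusions()].
#' @param cause Cause name to extract.
#' @param classification Output of [classify_admissions()] for `records`.
#' @param svi Output of [assign_svi_tertiles()].
#' @param city_units Character vector of unit ids forming the "in city"
#'   location group.
#' @return Data frame of case events: `record_id`, `cause`,
#'   `admission_date`, `unit_id`, `age_group`, `sex`, `location_group`,
#'   `svi_tertile`.
#' @export
extract_case_series <- function(records, cause, classification, svi,
                                city_units = character()) {
  ids <- classification$record_id[classification$cause == cause]
  ev <- records[records$record_id %in% ids, , drop = FALSE]
  m <- match(ev$unit_id, svi$unit_id)
  if (anyNA(m)) {
    stop("units absent from SVI assignment: ",
         paste(unique(ev$unit_id[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  data.frame(
    record_id = ev$record_id,
    cause = rep(cause, nrow(ev)),
    admission_date = ev$admission_date,
    unit_id = ev$unit_id,
    age_group = as.character(age_group(ev$age)),
    sex = as.character(ev$sex),
    location_group = ifelse(ev$unit_id %in% city_units,
                            "in_city", "not_in_city"),
    svi_tertile = svi$tertile[m],
    row.names = NULL, stringsAsFactors = FALSE
  )
}
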