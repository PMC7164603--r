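#' Build the personal-information table from admissions and patients
#'
#' Inner join of ADMISSIONS and PATIENTS on `SUBJECT_ID`, reduced to one row
#' per subject, with the three binary covariates used downstream:
#' `AGE_GROUP` (0 for ages less than or equal to 65, 1 for greater), `GENDER`
#' (0 = female, 1 = male) and `MORTALITY` (0 = survival, 1 = expired).
#' Subjects with several admissions are reduced to their earliest admission
#' for the age reference date, while `MORTALITY` is 1 if the subject expired
#' on any admission. Age is computed at admission (`ADMITTIME - DOB` in whole
#' years) unless PATIENTS already carries an `AGE` column.
#'
#' @param adm data.frame with `SUBJECT_ID`, `ADMITTIME` and the mortality
#'   source column.
#' @param pat data.frame with `SUBJECT_ID`, `GENDER` and `DOB` or `AGE`.
#' @param mortality_col name of the admissions column holding the 0/1
#'   survival status (default `"HOSPITAL_EXPIRE_FLAG"`).
#' @return data.frame with columns `SUBJECT_ID`, `AGE_GROUP`, `GENDER`,
#'   `MORTALITY`, one row per subject present in both inputs.
#' @export
build_personal_info <- function(adm, pat, mortality_col = "HOSPITAL_EXPIRE_FLAG") {
  adm <- as.data.frame(adm)
  pat <- as.data.frame(pat)
  for (col in c("SUBJECT_ID", mortality_col)) {
    if (!col %in% names(adm)) {
      stop(sprintf("ADMISSIONS is missing column `%s`", col), call. = FALSE)
    }
  }
  if (!"SUBJECT_ID" %in% names(pat) || !"GENDER" %in% names(pat)) {
    stop("PATIENTS must have SUBJECT_ID and GENDER columns", call. = FALSE)
  }
  has_age <- "AGE" %in% names(pat)
  has_admittime <- "ADMITTIME" %in% names(adm)
  if (!has_age && (!"DOB" %in% names(pat) || !has_admittime)) {
    stop("PATIENTS needs AGE, or DOB together with ADMISSIONS$ADMITTIME", call. = FALSE)
  }

  mort <- suppressWarnings(as.integer(adm[[mortality_col]]))
  if (any(is.na(mort)) || any(!mort %in% c(0L, 1L))) {
    stop(sprintf("column `%s` is not binary-codable", mortality_col), call. = FALSE)
  }
  # one row per subject: earliest admission; expired-on-any-admission flag
  ord <- if (has_admittime) {
    order(adm$SUBJECT_ID, adm$ADMITTIME)
  } else {
    order(adm$SUBJECT_ID)
  }
  adm <- adm[ord, , drop = FALSE]
  mort <- mort[ord]
  first <- !duplicated(adm$SUBJECT_ID)
  adm1 <- data.frame(SUBJECT_ID = as.integer(adm$SUBJECT_ID[first]))
  if (has_admittime) adm1$ADMITTIME <- adm$ADMITTIME[first]
  mort_by_subj <- tapply(mort, adm$SUBJECT_ID, max)
  adm1$MORTALITY <- as.integer(mort_by_subj[as.character(adm1$SUBJECT_ID)])

  joined <- merge(adm1, pat, by = "SUBJECT_ID")
  if (has_age) {
    age <- as.numeric(joined$AGE)
  } else {
    adm_date <- as.Date(joined$ADMITTIME)
    dob <- as.Date(joined$DOB)
    if (any(is.na(adm_date)) || any(is.na(dob))) {
      stop("unparseable ADMITTIME/DOB dates", call. = FALSE)
    }
    # age in whole years at admission
    age <- as.integer(floor(as.numeric(adm_date - dob) / 365.25))
  }
  g <- joined$GENDER
  gender <- ifelse(g %in% c("F", "f", "0", 0), 0L,
    ifelse(g %in% c("M", "m", "1", 1), 1L, NA_integer_)
  )
  if (any(is.na(gender))) {
    stop(sprintf(
      "GENDER values not binary-codable: %s",
      paste(unique(g[is.na(gender)]), collapse = ", ")
    ), call. = FALSE)
  }
  out <- data.frame(
    SUBJECT_ID = as.integer(joined$SUBJECT_ID),
    AGE_GROUP = as.integer(age > 65),
    GENDER = gender,
    MORTALITY = as.integer(joined$MORTALITY)
  )
  out[order(out$SUBJECT_ID), , drop = FALSE]
}

#' Extract first-48-hours drug exposure as a binary matrix
#'
#' Keeps prescriptions whose `ENDDATE - STARTDATE` equals exactly two days
#' (the literal first-48-hours criterion; `rule = "within"` relaxes it to at
#' most two days) and pivots the surviving `(SUBJECT_ID, DRUG)` pairs to a
#' binary indicator matrix. Duplicate qualifying prescriptions of the same
#' drug still yield a single 1. Column order is the drugs' first-appearance
#' order among qualifying rows. Subjects in `subjects` with no qualifying
#' prescription get an all-zero row, so the matrix can cover the full join
#' universe of the personal-information table.
#'
#' @param rx data.frame with `SUBJECT_ID`, `DRUG`, `STARTDATE`, `ENDDATE`.
#' @param subjects optional integer vector fixing the row universe; defaults
#'   to all subjects appearing anywhere in `rx`.
#' @param rule `"exact"` (`ENDDATE - STARTDATE == 2` days, the default) or
#'   `"within"` (`0 <= ENDDATE - STARTDATE <= 2`).
#' @return integer 0/1 matrix, rownames = subject ids, colnames = drug names.
#' @export
extract_48h_drugs <- function(rx, subjects = NULL, rule = c("exact", "within")) {
  rule <- match.arg(rule)
  for (col in c("SUBJECT_ID", "DRUG", "STARTDATE", "ENDDATE")) {
    if (!col %in% names(rx)) {
      stop(sprintf("PRESCRIPTIONS is missing column `%s`", col), call. = FALSE)
    }
  }
  parse_date <- function(x) {
    tryCatch(as.Date(as.character(x)), error = function(e) as.Date(rep(NA, length(x))))
  }
  start <- parse_date(rx$STARTDATE)
  end <- parse_date(rx$ENDDATE)
  if (nrow(rx) > 0 && (any(is.na(start)) || any(is.na(end)))) {
    stop("unparseable STARTDATE/ENDDATE values", call. = FALSE)
  }
  span <- as.numeric(end - start)
  keep <- if (rule == "exact") span == 2 else (span >= 0 & span <= 2)
  qual <- rx[keep, , drop = FALSE]
  if (is.null(subjects)) subjects <- unique(as.integer(rx$SUBJECT_ID))
  subjects <- as.integer(subjects)
  drugs <- unique(as.character(qual$DRUG)) # first-appearance order
  mat <- matrix(0L, length(subjects), length(drugs),
    dimnames = list(as.character(subjects), drugs)
  )
  if (nrow(qual) > 0) {
    ri <- match(as.integer(qual$SUBJECT_ID), subjects)
    ci <- match(as.character(qual$DRUG), drugs)
    ok <- !is.na(ri)
    mat[cbind(ri[ok], ci[ok])] <- 1L
  }
  mat
}

#' Assemble a cohort from personal information and the drug matrix
#'
#' Inner join on `SUBJECT_ID`: the drug indicators become the predictors and
#' `MORTALITY` the response; `AGE_GROUP` and `GENDER` are carried as
#' covariates (used for non-IID sorting, not as model inputs).
#'
#' @param info data.frame from [build_personal_info()].
#' @param drugs binary matrix from [extract_48h_drugs()].
#' @return a `patient_cohort`.
#' @export
assemble_dataset <- function(info, drugs) {
  common <- intersect(info$SUBJECT_ID, as.integer(rownames(drugs)))
  if (length(common) == 0L) {
    stop("empty join: no SUBJECT_ID common to the two tables", call. = FALSE)
  }
  common <- sort(common)
  info_i <- info[match(common, info$SUBJECT_ID), , drop = FALSE]
  feat <- drugs[match(as.character(common), rownames(drugs)), , drop = FALSE]
  new_patient_cohort(
    features = feat,
    age_group = info_i$AGE_GROUP, gender = info_i$GENDER,
    mortality = info_i$MORTALITY, ids = common
  )
}
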