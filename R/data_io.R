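# NONMEM-style rectangular dataset container and CSV reader/writer.

#' Construct and validate a longitudinal PK dataset
#'
#' A `pk_dataset` holds per-subject dosing events, timed concentration
#' observations and subject-constant covariates in the rectangular layout
#' used by most population-PK software (one row per event, columns
#' `ID, TIME, AMT, EVID, DV, <covariates>`).
#'
#' @param doses data frame with columns `subject_id`, `time` (h, >= 0),
#'   `amount` (dose mass, > 0) and `duration` (h, 0 = bolus).
#' @param observations data frame with columns `subject_id`, `time` (h),
#'   `dv` (concentration) and `missing_flag` (logical).
#' @param covariates data frame with a `subject_id` column and one column
#'   per covariate; values must be constant per subject (one row per
#'   subject).
#' @param covariate_kinds named character vector mapping covariate names to
#'   `"continuous"` or `"discrete"`.  Defaults to `"continuous"` for every
#'   covariate.
#' @return An object of class `pk_dataset` with elements `subjects`,
#'   `doses`, `observations`, `covariates`, `covariate_kinds` and `n_obs`
#'   (count of non-missing observations).
#' @export
pk_dataset <- function(doses, observations, covariates = NULL,
                       covariate_kinds = NULL) {
  doses <- as.data.frame(doses)
  observations <- as.data.frame(observations)
  need_d <- c("subject_id", "time", "amount", "duration")
  need_o <- c("subject_id", "time", "dv", "missing_flag")
  if (!all(need_d %in% names(doses)))
    stop("doses must have columns: ", paste(need_d, collapse = ", "))
  if (!all(need_o %in% names(observations)))
    stop("observations must have columns: ", paste(need_o, collapse = ", "))
  doses$subject_id <- as.character(doses$subject_id)
  observations$subject_id <- as.character(observations$subject_id)

  subjects <- unique(c(doses$subject_id, observations$subject_id))
  if (is.null(covariates)) {
    covariates <- data.frame(subject_id = subjects,
                             stringsAsFactors = FALSE)
  } else {
    covariates <- as.data.frame(covariates)
    covariates$subject_id <- as.character(covariates$subject_id)
  }
  cov_names <- setdiff(names(covariates), "subject_id")
  if (is.null(covariate_kinds))
    covariate_kinds <- setNames(rep("continuous", length(cov_names)),
                                cov_names)

  ds <- structure(
    list(subjects = subjects, doses = doses, observations = observations,
         covariates = covariates, covariate_kinds = covariate_kinds,
         n_obs = sum(!observations$missing_flag)),
    class = "pk_dataset")
  validate_pk_dataset(ds)
}

#' Validate a `pk_dataset`
#'
#' Checks the container invariants: positive dose amounts, non-negative
#' times and durations, non-negative observed concentrations, records
#' sorted by time within subject, every observed subject dosed at or before
#' its first observation, and a complete subject-constant covariate table.
#'
#' @param ds a `pk_dataset`.
#' @return `ds`, invisibly usable; errors name the offending row.
#' @export
validate_pk_dataset <- function(ds) {
  d <- ds$doses; o <- ds$observations
  if (any(bad <- !(d$amount > 0)))
    stop("dose amount must be > 0 (dose row ", which(bad)[1], ")")
  if (any(bad <- d$duration < 0))
    stop("dose duration must be >= 0 (dose row ", which(bad)[1], ")")
  if (any(bad <- d$time < 0))
    stop("negative dose time (dose row ", which(bad)[1], ")")
  if (any(bad <- o$time < 0))
    stop("negative observation time (observation row ", which(bad)[1], ")")
  if (any(bad <- !o$missing_flag & (is.na(o$dv) | o$dv < 0)))
    stop("non-missing dv must be >= 0 (observation row ", which(bad)[1], ")")
  for (df_name in c("doses", "observations")) {
    df <- ds[[df_name]]
    for (s in unique(df$subject_id)) {
      tt <- df$time[df$subject_id == s]
      if (is.unsorted(tt))
        stop("records not sorted by time within subject ", s,
             " (", df_name, ")")
    }
  }
  for (s in unique(o$subject_id)) {
    t_obs <- min(o$time[o$subject_id == s])
    t_dose <- d$time[d$subject_id == s]
    if (length(t_dose) == 0 || min(t_dose) > t_obs)
      stop("subject ", s, " has an observation before any dose")
  }
  cv <- ds$covariates
  if (anyDuplicated(cv$subject_id))
    stop("covariate table must have one row per subject")
  missing_subj <- setdiff(ds$subjects, cv$subject_id)
  if (length(missing_subj))
    stop("covariate values missing for subject ", missing_subj[1])
  cov_names <- setdiff(names(cv), "subject_id")
  for (nm in cov_names)
    if (anyNA(cv[[nm]]))
      stop("missing value in covariate ", nm)
  if (ds$n_obs != sum(!o$missing_flag))
    stop("n_obs inconsistent with observation flags")
  ds
}

#' Read a NONMEM-style CSV dataset
#'
#' Rows flagged as dose events become dosing records; all other rows become
#' observations.  A dose event is a row whose event column (`EVID` by
#' default) equals 1; when the file has no event column, rows with nonzero
#' `AMT` are taken as doses (the event column wins when both are present).
#' A `DV` that is empty or the sentinel `"."` is read as missing.  Any
#' column other than the mapped ones is treated as a subject-constant
#' covariate; a covariate varying within subject is an error.
#'
#' @param source path or connection to a comma-separated file with header.
#' @param column_map named character vector overriding the default column
#'   names `c(id = "ID", time = "TIME", amt = "AMT", evid = "EVID",
#'   dv = "DV", dur = "DUR")`.  The duration and event columns are optional
#'   in the file.
#' @param covariate_kinds optional named kind vector passed to
#'   [pk_dataset()].
#' @return A validated [pk_dataset()].
#' @export
read_pkdata <- function(source, column_map = NULL, covariate_kinds = NULL) {
  cm <- c(id = "ID", time = "TIME", amt = "AMT", evid = "EVID",
          dv = "DV", dur = "DUR")
  if (!is.null(column_map)) cm[names(column_map)] <- column_map
  raw <- read.csv(source, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  for (key in c("id", "time", "amt", "dv"))
    if (!cm[[key]] %in% names(raw))
      stop("required column '", cm[[key]], "' not found")

  num <- function(x) suppressWarnings(as.numeric(x))
  id <- as.character(raw[[cm[["id"]]]])
  time <- num(raw[[cm[["time"]]]])
  amt <- num(raw[[cm[["amt"]]]])
  amt[is.na(amt)] <- 0
  if (any(is.na(time)))
    stop("non-numeric time value (file row ", which(is.na(time))[1] + 1L, ")")
  if (cm[["evid"]] %in% names(raw)) {
    is_dose <- num(raw[[cm[["evid"]]]]) == 1
    is_dose[is.na(is_dose)] <- FALSE
  } else {
    is_dose <- amt != 0
  }
  dur <- if (cm[["dur"]] %in% names(raw)) {
    x <- num(raw[[cm[["dur"]]]]); x[is.na(x)] <- 0; x
  } else rep(0, nrow(raw))
  dv_raw <- trimws(raw[[cm[["dv"]]]])
  dv_missing <- dv_raw == "" | dv_raw == "."
  dv <- num(dv_raw)

  cov_cols <- setdiff(names(raw), unname(cm))
  covariates <- NULL
  if (length(cov_cols)) {
    usub <- unique(id)
    covariates <- data.frame(subject_id = usub, stringsAsFactors = FALSE)
    for (nm in cov_cols) {
      v <- num(raw[[nm]])
      vals <- vapply(usub, function(s) {
        u <- unique(v[id == s])
        if (length(u) > 1)
          stop("covariate ", nm, " varies within subject ", s)
        u
      }, numeric(1))
      covariates[[nm]] <- unname(vals)
    }
  }

  pk_dataset(
    doses = data.frame(subject_id = id[is_dose], time = time[is_dose],
                       amount = amt[is_dose], duration = dur[is_dose],
                       stringsAsFactors = FALSE),
    observations = data.frame(subject_id = id[!is_dose],
                              time = time[!is_dose],
                              dv = ifelse(dv_missing[!is_dose], NA_real_,
                                          dv[!is_dose]),
                              missing_flag = dv_missing[!is_dose],
                              stringsAsFactors = FALSE),
    covariates = covariates, covariate_kinds = covariate_kinds)
}

#' Write a `pk_dataset` as NONMEM-style CSV
#'
#' The inverse of [read_pkdata()]: rows are emitted in subject order with
#' each subject's doses and observations interleaved by time (doses first
#' on ties), numeric values are printed with enough digits to round-trip
#' exactly, and missing `DV` is written as `"."`.
#'
#' @param ds a [pk_dataset()].
#' @param sink path or connection.
#' @return Invisibly, the path/connection written to.
#' @export
write_pkdata <- function(ds, sink) {
  fmt <- function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "." else formatC(v, digits = 17, format = "g")
    }, character(1))
    out
  }
  cov_names <- setdiff(names(ds$covariates), "subject_id")
  rows <- list()
  for (s in ds$subjects) {
    d <- ds$doses[ds$doses$subject_id == s, , drop = FALSE]
    o <- ds$observations[ds$observations$subject_id == s, , drop = FALSE]
    ev <- rbind(
      data.frame(time = d$time, evid = 1, amt = d$amount, dur = d$duration,
                 dv = NA_real_, miss = FALSE),
      data.frame(time = o$time, evid = 0, amt = 0, dur = 0,
                 dv = o$dv, miss = o$missing_flag))
    ev <- ev[order(ev$time, -ev$evid), , drop = FALSE]
    cv <- ds$covariates[ds$covariates$subject_id == s, cov_names,
                        drop = FALSE]
    rows[[s]] <- cbind(data.frame(ID = s, stringsAsFactors = FALSE), ev,
                       cv[rep(1, nrow(ev)), , drop = FALSE])
  }
  all <- if (length(rows)) do.call(rbind, rows) else NULL
  header <- c("ID", "TIME", "AMT", "EVID", "DUR", "DV", cov_names)
  lines <- paste(header, collapse = ",")
  if (!is.null(all) && nrow(all) > 0) {
    body <- apply(cbind(all$ID, fmt(all$time), fmt(all$amt), all$evid,
                        fmt(all$dur),
                        ifelse(all$miss, ".", fmt(all$dv)),
                        if (length(cov_names))
                          vapply(seq_len(nrow(all)), function(i)
                            paste(fmt(unlist(all[i, cov_names])),
                                  collapse = ","), character(1))
                        else NULL),
                  1, paste, collapse = ",")
    lines <- c(lines, body)
  }
  writeLines(lines, sink)
  invisible(sink)
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat("<pk_dataset> ", length(x$subjects), " subjects, ",
      nrow(x$doses), " doses, ", x$n_obs, " non-missing observations\n",
      sep = "")
  cov <- setdiff(names(x$covariates), "subject_id")
  if (length(cov))
    cat("covariates: ", paste(cov, collapse = ", "), "\n", sep = "")
  invisible(x)
}
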