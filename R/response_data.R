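#' @title Patient survey responses
#'
#' @description
#' Item-level responses are held long-format: one row per
#' (patient, timepoint, term, attribute) with an ordinal `level`. A survey
#' *administration* is one completed survey, i.e. one (patient, timepoint)
#' pair; prevalence denominators downstream count administrations, so
#' attrition is handled by simply not contributing rows for missed timepoints.
#'
#' @name response_data
NULL

DEFAULT_TIMEPOINTS <- c("baseline", "mid_cycle_1", "mid_cycle_2")
RESPONSE_COLUMNS <- c("patient_id", "timepoint", "term_id", "attribute", "level")

#' Construct a validated response dataset
#'
#' @param responses data frame with columns
#'   `patient_id,timepoint,term_id,attribute,level`.
#' @param library the [term_library] the responses refer to.
#' @param timepoints ordered timepoint labels; defaults to the three study
#'   timepoints, but any set of >= 1 labels covering the data is accepted.
#' @return a `response_dataset` (list with `responses`, `library`,
#'   `timepoints`).
#' @details Validation (with offending row numbers): known term ids; attribute
#'   asked for the term; level inside the attribute's range; no duplicate
#'   (patient, timepoint, term, attribute) keys; known timepoint labels.
#' @export
response_dataset <- function(responses, library, timepoints = NULL) {
  stopifnot(inherits(library, "term_library"))
  missing_cols <- setdiff(RESPONSE_COLUMNS, names(responses))
  if (length(missing_cols) > 0) {
    abort_format(paste0("response table is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  responses <- as.data.frame(responses)[, RESPONSE_COLUMNS]
  responses$level <- suppressWarnings(as.integer(responses$level))
  if (is.null(timepoints)) {
    timepoints <- if (all(unique(responses$timepoint) %in% DEFAULT_TIMEPOINTS)) {
      DEFAULT_TIMEPOINTS
    } else {
      sort(unique(responses$timepoint))
    }
  }
  n <- nrow(responses)
  if (n > 0) {
    bad_tp <- which(!responses$timepoint %in% timepoints)
    if (length(bad_tp) > 0) {
      abort_validation(paste0("unknown timepoint at row(s) ", paste(utils::head(bad_tp, 5), collapse = ", ")))
    }
    bad_term <- which(!responses$term_id %in% library$term_id)
    if (length(bad_term) > 0) {
      abort_validation(paste0("unknown term_id at row(s) ", paste(utils::head(bad_term, 5), collapse = ", ")))
    }
    bad_attr <- which(!responses$attribute %in% attribute_kinds())
    if (length(bad_attr) > 0) {
      abort_validation(paste0("unknown attribute at row(s) ", paste(utils::head(bad_attr, 5), collapse = ", ")))
    }
    # attribute must be one the term actually asks about
    flags <- as.matrix(library[, attribute_kinds()])
    rownames(flags) <- library$term_id
    asked <- flags[cbind(responses$term_id, responses$attribute)] == 1L
    if (any(!asked)) {
      abort_validation(paste0("attribute not defined for term at row(s) ",
                              paste(utils::head(which(!asked), 5), collapse = ", ")))
    }
    max_lvl <- attribute_max_level(responses$attribute)
    bad_lvl <- which(is.na(responses$level) | responses$level < 0L | responses$level > max_lvl)
    if (length(bad_lvl) > 0) {
      abort_validation(paste0("level out of range at row(s) ", paste(utils::head(bad_lvl, 5), collapse = ", ")))
    }
    key <- paste(responses$patient_id, responses$timepoint, responses$term_id, responses$attribute, sep = "\r")
    if (anyDuplicated(key)) {
      abort_validation(paste0("duplicate (patient, timepoint, term, attribute) at row(s) ",
                              paste(utils::head(which(duplicated(key)), 5), collapse = ", ")))
    }
  }
  structure(list(responses = responses, library = library, timepoints = timepoints),
            class = "response_dataset")
}

#' Read item-level survey responses from CSV
#'
#' @param path CSV file with header `patient_id,timepoint,term_id,attribute,level`.
#' @param library the [term_library] the responses refer to.
#' @param timepoints optional ordered timepoint labels.
#' @return a validated `response_dataset`.
#' @export
read_responses <- function(path, library, timepoints = NULL) {
  if (!file.exists(path)) abort_format(paste0("response file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  response_dataset(df, library, timepoints)
}

#' Write a response dataset to CSV
#'
#' @param dataset a `response_dataset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_responses <- function(dataset, path) {
  stopifnot(inherits(dataset, "response_dataset"))
  utils::write.csv(dataset$responses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pool survey administrations across timepoints
#'
#' Concatenates all administrations' records into one table, the unit of
#' analysis for every score. Denominators downstream count administrations
#' (surveys actually completed), so patients who dropped out before a
#' timepoint contribute nothing there -- the attrition adjustment.
#'
#' @param dataset a `response_dataset`.
#' @param complete_case if `TRUE`, keep only patients with an administration
#'   at every timepoint of the dataset (the stricter alternative reading of
#'   attrition adjustment; not the default).
#' @return a `pooled_responses` object: list with `records` (long table plus
#'   an `admin_id` column), `administrations` (one row per survey with
#'   patient/timepoint), and `n_administrations`.
#' @export
pool_timepoints <- function(dataset, complete_case = FALSE) {
  stopifnot(inherits(dataset, "response_dataset"))
  records <- dataset$responses
  if (nrow(records) == 0) abort_validation("cannot pool an empty response dataset")
  records$admin_id <- paste(records$patient_id, records$timepoint, sep = "@")
  if (isTRUE(complete_case)) {
    tp_per_patient <- tapply(records$timepoint, records$patient_id,
                             function(tp) length(unique(tp)))
    keep <- names(tp_per_patient)[tp_per_patient == length(dataset$timepoints)]
    records <- records[records$patient_id %in% keep, , drop = FALSE]
    if (nrow(records) == 0) abort_validation("no complete-case patients to pool")
  }
  admins <- unique(records[, c("admin_id", "patient_id", "timepoint")])
  rownames(admins) <- NULL
  structure(list(records = records,
                 administrations = admins,
                 n_administrations = nrow(admins),
                 library = dataset$library),
            class = "pooled_responses")
}

#' Administration counts per timepoint
#'
#' @param pooled a `pooled_responses` object.
#' @return named integer vector of surveys per timepoint.
#' @export
administration_counts <- function(pooled) {
  stopifnot(inherits(pooled, "pooled_responses"))
  table(pooled$administrations$timepoint)
}

BEST_RESPONSE_LEVELS <- c("CR", "PR", "SD", "PD", "NE")

#' Read a patient characteristics table
#'
#' @param path CSV with at least a `best_response` column (levels CR, PR, SD,
#'   PD, NE); other demographic columns are passed through.
#' @return data frame.
#' @export
read_patient_table <- function(path) {
  if (!file.exists(path)) abort_format(paste0("patient table not found: ", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Cohort summary with overall response rate
#'
#' The overall response rate (ORR) is the proportion of patients with a best
#' response of complete (CR) or partial (PR) response, reported as a percent
#' to one decimal (half-up).
#'
#' @param patients data frame with a `best_response` column.
#' @return list with `n`, `counts` (per category), and `orr_percent`.
#' @export
cohort_summary <- function(patients) {
  if (!"best_response" %in% names(patients)) abort_format("patient table is missing column best_response")
  br <- patients$best_response
  unknown <- setdiff(unique(br), BEST_RESPONSE_LEVELS)
  if (length(unknown) > 0) {
    abort_validation(paste0("unknown best_response category: ", paste(unknown, collapse = ", ")))
  }
  counts <- table(factor(br, levels = BEST_RESPONSE_LEVELS))
  n <- length(br)
  orr <- (counts[["CR"]] + counts[["PR"]]) / n
  list(n = n, counts = counts, orr = orr, orr_percent = percent(orr))
}

#' Patient table matching the study cohort's best-response distribution
#'
#' Builds a 219-row patient table whose best-response counts follow the study
#' cohort (CR 3, PR 18, SD 79, PD 117, NE 2); demographics are filled
#' deterministically and are placeholders, only `best_response` carries the
#' reported arithmetic.
#'
#' @return data frame with columns `patient_id`, `age`, `gender`, `ecog`,
#'   `best_response`.
#' @export
study_patient_table <- function() {
  counts <- c(CR = 3L, PR = 18L, SD = 79L, PD = 117L, NE = 2L)
  n <- sum(counts)
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = rep(c(45L, 60L, 72L), length.out = n),
    gender = rep(c("male", "female"), length.out = n),
    ecog = rep(c(0L, 1L), length.out = n),
    best_response = rep(names(counts), counts),
    stringsAsFactors = FALSE
  )
}

#' @export
print.response_dataset <- function(x, ...) {
  cat(sprintf("response_dataset: %d records, %d patients, timepoints: %s\n",
              nrow(x$responses), length(unique(x$responses$patient_id)),
              paste(x$timepoints, collapse = ", ")))
  invisible(x)
}

#' @export
print.pooled_responses <- function(x, ...) {
  cat(sprintf("pooled_responses: %d administrations, %d records\n",
              x$n_administrations, nrow(x$records)))
  invisible(x)
}
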