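# Cohort container: longitudinal multimarker series in long format plus a
# per-patient index table.  Controls are ordered before cases (i = 1..n0
# controls, the rest cases), matching the likelihood's indexing convention.

#' Build a screening cohort from a long-format data frame
#'
#' @param data data.frame with columns \code{patient_id}, \code{status}
#'   (0 control / 1 case), \code{visit_index}, \code{age_years},
#'   \code{marker}, \code{raw_level}. Every patient must carry every marker
#'   at every visit (missing markers are not modelled).
#' @param diagnosis_age optional named vector (names = case patient ids) of
#'   clinical diagnosis ages; defaults to each case's last visit age.
#' @param markers marker ordering; defaults to order of first appearance.
#' @return object of class \code{screening_cohort}: a list with \code{data}
#'   (long table, transformed level added as \code{level}), \code{patients}
#'   (one row per patient: id, status, n_visits, d = last visit age,
#'   diagnosis_age) and \code{markers}.
#' @export
as_cohort <- function(data, diagnosis_age = NULL, markers = NULL) {
  need <- c("patient_id", "status", "visit_index", "age_years", "marker", "raw_level")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing cohort columns: ", paste(miss, collapse = ", "))
  data <- as.data.frame(data)[need]
  data$patient_id <- as.character(data$patient_id)
  data$marker <- as.character(data$marker)
  if (!all(data$status %in% c(0, 1))) stop("status must be 0 (control) or 1 (case)")
  if (any(data$raw_level <= -4)) stop("raw levels must be > -4")
  if (is.null(markers)) markers <- unique(data$marker)

  # per-patient bookkeeping; controls first, stable order within group
  stat <- tapply(data$status, data$patient_id, function(s) s[1])
  ids <- names(stat)[order(stat, match(names(stat), unique(data$patient_id)))]
  pat <- data.frame(patient_id = ids, status = as.numeric(stat[ids]),
                    row.names = NULL, stringsAsFactors = FALSE)
  ages <- split(data$age_years[data$marker == markers[1]],
                data$patient_id[data$marker == markers[1]])
  pat$n_visits <- vapply(ages[pat$patient_id], length, integer(1))
  pat$d <- vapply(ages[pat$patient_id], max, numeric(1))
  for (id in pat$patient_id) {
    a <- sort(ages[[id]])
    if (any(diff(a) <= 0)) stop("visit ages must be strictly increasing: ", id)
    for (m in markers) {
      nm <- sum(data$patient_id == id & data$marker == m)
      if (nm != length(a)) stop("patient ", id, " lacks marker ", m, " at some visits")
    }
  }
  pat$diagnosis_age <- ifelse(pat$status == 1, pat$d, NA_real_)
  if (!is.null(diagnosis_age)) {
    idx <- match(names(diagnosis_age), pat$patient_id)
    if (anyNA(idx)) stop("diagnosis_age names not all in cohort")
    if (any(diagnosis_age < pat$d[idx] - 1e-9)) {
      stop("diagnosis age must be at or after the last visit")
    }
    pat$diagnosis_age[idx] <- as.numeric(diagnosis_age)
  }

  data <- data[order(match(data$patient_id, pat$patient_id),
                     match(data$marker, markers), data$age_years), ]
  data$level <- transform_level(data$raw_level)
  rownames(data) <- NULL
  structure(list(data = data, patients = pat, markers = markers),
            class = "screening_cohort")
}

#' @export
print.screening_cohort <- function(x, ...) {
  n0 <- sum(x$patients$status == 0)
  n1 <- sum(x$patients$status == 1)
  cat("Screening cohort:", n0, "controls,", n1, "cases;",
      length(x$markers), "markers (", paste(x$markers, collapse = ", "), ")\n")
  cat("Visits per patient:", min(x$patients$n_visits), "-",
      max(x$patients$n_visits), "\n")
  invisible(x)
}

#' @export
summary.screening_cohort <- function(object, ...) {
  print(object)
  ag <- stats::aggregate(level ~ marker + status, data = object$data, FUN = mean)
  cat("Mean log-level by marker and status:\n")
  print(ag, row.names = FALSE)
  invisible(object)
}

#' Number of patients in a cohort
#' @param cohort a \code{screening_cohort}.
#' @export
n_patients <- function(cohort) nrow(cohort$patients)

#' Restrict a cohort to a subset of patients and/or markers
#'
#' @param cohort a \code{screening_cohort}.
#' @param ids patient ids to keep (default all).
#' @param markers markers to keep, in the requested order (default all).
#' @return a new \code{screening_cohort}.
#' @export
subset_cohort <- function(cohort, ids = NULL, markers = NULL) {
  ids <- ids %||% cohort$patients$patient_id
  markers <- markers %||% cohort$markers
  if (!all(markers %in% cohort$markers)) stop("unknown marker requested")
  d <- cohort$data[cohort$data$patient_id %in% ids &
                     cohort$data$marker %in% markers, ]
  da <- cohort$patients$diagnosis_age[cohort$patients$status == 1 &
                                        cohort$patients$patient_id %in% ids]
  names(da) <- cohort$patients$patient_id[cohort$patients$status == 1 &
                                            cohort$patients$patient_id %in% ids]
  out <- as_cohort(d[setdiff(names(d), "level")], diagnosis_age = da,
                   markers = markers)
  if (!is.null(cohort$truth)) {
    out$truth <- cohort$truth[cohort$truth$patient_id %in% ids &
                                cohort$truth$marker %in% markers, ]
  }
  out
}

#' Write / read a cohort as CSV (long format)
#'
#' Columns: patient_id, status, visit_index, age_years, marker, raw_level.
#' Diagnosis ages for cases are stored in a sidecar column
#' \code{diagnosis_age} (repeated per row) so the file round-trips.
#' @param cohort a \code{screening_cohort}.
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  d <- cohort$data[c("patient_id", "status", "visit_index", "age_years",
                     "marker", "raw_level")]
  d$diagnosis_age <- cohort$patients$diagnosis_age[
    match(d$patient_id, cohort$patients$patient_id)]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  da <- NULL
  if ("diagnosis_age" %in% names(d)) {
    cases <- unique(d[d$status == 1, c("patient_id", "diagnosis_age")])
    da <- stats::setNames(cases$diagnosis_age, cases$patient_id)
    da <- da[!is.na(da)]
  }
  as_cohort(d, diagnosis_age = da)
}

# Internal: pack a cohort into padded arrays for vectorized likelihood work.
# Returns Y (N x Tmax x K transformed levels, NA-padded), t (N x Tmax ages),
# mask (N x Tmax), Ti, status, d, ids, markers.
cohort_arrays <- function(cohort, markers = NULL) {
  markers <- markers %||% cohort$markers
  pat <- cohort$patients
  N <- nrow(pat)
  Tmax <- max(pat$n_visits)
  K <- length(markers)
  Y <- array(NA_real_, c(N, Tmax, K))
  tmat <- matrix(NA_real_, N, Tmax)
  d <- cohort$data
  pid_i <- match(d$patient_id, pat$patient_id)
  for (k in seq_len(K)) {
    dk <- d[d$marker == markers[k], ]
    ik <- match(dk$patient_id, pat$patient_id)
    ord <- order(ik, dk$age_years)
    dk <- dk[ord, ]; ik <- ik[ord]
    j <- stats::ave(seq_along(ik), ik, FUN = seq_along)
    Y[cbind(ik, j, k)] <- dk$level
    if (k == 1) tmat[cbind(ik, j)] <- dk$age_years
  }
  mask <- !is.na(tmat)
  list(Y = Y, t = tmat, mask = mask, Ti = pat$n_visits,
       status = pat$status, d = pat$d, diagnosis_age = pat$diagnosis_age,
       ids = pat$patient_id, markers = markers, N = N, Tmax = Tmax, K = K)
}
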