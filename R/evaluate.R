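# Shared evaluation layer: repeated stratified cross-validation, ROC
# metrics, paired permutation tests, screening horizons, lead times and
# contingency tables.

#' Stratified repeated k-fold plan
#'
#' Cases and controls are partitioned separately, so every test fold
#' preserves the cohort's case fraction to within one patient. Within each
#' repetition the test sets partition the cohort.
#'
#' @param cohort a \code{screening_cohort}.
#' @param k folds per repetition (default 5).
#' @param reps repetitions (default 2).
#' @param seed integer seed; the plan is deterministic given it.
#' @return object of class \code{fold_plan}: list \code{folds} of
#'   \code{list(train, test, rep, fold)} id sets, plus the plan parameters.
#' @export
make_folds <- function(cohort, k = 5, reps = 2, seed = 1L) {
  pat <- cohort$patients
  ids0 <- pat$patient_id[pat$status == 0]
  ids1 <- pat$patient_id[pat$status == 1]
  if (length(ids0) < k || length(ids1) < k) {
    stop("need at least k cases and k controls for stratified ", k, "-fold CV")
  }
  set.seed(seed)
  folds <- list()
  for (r in seq_len(reps)) {
    f0 <- rep_len(seq_len(k), length(ids0))[sample.int(length(ids0))]
    f1 <- rep_len(seq_len(k), length(ids1))[sample.int(length(ids1))]
    for (f in seq_len(k)) {
      test <- c(ids0[f0 == f], ids1[f1 == f])
      folds[[length(folds) + 1]] <- list(
        train = setdiff(pat$patient_id, test), test = test,
        rep = r, fold = f)
    }
  }
  structure(list(folds = folds, k = k, reps = reps, seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("Stratified", x$k, "-fold plan,", x$reps, "repetition(s):",
      length(x$folds), "train/test splits\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation; ties between a case and a control score
#' count one half.
#'
#' @param labels 0/1 vector (both classes present).
#' @param scores numeric risk scores.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: one class absent")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity at a fixed specificity
#'
#' The threshold is the smallest score cutoff achieving at least the target
#' specificity on the controls; scores at or above the threshold are called
#' abnormal (ties count as abnormal).
#'
#' @param labels 0/1 vector.
#' @param scores numeric risk scores.
#' @param specificity target specificity (default 0.90).
#' @return list with \code{sensitivity} and \code{threshold}.
#' @export
sensitivity_at_specificity <- function(labels, scores, specificity = 0.90) {
  stopifnot(length(labels) == length(scores))
  ctrl <- scores[labels == 0]; case <- scores[labels == 1]
  if (!length(ctrl) || !length(case)) stop("both classes must be present")
  cand <- sort(unique(c(scores, Inf)))
  spec <- vapply(cand, function(th) mean(ctrl < th), numeric(1))
  th <- cand[which(spec >= specificity)[1]]
  list(sensitivity = mean(case >= th), threshold = th)
}

#' Paired sign-flip permutation test
#'
#' One-sided test of mean(a - b) > 0 across paired fold metrics. When
#' \code{n_perm >= 2^length(a)} all sign assignments are enumerated and
#' \code{p = \#\{mean(perm) >= mean(obs)\} / 2^n}; otherwise random flips
#' give \code{p = (\#\{>= obs\} + 1) / (n_perm + 1)}.
#'
#' @param a,b equal-length paired metric vectors (e.g. per outer fold).
#' @param n_perm permutation budget (default 10,000).
#' @param seed seed for the sampled variant.
#' @return list: \code{p}, \code{observed} mean difference, \code{exact}.
#' @export
permutation_test_paired <- function(a, b, n_perm = 10000, seed = 1L) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n == 0) stop("no paired observations")
  d <- a - b
  obs <- mean(d)
  if (n_perm >= 2^n) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    perm <- as.vector(signs %*% d) / n
    p <- mean(perm >= obs - 1e-12)
    exact <- TRUE
  } else {
    set.seed(seed)
    perm <- replicate(n_perm, mean(d * sample(c(-1, 1), n, replace = TRUE)))
    p <- (sum(perm >= obs - 1e-12) + 1) / (n_perm + 1)
    exact <- FALSE
  }
  list(p = p, observed = obs, exact = exact)
}

#' Evaluation visit per patient at a screening horizon
#'
#' For horizon h (years), a case's evaluated visit is the last visit at
#' least h years before clinical diagnosis; controls, which have no
#' diagnosis date, are truncated symmetrically by calendar years before
#' their last visit. Horizon 0 ("all") evaluates each patient's final visit.
#'
#' @param cohort a \code{screening_cohort}.
#' @param horizon years before diagnosis (0, 1, 2, ...).
#' @return data.frame: patient_id, status, eval_visit (index), eval_age;
#'   patients with no qualifying visit are dropped (with a message).
#' @export
screen_horizon <- function(cohort, horizon = 0) {
  pat <- cohort$patients
  arr <- cohort_arrays(cohort)
  out <- data.frame(patient_id = pat$patient_id, status = pat$status,
                    eval_visit = NA_integer_, eval_age = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pat))) {
    ref <- if (pat$status[i] == 1) pat$diagnosis_age[i] else pat$d[i]
    ages <- arr$t[i, seq_len(arr$Ti[i])]
    ok <- which(ages <= ref - horizon + 1e-9)
    if (length(ok)) {
      out$eval_visit[i] <- max(ok)
      out$eval_age[i] <- ages[max(ok)]
    }
  }
  dropped <- out$patient_id[is.na(out$eval_visit)]
  if (length(dropped)) {
    message(length(dropped), " patient(s) with no qualifying visit at horizon ",
            horizon, "y excluded")
  }
  out[!is.na(out$eval_visit), ]
}

#' Lead time from a risk trajectory
#'
#' Years between the earliest visit whose risk reaches the threshold and
#' clinical diagnosis; \code{NA} if the trajectory never becomes abnormal.
#'
#' @param risks data.frame with \code{age_years} and \code{risk} for one
#'   patient (one row per scored visit).
#' @param threshold abnormality threshold (ties score as abnormal).
#' @param diagnosis_age clinical diagnosis age in years.
#' @return lead time in years, or \code{NA}.
#' @export
lead_time <- function(risks, threshold, diagnosis_age) {
  hit <- which(risks$risk >= threshold)
  if (!length(hit)) return(NA_real_)
  diagnosis_age - min(risks$age_years[hit])
}

#' Case-detection contingency table for two models
#'
#' A case is "diagnosed" by a model if any of its scored visits reaches that
#' fold's threshold. Counts are pooled over folds.
#'
#' @param detected_a,detected_b named logical vectors (names = case ids,
#'   pooled over folds; both must cover the same cases).
#' @return 2x2 matrix: rows model A diagnosed/missed, columns model B.
#' @export
contingency_table <- function(detected_a, detected_b) {
  stopifnot(setequal(names(detected_a), names(detected_b)))
  detected_b <- detected_b[names(detected_a)]
  m <- matrix(0L, 2, 2,
              dimnames = list(a = c("diagnosed", "missed"),
                              b = c("diagnosed", "missed")))
  m[1, 1] <- sum(detected_a & detected_b)
  m[1, 2] <- sum(detected_a & !detected_b)
  m[2, 1] <- sum(!detected_a & detected_b)
  m[2, 2] <- sum(!detected_a & !detected_b)
  m
}

#' Normal-approximation confidence interval across fold metrics
#'
#' @param x per-fold metric values.
#' @param level confidence level (default 0.95).
#' @return named vector: mean, lower, upper.
#' @export
fold_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  m <- mean(x)
  se <- stats::sd(x) / sqrt(length(x))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(mean = m, lower = m - z * se, upper = m + z * se)
}

# Metrics for one fold's test risks at one horizon.
# risks: data.frame(patient_id, visit_index, age_years, risk); the evaluated
# risk per patient is the prefix ending at that patient's horizon visit.
fold_metrics <- function(risks, cohort, horizon = 0, specificity = 0.90) {
  ev <- screen_horizon(cohort, horizon)
  sel <- merge(ev, risks, by = "patient_id")
  sel <- sel[sel$visit_index == sel$eval_visit, ]
  if (!nrow(sel) || length(unique(sel$status)) < 2) {
    return(list(auc = NA_real_, sensitivity = NA_real_,
                threshold = NA_real_, n = nrow(sel)))
  }
  ss <- sensitivity_at_specificity(sel$status, sel$risk, specificity)
  list(auc = auc_score(sel$status, sel$risk),
       sensitivity = ss$sensitivity, threshold = ss$threshold, n = nrow(sel))
}
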