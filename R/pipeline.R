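# End-to-end experiment orchestration: simulate (or load) a cohort, build
# the outer cross-validation plan, fit both model families over the
# scenario matrix (marker subsets), score test patients, and write the
# metric, lead-time and contingency reports with a reproducibility manifest.

scenario_tag <- function(markers, all_markers) {
  idx <- match(markers, all_markers)
  if (length(idx) == 1) sprintf("u(%d)", idx)
  else sprintf("m(%s)", paste(idx, collapse = ","))
}

#' Default experiment configuration
#'
#' @param generator arguments for [cohort_generator_config()] (ignored when
#'   \code{cohort_csv} is given).
#' @param cohort_csv optional path to a long-format cohort CSV.
#' @param scenarios list of marker-name vectors; default is the full matrix
#'   of the three panel markers: every CA125 pairing plus all univariate
#'   tests.
#' @param methods model families to run: subset of \code{c("bcp", "rnn")}.
#' @param k,reps outer cross-validation plan.
#' @param horizons screening horizons in years (0 = full history).
#' @param bcp_iter,bcp_burnin,bcp_chains MCMC scale for each fold's fit.
#' @param bcp_draws posterior draws per predictive density.
#' @param rnn_hidden,rnn_dropout,rnn_epochs,rnn_lr LSTM settings (no inner
#'   tuning when \code{rnn_tune = FALSE}).
#' @param rnn_tune run the inner tuning loop per outer fold.
#' @param prevalence prior prevalence used by the Bayesian screening rule
#'   (scalar, or table; ranking metrics are invariant to it).
#' @param specificity specificity level for thresholds (default 0.90).
#' @param seed global seed; per-stage seeds are derived from it.
#' @export
experiment_config <- function(generator = list(n_controls = 40, n_cases = 20),
                              cohort_csv = NULL,
                              scenarios = list(
                                c("CA125", "HE4", "glycodelin"),
                                c("CA125", "HE4"), c("CA125", "glycodelin"),
                                "CA125", "HE4", "glycodelin"),
                              methods = c("bcp", "rnn"),
                              k = 5, reps = 2, horizons = c(0, 1, 2),
                              bcp_iter = 1500, bcp_burnin = 500,
                              bcp_chains = 2, bcp_draws = 300,
                              rnn_hidden = 4, rnn_dropout = 0,
                              rnn_epochs = 60, rnn_lr = 1e-3,
                              rnn_tune = FALSE,
                              prevalence = 0.1, specificity = 0.90,
                              seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "experiment_config"
  cfg
}

read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw)
}

fit_and_score <- function(method, train, test, markers, cfg, fold_seed) {
  if (method == "bcp") {
    fit <- bcp_fit(train, markers = markers,
                   control = bcp_control(cfg$bcp_iter, cfg$bcp_burnin,
                                         cfg$bcp_chains),
                   seed = fold_seed)
    predict(fit, test, prevalence = cfg$prevalence,
            n_draws = cfg$bcp_draws, seed = fold_seed)
  } else {
    rcfg <- if (isTRUE(cfg$rnn_tune)) {
      lstm_tune(train, markers, epochs = cfg$rnn_epochs,
                learning_rate = cfg$rnn_lr, seed = fold_seed)$config
    } else {
      lstm_config(hidden = cfg$rnn_hidden, dropout = cfg$rnn_dropout,
                  learning_rate = cfg$rnn_lr, epochs = cfg$rnn_epochs)
    }
    fit <- lstm_fit(train, markers, rcfg, seed = fold_seed)
    predict(fit, test)
  }
}

#' Run a full screening experiment
#'
#' Executes simulate -> fold -> fit -> score -> evaluate for every scenario
#' (method x marker subset) and writes \code{metrics.csv} (per-fold AUC /
#' sensitivity / threshold per horizon), \code{summary.csv} (means with 95\%
#' CIs), \code{leadtime.csv}, \code{contingency.json} (each multimarker
#' scenario against the same-method first-marker univariate test) and
#' \code{manifest.json} to \code{out_dir}.
#'
#' @param config an \code{experiment_config}, or a path to a YAML file of
#'   its fields.
#' @param out_dir output directory (created if missing).
#' @param quiet suppress stage logging.
#' @return invisibly, a list with the cohort, fold plan, risk table and the
#'   three report data frames.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = tempfile(),
                           quiet = FALSE) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("[simulate] building cohort")
  cohort <- if (!is.null(config$cohort_csv)) {
    read_cohort_csv(config$cohort_csv)
  } else {
    gen <- config$generator
    gen$seed <- gen$seed %||% derive_seed(config$seed, 1)
    generate_cohort(do.call(cohort_generator_config, gen))
  }
  plan <- make_folds(cohort, k = config$k, reps = config$reps,
                     seed = derive_seed(config$seed, 2))
  say("[fold] %d splits (%d-fold x %d reps)", length(plan$folds),
      config$k, config$reps)

  risks_all <- list(); metrics <- list()
  for (method in config$methods) {
    for (sc in config$scenarios) {
      tag <- scenario_tag(sc, cohort$markers)
      say("[fit] %s %s", method, tag)
      for (fi in seq_along(plan$folds)) {
        fd <- plan$folds[[fi]]
        train <- subset_cohort(cohort, fd$train, sc)
        test <- subset_cohort(cohort, fd$test, sc)
        fold_seed <- derive_seed(config$seed, 100 + fi)
        r <- fit_and_score(method, train, test, sc, config, fold_seed)
        r$method <- method; r$scenario <- tag; r$fold <- fi
        r$rep <- fd$rep
        risks_all[[length(risks_all) + 1]] <- r
        for (h in config$horizons) {
          fm <- fold_metrics(r, test, horizon = h,
                             specificity = config$specificity)
          metrics[[length(metrics) + 1]] <- data.frame(
            model = method, scenario = tag, horizon = h, fold = fi,
            rep = fd$rep, auc = fm$auc, sensitivity = fm$sensitivity,
            threshold = fm$threshold, n = fm$n)
        }
      }
    }
  }
  risks <- do.call(rbind, risks_all)
  metrics <- do.call(rbind, metrics)

  say("[evaluate] summarizing %d fold-level metric rows", nrow(metrics))
  summ <- do.call(rbind, lapply(
    split(metrics, metrics[c("model", "scenario", "horizon")], drop = TRUE),
    function(g) {
      ca <- fold_ci(g$auc); cs <- fold_ci(g$sensitivity)
      data.frame(model = g$model[1], scenario = g$scenario[1],
                 horizon = g$horizon[1],
                 auc = ca[1], auc_lo = ca[2], auc_hi = ca[3],
                 sensitivity = cs[1], sens_lo = cs[2], sens_hi = cs[3])
    }))
  rownames(summ) <- NULL

  lt <- leadtime_report(risks, metrics, cohort)
  cont <- contingency_report(risks, metrics, cohort)

  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(lt, file.path(out_dir, "leadtime.csv"), row.names = FALSE)
  jsonlite::write_json(cont, file.path(out_dir, "contingency.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- list(
    package = "ocscreen",
    version = as.character(utils::packageVersion("ocscreen")),
    seed = config$seed,
    config = config[setdiff(names(config), "generator")],
    generator = if (is.null(config$cohort_csv)) config$generator,
    n_patients = n_patients(cohort),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  say("[done] reports in %s", out_dir)
  invisible(list(cohort = cohort, plan = plan, risks = risks,
                 metrics = metrics, summary = summ, leadtime = lt,
                 contingency = cont, out_dir = out_dir))
}

# Per-fold lead-time statistics, summarized across folds with 95% CIs.
leadtime_report <- function(risks, metrics, cohort) {
  pat <- cohort$patients
  out <- list()
  groups <- unique(risks[c("method", "scenario")])
  for (gi in seq_len(nrow(groups))) {
    method <- groups$method[gi]; tag <- groups$scenario[gi]
    per_fold <- list()
    for (fi in unique(risks$fold)) {
      thr <- metrics$threshold[metrics$model == method &
                                 metrics$scenario == tag &
                                 metrics$horizon == 0 & metrics$fold == fi]
      r <- risks[risks$method == method & risks$scenario == tag &
                   risks$fold == fi, ]
      case_ids <- intersect(unique(r$patient_id),
                            pat$patient_id[pat$status == 1])
      lts <- vapply(case_ids, function(id) {
        lead_time(r[r$patient_id == id, ], thr,
                  pat$diagnosis_age[pat$patient_id == id])
      }, numeric(1))
      lts <- lts[!is.na(lts)]
      if (length(lts)) {
        per_fold[[length(per_fold) + 1]] <-
          c(mean = mean(lts), median = stats::median(lts),
            min = min(lts), max = max(lts))
      }
    }
    if (!length(per_fold)) next
    pf <- do.call(rbind, per_fold)
    row <- data.frame(model = method, scenario = tag)
    for (stt in colnames(pf)) {
      ci <- fold_ci(pf[, stt])
      row[[stt]] <- ci[1]
      row[[paste0(stt, "_lo")]] <- ci[2]
      row[[paste0(stt, "_hi")]] <- ci[3]
    }
    out[[length(out) + 1]] <- row
  }
  do.call(rbind, out)
}

# Contingency of each multimarker scenario against the same-method
# univariate test on the panel's first marker, pooled over folds.
contingency_report <- function(risks, metrics, cohort) {
  pat <- cohort$patients
  detect_vec <- function(method, tag) {
    det <- logical(0)
    for (fi in unique(risks$fold)) {
      thr <- metrics$threshold[metrics$model == method &
                                 metrics$scenario == tag &
                                 metrics$horizon == 0 & metrics$fold == fi]
      r <- risks[risks$method == method & risks$scenario == tag &
                   risks$fold == fi, ]
      case_ids <- intersect(unique(r$patient_id),
                            pat$patient_id[pat$status == 1])
      v <- vapply(case_ids, function(id) {
        any(r$risk[r$patient_id == id] >= thr)
      }, logical(1))
      names(v) <- paste0(case_ids, ".f", fi)
      det <- c(det, v)
    }
    det
  }
  ref_tag <- "u(1)"
  out <- list()
  for (method in unique(risks$method)) {
    tags <- unique(risks$scenario[risks$method == method])
    if (!(ref_tag %in% tags)) next
    ref <- detect_vec(method, ref_tag)
    for (tag in setdiff(tags, ref_tag)) {
      if (!grepl("^m\\(", tag)) next
      m <- contingency_table(detect_vec(method, tag), ref)
      out[[paste(method, tag, "vs", ref_tag)]] <- list(
        model = method, scenario = tag, reference = ref_tag,
        both_diagnosed = m[1, 1], only_model = m[1, 2],
        only_reference = m[2, 1], both_missed = m[2, 2])
    }
  }
  out
}
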