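# Training (full-batch Adam on the cross-entropy loss), prediction and
# nested-CV hyperparameter tuning for the per-marker LSTM classifier.

#' LSTM model configuration
#'
#' The tuned quantities are the hidden size and the dropout rate; learning
#' rate and epoch count are fixed meta-parameters.
#'
#' @param hidden hidden neurons per channel (scalar, applied to every marker
#'   channel and the age channel).
#' @param dropout dropout rate on the concatenated last hidden state,
#'   in [0, 1).
#' @param learning_rate Adam learning rate.
#' @param epochs full-batch training epochs.
#' @export
lstm_config <- function(hidden = 8, dropout = 0.2, learning_rate = 1e-3,
                        epochs = 100) {
  stopifnot(hidden >= 1, dropout >= 0, dropout < 1,
            learning_rate > 0, epochs >= 1)
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 learning_rate = learning_rate, epochs = as.integer(epochs)),
            class = "lstm_config")
}

# Channel inputs for a cohort: standardized transformed marker levels plus
# standardized visit age as the final channel.  Returns list(x = list of
# N x Tmax matrices (0-padded), mask, labels, scaler).
lstm_inputs <- function(cohort, markers, scaler = NULL) {
  arr <- cohort_arrays(cohort, markers)
  chans <- vector("list", arr$K + 1)
  raw <- c(lapply(seq_len(arr$K), function(k) {
    m <- arr$Y[, , k, drop = FALSE]; dim(m) <- c(arr$N, arr$Tmax); m
  }), list(arr$t))
  if (is.null(scaler)) {
    scaler <- lapply(raw, function(m) {
      v <- m[arr$mask]
      list(mean = mean(v), sd = max(stats::sd(v), 1e-8))
    })
  }
  for (ch in seq_along(raw)) {
    m <- (raw[[ch]] - scaler[[ch]]$mean) / scaler[[ch]]$sd
    m[!arr$mask] <- 0
    chans[[ch]] <- m
  }
  list(x = chans, mask = arr$mask, labels = arr$status, ids = arr$ids,
       Ti = arr$Ti, scaler = scaler, arr = arr)
}

forward_all <- function(inp, weights, head, dropout_mask = NULL,
                        keep_cache = FALSE) {
  n_ch <- length(weights)
  outs <- lapply(seq_len(n_ch), function(ch) {
    forward_channel(inp$x[[ch]], inp$mask, weights[[ch]], keep_cache)
  })
  hcat <- do.call(cbind, lapply(outs, `[[`, "h_last"))
  hd <- if (is.null(dropout_mask)) hcat else hcat * dropout_mask
  logit_ <- drop(hd %*% head$We) + head$be
  list(risk = sigmoid(logit_), hcat = hcat, hd = hd, outs = outs)
}

# Flatten (channel weights, head) into one uniquely-named list for Adam.
flatten_params <- function(weights, head) {
  out <- list()
  for (ch in seq_along(weights)) {
    w <- weights[[ch]]
    names(w) <- paste0("ch", ch, ".", names(w))
    out <- c(out, w)
  }
  c(out, list(We = head$We, be = head$be))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(params)) {
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * grads[[nm]]
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - b1^st$t)
    vhat <- st$v[[nm]] / (1 - b2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

# Full loss gradient at the current weights (used by training and by the
# numerical gradient check).  Returns list(loss, grads) with grads shaped
# like (weights per channel, head).
lstm_loss_grads <- function(inp, weights, head, dropout_mask = NULL) {
  N <- length(inp$labels)
  fw <- forward_all(inp, weights, head, dropout_mask, keep_cache = TRUE)
  risk <- pmin(pmax(fw$risk, 1e-12), 1 - 1e-12)
  loss <- mean(-(inp$labels * log(risk) + (1 - inp$labels) * log(1 - risk)))
  dlogit <- (risk - inp$labels) / N
  gWe <- crossprod(fw$hd, dlogit)
  gbe <- sum(dlogit)
  dhd <- dlogit %o% drop(head$We)
  dh <- if (is.null(dropout_mask)) dhd else dhd * dropout_mask
  gw <- vector("list", length(weights))
  col0 <- 0
  for (ch in seq_along(weights)) {
    H <- ncol(weights[[ch]]$Uc)
    dh_ch <- dh[, col0 + seq_len(H), drop = FALSE]
    gw[[ch]] <- backward_channel(fw$outs[[ch]]$cache, weights[[ch]], dh_ch)
    col0 <- col0 + H
  }
  list(loss = loss, grads = gw, gWe = gWe, gbe = gbe, risk = fw$risk)
}

#' Fit the per-marker LSTM classifier
#'
#' One LSTM channel per selected marker plus one consuming the standardized
#' screening ages; last hidden states are concatenated, dropout is applied
#' to the concatenation at train time only, and a sigmoid head produces the
#' risk. Trained full-batch with Adam on the cross-entropy loss. Recurrent
#' kernels start from random orthogonal matrices, input weights from
#' Glorot-uniform draws, biases from zero. Standardization statistics are
#' computed on the training cohort only and stored with the model.
#'
#' @param cohort training \code{screening_cohort} (both classes present).
#' @param markers marker subset to use (default: all cohort markers).
#' @param config an \code{lstm_config}.
#' @param seed integer seed controlling initialization and dropout.
#' @return object of class \code{lstm_fit}: channel weights, head, scaler,
#'   config, loss trace, training AUC.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(30, 15, seed = 2)
#' fit <- lstm_fit(coh, config = lstm_config(hidden = 4, epochs = 30), seed = 1)
#' head(predict(fit, coh))
#' }
#' @export
lstm_fit <- function(cohort, markers = NULL, config = lstm_config(),
                     seed = 1L) {
  stopifnot(inherits(cohort, "screening_cohort"))
  markers <- markers %||% cohort$markers
  inp <- lstm_inputs(cohort, markers)
  if (length(unique(inp$labels)) < 2) {
    stop("training cohort must contain both cases and controls")
  }
  set.seed(seed)
  n_ch <- length(markers) + 1
  H <- config$hidden
  weights <- lapply(seq_len(n_ch), function(ch) new_channel_weights(H))
  sumH <- n_ch * H
  lim <- sqrt(6 / (sumH + 1))
  head_ <- list(We = matrix(stats::runif(sumH, -lim, lim), sumH, 1), be = 0)
  params <- list(weights = weights, head = head_)
  ad <- NULL
  loss_trace <- numeric(config$epochs)
  N <- length(inp$labels)
  for (ep in seq_len(config$epochs)) {
    dm <- NULL
    if (config$dropout > 0) {
      keep <- matrix(stats::rbinom(N * sumH, 1, 1 - config$dropout), N, sumH)
      dm <- keep / (1 - config$dropout)
    }
    lg <- lstm_loss_grads(inp, params$weights, params$head, dm)
    if (!is.finite(lg$loss)) stop("non-finite training loss at epoch ", ep)
    loss_trace[ep] <- lg$loss
    gflat <- flatten_params(lg$grads, list(We = lg$gWe, be = lg$gbe))
    pflat <- flatten_params(params$weights, params$head)
    if (is.null(ad)) ad <- adam_init(pflat)
    upd <- adam_step(pflat, gflat, ad, config$learning_rate)
    ad <- upd$state
    # unflatten
    per <- 12                                   # entries per channel
    for (ch in seq_len(n_ch)) {
      params$weights[[ch]][] <- upd$params[(ch - 1) * per + seq_len(per)]
    }
    params$head$We <- upd$params$We
    params$head$be <- upd$params$be
  }
  eval_fw <- forward_all(inp, params$weights, params$head)
  structure(list(weights = params$weights, head = params$head,
                 scaler = inp$scaler, markers = markers, config = config,
                 seed = seed, loss_trace = loss_trace,
                 train_auc = auc_score(inp$labels, eval_fw$risk)),
            class = "lstm_fit")
}

#' @export
print.lstm_fit <- function(x, ...) {
  cat("LSTM classifier:", length(x$markers), "marker channel(s) (",
      paste(x$markers, collapse = ", "), ") + age channel\n")
  cat("  hidden =", x$config$hidden, ", dropout =", x$config$dropout,
      ", epochs =", x$config$epochs, "\n")
  cat("  final training loss:", signif(utils::tail(x$loss_trace, 1), 4),
      "; training AUC:", signif(x$train_auc, 4), "\n")
  invisible(x)
}

#' @export
summary.lstm_fit <- function(object, ...) {
  print(object)
  cat("Loss trace (first/last 5):",
      paste(signif(utils::head(object$loss_trace, 5), 4), collapse = " "),
      "...",
      paste(signif(utils::tail(object$loss_trace, 5), 4), collapse = " "), "\n")
  invisible(object)
}

#' Risk trajectories from a fitted LSTM
#'
#' Evaluation-mode forward pass (no dropout) on every visit prefix with at
#' least \code{min_visits} visits, using the training-time scaler.
#'
#' @param object an \code{lstm_fit}.
#' @param newdata a \code{screening_cohort}.
#' @param min_visits shortest prefix scored (default 2).
#' @param ... unused.
#' @return data.frame: patient_id, visit_index, age_years, risk, model.
#' @export
predict.lstm_fit <- function(object, newdata, min_visits = 2, ...) {
  inp <- lstm_inputs(newdata, object$markers, scaler = object$scaler)
  arr <- inp$arr
  out <- list()
  for (jj in seq(min_visits, max(arr$Ti))) {
    sel <- which(arr$Ti >= jj)
    if (!length(sel)) next
    sub <- list(
      x = lapply(inp$x, function(m) m[sel, seq_len(jj), drop = FALSE]),
      mask = matrix(TRUE, length(sel), jj))
    fw <- forward_all(sub, object$weights, object$head)
    out[[length(out) + 1]] <- data.frame(
      patient_id = arr$ids[sel], visit_index = jj,
      age_years = arr$t[cbind(sel, jj)],
      risk = fw$risk, model = "rnn", stringsAsFactors = FALSE)
  }
  skipped <- arr$ids[arr$Ti < min_visits]
  if (length(skipped)) {
    warning("patients with fewer than ", min_visits, " visits skipped: ",
            paste(skipped, collapse = ", "))
  }
  res <- do.call(rbind, out)
  res[order(match(res$patient_id, arr$ids), res$visit_index), ]
}

#' Inner-loop hyperparameter tuning
#'
#' Stratified repeated k-fold cross-validation (default 10-fold, 3
#' repetitions) on the training cohort over a grid of hidden sizes and
#' dropout rates. Selects the configuration with the highest mean
#' validation AUC (risk at each patient's last visit); ties break toward
#' the smaller hidden size, then the lower dropout rate.
#'
#' @param cohort training \code{screening_cohort}.
#' @param markers marker subset.
#' @param hidden_grid,dropout_grid candidate values.
#' @param k,reps inner cross-validation plan.
#' @param epochs,learning_rate fixed meta-parameters for every candidate.
#' @param seed integer seed.
#' @return list: \code{config} (best \code{lstm_config}) and \code{results}
#'   (mean inner AUC per grid point).
#' @export
lstm_tune <- function(cohort, markers = NULL,
                      hidden_grid = c(4, 8, 16),
                      dropout_grid = c(0, 0.2, 0.4),
                      k = 10, reps = 3, epochs = 100, learning_rate = 1e-3,
                      seed = 1L) {
  markers <- markers %||% cohort$markers
  grid <- expand.grid(hidden = hidden_grid, dropout = dropout_grid)
  if (!nrow(grid)) stop("empty tuning grid")
  plan <- make_folds(cohort, k = k, reps = reps, seed = derive_seed(seed, 91))
  mean_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- lstm_config(hidden = grid$hidden[g], dropout = grid$dropout[g],
                       learning_rate = learning_rate, epochs = epochs)
    aucs <- vapply(plan$folds, function(fd) {
      tr <- subset_cohort(cohort, fd$train, markers)
      te <- subset_cohort(cohort, fd$test, markers)
      fit <- lstm_fit(tr, markers, cfg, seed = derive_seed(seed, 17 + g))
      risks <- predict(fit, te)
      last <- risks[!duplicated(risks$patient_id, fromLast = TRUE), ]
      lab <- te$patients$status[match(last$patient_id, te$patients$patient_id)]
      if (length(unique(lab)) < 2) return(NA_real_)
      auc_score(lab, last$risk)
    }, numeric(1))
    mean_auc[g] <- mean(aucs, na.rm = TRUE)
  }
  ord <- order(-mean_auc, grid$hidden, grid$dropout)
  best <- ord[1]
  list(config = lstm_config(hidden = grid$hidden[best],
                            dropout = grid$dropout[best],
                            learning_rate = learning_rate, epochs = epochs),
       results = cbind(grid, mean_auc = mean_auc))
}
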