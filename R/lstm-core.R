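# From-scratch LSTM.  One LSTM channel per biomarker plus one for screening
# age; the last hidden states are concatenated, passed through dropout and a
# sigmoid head.  Each channel consumes a scalar input per time step, so the
# input weights are 1 x H row vectors, the recurrent kernels H x H, biases
# 1 x H.  Implemented batched (patients x H matrices) with carry-forward
# masking for variable-length sequences; analytic BPTT gradients are checked
# against numerical differentiation in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

new_channel_weights <- function(H, zero = FALSE) {
  glorot <- function(n_in, n_out) {
    lim <- sqrt(6 / (n_in + n_out))
    matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
  }
  ortho <- function(H) {
    A <- matrix(stats::rnorm(H * H), H, H)
    qr_ <- qr(A)
    Q <- qr.Q(qr_)
    Q * sign(diag(qr.R(qr_)))[col(Q)]     # sign-fix for a proper Haar draw
  }
  if (zero) {
    w <- function() matrix(0, 1, H); u <- function() matrix(0, H, H)
  } else {
    w <- function() glorot(1, H); u <- function() ortho(H)
  }
  list(Wc = w(), Wi = w(), Wf = w(), Wo = w(),
       Uc = u(), Ui = u(), Uf = u(), Uo = u(),
       bc = matrix(0, 1, H), bi = matrix(0, 1, H),
       bf = matrix(0, 1, H), bo = matrix(0, 1, H))
}

#' One LSTM step
#'
#' Gate equations: candidate \code{tanh(h U_c + y W_c + b_c)}; input, forget
#' and output gates sigmoid with their own weights; cell update
#' \code{c = f * c_prev + i * candidate}; hidden state
#' \code{h = o * tanh(c)}.
#'
#' @param h_prev,c_prev 1 x H hidden and cell states.
#' @param y_in scalar input for this step.
#' @param weights channel weight list (Wc, Wi, Wf, Wo 1 x H; Uc, Ui, Uf, Uo
#'   H x H; bc, bi, bf, bo 1 x H).
#' @return list with elements \code{h} and \code{c} (1 x H).
#' @export
lstm_step <- function(h_prev, c_prev, y_in, weights) {
  h_prev <- matrix(h_prev, nrow = 1)
  c_prev <- matrix(c_prev, nrow = 1)
  H <- ncol(h_prev)
  w <- weights
  if (ncol(w$Uc) != H) stop("weight shapes inconsistent with hidden size")
  g <- tanh(h_prev %*% w$Uc + y_in * w$Wc + w$bc)
  i <- sigmoid(h_prev %*% w$Ui + y_in * w$Wi + w$bi)
  f <- sigmoid(h_prev %*% w$Uf + y_in * w$Wf + w$bf)
  o <- sigmoid(h_prev %*% w$Uo + y_in * w$Wo + w$bo)
  c_new <- f * c_prev + i * g
  list(h = o * tanh(c_new), c = c_new)
}

# Batched forward through one channel.
# x: N x T inputs (0 at padded steps), mask: N x T logical.
# Returns h_last (N x H) and, if keep_cache, per-step intermediates.
forward_channel <- function(x, mask, w, keep_cache = FALSE) {
  N <- nrow(x); Tt <- ncol(x); H <- ncol(w$Uc)
  h <- matrix(0, N, H); cc <- matrix(0, N, H)
  cache <- if (keep_cache) vector("list", Tt)
  ones <- rep(1, N)
  for (t in seq_len(Tt)) {
    xt <- x[, t]
    m <- as.numeric(mask[, t])
    g <- tanh(h %*% w$Uc + xt %o% drop(w$Wc) + ones %o% drop(w$bc))
    ii <- sigmoid(h %*% w$Ui + xt %o% drop(w$Wi) + ones %o% drop(w$bi))
    ff <- sigmoid(h %*% w$Uf + xt %o% drop(w$Wf) + ones %o% drop(w$bf))
    oo <- sigmoid(h %*% w$Uo + xt %o% drop(w$Wo) + ones %o% drop(w$bo))
    c_new <- ff * cc + ii * g
    tc <- tanh(c_new)
    h_new <- oo * tc
    if (keep_cache) {
      cache[[t]] <- list(x = xt, m = m, h_prev = h, c_prev = cc,
                         g = g, i = ii, f = ff, o = oo, tc = tc)
    }
    h <- m * h_new + (1 - m) * h
    cc <- m * c_new + (1 - m) * cc
  }
  list(h_last = h, cache = cache)
}

# BPTT through one channel given the gradient at the (carried) last hidden
# state.  Returns the weight-gradient list.
backward_channel <- function(cache, w, dh_last) {
  H <- ncol(w$Uc)
  zero_w <- matrix(0, 1, H); zero_u <- matrix(0, H, H)
  gr <- list(Wc = zero_w, Wi = zero_w, Wf = zero_w, Wo = zero_w,
             Uc = zero_u, Ui = zero_u, Uf = zero_u, Uo = zero_u,
             bc = zero_w, bi = zero_w, bf = zero_w, bo = zero_w)
  dh <- dh_last; dc <- matrix(0, nrow(dh_last), H)
  for (t in rev(seq_along(cache))) {
    cs <- cache[[t]]
    m <- cs$m
    dh_a <- dh * m; dc_a <- dc * m
    do_ <- dh_a * cs$tc
    da_o <- do_ * cs$o * (1 - cs$o)
    dct <- dc_a + dh_a * cs$o * (1 - cs$tc^2)
    df <- dct * cs$c_prev
    da_f <- df * cs$f * (1 - cs$f)
    di <- dct * cs$g
    da_i <- di * cs$i * (1 - cs$i)
    dg <- dct * cs$i
    da_c <- dg * (1 - cs$g^2)
    gr$Wc <- gr$Wc + colSums(cs$x * da_c); gr$Wi <- gr$Wi + colSums(cs$x * da_i)
    gr$Wf <- gr$Wf + colSums(cs$x * da_f); gr$Wo <- gr$Wo + colSums(cs$x * da_o)
    gr$Uc <- gr$Uc + crossprod(cs$h_prev, da_c)
    gr$Ui <- gr$Ui + crossprod(cs$h_prev, da_i)
    gr$Uf <- gr$Uf + crossprod(cs$h_prev, da_f)
    gr$Uo <- gr$Uo + crossprod(cs$h_prev, da_o)
    gr$bc <- gr$bc + colSums(da_c); gr$bi <- gr$bi + colSums(da_i)
    gr$bf <- gr$bf + colSums(da_f); gr$bo <- gr$bo + colSums(da_o)
    dh <- da_c %*% t(w$Uc) + da_i %*% t(w$Ui) +
      da_f %*% t(w$Uf) + da_o %*% t(w$Uo) + dh * (1 - m)
    dc <- dct * cs$f + dc * (1 - m)
  }
  gr
}

#' Cross-entropy loss
#'
#' Mean over patients of \eqn{-[o \log \hat o + (1-o) \log(1-\hat o)]}.
#' Predicted risks exactly at 0 or 1 are clipped to \code{[eps, 1-eps]}
#' with a warning.
#'
#' @param labels 0/1 vector.
#' @param risks predicted probabilities.
#' @param eps clipping bound (default 1e-7).
#' @export
cross_entropy_loss <- function(labels, risks, eps = 1e-7) {
  stopifnot(length(labels) == length(risks))
  if (any(risks <= 0 | risks >= 1)) {
    warning("risks clipped away from {0, 1} for the cross-entropy loss")
    risks <- pmin(pmax(risks, eps), 1 - eps)
  }
  mean(-(labels * log(risks) + (1 - labels) * log(1 - risks)))
}
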