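# Markov-random-field prior over the per-patient change indicators
# I = (I_1, ..., I_K).  The joint pmf is
#   P(I) \propto exp(mu_I * sum_k I_k + eta_I * I' R I)
# with R strictly upper triangular, so eta_I > 0 couples the indicators:
# a change point in one marker raises the conditional odds of one in the
# others.  K is small (markers per panel), so the normalizing constant is
# computed by exact enumeration of the 2^K states.

#' Default coupling matrix
#'
#' Strictly upper-triangular matrix of ones: every marker pair carries the
#' same coupling weight \code{eta_I}.
#'
#' @param K number of markers.
#' @return K x K strictly upper triangular 0/1 matrix.
#' @export
default_coupling_matrix <- function(K) {
  R <- matrix(0, K, K)
  R[upper.tri(R)] <- 1
  R
}

check_coupling_matrix <- function(R, K) {
  if (!is.matrix(R) || nrow(R) != K || ncol(R) != K) {
    stop("R must be a ", K, " x ", K, " matrix")
  }
  if (any(R[lower.tri(R, diag = TRUE)] != 0)) {
    stop("R must be strictly upper triangular")
  }
  invisible(R)
}

# All 2^K indicator configurations as a matrix (rows = states).
mrf_states <- function(K) {
  unname(as.matrix(expand.grid(rep(list(c(0, 1)), K))))
}

#' Unnormalized log-mass of an indicator configuration
#'
#' @param I binary vector (or matrix with configurations in rows).
#' @param mu_I sparsity parameter; \code{plogis(mu_I)} is the marginal
#'   change-point probability when \code{eta_I = 0}.
#' @param eta_I coupling coefficient, >= 0.
#' @param R strictly upper triangular coupling matrix.
#' @return numeric vector of unnormalized log-masses.
#' @export
mrf_log_potential <- function(I, mu_I, eta_I, R) {
  if (is.vector(I)) I <- matrix(I, nrow = 1)
  K <- ncol(I)
  check_coupling_matrix(R, K)
  quad <- rowSums((I %*% R) * I)
  mu_I * rowSums(I) + eta_I * quad
}

#' Exact log normalizing constant of the indicator MRF
#'
#' Enumerates all 2^K states; K is capped at 12.
#' @inheritParams mrf_log_potential
#' @param K number of markers.
#' @export
mrf_log_normconst <- function(mu_I, eta_I, R, K) {
  if (K > 12) stop("exact enumeration supported only for K <= 12")
  logsumexp(mrf_log_potential(mrf_states(K), mu_I, eta_I, R))
}

#' Normalized pmf of the indicator MRF over all 2^K states
#'
#' @inheritParams mrf_log_normconst
#' @return list with \code{states} (2^K x K matrix) and \code{prob}.
#' @export
mrf_pmf <- function(mu_I, eta_I, R, K) {
  states <- mrf_states(K)
  lp <- mrf_log_potential(states, mu_I, eta_I, R)
  p <- exp(lp - logsumexp(lp))
  list(states = states, prob = p)
}

#' Log pmf (normalized) of one configuration
#' @inheritParams mrf_log_potential
#' @export
mrf_log_pmf <- function(I, mu_I, eta_I, R) {
  K <- if (is.vector(I)) length(I) else ncol(I)
  mrf_log_potential(I, mu_I, eta_I, R) - mrf_log_normconst(mu_I, eta_I, R, K)
}

#' Conditional probability P(I_k = 1 | I_{-k})
#'
#' The full conditional of one indicator given the rest is logistic:
#' \eqn{P(I_k = 1 | I_{-k}) = plogis(mu_I + eta_I \sum_{k' \ne k} w_{kk'} I_{k'})}
#' with symmetric weights \eqn{w_{kk'} = R_{kk'} + R_{k'k}}.
#'
#' @param I current binary vector.
#' @param k index of the indicator being updated.
#' @inheritParams mrf_log_potential
#' @export
mrf_conditional_prob <- function(I, k, mu_I, eta_I, R) {
  W <- R + t(R)
  plogis_(mu_I + eta_I * sum(W[k, ] * I) - eta_I * W[k, k] * I[k])
}

#' Draw indicator vectors from the MRF by exact enumeration
#'
#' @param n number of vectors to draw.
#' @inheritParams mrf_log_normconst
#' @return n x K binary matrix.
#' @export
sample_indicators <- function(n, mu_I, eta_I, R, K) {
  pmf <- mrf_pmf(mu_I, eta_I, R, K)
  idx <- sample.int(nrow(pmf$states), n, replace = TRUE, prob = pmf$prob)
  pmf$states[idx, , drop = FALSE]
}
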