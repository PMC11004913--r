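# Likelihood of the joint multivariable change-point model, on the
# transformed scale.  Controls (and cases with an inactive indicator):
#   Y_ijk = theta_ik + eps_ijk,        eps ~ N(0, sig2_k)
# Cases with I_ik = 1 gain a hinge after the latent change point tau_ik:
#   Y_ijk = theta_ik + gamma_ik (t_ij - tau_ik)_+ + eps_ijk
# Everything factorizes over patients, markers and visits given the latents.

# Hinge mean shift, N x Tmax x K.  gam is on the natural scale.
mean_shift <- function(arr, I, gam, tau) {
  out <- array(0, dim = dim(arr$Y))
  for (k in seq_len(arr$K)) {
    act <- I[, k] == 1
    if (any(act)) {
      hinge <- pmax(arr$t[act, , drop = FALSE] - tau[act, k], 0)
      out[act, , k] <- gam[act, k] * hinge
    }
  }
  out
}

# Per patient-and-marker log-likelihood matrix (N x K).
loglik_matrix <- function(arr, theta, I, gam, tau, sig2) {
  ll <- matrix(0, arr$N, arr$K)
  shift <- mean_shift(arr, I, gam, tau)
  for (k in seq_len(arr$K)) {
    Yk <- arr$Y[, , k, drop = FALSE]; dim(Yk) <- c(arr$N, arr$Tmax)
    sk <- shift[, , k, drop = FALSE]; dim(sk) <- c(arr$N, arr$Tmax)
    r <- Yk - theta[, k] - sk
    ld <- stats::dnorm(r, 0, sqrt(sig2[k]), log = TRUE)
    ld[!arr$mask] <- 0
    ll[, k] <- rowSums(ld)
  }
  ll
}

#' Log-likelihood of the change-point model
#'
#' Sums normal log-densities over all patients, markers and visits: controls
#' and inactive case-markers contribute flat-mean terms, active case-markers
#' the hinge-mean terms with positive part \eqn{(t - \tau)_+}. The 1/sigma
#' Jacobian of the normal pdf is included.
#'
#' @param cohort a \code{screening_cohort}.
#' @param biomarker_params list with element \code{sig2}: per-marker residual
#'   variances (length K, positive).
#' @param subject_params list with N x K matrices \code{theta},
#'   \code{I} (binary; control rows must be 0), \code{gamma} (natural-scale
#'   slopes) and \code{tau} (change-point ages). \code{gamma}/\code{tau}
#'   entries are only read where \code{I == 1}.
#' @param markers optional marker subset/order.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(cohort, biomarker_params, subject_params,
                           markers = NULL) {
  arr <- cohort_arrays(cohort, markers)
  sig2 <- biomarker_params$sig2
  if (length(sig2) != arr$K) stop("sig2 must have one entry per marker")
  if (any(sig2 <= 0)) stop("residual variances must be positive")
  I <- subject_params$I
  if (any(I[arr$status == 0, ] != 0)) stop("controls cannot carry change points")
  gam <- subject_params$gamma
  tau <- subject_params$tau
  gam[I == 0] <- 0
  tau[I == 0] <- 0
  sum(loglik_matrix(arr, subject_params$theta, I, gam, tau, sig2))
}
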