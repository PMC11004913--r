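#' Log-transform raw biomarker levels
#'
#' Serum marker distributions are heavily right-skewed; all modelling in this
#' package is done on the shifted-log scale \eqn{Y = \log(Z + 4)}, where
#' \eqn{Z} is the raw assay level. The +4 shift keeps the transform defined
#' for the small negative values that background-corrected assays can report.
#'
#' @param z numeric vector of raw levels; every element must exceed -4.
#' @return numeric vector of transformed levels.
#' @seealso [inverse_transform_level()]
#' @examples
#' transform_level(c(12, 50, 30))
#' inverse_transform_level(transform_level(35)) # 35
#' @export
transform_level <- function(z) {
  if (!is.numeric(z)) stop("'z' must be numeric")
  if (any(z <= -4, na.rm = TRUE)) {
    stop("raw levels must be > -4 for the log(Z + 4) transform")
  }
  log(z + 4)
}

#' Inverse of the shifted-log level transform
#'
#' @param y numeric vector of transformed levels.
#' @return raw levels \eqn{Z = \exp(Y) - 4}.
#' @export
inverse_transform_level <- function(y) {
  if (!is.numeric(y)) stop("'y' must be numeric")
  exp(y) - 4
}
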