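#' Beta value from methylated/unmethylated probe intensities
#'
#' Computes the methylation fraction from raw probe intensities with the
#' standard +100 offset in the denominator, which regularizes low-intensity
#' probes:
#' \deqn{\beta = M / (U + M + 100)}
#'
#' @param meth Non-negative methylated-allele intensity (vector or matrix).
#' @param unmeth Non-negative unmethylated-allele intensity, same shape.
#' @param offset Denominator offset; 100 by convention.
#' @return Methylation fractions in \code{[0, 1)}, same shape as the input.
#' @examples
#' beta_from_intensities(900, 100)  # 900/1100
#' @export
beta_from_intensities <- function(meth, unmeth, offset = 100) {
  if (length(meth) != length(unmeth) &&
      length(meth) != 1 && length(unmeth) != 1)
    stop("meth and unmeth intensities must have compatible lengths")
  if (any(meth < 0) || any(unmeth < 0))
    stop("intensities must be non-negative")
  meth / (unmeth + meth + offset)
}

#' Beta/M-value transforms
#'
#' M-values are the logit (base 2) of beta values,
#' \code{M = log2(beta/(1-beta))}; they have approximately constant variance
#' across the methylation range and are the scale on which all linear models
#' in this package are fitted. \code{m_to_beta} is the exact inverse.
#'
#' @param beta Methylation fractions strictly inside (0, 1). Values at exactly
#'   0 or 1 are an error; clip first with [clip_beta()].
#' @param m M-values (any finite real).
#' @return Transformed values, same shape as the input.
#' @examples
#' beta_to_m(0.8)            # log2(4) = 2
#' m_to_beta(beta_to_m(0.137))
#' @export
beta_to_m <- function(beta) {
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE))
    stop("beta values must lie strictly in (0, 1); clip first (see clip_beta)")
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  # 1/(1 + 2^-m) is stable for large |m| (2^m/(2^m+1) overflows near m ~ 1024)
  1 / (1 + 2^(-m))
}

#' Clip beta values into the open unit interval
#'
#' Logit transforms and the entropy statistic need values strictly inside
#' (0, 1); measured or simulated fractions at exactly 0/1 are moved to the
#' boundary of a small margin.
#'
#' @param beta Numeric vector/matrix of methylation fractions.
#' @param eps Clipping margin (default 1e-6).
#' @return Values in \code{[eps, 1 - eps]}.
#' @export
clip_beta <- function(beta, eps = 1e-6) {
  pmin(pmax(beta, eps), 1 - eps)
}
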