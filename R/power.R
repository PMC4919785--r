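#' Analytic power of two-sample MR for a binary outcome
#'
#' Power of the two-sided Wald test of the pooled summary-statistic causal
#' estimate at level `alpha`, under the asymptotic normal approximation for a
#' binary outcome. The square-root non-centrality is
#' \deqn{\sqrt{NCP} = |\log OR| \sqrt{n \, R^2 \, K(1-K)}}
#' where \eqn{n} is the total outcome sample size, \eqn{K} the case fraction
#' and \eqn{R^2} the fraction of exposure variance explained by the
#' instrument; power is
#' \eqn{\Phi(\sqrt{NCP} - z_{1-\alpha/2}) + \Phi(-\sqrt{NCP} - z_{1-\alpha/2})}.
#' At `causal_or = 1` the power equals `alpha` exactly, and the function is
#' symmetric in `OR` and `1/OR`.
#'
#' @param n_total total outcome sample size (cases + controls).
#' @param case_fraction proportion of cases, in (0, 1).
#' @param r_squared instrument R-squared on the exposure, in (0, 1).
#' @param causal_or hypothesised causal odds ratio per exposure unit
#'   (vectorised; must be > 0).
#' @param alpha two-sided significance level (default 0.05).
#' @return power as a fraction in \[alpha, 1\], one value per `causal_or`.
#' @examples
#' # consortium-scale design: ~194k subjects, instrument R^2 = 1.5%
#' mr_power(194427, 63746 / 194427, 0.015, causal_or = c(0.9, 0.95))
#' @export
mr_power <- function(n_total, case_fraction, r_squared, causal_or,
                     alpha = 0.05) {
  .stop_if(n_total <= 0, "n_total must be positive")
  .stop_if(case_fraction <= 0 || case_fraction >= 1,
           "case_fraction must be in (0, 1)")
  .stop_if(r_squared <= 0 || r_squared >= 1, "r_squared must be in (0, 1)")
  .stop_if(any(!is.finite(causal_or)) || any(causal_or <= 0),
           "causal_or must be positive")
  .stop_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  z <- stats::qnorm(1 - alpha / 2)
  ncp_sqrt <- abs(log(causal_or)) *
    sqrt(n_total * r_squared * case_fraction * (1 - case_fraction))
  stats::pnorm(ncp_sqrt - z) + stats::pnorm(-ncp_sqrt - z)
}

#' Power curve over a grid of causal odds ratios
#'
#' @param causal_or numeric grid of odds ratios.
#' @inheritParams mr_power
#' @return data frame with columns `causal_or` and `power`, one row per grid
#'   point; power is monotone increasing in `|log(causal_or)|`.
#' @export
mr_power_curve <- function(causal_or, n_total, case_fraction, r_squared,
                           alpha = 0.05) {
  data.frame(
    causal_or = causal_or,
    power = mr_power(n_total, case_fraction, r_squared, causal_or, alpha)
  )
}
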