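#' Methylation attenuation of transcriptional activity
#'
#' Promoter methylation reduces both the effective binding of transcription
#' factors to a target gene and the gene's basal transcription.  The
#' attenuation is modelled as
#' \deqn{h(\beta) = \frac{1}{1 + (\beta / \beta_{1/2})^2}}
#' where \eqn{\beta \in [0, 1]} is the promoter methylation level of the gene
#' in a sample and \eqn{\beta_{1/2}} is the methylation level at which
#' activity is halved.  \eqn{h} is strictly decreasing with \eqn{h(0) = 1}
#' and \eqn{h(\beta_{1/2}) = 1/2}; with the default half-effect of 0.5,
#' \eqn{h(1) = 0.2}.
#'
#' @param beta Numeric vector of methylation levels in `[0, 1]`.
#' @param half_effect Methylation level at which activity is halved
#'   (default 0.5, the model's printed constant).  Must be positive.
#' @return Numeric vector of attenuation factors in `(0, 1]`.
#' @examples
#' methylation_attenuation(c(0, 0.5, 1))
#' @export
methylation_attenuation <- function(beta, half_effect = 0.5) {
  if (!is.numeric(beta)) {
    stop_genpnp("`beta` must be numeric.", "domain_error")
  }
  if (!is.numeric(half_effect) || length(half_effect) != 1 || half_effect <= 0) {
    stop_genpnp("`half_effect` must be a single positive number.", "domain_error")
  }
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad)) {
    stop_genpnp(
      sprintf(
        "Methylation levels must lie in [0, 1]; offending value(s): %s",
        paste(utils::head(signif(beta[bad], 4), 5), collapse = ", ")
      ),
      "domain_error"
    )
  }
  1 / (1 + (beta / half_effect)^2)
}
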