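#' Sigmoidal gene-activation profile
#'
#' Expected log-expression of a gene following a logistic activation program
#' along pseudotime: the gene sits at baseline \code{b}, switches on around
#' \code{t_on} with rate \code{k}, and saturates at its optimum \code{o}.
#'
#' @param t Pseudotime value(s) at which to evaluate the profile.
#' @param t_on Activation midpoint (pseudotime at half-amplitude).
#' @param k Activation rate; must be > 0.
#' @param o Optimum (saturating) log-expression; must satisfy \code{o >= b}.
#' @param b Baseline log-expression.
#' @return Numeric vector \code{b + (o - b) / (1 + exp(-k * (t - t_on)))}.
#' @examples
#' evaluate_activation_profile(0, t_on = 0, k = 1, o = 10, b = 0)  # midpoint: 5
#' @export
evaluate_activation_profile <- function(t, t_on, k, o, b) {
  stopifnot(is.numeric(t), is.numeric(t_on), is.numeric(k), is.numeric(o),
            is.numeric(b))
  if (!all(is.finite(c(t_on, k, o, b))) || any(!is.finite(t)))
    stop("evaluate_activation_profile: non-finite inputs")
  if (k <= 0) stop("evaluate_activation_profile: k must be > 0")
  if (o < b) stop("evaluate_activation_profile: o must be >= b")
  b + (o - b) / (1 + exp(-k * (t - t_on)))
}
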