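#' F-beta overlap measure between predicted and ground-truth heatmaps
#'
#' \deqn{F_\beta(S, T) = \frac{(1+\beta^2)\sum_i s_i t_i}{\sum_i s_i +
#' \sum_i t_i}}
#' where \eqn{s_i} is the predicted mass probability of pixel \eqn{i} and
#' \eqn{t_i} the binary ground truth. At \eqn{\beta = 1} and binary
#' \eqn{S} this is the Dice coefficient. By convention the measure is 1 when
#' both heatmaps are identically zero (a correct empty prediction is
#' rewarded, the ratio being 0/0 there).
#'
#' @param S predicted heatmap (array or vector, values in [0, 1]).
#' @param T_ ground-truth heatmap, congruent with \code{S}.
#' @param beta recall weight (default 1).
#' @return scalar in [0, 1].
#' @export
fbeta_measure <- function(S, T_, beta = 1) {
  if (length(S) != length(T_)) stop("shape mismatch between S and T")
  denom <- sum(S) + sum(T_)
  if (denom == 0) return(1)
  (1 + beta^2) * sum(S * T_) / denom
}

#' F-beta loss (1 - measure) and its gradient
#'
#' The training criterion is \code{1 - fbeta_measure(S, T, beta)}, a
#' differentiable overlap loss robust to the severe pixel class imbalance of
#' mass segmentation (a constant background prediction scores 0 overlap
#' instead of high accuracy). \code{fbeta_loss_grad} returns the closed-form
#' gradient with respect to each \eqn{s_i}:
#' \deqn{\frac{\partial L}{\partial s_i} = \frac{N}{D^2} -
#' \frac{(1+\beta^2)\, t_i}{D}}
#' with \eqn{N = (1+\beta^2)\sum s t} and \eqn{D = \sum s + \sum t}; it is
#' zero when \eqn{D = 0}.
#'
#' The optional \code{smooth} constant (default 0) gives the smoothed
#' training variant \eqn{((1+\beta^2)\sum st + \epsilon)/(\sum s + \sum t +
#' \epsilon)} standard in overlap-loss implementations: it leaves the
#' both-empty convention intact (\eqn{\epsilon/\epsilon = 1}) and, unlike
#' the raw ratio, gives empty-target patches a nonzero gradient that pushes
#' spurious foreground probability down instead of silently ignoring it.
#'
#' @inheritParams fbeta_measure
#' @param smooth nonnegative smoothing constant added to numerator and
#'   denominator (0 = the exact formula).
#' @return \code{fbeta_loss}: scalar loss in [0, 1]; \code{fbeta_loss_grad}:
#'   array of gradients congruent with \code{S}.
#' @export
fbeta_loss <- function(S, T_, beta = 1, smooth = 0) {
  if (length(S) != length(T_)) stop("shape mismatch between S and T")
  D <- sum(S) + sum(T_) + smooth
  if (D == 0) return(0)
  1 - ((1 + beta^2) * sum(S * T_) + smooth) / D
}

#' @rdname fbeta_loss
#' @export
fbeta_loss_grad <- function(S, T_, beta = 1, smooth = 0) {
  if (length(S) != length(T_)) stop("shape mismatch between S and T")
  D <- sum(S) + sum(T_) + smooth
  g <- array(0, dim = if (is.null(dim(S))) length(S) else dim(S))
  if (D == 0) return(g)
  N <- (1 + beta^2) * sum(S * T_) + smooth
  g[] <- N / D^2 - (1 + beta^2) * T_ / D
  g
}
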