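#' Loss weights
#'
#' Bundles the coefficients of the training objective
#' `total = main + lambda_kan * (gamma_a * ||W||_1 + gamma_e * sign_e * H(p))`
#' where `W` ranges over the spline-path parameters and `p` is the
#' distribution of their normalised absolute magnitudes.  The printed form of
#' the regularizer *adds* the entropy `H(p)` to the minimised loss
#' (`entropy_sign = +1`, the default); set `entropy_sign = -1` to *maximise*
#' entropy instead (the prose reading; see the methods vignette).
#'
#' @param lambda_kan Overall regularizer weight (default 0.001).
#' @param gamma_a Activation-sparsity (L1) coefficient (default 1).
#' @param gamma_e Entropy coefficient (default 1).
#' @param entropy_sign `+1` (default) or `-1`.
#' @return Object of class `"loss_weights"`.
#' @export
loss_weights <- function(lambda_kan = 0.001, gamma_a = 1.0, gamma_e = 1.0,
                         entropy_sign = 1) {
  stopifnot(lambda_kan >= 0, gamma_a >= 0, gamma_e >= 0,
            entropy_sign %in% c(-1, 1))
  structure(list(lambda_kan = lambda_kan, gamma_a = gamma_a,
                 gamma_e = gamma_e, entropy_sign = entropy_sign),
            class = "loss_weights")
}

#' Main reconstruction loss (mean absolute error on predicted noise)
#'
#' @param eps_pred,eps_true Equal-length numeric vectors (or matrices).
#' @return Non-negative scalar: `mean(|eps_pred - eps_true|)`.
#' @export
main_loss <- function(eps_pred, eps_true) {
  if (length(eps_pred) != length(eps_true))
    stop("shape error: prediction/target length mismatch", call. = FALSE)
  mean(abs(eps_pred - eps_true))
}

# Normalised absolute-magnitude distribution over all spline-path entries.
activation_distribution <- function(spline_weights) {
  a <- abs(unlist(spline_weights, use.names = FALSE))
  s <- sum(a)
  list(p = if (s > 0) a / s else a * 0, source_norm = s)
}

#' KAN regularization loss
#'
#' `gamma_a * sum(|w|) + gamma_e * entropy_sign * H(p)` with
#' `p_i = |w_i| / sum_j |w_j|` over every entry of every supplied spline-path
#' matrix, `0 log 0 := 0`, and both terms zero when all weights vanish.
#'
#' @param spline_weights List of numeric matrices/vectors: the spline-path
#'   weights (and standalone scales) of all KAN layers; see
#'   `kandiff:::spline_weight_set`.
#' @param weights A [loss_weights()] object.
#' @return Scalar regularization value (non-negative when
#'   `entropy_sign = +1`).
#' @export
kan_reg_loss <- function(spline_weights, weights = loss_weights()) {
  w <- unlist(spline_weights, use.names = FALSE)
  if (length(w) == 0L) return(0)
  if (any(!is.finite(w))) stop("invalid input: non-finite weights", call. = FALSE)
  dist <- activation_distribution(spline_weights)
  if (dist$source_norm == 0) return(0)
  p <- dist$p[dist$p > 0]
  H <- -sum(p * log(p))
  weights$gamma_a * dist$source_norm + weights$gamma_e * weights$entropy_sign * H
}

# Analytic gradient of kan_reg_loss, in the same list structure as the input.
# d/dw [ ga*S + ge*sgn_e*H ] with S = sum|w|, p = |w|/S:
#   dS/dw_i = sign(w_i);  dH/dw_i = sign(w_i) * (-log p_i - H) / S.
kan_reg_grad <- function(spline_weights, weights = loss_weights()) {
  w <- unlist(spline_weights, use.names = FALSE)
  S <- sum(abs(w))
  if (S == 0) return(lapply(spline_weights, function(x) x * 0))
  p <- abs(w) / S
  pn <- p[p > 0]
  H <- -sum(pn * log(pn))
  dH <- ifelse(p > 0, (-log(pmax(p, .Machine$double.xmin)) - H) / S, 0)
  g <- sign(w) * (weights$gamma_a + weights$gamma_e * weights$entropy_sign * dH)
  relist_like(g, spline_weights)
}

relist_like <- function(flat, template) {
  out <- template
  pos <- 0L
  for (i in seq_along(template)) {
    n <- length(template[[i]])
    x <- flat[pos + seq_len(n)]
    dim(x) <- dim(template[[i]])
    out[[i]] <- x
    pos <- pos + n
  }
  out
}

#' Total training loss
#'
#' `total = main + lambda_kan * reg`.
#'
#' @param main Main-loss value.
#' @param reg Regularizer value.
#' @param weights A [loss_weights()] object.
#' @return Scalar total loss.
#' @export
total_loss <- function(main, reg, weights = loss_weights()) {
  main + weights$lambda_kan * reg
}
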