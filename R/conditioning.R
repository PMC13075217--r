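#' Sinusoidal positional encoding of the diffusion noise scale
#'
#' Maps the scalar noise scale `sigma_t` of the current diffusion step into a
#' `d`-dimensional interleaved sin/cos embedding:
#' `z = (sin(sigma_t * e^{-0*lam}), cos(sigma_t * e^{-0*lam}), ...,
#' sin(sigma_t * e^{-(d/2-1)*lam}), cos(sigma_t * e^{-(d/2-1)*lam}))` with
#' `lam = log(10000) / (d/2)`.  Every component lies in `[-1, 1]`, which is why
#' the default KAN grid range is `[-1, 1]`: embeddings never need clamping.
#'
#' @param sigma_t Non-negative finite noise scale.
#' @param d Even embedding dimension, `d >= 2`.
#' @return An object of class `"noise_embedding"`: list with `sigma_t`, `d`,
#'   `lam` and the embedding vector `z`.
#' @export
positional_encode <- function(sigma_t, d) {
  if (length(d) != 1L || d < 2 || d %% 2 != 0)
    stop("invalid dimension: d must be an even integer >= 2", call. = FALSE)
  if (!is.finite(sigma_t) || sigma_t < 0)
    stop("invalid input: sigma_t must be finite and >= 0", call. = FALSE)
  lam <- log(10000) / (d / 2)
  structure(
    list(sigma_t = sigma_t, d = as.integer(d), lam = lam,
         z = pe_matrix(sigma_t, d)[, 1L]),
    class = "noise_embedding"
  )
}

# Batched positional encoding: one column per sigma value (d x B matrix).
pe_matrix <- function(sigmas, d) {
  lam <- log(10000) / (d / 2)
  freqs <- exp(-(0:(d / 2 - 1)) * lam)
  arg <- outer(freqs, sigmas)                 # (d/2) x B
  z <- matrix(0, nrow = d, ncol = length(sigmas))
  z[seq(1L, d, by = 2L), ] <- sin(arg)
  z[seq(2L, d, by = 2L), ] <- cos(arg)
  z
}

as_embedding_vec <- function(z) {
  if (inherits(z, "noise_embedding")) z$z else as.numeric(z)
}

#' Parameters of the linear affine conditioning layer
#'
#' The ablation-baseline conditioner: a single dense map `W z + b` whose
#' `2C`-dimensional output is split into the per-channel modulation pair
#' (`gamma`, `beta`).
#'
#' @param C Number of feature channels modulated.
#' @param d Embedding dimension.
#' @param W,b Optional explicit weights (`2C x d`) and bias (`2C`); defaults
#'   are fan-in scaled Gaussian weights and zero bias.
#' @return Object of class `"linear_affine_params"`.
#' @export
linear_affine_params <- function(C, d, W = NULL, b = NULL) {
  if (is.null(W)) W <- matrix(stats::rnorm(2 * C * d, sd = 1 / sqrt(d)), 2 * C, d)
  if (is.null(b)) b <- numeric(2 * C)
  stopifnot(nrow(W) == 2 * C, ncol(W) == d, length(b) == 2 * C)
  structure(list(C = as.integer(C), d = as.integer(d), W = W, b = b),
            class = "linear_affine_params")
}

#' Linear affine conditioning: embedding -> (gamma, beta)
#'
#' @param params A [linear_affine_params()] object.
#' @param z Embedding vector of length `d` (or a [positional_encode()] result).
#' @return List with numeric vectors `gamma` and `beta`, each of length `C`.
#' @export
linear_affine <- function(params, z) {
  z <- as_embedding_vec(z)
  if (length(z) != params$d)
    stop("shape error: embedding length != d", call. = FALSE)
  v <- drop(params$W %*% z + params$b)
  split_gamma_beta(v, params$C)
}

split_gamma_beta <- function(v, C) {
  list(gamma = v[seq_len(C)], beta = v[C + seq_len(C)])
}

silu <- function(x) x * stats::plogis(x)
silu_grad <- function(x) { s <- stats::plogis(x); s * (1 + x * (1 - s)) }

base_activation_fun <- function(name) {
  switch(name,
         silu = silu,
         identity = identity,
         stop("unknown base activation: ", name, call. = FALSE))
}

#' Parameters of a KAN (B-spline) conditioning layer
#'
#' A dual-path Kolmogorov-Arnold transform replacing the linear conditioner:
#' `out = scale_base * W_base %*% act(z) + scale_spline * (S * W_spline) %*% B(z)`
#' where `act` is the base activation (default SiLU), `B(z)` concatenates the
#' `n_basis` B-spline basis values of every embedding component (length
#' `d * n_basis`), and `S` is the optional standalone per-(output, input)
#' spline scale (initialised to 1, one multiplier broadcast over each input's
#' basis block).  With zero spline weights and an identity base activation the
#' layer reduces exactly to the bias-free linear conditioner.
#'
#' Spline weights are initialised near zero so a fresh KAN layer starts close
#' to its linear ablation; base weights use fan-in scaling.
#'
#' @param C Number of modulated channels.
#' @param d Embedding dimension.
#' @param grid A [build_grid()] object shared by all inputs of the layer.
#' @param base_activation `"silu"` (default) or `"identity"`.
#' @param scale_base,scale_spline Fixed path multipliers (default 1).
#' @param standalone_scale_spline Add a learnable per-(output, input)
#'   multiplier on the spline path (default `TRUE`).
#' @param W_base,W_spline,spline_scale Optional explicit parameters.
#' @param init_noise Spread of the near-zero spline-weight initialisation.
#' @return Object of class `"kan_layer_params"`.
#' @export
kan_layer_params <- function(C, d, grid = build_grid(5, 3),
                             base_activation = "silu",
                             scale_base = 1.0, scale_spline = 1.0,
                             standalone_scale_spline = TRUE,
                             W_base = NULL, W_spline = NULL,
                             spline_scale = NULL, init_noise = 0.01) {
  nb <- grid$n_basis
  if (is.null(W_base))
    W_base <- matrix(stats::rnorm(2 * C * d, sd = 1 / sqrt(d)), 2 * C, d)
  if (is.null(W_spline))
    W_spline <- matrix(stats::runif(2 * C * d * nb, -init_noise, init_noise),
                       2 * C, d * nb)
  if (is.null(spline_scale))
    spline_scale <- matrix(1, 2 * C, d)
  stopifnot(nrow(W_base) == 2 * C, ncol(W_base) == d,
            nrow(W_spline) == 2 * C, ncol(W_spline) == d * nb,
            nrow(spline_scale) == 2 * C, ncol(spline_scale) == d)
  structure(
    list(C = as.integer(C), d = as.integer(d), grid = grid,
         base_activation = base_activation,
         scale_base = scale_base, scale_spline = scale_spline,
         standalone_scale_spline = isTRUE(standalone_scale_spline),
         W_base = W_base, W_spline = W_spline, spline_scale = spline_scale),
    class = "kan_layer_params"
  )
}

# d*n_basis x B spline feature expansion of an embedding matrix (d x B):
# rows are grouped by input component, n_basis consecutive rows per component.
spline_expand <- function(grid, zmat) {
  d <- nrow(zmat); B <- ncol(zmat); nb <- grid$n_basis
  bm <- basis_matrix(grid, as.vector(zmat))    # (d*B) x nb, column-major over z
  phi <- array(aperm(array(bm, c(d, B, nb)), c(3L, 1L, 2L)), c(nb * d, B))
  phi
}

# effective spline weight with standalone scales folded in
kan_effective_spline_w <- function(params) {
  if (!params$standalone_scale_spline) return(params$W_spline)
  nb <- params$grid$n_basis
  params$W_spline * params$spline_scale[, rep(seq_len(params$d), each = nb), drop = FALSE]
}

#' KAN affine conditioning: embedding -> (gamma, beta)
#'
#' Evaluates the dual-path spline conditioner described in
#' [kan_layer_params()].
#'
#' @param params A [kan_layer_params()] object.
#' @param z Embedding vector of length `d` (or a [positional_encode()] result).
#' @return List with numeric vectors `gamma` and `beta`, each of length `C`.
#' @export
kan_affine <- function(params, z) {
  z <- as_embedding_vec(z)
  if (length(z) != params$d)
    stop("shape error: embedding length != d", call. = FALSE)
  zm <- matrix(z, ncol = 1L)
  act <- base_activation_fun(params$base_activation)
  out <- params$scale_base * drop(params$W_base %*% act(zm)) +
    params$scale_spline * drop(kan_effective_spline_w(params) %*% spline_expand(params$grid, zm))
  split_gamma_beta(out, params$C)
}

#' Feature-wise affine (FiLM) modulation
#'
#' Applies `h_out[c, l] = (1 + gamma[c]) * h_in[c, l] + beta[c]`, broadcasting
#' the per-channel pair across the time axis.  `gamma = beta = 0` is the
#' identity.
#'
#' @param h_in Feature map: numeric matrix with `C` rows (channels) and `L`
#'   columns (time positions); a plain vector is treated as one channel.
#' @param gamma,beta Numeric vectors of length `C`.
#' @return Modulated feature map, same shape as `h_in`.
#' @export
film_modulate <- function(h_in, gamma, beta) {
  vec_in <- is.null(dim(h_in))
  h <- if (vec_in) matrix(h_in, nrow = 1L) else h_in
  if (length(gamma) != nrow(h) || length(beta) != nrow(h))
    stop("shape error: gamma/beta length must equal channel count", call. = FALSE)
  out <- (1 + gamma) * h + beta
  if (vec_in) drop(out) else out
}
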