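#' Configuration of the conditional denoising backbone
#'
#' A 1-D multi-scale residual convolutional network realising the conditional
#' noise predictor `eps_theta(x_t, sigma_t, x~)`.  The noisy observation `x~`
#' is concatenated with `x_t` on the channel axis at the input (signal-based
#' conditioning); the noise level enters every cross-level Bridge module as a
#' feature-wise affine modulation whose (gamma, beta) pair is produced either
#' by a plain linear layer or by a KAN B-spline layer — the switch the whole
#' ablation hinges on.
#'
#' @param segment_length Samples per input segment (default 512); must be
#'   divisible by `2^(n_levels - 1)`.
#' @param hidden_features Channel width of every level (default 80).
#' @param n_levels Number of resolution levels (default 3).
#' @param blocks_per_level Residual blocks per encoder level (default 2).
#' @param conditioning_kind `"kan"` (default) or `"linear"`.
#' @param embedding_dim Even embedding dimension `d`
#'   (default `2 * hidden_features`).
#' @param grid_size,spline_order,grid_range KAN grid: number of grid points
#'   `G`, spline order `k`, and domain (defaults 5, 3, `c(-1, 1)`).
#' @param base_activation,scale_base,scale_spline,standalone_scale_spline
#'   KAN layer options (defaults SiLU, 1.0, 1.0, enabled).
#' @param sigma_map How the step index `t` is mapped to the encoded noise
#'   scale; `"sqrt_beta"` (default) encodes `sqrt(beta_t)`.
#' @return Object of class `"denoiser_config"`.
#' @export
denoiser_config <- function(segment_length = 512L, hidden_features = 80L,
                            n_levels = 3L, blocks_per_level = 2L,
                            conditioning_kind = c("kan", "linear"),
                            embedding_dim = 2L * hidden_features,
                            grid_size = 5L, spline_order = 3L,
                            grid_range = c(-1, 1),
                            base_activation = "silu",
                            scale_base = 1.0, scale_spline = 1.0,
                            standalone_scale_spline = TRUE,
                            sigma_map = "sqrt_beta") {
  conditioning_kind <- match.arg(conditioning_kind)
  if (segment_length %% 2^(n_levels - 1) != 0)
    stop("segment_length must be divisible by 2^(n_levels - 1)", call. = FALSE)
  if (embedding_dim %% 2 != 0)
    stop("embedding_dim must be even", call. = FALSE)
  structure(
    list(segment_length = as.integer(segment_length),
         hidden_features = as.integer(hidden_features),
         n_levels = as.integer(n_levels),
         blocks_per_level = as.integer(blocks_per_level),
         conditioning_kind = conditioning_kind,
         embedding_dim = as.integer(embedding_dim),
         grid_size = as.integer(grid_size),
         spline_order = as.integer(spline_order),
         grid_range = as.numeric(grid_range),
         base_activation = base_activation,
         scale_base = scale_base, scale_spline = scale_spline,
         standalone_scale_spline = isTRUE(standalone_scale_spline),
         sigma_map = sigma_map),
    class = "denoiser_config"
  )
}

new_conv <- function(c_out, c_in, kernel, zero = FALSE) {
  fan_in <- c_in * kernel
  W <- if (zero) matrix(0, c_out, fan_in)
       else matrix(stats::rnorm(c_out * fan_in, sd = sqrt(1 / fan_in)), c_out, fan_in)
  list(W = W, b = numeric(c_out))
}

#' Initialise a denoiser model
#'
#' Builds the parameter tree for [predict_noise()].  The final output
#' projection is zero-initialised so a freshly created model predicts zero
#' noise for any input (a standard stabilisation for diffusion backbones that
#' the shape tests also rely on).
#'
#' @param config A [denoiser_config()].
#' @param seed Optional integer seed for reproducible initialisation.
#' @return Object of class `"kan_denoiser"`: list with `config` and `params`.
#' @export
init_denoiser <- function(config, seed = NULL) {
  stopifnot(inherits(config, "denoiser_config"))
  if (!is.null(seed)) set.seed(seed)
  C <- config$hidden_features
  d <- config$embedding_dim
  grid <- build_grid(config$grid_size, config$spline_order,
                     config$grid_range[1], config$grid_range[2])
  mk_block <- function() list(conv1 = new_conv(C, C, 3), conv2 = new_conv(C, C, 3))
  mk_affine <- function() {
    if (config$conditioning_kind == "linear") {
      linear_affine_params(C, d)
    } else {
      kan_layer_params(C, d, grid = grid,
                       base_activation = config$base_activation,
                       scale_base = config$scale_base,
                       scale_spline = config$scale_spline,
                       standalone_scale_spline = config$standalone_scale_spline)
    }
  }
  params <- list(
    conv_in = new_conv(C, 2, 3),
    enc = lapply(seq_len(config$n_levels), function(l)
      lapply(seq_len(config$blocks_per_level), function(b) mk_block())),
    bridge = lapply(seq_len(config$n_levels), function(l)
      list(proj = new_conv(C, C, 1), affine = mk_affine())),
    dec = if (config$n_levels > 1)
      lapply(seq_len(config$n_levels - 1), function(l) mk_block()) else list(),
    conv_out = new_conv(1, C, 3, zero = TRUE)
  )
  structure(list(config = config, params = params, grid = grid),
            class = "kan_denoiser")
}

## ---- low-level array ops (C x L x B activations) -------------------------

shift_stack <- function(h) {
  dm <- dim(h); C <- dm[1]; L <- dm[2]
  X <- array(0, c(3L * C, L, dm[3]))
  X[seq_len(C), 2:L, ] <- h[, seq_len(L - 1L), , drop = FALSE]
  X[C + seq_len(C), , ] <- h
  X[2L * C + seq_len(C), seq_len(L - 1L), ] <- h[, 2:L, , drop = FALSE]
  X
}

conv3_fwd <- function(p, h) {
  dm <- dim(h)
  X <- shift_stack(h); dim(X) <- c(3L * dm[1], dm[2] * dm[3])
  Y <- p$W %*% X + p$b
  array(Y, c(nrow(p$W), dm[2], dm[3]))
}

conv3_bwd <- function(p, h, dY) {
  dm <- dim(h); C <- dm[1]; L <- dm[2]; B <- dm[3]
  X <- shift_stack(h); dim(X) <- c(3L * C, L * B)
  dYm <- dY; dim(dYm) <- c(nrow(p$W), L * B)
  dW <- tcrossprod(dYm, X)
  db <- rowSums(dYm)
  dX <- crossprod(p$W, dYm); dim(dX) <- c(3L * C, L, B)
  dh <- array(0, dm)
  dh[, seq_len(L - 1L), ] <- dX[seq_len(C), 2:L, , drop = FALSE]
  dh <- dh + dX[C + seq_len(C), , , drop = FALSE]
  dh[, 2:L, ] <- dh[, 2:L, , drop = FALSE] +
    dX[2L * C + seq_len(C), seq_len(L - 1L), , drop = FALSE]
  list(dh = dh, grads = list(W = dW, b = db))
}

conv1_fwd <- function(p, h) {
  dm <- dim(h)
  H <- h; dim(H) <- c(dm[1], dm[2] * dm[3])
  Y <- p$W %*% H + p$b
  array(Y, c(nrow(p$W), dm[2], dm[3]))
}

conv1_bwd <- function(p, h, dY) {
  dm <- dim(h)
  H <- h; dim(H) <- c(dm[1], dm[2] * dm[3])
  dYm <- dY; dim(dYm) <- c(nrow(p$W), dm[2] * dm[3])
  dh <- crossprod(p$W, dYm); dim(dh) <- dm
  list(dh = dh, grads = list(W = tcrossprod(dYm, H), b = rowSums(dYm)))
}

avgpool_fwd <- function(h) {
  L <- dim(h)[2]
  (h[, seq(1L, L, 2L), , drop = FALSE] + h[, seq(2L, L, 2L), , drop = FALSE]) / 2
}

avgpool_bwd <- function(d, L_full) {
  dm <- dim(d)
  dh <- array(0, c(dm[1], L_full, dm[3]))
  dh[, seq(1L, L_full, 2L), ] <- d / 2
  dh[, seq(2L, L_full, 2L), ] <- d / 2
  dh
}

upsample_fwd <- function(g) {
  L <- dim(g)[2]
  g[, rep(seq_len(L), each = 2L), , drop = FALSE]
}

upsample_bwd <- function(d) {
  L <- dim(d)[2]
  d[, seq(1L, L, 2L), , drop = FALSE] + d[, seq(2L, L, 2L), , drop = FALSE]
}

expand_cb <- function(m, L) {                 # C x B -> C x L x B
  aperm(array(m, c(nrow(m), ncol(m), L)), c(1L, 3L, 2L))
}

film3_fwd <- function(h, gamma, beta) {
  L <- dim(h)[2]
  (1 + expand_cb(gamma, L)) * h + expand_cb(beta, L)
}

## ---- conditioning (batched, z has no trainable upstream) -----------------

affine_fwd_batch <- function(aff, z, phi = NULL) {
  if (inherits(aff, "linear_affine_params")) {
    list(V = aff$W %*% z + aff$b, act = NULL)
  } else {
    actf <- base_activation_fun(aff$base_activation)
    A <- actf(z)
    V <- aff$scale_base * (aff$W_base %*% A) +
      aff$scale_spline * (kan_effective_spline_w(aff) %*% phi)
    list(V = V, act = A)
  }
}

affine_bwd_batch <- function(aff, z, phi, cache, dV) {
  if (inherits(aff, "linear_affine_params")) {
    list(W = tcrossprod(dV, z), b = rowSums(dV))
  } else {
    nb <- aff$grid$n_basis; d <- aff$d
    dWb <- aff$scale_base * tcrossprod(dV, cache$act)
    dWeff <- aff$scale_spline * tcrossprod(dV, phi)
    if (aff$standalone_scale_spline) {
      Sexp <- aff$spline_scale[, rep(seq_len(d), each = nb), drop = FALSE]
      dWs <- dWeff * Sexp
      agg <- kronecker(diag(d), matrix(1, nb, 1))      # (d*nb) x d block sums
      dS <- (dWeff * aff$W_spline) %*% agg
      list(W_base = dWb, W_spline = dWs, spline_scale = dS)
    } else {
      list(W_base = dWb, W_spline = dWeff, spline_scale = aff$spline_scale * 0)
    }
  }
}

## ---- full network --------------------------------------------------------

# Batched forward pass.  xt, cond: L x B matrices; sigmas: length-B vector.
# Returns predicted noise (L x B) plus, if keep_cache, everything backward needs.
denoiser_forward <- function(model, xt, sigmas, cond, keep_cache = FALSE) {
  cfg <- model$config; p <- model$params
  L <- nrow(xt); B <- ncol(xt)
  if (L != cfg$segment_length)
    stop("shape error: segment length mismatch", call. = FALSE)
  if (!all(is.finite(xt)) || !all(is.finite(cond)) || !all(is.finite(sigmas)))
    stop("invalid input: non-finite values", call. = FALSE)
  if (length(sigmas) == 1L) sigmas <- rep(sigmas, B)
  z <- pe_matrix(sigmas, cfg$embedding_dim)
  phi <- if (cfg$conditioning_kind == "kan") spline_expand(model$grid, z) else NULL

  input <- array(0, c(2L, L, B))
  input[1L, , ] <- xt; input[2L, , ] <- cond
  cache <- list(z = z, phi = phi, input = input,
                enc_in = vector("list", cfg$n_levels),
                blk = vector("list", cfg$n_levels),
                bridge_h = vector("list", cfg$n_levels),
                bridge_p = vector("list", cfg$n_levels),
                gamma = vector("list", cfg$n_levels),
                beta = vector("list", cfg$n_levels),
                aff = vector("list", cfg$n_levels),
                dec_in = vector("list", max(cfg$n_levels - 1L, 0L)),
                dec_a1 = vector("list", max(cfg$n_levels - 1L, 0L)),
                dec_u = vector("list", max(cfg$n_levels - 1L, 0L)))

  h <- conv3_fwd(p$conv_in, input)
  skips <- vector("list", cfg$n_levels)
  for (l in seq_len(cfg$n_levels)) {
    cache$enc_in[[l]] <- h
    blocks <- vector("list", cfg$blocks_per_level)
    for (b in seq_len(cfg$blocks_per_level)) {
      a1 <- conv3_fwd(p$enc[[l]][[b]]$conv1, h)
      u <- silu(a1)
      a2 <- conv3_fwd(p$enc[[l]][[b]]$conv2, u)
      blocks[[b]] <- list(h_in = h, a1 = a1, u = u)
      h <- h + a2
    }
    cache$blk[[l]] <- blocks
    ac <- affine_fwd_batch(p$bridge[[l]]$affine, z, phi)
    gb <- list(gamma = ac$V[seq_len(cfg$hidden_features), , drop = FALSE],
               beta = ac$V[cfg$hidden_features + seq_len(cfg$hidden_features), , drop = FALSE])
    pr <- conv1_fwd(p$bridge[[l]]$proj, h)
    skips[[l]] <- film3_fwd(pr, gb$gamma, gb$beta)
    cache$bridge_h[[l]] <- h; cache$bridge_p[[l]] <- pr
    cache$gamma[[l]] <- gb$gamma; cache$beta[[l]] <- gb$beta
    cache$aff[[l]] <- ac
    if (l < cfg$n_levels) h <- avgpool_fwd(h)
  }

  g <- skips[[cfg$n_levels]]
  if (cfg$n_levels > 1) {
    for (l in seq(cfg$n_levels - 1L, 1L)) {
      g <- upsample_fwd(g) + skips[[l]]
      cache$dec_in[[l]] <- g
      a1 <- conv3_fwd(p$dec[[l]]$conv1, g)
      u <- silu(a1)
      cache$dec_a1[[l]] <- a1; cache$dec_u[[l]] <- u
      g <- g + conv3_fwd(p$dec[[l]]$conv2, u)
    }
  }
  cache$g_final <- g
  out <- conv3_fwd(p$conv_out, g)
  eps <- out[1L, , ]; dim(eps) <- c(L, B)
  if (keep_cache) list(eps = eps, cache = cache) else list(eps = eps)
}

# Backward pass: gradient of a scalar loss wrt all parameters, given
# d(loss)/d(eps) as an L x B matrix.  Mirrors denoiser_forward exactly.
denoiser_backward <- function(model, cache, deps) {
  cfg <- model$config; p <- model$params
  L <- cfg$segment_length; B <- ncol(deps)
  C <- cfg$hidden_features
  gr <- list()

  dOut <- array(deps, c(1L, L, B))
  cb <- conv3_bwd(p$conv_out, cache$g_final, dOut)
  gr$conv_out <- cb$grads
  dg <- cb$dh

  dskips <- vector("list", cfg$n_levels)
  gr$dec <- list()
  if (cfg$n_levels > 1) {
    for (l in seq_len(cfg$n_levels - 1L)) {
      b2 <- conv3_bwd(p$dec[[l]]$conv2, cache$dec_u[[l]], dg)
      da1 <- b2$dh * silu_grad(cache$dec_a1[[l]])
      b1 <- conv3_bwd(p$dec[[l]]$conv1, cache$dec_in[[l]], da1)
      gr$dec[[l]] <- list(conv1 = b1$grads, conv2 = b2$grads)
      dv <- dg + b1$dh                      # gradient at upsample(g) + skip[l]
      dskips[[l]] <- dv
      dg <- upsample_bwd(dv)
    }
  }
  dskips[[cfg$n_levels]] <- dg

  gr$enc <- vector("list", cfg$n_levels)
  gr$bridge <- vector("list", cfg$n_levels)
  dh_next <- NULL                            # gradient flowing from level below
  for (l in seq(cfg$n_levels, 1L)) {
    dh <- if (l < cfg$n_levels) avgpool_bwd(dh_next, dim(cache$bridge_h[[l]])[2]) else NULL
    # bridge: film then 1x1 projection
    ds <- dskips[[l]]
    Ll <- dim(ds)[2]
    dp <- (1 + expand_cb(cache$gamma[[l]], Ll)) * ds
    dgamma <- colSums(aperm(ds * cache$bridge_p[[l]], c(2L, 1L, 3L)))
    dbeta <- colSums(aperm(ds, c(2L, 1L, 3L)))
    dV <- rbind(dgamma, dbeta)
    gr$bridge[[l]] <- list(
      proj = NULL,
      affine = affine_bwd_batch(p$bridge[[l]]$affine, cache$z, cache$phi,
                                cache$aff[[l]], dV))
    pb <- conv1_bwd(p$bridge[[l]]$proj, cache$bridge_h[[l]], dp)
    gr$bridge[[l]]$proj <- pb$grads
    dh <- if (is.null(dh)) pb$dh else dh + pb$dh
    # residual blocks in reverse
    gr$enc[[l]] <- vector("list", cfg$blocks_per_level)
    for (b in seq(cfg$blocks_per_level, 1L)) {
      bc <- cache$blk[[l]][[b]]
      b2 <- conv3_bwd(p$enc[[l]][[b]]$conv2, bc$u, dh)
      da1 <- b2$dh * silu_grad(bc$a1)
      b1 <- conv3_bwd(p$enc[[l]][[b]]$conv1, bc$h_in, da1)
      gr$enc[[l]][[b]] <- list(conv1 = b1$grads, conv2 = b2$grads)
      dh <- dh + b1$dh
    }
    dh_next <- dh
  }
  cb_in <- conv3_bwd(p$conv_in, cache$input, dh_next)
  gr$conv_in <- cb_in$grads
  gr
}

#' Predict the injected diffusion noise
#'
#' Evaluates the conditional noise predictor `eps_theta(x_t, sigma_t, x~)` on
#' one segment.  `model` may be a [init_denoiser()] network or, for testing,
#' any function `f(x_t, sigma_t, x_cond)` returning a same-length vector
#' (a "stub model").
#'
#' @param model A `"kan_denoiser"` object or a function.
#' @param x_t Numeric vector: the current diffusion state.
#' @param sigma_t Non-negative noise scale encoded for conditioning.
#' @param x_cond Numeric vector: the noisy observation used as guide.
#' @return Numeric vector of predicted noise, same length as `x_t`.
#' @export
predict_noise <- function(model, x_t, sigma_t, x_cond) UseMethod("predict_noise")

#' @export
predict_noise.kan_denoiser <- function(model, x_t, sigma_t, x_cond) {
  if (length(x_t) != length(x_cond))
    stop("shape error: x_t and x_cond lengths differ", call. = FALSE)
  out <- denoiser_forward(model, matrix(x_t, ncol = 1L), sigma_t,
                          matrix(x_cond, ncol = 1L))
  drop(out$eps)
}

#' @export
predict_noise.function <- function(model, x_t, sigma_t, x_cond) {
  model(x_t, sigma_t, x_cond)
}

# Batched prediction used by the sampler (L x B matrices).
predict_noise_batch <- function(model, Xt, sigmas, Cond) {
  if (inherits(model, "kan_denoiser")) {
    denoiser_forward(model, Xt, sigmas, Cond)$eps
  } else {
    out <- vapply(seq_len(ncol(Xt)),
                  function(j) predict_noise(model, Xt[, j],
                                            if (length(sigmas) > 1) sigmas[j] else sigmas,
                                            Cond[, j]),
                  numeric(nrow(Xt)))
    matrix(out, nrow = nrow(Xt))
  }
}

#' Parameter counts by component
#'
#' Reports how many trainable parameters sit in each part of the network.
#' Switching `conditioning_kind` between `"linear"` and `"kan"` changes only
#' the `bridge_affine` row — the ablation-fairness contract.
#'
#' @param model A `"kan_denoiser"` object.
#' @return A data frame with columns `component` and `n_params`.
#' @export
count_params <- function(model) {
  stopifnot(inherits(model, "kan_denoiser"))
  nleaf <- function(x) sum(vapply(x, length, integer(1)))
  p <- model$params
  affine_n <- sum(vapply(p$bridge, function(br) {
    a <- br$affine
    if (inherits(a, "linear_affine_params")) length(a$W) + length(a$b)
    else length(a$W_base) + length(a$W_spline) +
      if (a$standalone_scale_spline) length(a$spline_scale) else 0L
  }, numeric(1)))
  enc_n <- sum(unlist(lapply(p$enc, function(lv)
    lapply(lv, function(bk) lapply(bk, nleaf)))))
  dec_n <- sum(unlist(lapply(p$dec, function(bk) lapply(bk, nleaf))))
  proj_n <- sum(vapply(p$bridge, function(br) nleaf(br$proj), numeric(1)))
  data.frame(
    component = c("conv_in", "encoder", "decoder", "bridge_proj",
                  "bridge_affine", "conv_out"),
    n_params = c(nleaf(p$conv_in), enc_n, dec_n, proj_n, affine_n,
                 nleaf(p$conv_out))
  )
}

# Collect the spline-path weight matrices (W_spline + standalone scales) of
# every KAN bridge — the regularizer's target set.
spline_weight_set <- function(model) {
  if (model$config$conditioning_kind != "kan") return(list())
  out <- list()
  for (br in model$params$bridge) {
    a <- br$affine
    out <- c(out, list(a$W_spline))
    if (a$standalone_scale_spline) out <- c(out, list(a$spline_scale))
  }
  out
}
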