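## parameter-tree utilities ------------------------------------------------
## Gradient trees produced by denoiser_backward mirror the trainable subset
## of the parameter tree (conv W/b, bridge proj, affine leaves); the walkers
## below traverse the GRAD structure so non-trainable fields (grid, scalars)
## are never touched.

flatten_tree <- function(x) {
  if (is.numeric(x)) return(list(x))
  do.call(c, lapply(x, flatten_tree))
}

# write flat leaves (same order as flatten_tree of `grads`) back into params
assign_flat <- function(params, grads, flat, counter = new.env()) {
  if (is.null(counter$i)) counter$i <- 0L
  rec <- function(p, g) {
    if (is.numeric(g)) {
      counter$i <- counter$i + 1L
      leaf <- flat[[counter$i]]
      dim(leaf) <- dim(p)
      return(leaf)
    }
    for (i in seq_along(g)) {
      nm <- names(g)[i]
      key <- if (!is.null(nm) && nzchar(nm)) nm else i
      p[[key]] <- rec(p[[key]], g[[i]])
    }
    p
  }
  rec(params, grads)
}

adam_init <- function(grads) {
  flat <- flatten_tree(grads)
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  g <- flatten_tree(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- vector("list", length(g))
  for (i in seq_along(g)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g[[i]]^2
    upd[[i]] <- lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  p_flat <- flatten_tree_matching(params, grads)
  new_flat <- mapply(function(p, u) p - u, p_flat, upd, SIMPLIFY = FALSE)
  list(params = assign_flat(params, grads, new_flat), state = state)
}

# flatten params in the order dictated by the grad structure
flatten_tree_matching <- function(params, grads) {
  out <- list()
  rec <- function(p, g) {
    if (is.numeric(g)) { out[[length(out) + 1L]] <<- p; return(invisible()) }
    for (i in seq_along(g)) {
      nm <- names(g)[i]
      key <- if (!is.null(nm) && nzchar(nm)) nm else i
      rec(p[[key]], g[[i]])
    }
  }
  rec(params, grads)
  out
}

# Full-model gradients of total_loss for one minibatch (used by the trainer
# and by the finite-difference gradient checks in the tests).
denoiser_loss_grads <- function(model, Xt, sigmas, Cond, Eps,
                                weights = loss_weights()) {
  fw <- denoiser_forward(model, Xt, sigmas, Cond, keep_cache = TRUE)
  r <- fw$eps - Eps
  main <- mean(abs(r))
  deps <- sign(r) / length(r)
  grads <- denoiser_backward(model, fw$cache, deps)
  reg <- 0
  if (model$config$conditioning_kind == "kan" && weights$lambda_kan > 0) {
    sw <- spline_weight_set(model)
    reg <- kan_reg_loss(sw, weights)
    rg <- kan_reg_grad(sw, weights)
    j <- 0L
    for (l in seq_along(model$params$bridge)) {
      a <- model$params$bridge[[l]]$affine
      j <- j + 1L
      grads$bridge[[l]]$affine$W_spline <-
        grads$bridge[[l]]$affine$W_spline + weights$lambda_kan * rg[[j]]
      if (a$standalone_scale_spline) {
        j <- j + 1L
        grads$bridge[[l]]$affine$spline_scale <-
          grads$bridge[[l]]$affine$spline_scale + weights$lambda_kan * rg[[j]]
      }
    }
  }
  list(grads = grads, main = main, reg = reg,
       total = total_loss(main, reg, weights))
}

#' Train a denoiser by DDPM noise prediction
#'
#' Minimises the mean-absolute noise-prediction error plus the KAN
#' regularizer with Adam.  Each optimizer step draws a minibatch of clean
#' segments, a uniform step index `t` per segment, diffuses them with
#' [forward_diffuse()], and regresses the injected noise.  Per-step RNG
#' seeds are derived from `(seed, step)`, so a run is bitwise reproducible
#' and training can be resumed deterministically by passing the returned
#' optimizer state and `step_offset`.
#'
#' @param model A [init_denoiser()] model.
#' @param dataset A [make_dataset()] result (or any list with `clean`,
#'   `noisy` matrices and a `meta$split` column).
#' @param schedule A [make_quadratic_schedule()].
#' @param steps Number of optimizer steps.
#' @param batch_size Minibatch size.
#' @param lr Initial learning rate (Adam).
#' @param lr_gamma,lr_step Step decay: the rate is multiplied by `lr_gamma`
#'   after every `lr_step` steps (`Inf` disables decay).
#' @param weights A [loss_weights()].
#' @param seed Master seed.
#' @param split Which split to train on (default `"train"`).
#' @param val_every Evaluate validation main loss every so many steps
#'   (0 disables); the parameters with the best validation loss are kept in
#'   `best_params`.
#' @param opt_state,step_offset Resume support: pass the `opt_state` and
#'   `steps_done` of a previous run.
#' @param verbose Print progress lines.
#' @return List with `model` (trained), `log` (per-step data frame),
#'   `opt_state`, `steps_done`, `best_params`, `best_val`.
#' @export
fit_denoiser <- function(model, dataset, schedule, steps = 300L,
                         batch_size = 32L, lr = 1e-3, lr_gamma = 0.1,
                         lr_step = Inf, weights = loss_weights(), seed = 1L,
                         split = "train", val_every = 0L, opt_state = NULL,
                         step_offset = 0L, verbose = FALSE) {
  idx_tr <- which(dataset$meta$split == split)
  if (length(idx_tr) == 0L) stop("no segments in split '", split, "'", call. = FALSE)
  X0 <- t(dataset$clean[idx_tr, , drop = FALSE])
  Cond <- t(dataset$noisy[idx_tr, , drop = FALSE])
  L <- nrow(X0); N <- ncol(X0)
  idx_val <- which(dataset$meta$split == "val")
  log <- vector("list", steps)
  best_val <- Inf; best_params <- NULL

  for (step in seq_len(steps)) {
    gstep <- step + step_offset
    set.seed((as.integer(seed) + 7919L * gstep) %% 2147483647L)
    bi <- sample.int(N, min(batch_size, N))
    B <- length(bi)
    tvec <- sample.int(schedule$T, B, replace = TRUE)
    Eps <- matrix(stats::rnorm(L * B), L, B)
    ab <- schedule$alpha_bar[tvec]
    Xt <- X0[, bi, drop = FALSE] * rep(sqrt(ab), each = L) +
      Eps * rep(sqrt(1 - ab), each = L)
    sigmas <- sigma_for_step(schedule, tvec, model$config$sigma_map)

    lg <- denoiser_loss_grads(model, Xt, sigmas, Cond[, bi, drop = FALSE],
                              Eps, weights)
    if (is.null(opt_state)) opt_state <- adam_init(lg$grads)
    lr_t <- lr * lr_gamma^(if (is.finite(lr_step)) floor((gstep - 1) / lr_step) else 0)
    st <- adam_step(model$params, lg$grads, opt_state, lr_t)
    model$params <- st$params
    opt_state <- st$state

    val <- NA_real_
    if (val_every > 0 && length(idx_val) > 0 && gstep %% val_every == 0) {
      val <- validation_loss(model, dataset, schedule, idx_val,
                             seed = as.integer(seed) + 31L)
      if (val < best_val) { best_val <- val; best_params <- model$params }
    }
    log[[step]] <- data.frame(step = gstep, main = lg$main, reg = lg$reg,
                              total = lg$total, lr = lr_t, val = val)
    if (verbose && (step %% 25L == 0L || step == 1L))
      message(sprintf("step %d  main %.4f  reg %.4f  total %.4f",
                      gstep, lg$main, lg$reg, lg$total))
  }
  list(model = model, log = do.call(rbind, log), opt_state = opt_state,
       steps_done = steps + step_offset,
       best_params = best_params, best_val = best_val)
}

# Mean |eps_hat - eps| on a fixed diffused version of the given segments.
validation_loss <- function(model, dataset, schedule, idx, seed = 1L) {
  set.seed(as.integer(seed))
  X0 <- t(dataset$clean[idx, , drop = FALSE])
  Cond <- t(dataset$noisy[idx, , drop = FALSE])
  L <- nrow(X0); B <- ncol(X0)
  tvec <- sample.int(schedule$T, B, replace = TRUE)
  Eps <- matrix(stats::rnorm(L * B), L, B)
  ab <- schedule$alpha_bar[tvec]
  Xt <- X0 * rep(sqrt(ab), each = L) + Eps * rep(sqrt(1 - ab), each = L)
  eh <- denoiser_forward(model, Xt, sigma_for_step(schedule, tvec, model$config$sigma_map),
                         Cond)$eps
  mean(abs(eh - Eps))
}

## checkpoints --------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS archive holding a JSON-serializable `header`
#' (the full [denoiser_config()] as a plain list plus format version), the
#' parameter tree, and optionally the optimizer state and training log.
#'
#' @param model A `"kan_denoiser"`.
#' @param path Destination file.
#' @param opt_state,log Optional training state to embed.
#' @return `save_checkpoint` invisibly returns `path`; `load_checkpoint`
#'   returns a list with `model`, `opt_state`, `log`, `header`.
#' @export
save_checkpoint <- function(model, path, opt_state = NULL, log = NULL) {
  stopifnot(inherits(model, "kan_denoiser"))
  header <- c(unclass(model$config), list(format = "kandiff-checkpoint-1"))
  # header must round-trip through JSON (the documented contract)
  jsonlite::fromJSON(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  saveRDS(list(header = header, params = model$params,
               opt_state = opt_state, log = log), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$header$format) || ck$header$format != "kandiff-checkpoint-1")
    stop("incompatible checkpoint header", call. = FALSE)
  hdr <- ck$header; hdr$format <- NULL
  config <- do.call(denoiser_config, hdr)
  grid <- build_grid(config$grid_size, config$spline_order,
                     config$grid_range[1], config$grid_range[2])
  model <- structure(list(config = config, params = ck$params, grid = grid),
                     class = "kan_denoiser")
  list(model = model, opt_state = ck$opt_state, log = ck$log, header = ck$header)
}
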