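#' Quadratic beta noise schedule
#'
#' Builds the DDPM noise schedule used throughout: `beta_t` interpolates
#' linearly in `sqrt(beta)` between `sqrt(beta_start)` and `sqrt(beta_end)`
#' and is then squared (the common "quadratic" schedule), so both endpoints
#' are hit exactly.  Derived vectors `alpha = 1 - beta`, the running product
#' `alpha_bar`, and the per-step sampling variance are precomputed.
#'
#' @param n_steps Number of diffusion steps `T` (default 50).
#' @param beta_start,beta_end Endpoint variances, `0 < beta_start < beta_end
#'   < 1` (defaults 1e-4 and 0.5).
#' @param variance Reverse-process variance rule: `"beta"` (default,
#'   `sigma_t^2 = beta_t`) or `"posterior"` (the tilde-posterior variance
#'   `beta_t (1 - alpha_bar_{t-1}) / (1 - alpha_bar_t)`, zero at `t = 1`).
#' @return Object of class `"noise_schedule"` with fields `T`, `beta`,
#'   `alpha`, `alpha_bar`, `posterior_var`, `variance`.
#' @export
make_quadratic_schedule <- function(n_steps = 50L, beta_start = 1e-4,
                                    beta_end = 0.5,
                                    variance = c("beta", "posterior")) {
  variance <- match.arg(variance)
  if (!(beta_start > 0 && beta_start < beta_end && beta_end < 1))
    stop("schedule error: need 0 < beta_start < beta_end < 1", call. = FALSE)
  if (n_steps < 1) stop("schedule error: n_steps must be >= 1", call. = FALSE)
  n_steps <- as.integer(n_steps)
  beta <- if (n_steps == 1L) beta_end else {
    s <- sqrt(beta_start) +
      (seq_len(n_steps) - 1) / (n_steps - 1) * (sqrt(beta_end) - sqrt(beta_start))
    s^2
  }
  # pin endpoints exactly against rounding in the interpolation
  beta[1L] <- if (n_steps == 1L) beta_end else beta_start
  beta[n_steps] <- beta_end
  alpha <- 1 - beta
  alpha_bar <- cumprod(alpha)
  pv <- switch(variance,
               beta = beta,
               posterior = beta * (1 - c(1, alpha_bar[-n_steps])) / (1 - alpha_bar))
  structure(list(T = n_steps, beta = beta, alpha = alpha,
                 alpha_bar = alpha_bar, posterior_var = pv,
                 variance = variance),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("noise_schedule: T = %d, beta in [%g, %g], variance rule '%s'\n",
              x$T, x$beta[1], x$beta[x$T], x$variance))
  invisible(x)
}

check_step <- function(schedule, t) {
  if (length(t) != 1L || t < 1 || t > schedule$T || t != round(t))
    stop("index error: t must be an integer in 1..T", call. = FALSE)
  as.integer(t)
}

# Noise scale fed to the positional encoder for step t.
sigma_for_step <- function(schedule, t, kind = "sqrt_beta") {
  switch(kind,
         sqrt_beta = sqrt(schedule$beta[t]),
         step_frac = t / schedule$T,
         stop("unknown sigma_map: ", kind, call. = FALSE))
}

#' Closed-form forward diffusion
#'
#' Jumps straight to step `t` of the forward chain:
#' `x_t = sqrt(alpha_bar_t) * x0 + sqrt(1 - alpha_bar_t) * eps`.
#'
#' @param x0 Clean segment.
#' @param t Step index in `1..T`.
#' @param eps Standard normal draw, same length as `x0`.
#' @param schedule A [make_quadratic_schedule()] object.
#' @return The diffused segment `x_t`.
#' @export
forward_diffuse <- function(x0, t, eps, schedule) {
  t <- check_step(schedule, t)
  stopifnot(length(eps) == length(x0))
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' One reverse diffusion step
#'
#' Computes `x_{t-1} = mu_theta + sigma_t * xi` with
#' `mu_theta = (x_t - beta_t / sqrt(1 - alpha_bar_t) * eps_hat) / sqrt(alpha_t)`
#' and `eps_hat = predict_noise(model, x_t, sigma_scale(t), x_cond)`.
#' The final step (`t = 1`) is deterministic (`xi = 0`).
#'
#' @param x_t Current state.
#' @param t Step index.
#' @param x_cond Noisy observation used as conditional guide.
#' @param model Noise predictor (network or stub function).
#' @param schedule Noise schedule.
#' @param noise Optional explicit `xi` draw (for oracles/tests); default
#'   `rnorm` from the current RNG state.
#' @param sigma_map Step-to-noise-scale rule (see [denoiser_config()]).
#' @return The segment `x_{t-1}`.
#' @export
reverse_step <- function(x_t, t, x_cond, model, schedule, noise = NULL,
                         sigma_map = "sqrt_beta") {
  t <- check_step(schedule, t)
  eps_hat <- predict_noise(model, x_t, sigma_for_step(schedule, t, sigma_map), x_cond)
  mu <- (x_t - schedule$beta[t] / sqrt(1 - schedule$alpha_bar[t]) * eps_hat) /
    sqrt(schedule$alpha[t])
  if (t == 1L) return(mu)
  if (is.null(noise)) noise <- stats::rnorm(length(x_t))
  mu + sqrt(schedule$posterior_var[t]) * noise
}

#' Conditional reverse-diffusion sampling
#'
#' Draws `x_T` from a standard normal and applies [reverse_step()] for
#' `t = T, ..., 1`, guided by the noisy observation.  Fully reproducible from
#' `seed`.
#'
#' @param x_cond Noisy segment used as the conditional guide.
#' @param model Noise predictor.
#' @param schedule Noise schedule.
#' @param seed Optional integer seed.
#' @param sigma_map Step-to-noise-scale rule.
#' @return The denoised estimate `x0_hat`, same length as `x_cond`.
#' @export
ddpm_sample <- function(x_cond, model, schedule, seed = NULL,
                        sigma_map = "sqrt_beta") {
  drop(ddpm_sample_batch(matrix(x_cond, ncol = 1L), model, schedule,
                         seed = seed, sigma_map = sigma_map))
}

# Batched sampler: each column of Cond is an independent chain.
ddpm_sample_batch <- function(Cond, model, schedule, seed = NULL,
                              sigma_map = "sqrt_beta") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  L <- nrow(Cond); B <- ncol(Cond)
  x <- matrix(stats::rnorm(L * B), L, B)
  for (t in seq(schedule$T, 1L)) {
    eps_hat <- predict_noise_batch(model, x, sigma_for_step(schedule, t, sigma_map), Cond)
    mu <- (x - schedule$beta[t] / sqrt(1 - schedule$alpha_bar[t]) * eps_hat) /
      sqrt(schedule$alpha[t])
    x <- if (t == 1L) mu else
      mu + sqrt(schedule$posterior_var[t]) * matrix(stats::rnorm(L * B), L, B)
  }
  x
}

#' Multi-shot averaging inference
#'
#' Runs `shots` independent reverse-diffusion chains for the same noisy
#' segment and returns their arithmetic mean.  Shot `s` uses the derived seed
#' `seed + s - 1`, so `shots = 1` reproduces a single [ddpm_sample()] with the
#' master seed.
#'
#' @inheritParams ddpm_sample
#' @param shots Number of independent chains to average (>= 1).
#' @return The averaged denoised segment.
#' @export
multi_shot_denoise <- function(x_cond, model, schedule, shots = 1L,
                               seed = NULL, sigma_map = "sqrt_beta") {
  if (length(shots) != 1L || shots < 1 || shots != round(shots))
    stop("invalid argument: shots must be a positive integer", call. = FALSE)
  drop(multi_shot_denoise_batch(matrix(x_cond, ncol = 1L), model, schedule,
                                shots = shots, seed = seed,
                                sigma_map = sigma_map))
}

multi_shot_denoise_batch <- function(Cond, model, schedule, shots = 1L,
                                     seed = NULL, sigma_map = "sqrt_beta") {
  acc <- matrix(0, nrow(Cond), ncol(Cond))
  for (s in seq_len(shots)) {
    sub <- if (is.null(seed)) NULL else as.integer(seed) + s - 1L
    acc <- acc + ddpm_sample_batch(Cond, model, schedule, seed = sub,
                                   sigma_map = sigma_map)
  }
  acc / shots
}
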