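test_that("fresh model predicts zero and honours the shape contract", {
  for (L in c(64L, 512L)) {
    cfg <- denoiser_config(segment_length = L, hidden_features = 4L,
                           n_levels = 2L, blocks_per_level = 1L,
                           embedding_dim = 6L)
    m <- init_denoiser(cfg, seed = 1)
    x <- rnorm(L)
    out <- predict_noise(m, x, 0.3, rnorm(L))
    expect_length(out, L)
    expect_equal(out, numeric(L))    # zero-initialised output projection
  }
  expect_error(denoiser_config(segment_length = 10L, n_levels = 3L),
               "divisible")
})

test_that("input validation catches shape and finiteness problems", {
  m <- init_denoiser(tiny_config(), seed = 1)
  expect_error(predict_noise(m, rnorm(32), 0.1, rnorm(16)), "shape error")
  expect_error(predict_noise(m, rnorm(16), 0.1, rnorm(16)), "shape error")
  x <- rnorm(32); x[3] <- NA
  expect_error(predict_noise(m, x, 0.1, rnorm(32)), "invalid input")
})

# nudge the zero-initialised output projection so signal reaches the output
activate <- function(m, seed = 11) {
  set.seed(seed)
  m$params$conv_out$W <- matrix(rnorm(length(m$params$conv_out$W), sd = 0.3),
                                nrow = 1)
  m
}

test_that("conditioning wiring is alive: sigma changes the output", {
  m <- activate(init_denoiser(tiny_config(), seed = 2))
  x <- rnorm(32); cond <- rnorm(32)
  o1 <- predict_noise(m, x, 0.05, cond)
  o2 <- predict_noise(m, x, 0.6, cond)
  expect_gt(max(abs(o1 - o2)), 1e-8)
  # and the conditional input matters too (signal-based conditioning)
  o3 <- predict_noise(m, x, 0.05, cond + 1)
  expect_gt(max(abs(o1 - o3)), 1e-8)
})

test_that("linear->kan switch changes only the bridge affine parameter count", {
  mk <- count_params(init_denoiser(tiny_config("kan"), seed = 1))
  ml <- count_params(init_denoiser(tiny_config("linear"), seed = 1))
  other <- mk$component != "bridge_affine"
  expect_identical(mk$n_params[other], ml$n_params[other])
  expect_false(mk$n_params[!other] == ml$n_params[!other])
})

test_that("zero-spline KAN network equals the matched linear network", {
  cfgk <- tiny_config("kan", act = "identity")
  mk <- activate(init_denoiser(cfgk, seed = 3))
  for (l in seq_along(mk$params$bridge)) {
    mk$params$bridge[[l]]$affine$W_spline[] <- 0
  }
  ml <- mk
  ml$config <- tiny_config("linear")
  for (l in seq_along(ml$params$bridge)) {
    a <- mk$params$bridge[[l]]$affine
    ml$params$bridge[[l]]$affine <-
      linear_affine_params(a$C, a$d, W = a$W_base, b = numeric(2 * a$C))
  }
  set.seed(4)
  x <- rnorm(32); cond <- rnorm(32)
  ok <- predict_noise(mk, x, 0.3, cond)
  ol <- predict_noise(ml, x, 0.3, cond)
  expect_lt(max(abs(ok - ol)), 1e-6)
})

test_that("analytic gradients match finite differences through the whole net", {
  set.seed(9)
  m <- activate(init_denoiser(tiny_config("kan"), seed = 2), seed = 12)
  B <- 2L; L <- 32L
  Xt <- matrix(rnorm(L * B), L, B); Cond <- matrix(rnorm(L * B), L, B)
  Eps <- matrix(rnorm(L * B), L, B); sig <- c(0.1, 0.5)
  w <- loss_weights(lambda_kan = 0.01)
  lg <- kandiff:::denoiser_loss_grads(m, Xt, sig, Cond, Eps, w)
  probes <- list(
    c("conv_in", "W"), c("conv_out", "W"),
    list("enc", 1L, 1L, "conv1", "W"), list("enc", 2L, 1L, "conv2", "b"),
    list("dec", 1L, "conv1", "W"),
    list("bridge", 1L, "proj", "W"), list("bridge", 2L, "affine", "W_base"),
    list("bridge", 1L, "affine", "W_spline"),
    list("bridge", 2L, "affine", "spline_scale")
  )
  h <- 1e-6
  for (pr in probes) {
    pr <- as.list(pr)
    leaf <- m$params[[pr[[1]]]]
    for (k in pr[-1]) leaf <- leaf[[k]]
    idx <- which.max(abs(leaf))        # probe the largest-magnitude entry
    poke <- function(mod, delta) {
      path <- pr
      ref <- mod$params
      # descend and rebuild
      setv <- function(x, depth) {
        if (depth > length(path)) { x[idx] <- x[idx] + delta; return(x) }
        x[[path[[depth]]]] <- setv(x[[path[[depth]]]], depth + 1)
        x
      }
      mod$params <- setv(ref, 1)
      mod
    }
    lp <- kandiff:::denoiser_loss_grads(poke(m, h), Xt, sig, Cond, Eps, w)$total
    lm <- kandiff:::denoiser_loss_grads(poke(m, -h), Xt, sig, Cond, Eps, w)$total
    num <- (lp - lm) / (2 * h)
    ana <- lg$grads
    for (k in pr) ana <- ana[[k]]
    ana <- ana[idx]
    expect_lt(abs(ana - num) / max(abs(num), 1e-6), 1e-4)
  }
})

test_that("initialisation is reproducible from its seed", {
  m1 <- init_denoiser(tiny_config(), seed = 7)
  m2 <- init_denoiser(tiny_config(), seed = 7)
  expect_identical(m1$params, m2$params)
})
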