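# Independent literal-transcription oracles.  These share no code with the
# package internals: scalar recursion, explicit loops, no vectorisation.

# Cox-de Boor recursion, one basis function at a time.
oracle_cdb <- function(knots, i, k, z) {
  if (k == 0) return(as.numeric(knots[i] <= z && z < knots[i + 1]))
  d1 <- knots[i + k] - knots[i]
  d2 <- knots[i + k + 1] - knots[i + 1]
  t1 <- if (d1 == 0) 0 else (z - knots[i]) / d1 * oracle_cdb(knots, i, k - 1, z)
  t2 <- if (d2 == 0) 0 else (knots[i + k + 1] - z) / d2 * oracle_cdb(knots, i + 1, k - 1, z)
  t1 + t2
}

oracle_basis <- function(grid, z) {
  vapply(seq_len(grid$n_basis),
         function(i) oracle_cdb(grid$extended_knots, i, grid$k, z),
         numeric(1))
}

# Interleaved sin/cos positional encoding, term by term.
oracle_pe <- function(sigma, d) {
  lam <- log(10000) / (d / 2)
  z <- numeric(d)
  for (i in 0:(d / 2 - 1)) {
    z[2 * i + 1] <- sin(sigma * exp(-i * lam))
    z[2 * i + 2] <- cos(sigma * exp(-i * lam))
  }
  z
}

# Explicit double-sum KAN layer output.
oracle_kan <- function(params, z) {
  act <- if (params$base_activation == "identity") function(x) x
         else function(x) x / (1 + exp(-x))
  nb <- params$grid$n_basis
  n_out <- nrow(params$W_base)
  out <- numeric(n_out)
  for (o in seq_len(n_out)) {
    acc <- 0
    for (i in seq_len(params$d)) {
      acc <- acc + params$scale_base * params$W_base[o, i] * act(z[i])
      bi <- oracle_basis(params$grid, z[i])
      for (j in seq_len(nb)) {
        s <- if (params$standalone_scale_spline) params$spline_scale[o, i] else 1
        acc <- acc + params$scale_spline * s *
          params$W_spline[o, (i - 1) * nb + j] * bi[j]
      }
    }
    out[o] <- acc
  }
  out
}

# Naive elementwise metric loops.
oracle_ssd <- function(x, y) { s <- 0; for (i in seq_along(x)) s <- s + (x[i] - y[i])^2; s }
oracle_mad <- function(x, y) { m <- 0; for (i in seq_along(x)) m <- max(m, abs(x[i] - y[i])); m }
oracle_prd <- function(x, y) {
  mu <- sum(x) / length(x)
  num <- 0; den <- 0
  for (i in seq_along(x)) { num <- num + (x[i] - y[i])^2; den <- den + (x[i] - mu)^2 }
  100 * sqrt(num / den)
}
oracle_cossim <- function(x, y) {
  a <- 0; b <- 0; d <- 0
  for (i in seq_along(x)) { a <- a + x[i] * y[i]; b <- b + x[i]^2; d <- d + y[i]^2 }
  a / (sqrt(b) * sqrt(d))
}
oracle_entropy <- function(p) { h <- 0; for (q in p) if (q > 0) h <- h - q * log(q); h }

# Tiny denoiser configs used across test files.
tiny_config <- function(kind = "kan", L = 32L, act = "silu") {
  denoiser_config(segment_length = L, hidden_features = 4L, n_levels = 2L,
                  blocks_per_level = 1L, conditioning_kind = kind,
                  embedding_dim = 6L, base_activation = act)
}
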