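#' Build a fixed uniform B-spline grid
#'
#' Constructs the knot layout used by every KAN conditioning layer: `G`
#' uniformly spaced interior grid points on `[range_lo, range_hi]`, extended
#' by `k` equally spaced knots beyond each boundary so that order-`k` basis
#' functions are well defined up to the edges of the domain.
#'
#' With `G` interior points and order `k` the layout yields
#' `n_basis = G + k - 1` basis functions.  Interior point `i` (1-based) sits at
#' `range_lo + (range_hi - range_lo) * (i - 1) / (G - 1)`.
#'
#' @param G Number of interior grid points (integer, >= 2).
#' @param k Spline order (integer, >= 0); `k = 3` gives cubic splines.
#' @param range_lo,range_hi Domain bounds, `range_lo < range_hi`.  The default
#'   `[-1, 1]` matches the bounded sin/cos noise embedding fed to KAN layers.
#' @return An object of class `"spline_grid"`: a list with fields `G`, `k`,
#'   `range_lo`, `range_hi`, `interior_knots` (length `G`), `extended_knots`
#'   (length `G + 2k`) and `n_basis`.
#' @examples
#' g <- build_grid(5, 3, -1, 1)
#' g$interior_knots   # -1 -0.5 0 0.5 1
#' g$n_basis          # 7
#' @export
build_grid <- function(G, k, range_lo = -1, range_hi = 1) {
  if (!is.numeric(G) || length(G) != 1L || G != round(G) || G < 2)
    stop("invalid grid: G must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 0)
    stop("invalid grid: k must be a single integer >= 0", call. = FALSE)
  if (!is.finite(range_lo) || !is.finite(range_hi) || range_lo >= range_hi)
    stop("invalid grid: need finite range_lo < range_hi", call. = FALSE)
  G <- as.integer(G); k <- as.integer(k)
  h <- (range_hi - range_lo) / (G - 1)
  interior <- range_lo + h * (seq_len(G) - 1)
  extended <- range_lo + h * ((1 - k):(G + k) - 1)
  structure(
    list(G = G, k = k, range_lo = range_lo, range_hi = range_hi,
         interior_knots = interior, extended_knots = extended,
         n_basis = G + k - 1L),
    class = "spline_grid"
  )
}

#' @export
print.spline_grid <- function(x, ...) {
  cat(sprintf("spline_grid: G = %d points on [%g, %g], order k = %d, %d basis functions\n",
              x$G, x$range_lo, x$range_hi, x$k, x$n_basis))
  invisible(x)
}

# Clamp evaluation points into [lo, hi) so the half-open order-0 indicators
# partition the domain and the right endpoint belongs to the last interval.
clamp_to_grid <- function(grid, z) {
  if (any(!is.finite(z)))
    stop("invalid input: spline evaluation points must be finite", call. = FALSE)
  span <- grid$range_hi - grid$range_lo
  hi_open <- grid$range_hi - span * .Machine$double.eps
  pmin(pmax(z, grid$range_lo), hi_open)
}

#' Order-0 B-spline indicator functions
#'
#' Evaluates the order-0 basis at a single point: component `i` is 1 iff
#' `extended_knots[i] <= z < extended_knots[i + 1]` (left-closed, right-open;
#' the right domain endpoint is folded into the last interior interval).
#'
#' @param grid A [build_grid()] object.
#' @param z A single finite numeric value (clamped into the grid range).
#' @return Numeric 0/1 vector of length `G + 2k - 1`, summing to 1.
#' @export
basis_order0 <- function(grid, z) {
  stopifnot(inherits(grid, "spline_grid"), length(z) == 1L)
  z <- clamp_to_grid(grid, z)
  s <- grid$extended_knots
  as.numeric(s[-length(s)] <= z & z < s[-1L])
}

#' Evaluate the order-k B-spline basis at one point
#'
#' Runs the Cox-de Boor recursion up from the order-0 indicators, with the
#' standard `0/0 := 0` convention.  The returned values are non-negative, at
#' most `k + 1` of them are nonzero, and they sum to one everywhere on the
#' grid range (partition of unity).
#'
#' @inheritParams basis_order0
#' @return Numeric vector of length `grid$n_basis`.
#' @seealso [basis_matrix()] for many points at once.
#' @export
spline_basis <- function(grid, z) {
  stopifnot(length(z) == 1L)
  drop(basis_matrix(grid, z))
}

#' Evaluate the B-spline basis matrix
#'
#' Vectorised Cox-de Boor recursion: row `j` holds the `n_basis` order-`k`
#' basis values at `Z[j]`.  This is the feature expansion `B(z)` used on the
#' spline path of a KAN layer.
#'
#' @param grid A [build_grid()] object.
#' @param Z Numeric vector of finite evaluation points.
#' @return Matrix of shape `length(Z) x grid$n_basis`.
#' @export
basis_matrix <- function(grid, Z) {
  stopifnot(inherits(grid, "spline_grid"))
  Z <- clamp_to_grid(grid, as.numeric(Z))
  s <- grid$extended_knots
  m <- length(Z)
  # order 0: indicator of the knot interval containing each point
  B <- outer(Z, s[-length(s)], `>=`) & outer(Z, s[-1L], `<`)
  B <- matrix(as.numeric(B), nrow = m)
  if (grid$k > 0) {
    for (ord in seq_len(grid$k)) {
      ncur <- ncol(B) - 1L
      Bnew <- matrix(0, nrow = m, ncol = ncur)
      for (i in seq_len(ncur)) {
        d1 <- s[i + ord] - s[i]
        d2 <- s[i + ord + 1L] - s[i + 1L]
        t1 <- if (d1 > 0) (Z - s[i]) / d1 * B[, i] else 0        # 0/0 := 0
        t2 <- if (d2 > 0) (s[i + ord + 1L] - Z) / d2 * B[, i + 1L] else 0
        Bnew[, i] <- t1 + t2
      }
      B <- Bnew
    }
  }
  stopifnot(ncol(B) == grid$n_basis)
  B
}
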