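#' @importFrom Matrix sparseMatrix
NULL

# Conservative linear-deposition (scatter) operator for u(x) -> (1/a) u(x/a).
# Column j carries the mass dx*u_j of source node j to position a*x_j,
# split linearly between the two bracketing nodes. Mass is conserved to
# machine precision and the first moment is scaled by exactly `a`; since
# a <= 1 no mass can leave [0, A]. Entries are independent of dx.
remap_operator <- function(a, grid, method = c("scatter", "gather")) {
  method <- match.arg(method)
  n <- grid$N + 1L
  j <- 0:grid$N
  if (method == "scatter") {
    pos <- a * j                      # target position in units of dx
    q <- floor(pos + 1e-12)
    q <- pmin(q, grid$N)              # a = 1, j = N lands exactly on x_N
    w <- pos - q
    w[abs(w) < 1e-12] <- 0
    ii <- c(q + 1L, q + 2L)
    jj <- c(j + 1L, j + 1L)
    xx <- c(1 - w, w)
    keep <- xx > 0 & ii <= n
    Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                         dims = c(n, n))
  } else {
    # Gather form: row i reads (1/a) * interp(u, x_i / a), zero beyond A.
    pos <- j / a
    keep_i <- which(pos <= grid$N + 1e-12)
    q <- floor(pos[keep_i] + 1e-12)
    q <- pmin(q, grid$N)
    w <- pos[keep_i] - q
    w[abs(w) < 1e-12] <- 0
    ii <- c(keep_i, keep_i)           # already 1-based row indices
    jj <- c(q + 1L, q + 2L)
    xx <- c((1 - w) / a, w / a)
    keep <- xx > 0 & jj <= n
    Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                         dims = c(n, n))
  }
}

# Deposit point masses `mass` at arbitrary positions `pos` (damage units),
# linearly split between bracketing nodes; returns a density vector.
# Used by the state-dependent repair kernel, whose targets rho(x_j) x_j
# need not be a uniform rescaling.
deposit_mass <- function(mass, pos, grid) {
  if (any(pos < -1e-12) || any(pos > grid$A + 1e-12))
    stop("deposit positions must lie in [0, A]", call. = FALSE)
  n <- grid$N + 1L
  s <- pmin(pmax(pos / grid$dx, 0), grid$N)
  q <- pmin(floor(s + 1e-12), grid$N)
  w <- s - q
  w[abs(w) < 1e-12] <- 0
  idx <- c(q + 1L, pmin(q + 2L, n))
  val <- c((1 - w) * mass, w * mass)
  out <- numeric(n)
  acc <- rowsum(val, idx)
  out[as.integer(rownames(acc))] <- acc[, 1L]
  out / grid$dx
}

#' Conservative remap of a density under damage rescaling
#'
#' Discrete realization of the delta-kernel rescaling
#' \eqn{u(x) \mapsto (1/a)\,u(x/a)}: every node's mass
#' \eqn{m_j = u_j \Delta x} is deposited at the contracted position
#' \eqn{a x_j} and split linearly between the two bracketing nodes
#' (the scatter, or deposition, form). Total mass is preserved to
#' machine precision and the total first moment is scaled by exactly
#' `a`. The `gather` variant interpolates the source density at
#' \eqn{x_i/a} with prefactor \eqn{1/a}; it is consistent with the same
#' continuum operator but is not exactly conservative, and is retained
#' for comparison only.
#'
#' @param u Nonnegative density vector (length `N + 1`).
#' @param a Rescaling fraction in (0, 1\]. Partition and retention
#'   fractions are always <= 1, so `a > 1` is rejected.
#' @param grid A [make_grid()] grid.
#' @param method `"scatter"` (default, conservative) or `"gather"`.
#' @return The remapped density vector.
#' @examples
#' g <- make_grid(2, 400)
#' u <- gaussian_ic(g, 1, 0.8, 0.1)
#' v <- remap_density(u, 0.5, g)
#' all.equal(density_mass(v, g), density_mass(u, g))
#' all.equal(density_moment(v, g), 0.5 * density_moment(u, g))
#' @export
remap_density <- function(u, a, grid, method = c("scatter", "gather")) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "damage_grid"))
  check_density(u, grid)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0 || a > 1)
    stop("rescaling fraction 'a' must lie in (0, 1]", call. = FALSE)
  if (a == 1 && method == "scatter") return(u)
  as.numeric(remap_operator(a, grid, method) %*% u)
}

source_pair <- function(source_P, source_W, grid) {
  structure(
    list(source_P = source_P, source_W = source_W,
         net_cells_P = grid$dx * sum(source_P),
         net_cells_W = grid$dx * sum(source_W),
         net_damage_P = grid$dx * sum(grid$x * source_P),
         net_damage_W = grid$dx * sum(grid$x * source_W)),
    class = "source_pair"
  )
}

#' Division source terms from the partition kernels
#'
#' Assembles the reaction terms of the stem and TD equations that arise
#' from the three division modes with delta-function partition kernels:
#' \deqn{S_P = \lambda_P [p_1(R_{\alpha_1} + R_{\alpha_2}) +
#'   p_3 R_{\gamma_1}] P - \lambda_P P,\quad
#'   S_W = \lambda_P [p_2(R_{\beta_1} + R_{\beta_2}) + p_3 R_{\gamma_2}] P,}
#' where \eqn{R_a} is the conservative remap by fraction `a`. Cell-number
#' bookkeeping gives \eqn{\int S_P = (2p_1 + p_3 - 1)\lambda_P \bar P}
#' and \eqn{\int S_W = (2p_2 + p_3)\lambda_P \bar P}; because each
#' fraction pair sums to one, division conserves the total damage first
#' moment exactly: \eqn{\int x (S_P + S_W)\,dx = 0}.
#'
#' @param P Stem density vector.
#' @param rates A list with `p1`, `p2`, `p3`, `lambdaP` (as returned by
#'   [effective_rates()]).
#' @param fractions A [partition_fractions()] object.
#' @param grid A [make_grid()] grid.
#' @param method Remap variant, see [remap_density()].
#' @return A `source_pair`: `source_P`, `source_W` plus net cell-number
#'   and damage diagnostics (mass-weighted sums of the vectors).
#' @export
division_sources <- function(P, rates, fractions, grid,
                             method = c("scatter", "gather")) {
  method <- match.arg(method)
  stopifnot(inherits(fractions, "partition_fractions"))
  check_density(P, grid, "P")
  lamP <- rates$lambdaP
  rm <- function(a) remap_density(P, a, grid, method)
  sP <- lamP * (rates$p1 * (rm(fractions$alpha1) + rm(fractions$alpha2)) +
                rates$p3 * rm(fractions$gamma1)) - lamP * P
  sW <- lamP * (rates$p2 * (rm(fractions$beta1) + rm(fractions$beta2)) +
                rates$p3 * rm(fractions$gamma2))
  source_pair(sP, sW, grid)
}

# Evaluate the retention function on the grid and validate its range.
dediff_rho_values <- function(rule, grid) {
  r <- vapply(grid$x, rule$rho_fun, numeric(1))
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1))
    stop("state-dependent retention rho(x') must lie in [0, 1]",
         call. = FALSE)
  r
}

#' Dedifferentiation source terms
#'
#' TD cells revert to the stem compartment at rate `lambdaR` according
#' to a [dediff_rule()]. The TD loss is
#' \eqn{L(x) = \lambda_R \chi(x) W(x)} with \eqn{\chi \equiv 1} for the
#' constant and repair variants and \eqn{\chi = 1[x \ge x_c]} for the
#' threshold variant. The stem gain equals the loss pointwise (constant,
#' threshold), its conservative remap by `rho` (partial repair), or a
#' per-node deposition of the lost mass at \eqn{\rho(x_j) x_j}
#' (state-dependent repair). Cell number is always conserved:
#' \eqn{\int \mathrm{gain} = \int L}.
#'
#' @param W TD density vector.
#' @param lambdaR Effective dedifferentiation rate (>= 0).
#' @param rule A [dediff_rule()].
#' @param grid A [make_grid()] grid.
#' @return A `source_pair` with `source_P` (the stem gain) and
#'   `source_W` (minus the TD loss).
#' @export
dedifferentiation_sources <- function(W, lambdaR, rule, grid) {
  stopifnot(inherits(rule, "dediff_rule"))
  check_density(W, grid, "W")
  if (lambdaR < 0) stop("'lambdaR' must be >= 0", call. = FALSE)
  chi <- if (rule$variant == "threshold")
    as.numeric(grid$x >= rule$xc - 1e-12) else 1
  loss <- lambdaR * chi * W
  gain <- switch(rule$variant,
    constant = ,
    threshold = loss,
    partial_repair = {
      if (rule$rho == 0) {
        out <- numeric(grid$N + 1L)
        out[1L] <- sum(loss)        # all returning mass at the x = 0 node
        out
      } else remap_density(loss, rule$rho, grid)
    },
    state_dependent = {
      r <- dediff_rho_values(rule, grid)
      deposit_mass(loss * grid$dx, r * grid$x, grid)
    }
  )
  source_pair(gain, -loss, grid)
}
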