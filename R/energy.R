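# Quadratic elastic energy density of a membrane region and its
# Euler-Lagrange system.
#
# A region is a stretch of membrane with fixed monolayer phase content:
# either a full bilayer (upper and lower monolayer, each Lo or Ld) or a
# peptide strip (upper monolayer replaced by a rigid adsorbed helix; only
# the lower monolayer and the mid-surface remain elastic).
#
# Fields (functions of x):
#   n_u, n_l : director x-projections of the upper/lower monolayer
#   H_u, H_l : z-coordinates of the monolayer neutral surfaces [nm]
#   M        : z-coordinate of the bilayer mid-surface [nm]
# The energy density is quadratic in the jet
#   u = (n_u, n_u', n_u'', n_l, n_l', n_l'', H_u, H_u', H_l, H_l', M, M')
# (7 slots for a strip, where the upper fields are absent).

.slots_full  <- c("n_u", "dn_u", "d2n_u", "n_l", "dn_l", "d2n_l",
                  "H_u", "dH_u", "H_l", "dH_l", "M", "dM")
.slots_strip <- c("n_l", "dn_l", "d2n_l", "H_l", "dH_l", "M", "dM")

# field -> jet-slot indices (by derivative order 0,1[,2])
.fields_full  <- list(n_u = c(1, 2, 3), n_l = c(4, 5, 6),
                      H_u = c(7, 8), H_l = c(9, 10), M = c(11, 12))
.fields_strip <- list(n_l = c(1, 2, 3), H_l = c(4, 5), M = c(6, 7))

# Elastic energy per unit area of one monolayer, as a function of its jet.
# side = "upper": tilt T = n - H', stretching alpha = -(h/2)n' - (H-M)/h + 1;
# side = "lower": tilt T = n + H', stretching alpha = -(h/2)n' + (H-M)/h + 1.
# These are the volumetric-incompressibility forms; the lower-monolayer
# relation mirrors the upper one.
.w_mono <- function(n, dn, d2n, H, dH, M, dM, p, sigma, side) {
  s <- if (side == "upper") -1 else 1
  tilt <- n + s * dH
  alpha <- -(p$h / 2) * dn + s * (H - M) / p$h + 1
  galpha <- -(p$h / 2) * d2n + s * (dH - dM) / p$h
  p$km / 2 * (dn + p$J0)^2 - p$km / 2 * p$J0^2 +
    p$kt / 2 * tilt^2 +
    p$kc * tilt * d2n +
    p$kgr / 2 * d2n^2 +
    p$kA / 2 * (alpha - p$alpha0)^2 - p$kA / 2 * p$alpha0^2 -
    p$kc * galpha^2 +
    p$B * tilt * galpha +
    p$C * galpha * d2n +
    sigma / 2 * dH^2
}

# Bilayer (or strip) energy density from a full jet vector.
# pu = NULL marks a peptide strip: upper-monolayer terms are not evaluated.
.w_region <- function(u, pu, pl, sigma) {
  if (is.null(pu)) {
    .w_mono(u[1], u[2], u[3], u[4], u[5], u[6], u[7], pl, sigma, "lower")
  } else {
    .w_mono(u[1], u[2], u[3], u[7], u[8], u[11], u[12], pu, sigma, "upper") +
      .w_mono(u[4], u[5], u[6], u[9], u[10], u[11], u[12], pl, sigma, "lower")
  }
}

# Exact polarization of the (quadratic) density into w = u'Qu/2 + b'u + c.
.polarize <- function(pu, pl, sigma) {
  d <- if (is.null(pu)) 7L else 12L
  w <- function(u) .w_region(u, pu, pl, sigma)
  c0 <- w(numeric(d))
  E <- diag(d)
  wp <- vapply(seq_len(d), function(i) w(E[, i]), 0)
  wm <- vapply(seq_len(d), function(i) w(-E[, i]), 0)
  b <- (wp - wm) / 2
  Q <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in i:d) {
    Q[i, j] <- Q[j, i] <- w(E[, i] + E[, j]) - wp[i] - wp[j] + c0
  }
  list(Q = Q, b = b, c = c0)
}

#' Elastic energy density of a membrane region
#'
#' Evaluates the quadratic tilt-splay energy density at a point, given the
#' local field values and derivatives, measured relative to the flat
#' (undeformed, uniformly stretched) state of the region, whose energy is
#' zero by construction.
#'
#' @param fields named numeric vector of field deviations from the flat
#'   state. Names for a full bilayer region: `n_u`, `dn_u`, `d2n_u`, `n_l`,
#'   `dn_l`, `d2n_l`, `H_u`, `dH_u`, `H_l`, `dH_l`, `M`, `dM` (missing
#'   entries default to 0). For a peptide strip (`upper = NULL`) only the
#'   lower-monolayer and mid-surface slots apply.
#' @param upper `phase_params` of the upper monolayer, or `NULL` for a
#'   peptide strip (upper-monolayer terms are then not evaluated).
#' @param lower `phase_params` of the lower monolayer.
#' @param sys `system_constants`.
#' @return energy per unit area, kB*T/nm^2.
#' @examples
#' p <- default_parameter_set()
#' energy_density(c(n_u = 0.1), upper = p$disordered, lower = p$disordered,
#'                sys = p$system)  # (kt/2) * 0.1^2
#' @export
energy_density <- function(fields, upper, lower, sys) {
  slots <- if (is.null(upper)) .slots_strip else .slots_full
  u <- stats::setNames(numeric(length(slots)), slots)
  if (length(fields)) {
    if (is.null(names(fields)) || !all(names(fields) %in% slots))
      stop("'fields' must be a named vector with names among: ",
           paste(slots, collapse = ", "), call. = FALSE)
    u[names(fields)] <- fields
  }
  rs <- .region_system(upper, lower, sys)
  du <- as.numeric(u)
  sum(rs$g * du) + 0.5 * sum(du * (rs$Q %*% du))
}

# Ground (flat) state of a region: constant fields minimizing the density,
# with the mid-surface gauge M = 0. Returns the full jet vector u_inf
# (derivative slots zero), the flat density w_flat, and the gradient
# g = Q u_inf + b used for the linear part of deviations.
.ground_state <- function(Q, b, c0, strip) {
  vslots <- if (strip) c(1L, 4L) else c(1L, 4L, 7L, 9L)  # n's and H's
  d <- nrow(Q)
  u <- numeric(d)
  K <- Q[vslots, vslots, drop = FALSE]
  u[vslots] <- solve(K, -b[vslots])
  g <- as.numeric(Q %*% u + b)
  # value slots of g vanish by construction; derivative slots may not (J0 != 0)
  list(u_inf = u, w_flat = 0.5 * sum(u * (Q %*% u)) + sum(b * u) + c0, g = g)
}

# Euler-Lagrange polynomial matrix A(lambda):
# A_ij(l) = sum_{p,q} (-1)^p l^(p+q) Q[(i,p),(j,q)].
.el_matrix_builder <- function(Q, fields) {
  nf <- length(fields)
  # blocks[[p+1]][[q+1]] is the nf x nf matrix of Q entries for deriv (p, q)
  maxp <- max(lengths(fields)) - 1L
  blocks <- vector("list", maxp + 1L)
  for (p in 0:maxp) {
    blocks[[p + 1L]] <- vector("list", maxp + 1L)
    for (q in 0:maxp) {
      Bpq <- matrix(0, nf, nf)
      for (i in seq_len(nf)) for (j in seq_len(nf)) {
        si <- fields[[i]]; sj <- fields[[j]]
        if (p < length(si) && q < length(sj))
          Bpq[i, j] <- Q[si[p + 1L], sj[q + 1L]]
      }
      blocks[[p + 1L]][[q + 1L]] <- Bpq
    }
  }
  function(lambda) {
    A <- matrix(0 + 0i, nf, nf)
    for (p in 0:maxp) for (q in 0:maxp) {
      A <- A + (-1)^p * lambda^(p + q) * blocks[[p + 1L]][[q + 1L]]
    }
    A
  }
}

# Coefficients of det A(lambda) by evaluation on a circle + inverse FFT.
.char_poly <- function(Afun, nf) {
  degmax <- 4L * nf                       # loose bound
  N <- 2L * degmax
  r <- 2.0
  zs <- r * exp(2i * pi * (0:(N - 1)) / N)
  cdet <- function(A) prod(eigen(A, only.values = TRUE)$values)
  vals <- vapply(zs, function(z) cdet(Afun(z)), 0 + 0i)
  ch <- stats::fft(vals) / N    # ch[k+1] ~ c_k r^k
  m <- Mod(ch[seq_len(degmax + 1L)])
  tol <- 1e-10 * max(m)
  keep <- which(m > tol)
  if (!length(keep)) stop("characteristic polynomial is numerically zero")
  deg <- max(keep) - 1L
  m0 <- min(keep) - 1L
  coefs <- Re(ch[seq_len(deg + 1L)]) / r^(0:deg)
  list(coefs = coefs, deg = deg, m0 = m0)
}

# All polynomial solutions of the homogeneous EL system (the lambda = 0
# block), found by a degree-capped ansatz. Returns a matrix basis: each
# column is a stacked field-coefficient vector, fields x degrees.
.polynomial_solutions <- function(Q, fields, expected, dmax = 5L) {
  nf <- length(fields)
  maxp <- max(lengths(fields)) - 1L
  nc <- nf * (dmax + 1L)
  # residual coefficient map: EL_i(x) = sum_t res[i, t] x^t
  rows <- nf * (dmax + 1L)
  Fmap <- matrix(0, rows, nc)
  fact <- function(m, r) {  # falling factorial m!/(m-r)!
    if (r == 0L) 1 else if (r > m) 0 else prod(seq.int(m - r + 1L, m))
  }
  for (j in seq_len(nf)) for (m in 0:dmax) {
    col <- (j - 1L) * (dmax + 1L) + m + 1L
    for (i in seq_len(nf)) for (p in 0:maxp) for (q in 0:maxp) {
      si <- fields[[i]]; sj <- fields[[j]]
      if (p >= length(si) || q >= length(sj)) next
      qij <- Q[si[p + 1L], sj[q + 1L]]
      if (qij == 0) next
      r <- p + q
      if (r > m) next
      # (-1)^p * qij * m!/(m-r)! x^(m-r) contributes to residual row (i, t=m-r)
      t <- m - r
      row <- (i - 1L) * (dmax + 1L) + t + 1L
      Fmap[row, col] <- Fmap[row, col] + (-1)^p * qij * fact(m, r)
    }
  }
  sv <- svd(Fmap, nu = 0)
  tolsv <- max(sv$d) * 1e-10
  null_idx <- which(sv$d < tolsv)
  V <- sv$v[, null_idx, drop = FALSE]
  if (ncol(V) < expected)
    stop(sprintf("found %d polynomial EL solutions, expected %d (raise dmax?)",
                 ncol(V), expected))
  if (ncol(V) > expected)
    warning(sprintf("found %d polynomial EL solutions, expected %d",
                    ncol(V), expected))
  list(V = V, dmax = dmax)
}
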