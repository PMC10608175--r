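# Parameter scans and nuisance-parameter optimization: line tension vs
# monolayer shift, peptide-domain interaction profiles, and domain-domain
# fusion barriers. All optimizations are deterministic (grids + local
# refinement); the energy is smooth and piecewise-analytic in every scanned
# variable.

.scan_cache <- new.env(parent = emptyenv())

#' Construct an energy profile object
#'
#' @param abscissa one of `"L"`, `"X"`, `"D"`.
#' @param grid ordered sample points, nm.
#' @param energy energy per unit boundary length at each point, kB*T/nm
#'   (after subtraction of `reference`).
#' @param reference the subtracted reference energy, kB*T/nm.
#' @param extrema data frame of located extrema (`type`, `position`, `value`).
#' @param details named list of scan-specific summaries.
#' @return object of class `energy_profile`.
#' @export
energy_profile <- function(abscissa, grid, energy, reference = 0,
                           extrema = NULL, details = list()) {
  stopifnot(abscissa %in% c("L", "X", "D"), length(grid) == length(energy),
            length(grid) > 0, !is.unsorted(grid, strictly = TRUE))
  structure(list(abscissa = abscissa, grid = grid, energy = energy,
                 reference = reference, extrema = extrema, details = details),
            class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf("<energy_profile> E(%s), %d points on [%.3g, %.3g] nm\n",
              x$abscissa, length(x$grid), min(x$grid), max(x$grid)))
  cat(sprintf("  reference: %.6g kBT/nm\n", x$reference))
  if (!is.null(x$extrema) && nrow(x$extrema)) {
    for (i in seq_len(nrow(x$extrema)))
      cat(sprintf("  %s at %s = %.4g nm: %.5g kBT/nm\n", x$extrema$type[i],
                  x$abscissa, x$extrema$position[i], x$extrema$value[i]))
  }
  invisible(x)
}

#' @export
as.data.frame.energy_profile <- function(x, ...) {
  df <- data.frame(x$grid, x$energy)
  names(df) <- c(x$abscissa, "energy")
  df
}

# indices of interior local minima (or maxima) of y
.local_extrema_idx <- function(y, maximize = FALSE) {
  if (maximize) y <- -y
  n <- length(y)
  which(vapply(seq_len(n), function(i) {
    i > 1L && i < n && y[i] <= y[i - 1L] && y[i] <= y[i + 1L] &&
      (y[i] < y[i - 1L] || y[i] < y[i + 1L])
  }, NA))
}

# refine an extremum of f near x0 within [x0 - w, x0 + w] (clipped)
.refine_extremum <- function(f, x0, w, lo = -Inf, hi = Inf, maximize = FALSE,
                             tol = 1e-4) {
  a <- max(lo, x0 - w); b <- min(hi, x0 + w)
  if (b - a < 2 * tol) return(list(position = x0, value = f(x0)))
  o <- stats::optimize(f, c(a, b), maximum = maximize, tol = tol)
  list(position = if (maximize) o$maximum else o$minimum,
       value = if (maximize) o$objective else o$objective)
}

#' Elastic line-tension contribution vs monolayer shift
#'
#' Solves the single Lo/Ld boundary for each relative monolayer shift L and
#' locates the two symmetric minima. The profile is the elastic contribution
#' to the line tension of the domain boundary (the chemical contribution is
#' an additive constant and is not modeled); the misregistration penalty
#' `0.016 |L|` is included by default.
#'
#' @param L_grid shift grid, nm.
#' @param params `parameter_set`.
#' @param include_misregistration include the misregistration penalty.
#' @return `energy_profile` with abscissa `"L"` and located minima.
#' @export
line_tension_vs_shift <- function(L_grid = seq(-5, 5, by = 0.1),
                                  params = default_parameter_set(),
                                  include_misregistration = TRUE) {
  f <- function(L) solve_equilibrium(
    single_boundary(L, params,
                    include_misregistration = include_misregistration))$energy
  E <- vapply(L_grid, f, 0)
  idx <- .local_extrema_idx(E)
  step <- if (length(L_grid) > 1) max(diff(L_grid)) else 0.1
  ext <- do.call(rbind, lapply(idx, function(i) {
    r <- .refine_extremum(f, L_grid[i], step, min(L_grid), max(L_grid))
    data.frame(type = "min", position = r$position, value = r$value)
  }))
  energy_profile("L", L_grid, E, reference = 0, extrema = ext)
}

#' Peptide-domain interaction profile
#'
#' Energy as a function of the coordinate X of the right edge of an adsorbed
#' peptide near a single Lo/Ld boundary held at shift `L0`. The reference is
#' the peptide-at-infinity energy: the isolated boundary plus an isolated
#' peptide far in the disordered phase, so the profile tends to 0 as
#' X grows into the Ld phase. The profile's global minimum is the boundary
#' well; its maximum is the barrier a peptide must overcome to cross from
#' the Ld phase into the Lo domain interior.
#'
#' @param L0 fixed monolayer shift of the boundary, nm.
#' @param X_grid grid of peptide right-edge coordinates, nm (spanning both
#'   phases; the ordered phase lies toward negative x).
#' @inheritParams line_tension_vs_shift
#' @return `energy_profile` with abscissa `"X"`; `details` holds
#'   `well_depth`, `well_X`, `crossing_barrier`, `barrier_X`, `lo_plateau`.
#' @export
peptide_domain_profile <- function(L0, X_grid = seq(-8, 10, by = 0.1),
                                   params = default_parameter_set(),
                                   include_misregistration = TRUE) {
  ref <- solve_equilibrium(single_boundary(
    L0, params, include_misregistration = include_misregistration))$energy +
    solve_equilibrium(peptide_in_phase("disordered", params))$energy
  f <- function(X) solve_equilibrium(single_boundary(
    L0, params, peptide_X = X,
    include_misregistration = include_misregistration))$energy - ref
  E <- vapply(X_grid, f, 0)
  step <- max(diff(X_grid))
  imin <- which.min(E)
  rmin <- .refine_extremum(f, X_grid[imin], step, min(X_grid), max(X_grid))
  imax <- which.max(E)
  rmax <- .refine_extremum(f, X_grid[imax], step, min(X_grid), max(X_grid),
                           maximize = TRUE)
  ext <- data.frame(type = c("min", "max"),
                    position = c(rmin$position, rmax$position),
                    value = c(rmin$value, rmax$value))
  energy_profile("X", X_grid, E, reference = ref, extrema = ext,
                 details = list(well_depth = -rmin$value, well_X = rmin$position,
                                crossing_barrier = rmax$value,
                                barrier_X = rmax$position,
                                lo_plateau = E[1L]))
}

#' Joint minimization over monolayer shift and peptide position
#'
#' Minimizes the energy of a single boundary plus one adsorbed peptide
#' jointly over the shift L (on one sign branch) and the peptide right-edge
#' coordinate X, by a nested coarse grid followed by alternating local
#' refinement.
#'
#' @param branch `"positive"` or `"negative"` sign branch of L.
#' @param L_max largest |L| searched, nm.
#' @param X_range search interval for X, nm.
#' @inheritParams line_tension_vs_shift
#' @return list with `L`, `X`, `energy` (absolute, kB*T/nm) and `branch`.
#' @export
joint_minimum_peptide_shift <- function(params = default_parameter_set(),
                                        branch = c("positive", "negative"),
                                        L_max = 4, X_range = c(-4, 6),
                                        include_misregistration = TRUE) {
  branch <- match.arg(branch)
  sgn <- if (branch == "positive") 1 else -1
  f <- function(L, X) solve_equilibrium(single_boundary(
    L, params, peptide_X = X,
    include_misregistration = include_misregistration))$energy
  Ls <- sgn * seq(0, L_max, by = 0.2)
  Xs <- seq(X_range[1], X_range[2], by = 0.5)
  Egrid <- outer(Ls, Xs, Vectorize(f))
  ij <- arrayInd(which.min(Egrid), dim(Egrid))
  L <- Ls[ij[1]]; X <- Xs[ij[2]]
  wL <- 0.25; wX <- 0.6
  for (it in 1:3) {
    oX <- .refine_extremum(function(x) f(L, x), X, wX, X_range[1], X_range[2])
    X <- oX$position
    Lint <- sort(sgn * c(0, L_max))
    oL <- .refine_extremum(function(l) f(l, X), L, wL, Lint[1], Lint[2])
    L <- oL$position
    wL <- wL / 2; wX <- wX / 2
  }
  list(L = L, X = X, energy = f(L, X), branch = branch)
}

# basin-restricted line minimization: from x0, walk downhill in steps until
# the energy first increases (never hopping over an intervening maximum),
# then refine by golden-section/Brent inside the bracketing interval. Used
# for the adiabatic tracking of the optimizer path along a D scan.
.local_line_min <- function(g, x0, lo, hi, step = 0.05, tol = 1e-4) {
  x0 <- min(max(x0, lo), hi)
  f0 <- g(x0)
  xp <- min(hi, x0 + step); xm <- max(lo, x0 - step)
  fp <- if (xp > x0) g(xp) else Inf
  fm <- if (xm < x0) g(xm) else Inf
  if (f0 <= fp && f0 <= fm) {
    if (max(xp - x0, x0 - xm) < 2 * tol) return(list(x = x0, f = f0))
    o <- stats::optimize(g, c(xm, xp), tol = tol)
    if (o$objective < f0) return(list(x = o$minimum, f = o$objective))
    return(list(x = x0, f = f0))
  }
  dir <- if (fp < fm) 1 else -1
  xc <- if (dir > 0) xp else xm; fc <- min(fp, fm)
  repeat {
    xn <- xc + dir * step
    if (xn > hi || xn < lo) {
      xn <- if (dir > 0) hi else lo
      fn <- g(xn)
      if (fn < fc) { xc <- xn; fc <- fn }
      break
    }
    fn <- g(xn)
    if (fn >= fc) break
    xc <- xn; fc <- fn
  }
  a <- max(lo, xc - step); b <- min(hi, xc + step)
  o <- stats::optimize(g, c(a, b), tol = tol)
  if (o$objective < fc) list(x = o$minimum, f = o$objective) else
    list(x = xc, f = fc)
}

# memoized optimum of an isolated domain boundary (one side), optionally
# with a peptide at the boundary; frame: the facing (protruding) monolayer
# edge at x = 0, ordered phase toward -x ("left" side) or +x ("right"
# side), the other monolayer edge receding from the gap by l (matching the
# domain_pair distance convention). With peptide_side = "disordered" the
# peptide strip is restricted to the disordered side of the upper-leaflet
# edge (the boundary well a peptide reaches by diffusion without crossing
# into the ordered phase); "free" searches the whole axis and finds the
# model's global optimum, in which the peptide is absorbed at the ordered
# edge from inside.
.iso_boundary_optimum <- function(side, sgn, pep, params,
                                  include_misregistration = TRUE, L_max = 6,
                                  peptide_side = "free") {
  key <- paste(.params_key(params$ordered, params$disordered, params$system),
               params$peptide$delta_L, side, sgn, pep,
               include_misregistration, peptide_side, sep = "|")
  if (!is.null(.scan_cache[[key]])) return(.scan_cache[[key]])
  dL <- params$peptide$delta_L
  build <- function(l, xo) {
    if (side == "left") {
      membrane_configuration(
        upper_lo = matrix(c(-Inf, if (sgn > 0) 0 else -l), 1),
        lower_lo = matrix(c(-Inf, if (sgn > 0) -l else 0), 1),
        peptide_X = if (pep) xo else numeric(0),
        params = params,
        include_misregistration = include_misregistration)
    } else {
      membrane_configuration(
        upper_lo = matrix(c(if (sgn > 0) 0 else l, Inf), 1),
        lower_lo = matrix(c(if (sgn > 0) l else 0, Inf), 1),
        peptide_X = if (pep) xo else numeric(0),
        params = params,
        include_misregistration = include_misregistration)
    }
  }
  # upper-leaflet edge position and the implied bound on the peptide
  # right-edge coordinate xo ("disordered" basin: strip fully in Ld)
  xo_box <- function(l) {
    if (peptide_side == "free") return(c(-6, 7))
    edge <- if (side == "left") (if (sgn > 0) 0 else -l) else
      (if (sgn > 0) 0 else l)
    if (side == "left") c(edge + dL, 7) else c(-6, edge)
  }
  f <- function(l, xo = 0) solve_equilibrium(build(l, xo))$energy
  if (!pep) {
    ls <- seq(0, L_max, by = 0.1)
    E <- vapply(ls, f, 0)
    i <- which.min(E)
    r <- .refine_extremum(f, ls[i], 0.1, 0, L_max)
    out <- list(E = r$value, l = r$position, xo = NA_real_)
  } else {
    ls <- seq(0, L_max, by = 0.2)
    xs <- seq(-5, 6, by = 0.25)
    Eg <- outer(ls, xs, Vectorize(function(l, x) {
      bb <- xo_box(l)
      if (x < bb[1] || x > bb[2]) Inf else f(l, x)
    }))
    ij <- arrayInd(which.min(Eg), dim(Eg))
    l <- ls[ij[1]]; xo <- xs[ij[2]]
    for (it in 1:4) {
      bb <- xo_box(l)
      ox <- .local_line_min(function(x) f(l, x), xo, bb[1], bb[2])
      xo <- ox$x
      ol <- .local_line_min(function(v) {
        b2 <- xo_box(v)
        f(v, min(max(xo, b2[1]), b2[2]))
      }, l, 0, L_max)
      l <- ol$x
      bb <- xo_box(l)
      xo <- min(max(xo, bb[1]), bb[2])
    }
    out <- list(E = f(l, xo), l = l, xo = xo)
  }
  .scan_cache[[key]] <- out
  out
}

#' Domain-domain interaction profile E(D) - E(infinity)
#'
#' For each edge-to-edge distance D between two liquid-ordered domains
#' (measured between the facing, protruding monolayer edges, see
#' [domain_pair()]), the elastic energy is minimized over the monolayer
#' shift magnitudes of both domains (signs fixed by the topology) and over
#' the positions of any peptides at the facing boundaries, then the
#' additively computed D = infinity reference (two isolated optimized
#' boundaries) is subtracted. The scan proceeds from large to small D with
#' warm-started coordinate descent; each coordinate update is a
#' basin-restricted downhill line search, so the optimizer tracks the
#' adiabatic continuation of the separated-domain state rather than hopping
#' between distant energy basins.
#'
#' @param topology one row of [boundary_topologies()] (or a list with
#'   elements `left`, `right` in `"upper"`/`"lower"` and `peptides` 0:2).
#' @param D_grid distances, nm; the default is dense (0.25 nm) out to 8 nm
#'   and coarser beyond, extending to 120 nm: boundary-boundary interactions
#'   decay as exp(-2 lambda D) in the slow tension mode, but each peptide's
#'   rigid-rotation constraint carries a net capillary source, so
#'   peptide-peptide interactions across the gap decay only as
#'   exp(-lambda D) with a ~20 nm decay length.
#' @param L_max largest shift magnitude searched, nm.
#' @param X_halfwidth peptide search half-width around its boundary well, nm.
#' @param reoptimize_peptides re-optimize peptide positions at every D
#'   (default); if `FALSE`, peptides stay at their isolated-boundary wells.
#' @param peptide_side `"free"` (default) optimizes each peptide position
#'   without phase restrictions at every D (matching a global minimization
#'   over peptide positions and shifts; peptides may end up absorbed at an
#'   ordered domain's edge from inside). `"disordered"` restricts every
#'   peptide strip to the upper-leaflet disordered phase, both in the
#'   isolated-boundary references and during the D sweep (where the
#'   disordered phase is the shrinking gap between the domains): the state a
#'   peptide reaches by diffusion through the surrounding phase without
#'   crossing into an ordered domain. The merging pathway then has to
#'   squeeze the peptide(s) inside the closing gap, and the scan truncates
#'   at the distance where the strips no longer fit.
#' @inheritParams line_tension_vs_shift
#' @return `energy_profile` with abscissa `"D"`; `details` carries the
#'   reference energy, the optimum trajectory and a truncation flag for
#'   geometrically infeasible small D.
#' @export
interaction_profile <- function(topology,
                                params = default_parameter_set(),
                                D_grid = c(seq(0.25, 8, by = 0.25),
                                           seq(8.5, 15, by = 0.5),
                                           seq(16, 40, by = 2),
                                           seq(44, 120, by = 4)),
                                L_max = 6, X_halfwidth = 6,
                                reoptimize_peptides = TRUE,
                                peptide_side = c("free", "disordered"),
                                include_misregistration = TRUE) {
  npep <- topology$peptides
  stopifnot(npep %in% 0:2)
  peptide_side <- match.arg(peptide_side)
  sgn_l <- if (topology$left == "upper") 1 else -1
  sgn_r <- if (topology$right == "upper") 1 else -1
  dL <- params$peptide$delta_L

  iso_l <- .iso_boundary_optimum("left", sgn_l, npep == 2, params,
                                 include_misregistration, L_max, peptide_side)
  iso_r <- .iso_boundary_optimum("right", sgn_r, npep >= 1, params,
                                 include_misregistration, L_max, peptide_side)
  E_inf <- iso_l$E + iso_r$E

  # theta: ll, lr (shift magnitudes), xol (left peptide X, absolute),
  # xor (right peptide X, relative to right domain edge D)
  th <- c(ll = iso_l$l, lr = iso_r$l,
          xol = if (npep == 2) iso_l$xo else NA_real_,
          xor = if (npep >= 1) iso_r$xo else NA_real_)
  well_l <- th[["xol"]]; well_r <- th[["xor"]]

  ED <- function(D, th) {
    px <- c(if (npep == 2) th[["xol"]],
            if (npep >= 1) D + th[["xor"]])
    solve_equilibrium(domain_pair(
      D, L_left = sgn_l * th[["ll"]], L_right = sgn_r * th[["lr"]],
      params = params, peptide_X = sort(px),
      include_misregistration = include_misregistration))$energy
  }

  # disordered-side basin bounds in the pair frame: the strip must stay on
  # the disordered side of its domain's upper-leaflet edge (which sits at
  # the gap edge for an "upper" boundary and recedes by the shift magnitude
  # for a "lower" one, so the bound moves with the current shift)
  constrained <- peptide_side == "disordered"
  xol_min <- function(ll) if (sgn_l > 0) dL else dL - ll
  xor_max <- function(lr) if (sgn_r > 0) 0 else lr
  # a lone gap peptide is also barred from the *left* domain's ordered
  # upper leaflet (with two peptides the non-overlap chain implies this)
  xor_min <- function(D, ll) {
    if (npep == 2) -Inf else dL - D - (if (sgn_l > 0) 0 else ll)
  }
  clamp_th <- function(D, th) {
    if (!constrained) return(th)
    if (npep == 2)
      th[["xol"]] <- max(th[["xol"]], xol_min(th[["ll"]]))
    if (npep >= 1)
      th[["xor"]] <- min(max(th[["xor"]], xor_min(D, th[["ll"]])),
                         xor_max(th[["lr"]]))
    th
  }

  Ds <- sort(D_grid, decreasing = TRUE)
  Eout <- rep(NA_real_, length(Ds))
  traj <- vector("list", length(Ds))
  truncated <- FALSE
  for (k in seq_along(Ds)) {
    D <- Ds[k]
    # feasible boxes for this D
    box <- list(ll = c(0, L_max), lr = c(0, L_max))
    if (npep == 2) box$xol <- c(well_l - X_halfwidth, well_l + X_halfwidth)
    if (npep >= 1) box$xor <- c(well_r - X_halfwidth, well_r + X_halfwidth)
    if (npep == 2) {
      # strips must not overlap: xol <= D + xor - dL
      xol_lo <- if (constrained) max(box$xol[1], xol_min(L_max)) else
        box$xol[1]
      xor_hi <- if (constrained) min(box$xor[2], xor_max(L_max)) else
        box$xor[2]
      if (xol_lo > D + xor_hi - dL - 2e-3) {
        truncated <- TRUE
        break
      }
      th[["xol"]] <- min(th[["xol"]], D + th[["xor"]] - dL - 2e-3)
    } else if (npep == 1 && constrained) {
      # the strip must fit inside the disordered gap
      if (xor_min(D, L_max) > min(box$xor[2], xor_max(L_max))) {
        truncated <- TRUE
        break
      }
    }
    th <- clamp_th(D, th)
    coords <- c("ll", "lr",
                if (npep >= 1 && reoptimize_peptides) "xor",
                if (npep == 2 && reoptimize_peptides) "xol")
    Ecur <- ED(D, th)
    for (sweep in 1:12) {
      Eprev <- Ecur
      for (cn in coords) {
        lohi <- box[[cn]]
        if (npep == 2) {
          if (cn == "xol") lohi[2] <- min(lohi[2], D + th[["xor"]] - dL - 2e-3)
          if (cn == "xor") lohi[1] <- max(lohi[1], th[["xol"]] - D + dL + 2e-3)
        }
        if (constrained) {
          if (cn == "xol") lohi[1] <- max(lohi[1], xol_min(th[["ll"]]))
          if (cn == "xor") {
            lohi[2] <- min(lohi[2], xor_max(th[["lr"]]))
            lohi[1] <- max(lohi[1], xor_min(D, th[["ll"]]))
          }
        }
        if (lohi[2] - lohi[1] < 1e-6) next
        g <- function(v) {
          t2 <- th; t2[[cn]] <- v
          # shift moves the disordered-side bounds: drag the peptide along
          if (constrained && cn == "ll") {
            if (npep == 2) t2[["xol"]] <- max(t2[["xol"]], xol_min(v))
            else t2[["xor"]] <- max(t2[["xor"]], xor_min(D, v))
          }
          if (constrained && cn == "lr" && npep >= 1)
            t2[["xor"]] <- min(t2[["xor"]], xor_max(v))
          ED(D, t2)
        }
        r <- .local_line_min(g, th[[cn]], lohi[1], lohi[2], tol = 2e-4)
        if (r$f < Ecur) { th[[cn]] <- r$x; Ecur <- r$f; th <- clamp_th(D, th) }
      }
      if (Eprev - Ecur < 1e-5) break
    }
    Eout[k] <- Ecur
    traj[[k]] <- th
  }
  keep <- !is.na(Eout)
  Ds <- Ds[keep]; Eout <- Eout[keep]; traj <- traj[keep]
  ord <- order(Ds)
  energy_profile("D", Ds[ord], Eout[ord] - E_inf, reference = E_inf,
                 details = list(topology = topology, truncated = truncated,
                                trajectory = traj[ord],
                                iso_left = iso_l, iso_right = iso_r))
}

#' Fusion energy barrier of an interaction profile
#'
#' The barrier is the maximum of E(D) - E(infinity) over D, refined locally
#' by quadratic interpolation around the grid maximum; 0 if the profile is
#' monotone non-increasing toward contact. The profile must have reached its
#' far-field plateau at the largest scanned D.
#'
#' @param profile an `energy_profile` with abscissa `"D"` (values already
#'   relative to the D = infinity reference).
#' @param plateau_tol maximum |E(D_max)| accepted as a plateau, kB*T/nm.
#' @return list with `barrier` (kB*T/nm) and `D_barrier` (nm).
#' @export
fusion_barrier <- function(profile, plateau_tol = 5e-3) {
  stopifnot(inherits(profile, "energy_profile"), profile$abscissa == "D")
  y <- profile$energy; x <- profile$grid
  if (abs(y[length(y)]) > plateau_tol)
    stop("no far-field plateau detected at D = ", max(x),
         " nm; widen the D grid", call. = FALSE)
  i <- which.max(y)
  if (y[i] <= 1e-9 || i == length(y))
    return(list(barrier = 0, D_barrier = NA_real_))
  if (i > 1L && i < length(y)) {
    # quadratic refinement through the three points around the maximum
    x3 <- x[(i - 1):(i + 1)]; y3 <- y[(i - 1):(i + 1)]
    cf <- unname(solve(cbind(1, x3, x3^2), y3))
    if (cf[3] < 0) {
      xs <- -cf[2] / (2 * cf[3])
      if (xs > x3[1] && xs < x3[3]) {
        ys <- cf[1] + cf[2] * xs + cf[3] * xs^2
        return(list(barrier = unname(ys), D_barrier = unname(xs)))
      }
    }
  }
  list(barrier = unname(y[i]), D_barrier = unname(x[i]))
}
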