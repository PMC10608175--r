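# Constrained quadratic minimization over the piecewise-analytic solution
# basis: the production solver.

#' Misregistration energy of offset monolayer domain edges
#'
#' Energy per unit boundary length of the strip where an ordered monolayer
#' faces a disordered one across the bilayer midplane:
#' `density * |L|` for a strip of width `|L|`.
#'
#' @param L relative monolayer shift (misregistered strip width), nm.
#' @param density energy per unit misregistered area, kB*T/nm^2.
#' @return energy per unit boundary length, kB*T/nm.
#' @export
misregistration_energy <- function(L, density = 0.016) {
  density * abs(L)
}

#' Solve the membrane boundary-value problem
#'
#' Minimizes the total elastic energy (the integral of the quadratic
#' tilt-splay density over all regions, plus the misregistration penalty)
#' over the per-region Euler-Lagrange solution bases, subject to the
#' configuration's continuity, peptide-jump and decay constraints. The energy
#' is reported per unit length along the domain boundary, relative to the
#' undeformed flat membrane.
#'
#' @param config a `membrane_config`, see [single_boundary()],
#'   [domain_pair()], [membrane_configuration()].
#' @param check if `TRUE`, verify constraint rank and positive definiteness
#'   of the reduced Hessian (slower; used in validation).
#' @return an `equilibrium_solution`: list with `energy` (total, kB*T/nm),
#'   `elastic` and `misregistration` components, the basis coefficients and
#'   region bookkeeping for shape evaluation via [membrane_shape()].
#' @export
solve_equilibrium <- function(config, check = FALSE) {
  stopifnot(inherits(config, "membrane_config"))
  params <- config$params
  sys <- params$system
  breaks <- config$breaks
  nreg <- length(config$regions)
  stopifnot(nreg == length(breaks) + 1L)

  phase_par <- function(lbl) {
    switch(lbl, ordered = params$ordered, disordered = params$disordered,
           stop("unknown phase label: ", lbl))
  }

  regs <- vector("list", nreg)
  offs <- integer(nreg)
  ntot <- 0L
  for (i in seq_len(nreg)) {
    r <- config$regions[[i]]
    pu <- if (is.na(r$upper)) NULL else phase_par(r$upper)
    pl <- phase_par(r$lower)
    rs <- .region_system(pu, pl, sys)
    role <- if (i == 1L) "leftinf" else if (i == nreg) "rightinf" else
      if (is.na(r$upper) && isTRUE(config$rigid_lower_under_peptide))
        "rigid" else "finite"
    a <- if (i == 1L) -Inf else breaks[i - 1L]
    b <- if (i == nreg) Inf else breaks[i]
    T <- if (role == "finite") b - a else Inf
    nm <- length(.role_modes(rs, role))
    regs[[i]] <- list(rs = rs, role = role, a = a, b = b, T = T, nm = nm)
    offs[i] <- ntot
    ntot <- ntot + nm
  }

  G <- matrix(0, ntot, ntot)
  lvec <- numeric(ntot)
  for (i in seq_len(nreg)) {
    rg <- regs[[i]]
    idx <- offs[i] + seq_len(rg$nm)
    G[idx, idx] <- .region_gram(rg$rs, rg$role, rg$T)
    if (!rg$rs$g_zero) lvec[idx] <- .region_linvec(rg$rs, rg$role, rg$T)
  }

  # --- constraints ---------------------------------------------------------
  rows <- list(); rhs <- numeric(0); labels <- character(0)
  add_row <- function(row, r, lab) {
    rows[[length(rows) + 1L]] <<- row
    rhs <<- c(rhs, r)
    labels <<- c(labels, lab)
  }
  edgeV <- function(i, edge) .edge_values(regs[[i]]$rs, regs[[i]]$role,
                                          regs[[i]]$T, edge)
  uinf <- function(i) stats::setNames(regs[[i]]$rs$u_inf, regs[[i]]$rs$slots)

  is_strip <- vapply(config$regions, function(r) is.na(r$upper), NA)

  # continuity of the director field and of the monolayer neutral surfaces;
  # the mid-surface and the director derivative are free at interfaces (their
  # matching conditions arise naturally from the minimization)
  cont <- getOption("memelastic.continuity", c("n", "H"))
  low_q <- c(if ("n" %in% cont) "n_l", if ("dn" %in% cont) "dn_l",
             if ("H" %in% cont) "H_l", if ("M" %in% cont) "M")
  upp_q <- c(if ("n" %in% cont) "n_u", if ("dn" %in% cont) "dn_u",
             if ("H" %in% cont) "H_u")
  for (m in seq_along(breaks)) {
    iL <- m; iR <- m + 1L
    VL <- edgeV(iL, "b"); VR <- edgeV(iR, "a")
    uL <- uinf(iL); uR <- uinf(iR)
    qts <- low_q
    if (!is_strip[iL] && !is_strip[iR]) qts <- c(qts, upp_q)
    for (q in qts) {
      row <- numeric(ntot)
      row[offs[iL] + seq_len(regs[[iL]]$nm)] <- VL[, q]
      row[offs[iR] + seq_len(regs[[iR]]$nm)] <- -VR[, q]
      if (max(abs(row)) < 1e-12) {
        # both sides rigid for this quantity: nothing to match
        if (abs(uR[q] - uL[q]) > 1e-9)
          stop("inconsistent rigid interface at x=", breaks[m])
        next
      }
      add_row(row, uR[q] - uL[q], sprintf("continuity %s at x=%.4g", q, breaks[m]))
    }
  }

  # peptide strips: director jump and helix-rotation tie across each strip
  if (!is.null(config$strips) && nrow(config$strips)) {
    dL <- params$peptide$delta_L
    for (s in seq_len(nrow(config$strips))) {
      st <- config$strips[s, ]
      m1 <- which(abs(breaks - st$x1) < 1e-9)
      m2 <- which(abs(breaks - st$x2) < 1e-9)
      if (length(m1) != 1L || length(m2) != 1L)
        stop("strip edges must coincide with region breakpoints")
      iL <- m1; iR <- m2 + 1L
      if (!is_strip[m1 + 1L])
        stop("region under the peptide strip is not a strip region")
      VL <- edgeV(iL, "b"); VR <- edgeV(iR, "a")
      uL <- uinf(iL); uR <- uinf(iR)
      # director jump n_u(x2+) - n_u(x1-) = dn
      row <- numeric(ntot)
      row[offs[iL] + seq_len(regs[[iL]]$nm)] <- -VL[, "n_u"]
      row[offs[iR] + seq_len(regs[[iR]]$nm)] <- VR[, "n_u"]
      add_row(row, st$dn, sprintf("peptide director jump at X0=%.4g", st$X0))
      # rotation tie: H_u(x2) - H_u(x1) = dL * (n1 + n2)/2
      row <- numeric(ntot)
      row[offs[iL] + seq_len(regs[[iL]]$nm)] <-
        -VL[, "H_u"] - (dL / 2) * VL[, "n_u"]
      row[offs[iR] + seq_len(regs[[iR]]$nm)] <-
        VR[, "H_u"] - (dL / 2) * VR[, "n_u"]
      add_row(row, uL["H_u"] - uR["H_u"],
              sprintf("peptide rotation tie at X0=%.4g", st$X0))
    }
  }

  R <- do.call(rbind, rows)
  if (is.null(R)) R <- matrix(0, 0L, ntot)   # uniform membrane: no interfaces
  ncon <- nrow(R)

  if (ntot == 0L) {
    # no basis modes and no constraints: the undeformed state is exact
    e_mis <- if (isTRUE(config$include_misregistration))
      sys$misregistration_density * config$misreg_width else 0
    out <- list(energy = e_mis, elastic = 0, misregistration = e_mis,
                coefficients = numeric(0), offsets = offs, regions = regs,
                config = config, n_constraints = 0L)
    class(out) <- "equilibrium_solution"
    return(out)
  }

  if (check) {
    qrR <- qr(t(R))
    if (qrR$rank < ncon)
      stop("rank-deficient constraint set (", ncon - qrR$rank,
           " redundant rows); offending interfaces: ",
           paste(utils::head(labels, 5), collapse = "; "))
  }

  KKT <- rbind(cbind(G, t(R)), cbind(R, matrix(0, ncon, ncon)))
  sol <- tryCatch(solve(KKT, c(-lvec, rhs)),
                  error = function(e) stop("singular KKT system: ",
                                           conditionMessage(e), call. = FALSE))
  C <- sol[seq_len(ntot)]
  if (ncon && max(abs(R %*% C - rhs)) > 1e-6 * max(1, max(abs(rhs))))
    stop("constraint residual too large; inconsistent constraints?")

  if (check) {
    qrR <- qr(t(R))
    Z <- qr.Q(qrR, complete = TRUE)[, -seq_len(qrR$rank), drop = FALSE]
    H <- crossprod(Z, G %*% Z)
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-7 * max(abs(ev)))
      stop("reduced Hessian is not positive semi-definite")
  }

  e_el <- 0.5 * sum(C * (G %*% C)) + sum(lvec * C)
  e_mis <- if (isTRUE(config$include_misregistration))
    sys$misregistration_density * config$misreg_width else 0

  out <- list(energy = e_el + e_mis, elastic = e_el, misregistration = e_mis,
              coefficients = C, offsets = offs, regions = regs,
              config = config, n_constraints = ncon)
  class(out) <- "equilibrium_solution"
  out
}

#' @export
print.equilibrium_solution <- function(x, ...) {
  cat("<equilibrium_solution>\n")
  cat(sprintf("  energy per unit boundary length: %.6g kBT/nm\n", x$energy))
  cat(sprintf("  elastic: %.6g, misregistration: %.6g kBT/nm\n",
              x$elastic, x$misregistration))
  cat(sprintf("  %d regions, %d basis modes, %d constraints\n",
              length(x$regions), length(x$coefficients), x$n_constraints))
  invisible(x)
}

#' Membrane shape of an equilibrium solution
#'
#' Samples the monolayer neutral surfaces and mid-surface (and director
#' projections) of a solved configuration.
#'
#' @param sol an `equilibrium_solution`.
#' @param x positions at which to sample, nm.
#' @return data frame with columns `x`, `H_u`, `H_l`, `M`, `n_u`, `n_l`
#'   (absolute z-coordinates in nm; `H_u`/`n_u` are `NA` under peptide
#'   strips).
#' @export
membrane_shape <- function(sol, x = NULL) {
  cfg <- sol$config
  breaks <- cfg$breaks
  if (is.null(x)) {
    lo <- if (length(breaks)) min(breaks) - 15 else -15
    hi <- if (length(breaks)) max(breaks) + 15 else 15
    x <- seq(lo, hi, by = 0.05)
  }
  n <- length(x)
  out <- data.frame(x = x, H_u = NA_real_, H_l = NA_real_, M = NA_real_,
                    n_u = NA_real_, n_l = NA_real_)
  ridx <- findInterval(x, breaks) + 1L
  for (i in unique(ridx)) {
    rg <- sol$regions[[i]]
    sel <- which(ridx == i)
    tloc <- if (rg$role == "leftinf") x[sel] - rg$b else x[sel] - rg$a
    C <- sol$coefficients[sol$offsets[i] + seq_len(rg$nm)]
    dev <- .eval_fields(rg$rs, rg$role, rg$T, C, tloc)
    uinf <- stats::setNames(rg$rs$u_inf, rg$rs$slots)
    fl <- colnames(dev)
    vals <- sweep(dev, 2L, uinf[fl], "+")
    for (f in fl) out[sel, f] <- vals[, f]
  }
  out
}
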