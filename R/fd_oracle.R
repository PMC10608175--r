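# Independent cross-check solver: direct variational minimization of the
# same energy functional on a dense finite-difference grid over a truncated
# domain. Completely separate solution path from the analytic basis solver
# (no characteristic roots, no exponential modes); used to validate it.
#
# Each segment (stretch between consecutive breakpoints) owns its nodes, so
# no continuity is implied by storage; the same interface conditions as the
# production solver (continuity of the directors and neutral surfaces) are
# imposed as explicit constraint rows.

#' Finite-difference solution of the membrane boundary-value problem
#'
#' Minimizes the discretized elastic energy on a truncated domain, one dense
#' uniform grid per segment with one-sided stencils at segment ends, subject
#' to the same interface conditions as [solve_equilibrium()]. Far boundaries
#' are clamped to the flat state, with a free common vertical offset at the
#' right end. Intended as an independent numerical oracle; second-order
#' accurate in `h`.
#'
#' @param config a `membrane_config`.
#' @param h target grid spacing, nm.
#' @param halfwidth distance from the outermost breakpoints to the domain
#'   truncation, nm (deformations decay with a ~1 nm decay length).
#' @return list with `energy`, `elastic`, `misregistration` (kB*T/nm), and
#'   per-node `x` and `fields` (matrix with columns `n_u`, `n_l`, `H_u`,
#'   `H_l`, `M`; interface nodes appear once per adjoining segment).
#' @export
solve_equilibrium_fd <- function(config, h = 0.02, halfwidth = 20) {
  stopifnot(inherits(config, "membrane_config"))
  params <- config$params
  sys <- params$system
  breaks <- config$breaks
  if (!length(breaks)) breaks <- 0
  cuts <- c(min(breaks) - halfwidth, breaks, max(breaks) + halfwidth)
  nseg <- length(cuts) - 1L

  phase_par <- function(lbl) switch(lbl, ordered = params$ordered,
                                    disordered = params$disordered)
  is_strip <- vapply(config$regions, function(r) is.na(r$upper), NA)
  stopifnot(length(config$regions) == nseg)

  # --- per-segment layout ---------------------------------------------------
  seg <- vector("list", nseg)
  ndof <- 0L
  for (s in seq_len(nseg)) {
    a <- cuts[s]; b <- cuts[s + 1L]
    m <- max(4L, ceiling((b - a) / h))
    xx <- seq(a, b, length.out = m + 1L)
    flds <- if (is_strip[s]) c("n_l", "H_l", "M") else
      c("n_u", "n_l", "H_u", "H_l", "M")
    off <- stats::setNames(ndof + (seq_along(flds) - 1L) * (m + 1L), flds)
    ndof <- ndof + length(flds) * (m + 1L)
    pu <- if (is_strip[s]) NULL else phase_par(config$regions[[s]]$upper)
    pl <- phase_par(config$regions[[s]]$lower)
    seg[[s]] <- list(x = xx, m = m, hh = xx[2] - xx[1], off = off,
                     rs = .region_system(pu, pl, sys))
  }
  gcol <- function(s, f, nodes) seg[[s]]$off[[f]] + nodes

  # difference operators on m+1 nodes with spacing hh (local triplets)
  d1_op <- function(m, hh) {
    i <- c(1, 1, 1, rep(2:m, each = 2), m + 1, m + 1, m + 1)
    j <- c(1, 2, 3, as.vector(rbind(1:(m - 1), 3:(m + 1))), m - 1, m, m + 1)
    v <- c(-1.5, 2, -0.5, rep(c(-0.5, 0.5), m - 1), 0.5, -2, 1.5) / hh
    list(i = i, j = j, v = v)
  }
  d2_op <- function(m, hh) {
    i <- c(rep(1, 4), rep(2:m, each = 3), rep(m + 1, 4))
    j <- c(1:4, as.vector(rbind(1:(m - 1), 2:m, 3:(m + 1))), (m - 2):(m + 1))
    v <- c(c(2, -5, 4, -1), rep(c(1, -2, 1), m - 1), c(-1, 4, -5, 2)) / hh^2
    list(i = i, j = j, v = v)
  }

  trip <- list()
  fvec <- numeric(ndof)
  const0 <- 0
  for (s in seq_len(nseg)) {
    sg <- seg[[s]]
    m <- sg$m; hh <- sg$hh
    rs <- sg$rs
    wt <- rep(hh, m + 1L); wt[c(1, m + 1L)] <- hh / 2
    d1 <- d1_op(m, hh); d2 <- d2_op(m, hh)
    slotmap <- lapply(rs$slots, function(sl) {
      f <- sub("^d2|^d", "", sl)
      p <- if (startsWith(sl, "d2")) 2L else if (startsWith(sl, "d")) 1L else 0L
      list(f = f, p = p)
    })
    Smat <- lapply(slotmap, function(sm) {
      if (sm$p == 0L)
        Matrix::sparseMatrix(i = seq_len(m + 1L), j = gcol(s, sm$f, seq_len(m + 1L)),
                             x = rep(1, m + 1L), dims = c(m + 1L, ndof))
      else if (sm$p == 1L)
        Matrix::sparseMatrix(i = d1$i, j = gcol(s, sm$f, d1$j), x = d1$v,
                             dims = c(m + 1L, ndof))
      else
        Matrix::sparseMatrix(i = d2$i, j = gcol(s, sm$f, d2$j), x = d2$v,
                             dims = c(m + 1L, ndof))
    })
    W <- Matrix::Diagonal(x = wt)
    for (p in seq_along(Smat)) {
      SpW <- Matrix::t(Smat[[p]]) %*% W
      for (q in seq_along(Smat)) {
        if (rs$Q[p, q] == 0) next
        Hpq <- SpW %*% Smat[[q]] * rs$Q[p, q]
        tr <- Matrix::summary(methods::as(Hpq, "TsparseMatrix"))
        trip[[length(trip) + 1L]] <- tr
      }
      if (rs$b[p] != 0) fvec <- fvec + as.numeric(SpW %*% rep(rs$b[p], m + 1L))
    }
    const0 <- const0 + sum(wt) * (rs$c - rs$w_flat)
  }
  allt <- do.call(rbind, trip)
  Hmat <- Matrix::sparseMatrix(i = allt$i, j = allt$j, x = allt$x,
                               dims = c(ndof, ndof))
  Hmat <- (Hmat + Matrix::t(Hmat)) / 2

  # --- constraints ----------------------------------------------------------
  ci <- list(); cj <- list(); cv <- list(); crhs <- numeric(0)
  nrowc <- 0L
  add_con <- function(cols, vals, r) {
    nrowc <<- nrowc + 1L
    k <- length(ci) + 1L
    ci[[k]] <<- rep(nrowc, length(cols)); cj[[k]] <<- cols; cv[[k]] <<- vals
    crhs <<- c(crhs, r)
  }
  uinf_named <- function(s) stats::setNames(seg[[s]]$rs$u_inf, seg[[s]]$rs$slots)

  # left clamp: first two nodes at the flat state of the leftmost region
  uL <- uinf_named(1L)
  for (f in names(seg[[1L]]$off)) {
    for (nd in 1:2) add_con(gcol(1L, f, nd), 1, uL[[f]])
  }
  # right end: directors vanish; surfaces flat with a free common offset
  sN <- nseg; mN <- seg[[sN]]$m + 1L
  uR <- uinf_named(sN)
  for (f in c("n_u", "n_l")) {
    add_con(gcol(sN, f, mN), 1, 0)
    add_con(gcol(sN, f, mN - 1L), 1, 0)
  }
  for (f in c("H_u", "H_l")) {
    add_con(c(gcol(sN, f, mN), gcol(sN, "M", mN)), c(1, -1),
            uR[[f]] - uR[["M"]])
    add_con(c(gcol(sN, f, mN), gcol(sN, f, mN - 1L)), c(1, -1), 0)
  }
  add_con(c(gcol(sN, "M", mN), gcol(sN, "M", mN - 1L)), c(1, -1), 0)

  # interface conditions (same set as the production solver)
  cont <- getOption("memelastic.continuity", c("n", "H"))
  d1_end <- function(s, side, f) {
    m <- seg[[s]]$m; hh <- seg[[s]]$hh
    if (side == "b") list(cols = gcol(s, f, (m - 1L):(m + 1L)),
                          vals = c(0.5, -2, 1.5) / hh)
    else list(cols = gcol(s, f, 1:3), vals = c(-1.5, 2, -0.5) / hh)
  }
  match_q <- function(sL, sR, f, deriv = FALSE) {
    mL <- seg[[sL]]$m + 1L
    if (!deriv) {
      add_con(c(gcol(sL, f, mL), gcol(sR, f, 1L)), c(1, -1), 0)
    } else {
      eL <- d1_end(sL, "b", f); eR <- d1_end(sR, "a", f)
      add_con(c(eL$cols, eR$cols), c(eL$vals, -eR$vals), 0)
    }
  }
  for (k in seq_len(nseg - 1L)) {
    sL <- k; sR <- k + 1L
    qs <- c(if ("n" %in% cont) "n_l", if ("H" %in% cont) "H_l",
            if ("M" %in% cont) "M")
    if (!is_strip[sL] && !is_strip[sR])
      qs <- c(qs, if ("n" %in% cont) "n_u", if ("H" %in% cont) "H_u")
    for (f in qs) match_q(sL, sR, f)
    if ("dn" %in% cont) {
      match_q(sL, sR, "n_l", deriv = TRUE)
      if (!is_strip[sL] && !is_strip[sR]) match_q(sL, sR, "n_u", deriv = TRUE)
    }
  }

  # peptide strips: director jump and rotation tie across each strip
  if (!is.null(config$strips) && nrow(config$strips)) {
    dLp <- params$peptide$delta_L
    for (sp in seq_len(nrow(config$strips))) {
      st <- config$strips[sp, ]
      sL <- which(abs(cuts[-1] - st$x1) < 1e-9)[1]       # segment ending at x1
      sR <- which(abs(cuts[-length(cuts)] - st$x2) < 1e-9)[1]  # starting at x2
      mL <- seg[[sL]]$m + 1L
      add_con(c(gcol(sR, "n_u", 1L), gcol(sL, "n_u", mL)), c(1, -1), st$dn)
      add_con(c(gcol(sR, "H_u", 1L), gcol(sL, "H_u", mL),
                gcol(sL, "n_u", mL), gcol(sR, "n_u", 1L)),
              c(1, -1, -dLp / 2, -dLp / 2), 0)
    }
  }

  A <- Matrix::sparseMatrix(i = unlist(ci), j = unlist(cj), x = unlist(cv),
                            dims = c(nrowc, ndof))
  KKT <- rbind(cbind(Hmat, Matrix::t(A)),
               cbind(A, Matrix::Matrix(0, nrowc, nrowc, sparse = TRUE)))
  sol <- Matrix::solve(KKT, c(-fvec, crhs))
  y <- as.numeric(sol[seq_len(ndof)])

  e_el <- 0.5 * sum(y * as.numeric(Hmat %*% y)) + sum(fvec * y) + const0
  e_mis <- if (isTRUE(config$include_misregistration))
    sys$misregistration_density * config$misreg_width else 0

  xout <- unlist(lapply(seg, `[[`, "x"))
  fieldnames <- c("n_u", "n_l", "H_u", "H_l", "M")
  fout <- do.call(rbind, lapply(seq_len(nseg), function(s) {
    m1 <- seg[[s]]$m + 1L
    sapply(fieldnames, function(f)
      if (f %in% names(seg[[s]]$off)) y[gcol(s, f, seq_len(m1))] else
        rep(NA_real_, m1))
  }))
  list(energy = e_el + e_mis, elastic = e_el, misregistration = e_mis,
       x = xout, fields = fout)
}
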