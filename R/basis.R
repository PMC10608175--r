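# Per-region Euler-Lagrange solution basis.
#
# For a homogeneous region the EL equations of the quadratic density form a
# linear constant-coefficient ODE system; solutions are sums of
# (polynomial) x exp(lambda x) modes, where lambda runs over the roots of
# det A(lambda) and the lambda = 0 block contributes polynomial modes.
# Decaying/growing exponentials are anchored at the region edge where they
# are largest, so every basis function has magnitude <= O(1) on its region.

.sys_cache <- new.env(parent = emptyenv())

.params_key <- function(pu, pl, sys) {
  f <- function(p) {
    if (is.null(p)) return("strip")
    paste(format(unlist(p[c("h", "km", "kt", "kA", "J0", "kc", "kgr", "B", "C",
                            "alpha0")]), digits = 17), collapse = ",")
  }
  paste(f(pu), f(pl), format(sys$sigma, digits = 17), sep = ";")
}

# tiny polynomial helpers (coefficient vectors, increasing degree, complex)
.pmul <- function(a, b) {
  la <- length(a); lb <- length(b)
  r <- rep(0 + 0i, la + lb - 1L)
  for (i in seq_len(la)) {
    idx <- i:(i + lb - 1L)
    r[idx] <- r[idx] + a[i] * b
  }
  r
}
.pval <- function(cf, x) {
  r <- cf[length(cf)]
  if (length(cf) > 1L) for (k in (length(cf) - 1L):1L) r <- r * x + cf[k]
  r
}
.ptrim <- function(cf, tol = 1e-13) {
  m <- max(Mod(cf))
  if (m == 0) return(cf[1L])
  keep <- which(Mod(cf) > tol * m)
  cf[seq_len(max(keep))]
}
# derivative of P(u) e^(lambda u), returned as the polynomial factor
.pderiv_exp <- function(cf, lambda) {
  d <- lambda * cf
  if (length(cf) > 1L)
    d[seq_len(length(cf) - 1L)] <- d[seq_len(length(cf) - 1L)] +
      (seq_len(length(cf) - 1L)) * cf[-1L]
  d
}

# jet polynomials (nslots x deg+1) from field polynomials (nfield x deg+1)
.jetpolys <- function(polymat, lambda, fields, nslots) {
  dcols <- ncol(polymat)
  J <- matrix(0 + 0i, nslots, dcols)
  for (f in seq_along(fields)) {
    cf <- polymat[f, ]
    sl <- fields[[f]]
    J[sl[1L], ] <- cf
    for (p in seq_along(sl)[-1L]) {
      cf <- .pderiv_exp(cf, lambda)
      J[sl[p], ] <- cf
    }
  }
  J
}

.make_mode <- function(kind, terms, fields, nslots) {
  # normalize and attach jet polynomials
  sc <- max(vapply(terms, function(t) max(Mod(t$polymat)), 0))
  terms <- lapply(terms, function(t) {
    t$polymat <- t$polymat / sc
    t$J <- .jetpolys(t$polymat, t$lam, fields, nslots)
    t
  })
  list(kind = kind, terms = terms)
}

# mirror a mode through x -> -x (director projections change sign)
.mirror_mode <- function(mode, fields, nslots, nsign) {
  terms <- lapply(mode$terms, function(t) {
    pm <- t$polymat
    for (m in seq_len(ncol(pm))) pm[, m] <- pm[, m] * (-1)^(m - 1L)
    pm <- pm * nsign
    list(lam = -t$lam, polymat = pm)
  })
  kind <- switch(mode$kind, exp_pos = "exp_neg", exp_neg = "exp_pos", mode$kind)
  .make_mode(kind, terms, fields, nslots)
}

# Build (and cache) the full analytic description of a region type.
.region_system <- function(pu, pl, sys) {
  key <- .params_key(pu, pl, sys)
  if (!is.null(.sys_cache[[key]])) return(.sys_cache[[key]])

  strip <- is.null(pu)
  slots <- if (strip) .slots_strip else .slots_full
  fields <- if (strip) .fields_strip else .fields_full
  nslots <- length(slots)
  nf <- length(fields)
  nsign <- ifelse(grepl("^n", names(fields)), -1, 1)  # parity of each field

  pol <- .polarize(pu, pl, sys$sigma)
  gs <- .ground_state(pol$Q, pol$b, pol$c, strip)
  Afun <- .el_matrix_builder(pol$Q, fields)
  ch <- .char_poly(Afun, nf)

  # --- nonzero roots ------------------------------------------------------
  nzcoefs <- ch$coefs[(ch$m0 + 1L):(ch$deg + 1L)]
  roots <- polyroot(nzcoefs)
  retol <- 1e-6
  if (any(abs(Re(roots)) < retol * (1 + Mod(roots))))
    stop("characteristic root with vanishing real part: non-decaying mode")
  pos <- roots[Re(roots) > 0]
  if (2L * length(pos) != length(roots))
    stop("characteristic roots are not sign-symmetric")

  # cluster positive roots
  ord <- order(Re(pos), Im(pos))
  pos <- pos[ord]
  clusters <- list()
  used <- rep(FALSE, length(pos))
  for (i in seq_along(pos)) {
    if (used[i]) next
    grp <- which(!used & Mod(pos - pos[i]) < 1e-5 * (1 + Mod(pos[i])))
    used[grp] <- TRUE
    clusters[[length(clusters) + 1L]] <- pos[grp]
  }

  has_chains <- FALSE
  imtol <- 1e-7
  # pair complex clusters with their conjugates; keep Im >= 0 representatives
  reps <- list()
  taken <- rep(FALSE, length(clusters))
  for (i in seq_along(clusters)) {
    if (taken[i]) next
    lam <- mean(clusters[[i]])
    if (abs(Im(lam)) < imtol * (1 + Mod(lam))) {
      reps[[length(reps) + 1L]] <- list(lam = complex(real = Re(lam)),
                                        mult = length(clusters[[i]]),
                                        type = "real")
      taken[i] <- TRUE
    } else {
      j <- which(!taken & vapply(clusters, function(cl)
        Mod(mean(cl) - Conj(lam)) < 1e-5 * (1 + Mod(lam)), NA))
      j <- setdiff(j, i)
      if (!length(j))
        stop("complex characteristic root without conjugate partner")
      j <- j[1L]
      taken[c(i, j)] <- TRUE
      if (Im(lam) < 0) lam <- Conj(lam)
      reps[[length(reps) + 1L]] <- list(lam = lam,
                                        mult = length(clusters[[i]]),
                                        type = "complex")
    }
  }

  # eigen/Jordan vectors for one root
  root_vectors <- function(lam, mult) {
    A <- Afun(lam)
    sv <- svd(A)
    nullity <- sum(sv$d < 1e-8 * max(sv$d))
    if (nullity < 1L) stop("no nullspace at characteristic root")
    V <- sv$v[, nf - seq_len(nullity) + 1L, drop = FALSE]
    out <- lapply(seq_len(nullity), function(k) {
      v <- V[, k]
      matrix(v, ncol = 1L)  # polymat column: degree 0
    })
    if (nullity < mult) {
      # first-order Jordan chains: A(l) w = -A'(l) v
      hstep <- 1e-6 * (1 + Mod(lam))
      dA <- (Afun(lam + hstep) - Afun(lam - hstep)) / (2 * hstep)
      qa <- qr(A, LAPACK = TRUE)
      for (k in seq_len(mult - nullity)) {
        v <- V[, ((k - 1L) %% nullity) + 1L]
        rhs <- -dA %*% v
        w <- qr.coef(qa, rhs)
        w[is.na(w)] <- 0
        if (max(Mod(A %*% w - rhs)) > 1e-6 * max(Mod(rhs), 1))
          stop("Jordan chain inconsistent at repeated characteristic root")
        out[[length(out) + 1L]] <- cbind(w, v)
      }
      has_chains <<- TRUE
    }
    out
  }

  modes_pos <- list()
  roots_pos <- complex(0)
  for (rp in reps) {
    roots_pos <- c(roots_pos, rep(rp$lam, rp$mult),
                   if (rp$type == "complex") rep(Conj(rp$lam), rp$mult))
    vecs <- root_vectors(rp$lam, rp$mult)
    for (pm in vecs) {
      if (rp$type == "real") {
        # canonicalize to a real vector
        v <- pm[, ncol(pm)]
        piv <- which.max(Mod(v))
        pm <- pm / v[piv]
        pmr <- matrix(complex(real = Re(pm)), nrow = nf)
        modes_pos[[length(modes_pos) + 1L]] <-
          .make_mode("exp_pos", list(list(lam = rp$lam, polymat = pmr)),
                     fields, nslots)
      } else {
        lam <- rp$lam
        modes_pos[[length(modes_pos) + 1L]] <- .make_mode("exp_pos", list(
          list(lam = lam, polymat = 0.5 * pm),
          list(lam = Conj(lam), polymat = 0.5 * Conj(pm))), fields, nslots)
        modes_pos[[length(modes_pos) + 1L]] <- .make_mode("exp_pos", list(
          list(lam = lam, polymat = -0.5i * pm),
          list(lam = Conj(lam), polymat = 0.5i * Conj(pm))), fields, nslots)
      }
    }
  }
  n_expect <- (ch$deg - ch$m0) %/% 2L
  if (length(modes_pos) != n_expect)
    stop(sprintf("constructed %d growing modes, expected %d",
                 length(modes_pos), n_expect))

  modes_neg <- lapply(modes_pos, .mirror_mode, fields = fields,
                      nslots = nslots, nsign = nsign)

  # --- polynomial (lambda = 0) modes --------------------------------------
  modes_poly <- list()
  if (ch$m0 > 0L) {
    psol <- .polynomial_solutions(pol$Q, fields, expected = ch$m0)
    for (k in seq_len(ncol(psol$V))) {
      pm <- matrix(psol$V[, k], nrow = psol$dmax + 1L)  # degrees x fields
      pm <- t(pm)
      keep <- which(colSums(abs(pm)) > 1e-10 * max(abs(pm)))
      pm <- pm[, seq_len(if (length(keep)) max(keep) else 1L), drop = FALSE]
      pmc <- matrix(complex(real = pm), nrow = nf)
      modes_poly[[length(modes_poly) + 1L]] <-
        .make_mode("poly", list(list(lam = 0 + 0i, polymat = pmc)),
                   fields, nslots)
    }
  }

  # uniform vertical shift (exact zero-energy mode), used in outer regions
  shiftvec <- matrix(0 + 0i, nf, 1L)
  shiftvec[grep("^H|^M", names(fields)), 1L] <- 1 + 0i
  mode_shift <- .make_mode("shift", list(list(lam = 0 + 0i, polymat = shiftvec)),
                           fields, nslots)

  rs <- new.env(parent = emptyenv())
  rs$strip <- strip; rs$slots <- slots; rs$fields <- fields
  rs$nslots <- nslots; rs$nf <- nf
  rs$Q <- pol$Q; rs$b <- pol$b; rs$c <- pol$c
  rs$u_inf <- gs$u_inf; rs$w_flat <- gs$w_flat; rs$g <- gs$g
  rs$g_zero <- max(abs(gs$g)) < 1e-12
  rs$Afun <- Afun; rs$char <- ch
  rs$modes_pos <- modes_pos; rs$modes_neg <- modes_neg
  rs$roots_pos <- roots_pos
  rs$modes_poly <- modes_poly; rs$mode_shift <- mode_shift
  rs$has_chains <- has_chains
  rs$pstruct <- list()
  .sys_cache[[key]] <- rs
  rs
}

# basis-mode list for a region role
.role_modes <- function(rs, role) {
  switch(role,
    finite   = c(rs$modes_neg, rs$modes_pos, rs$modes_poly),
    rightinf = c(rs$modes_neg, list(rs$mode_shift)),
    leftinf  = rs$modes_pos,
    rigid    = list(rs$mode_shift),  # flat strip with a free vertical offset
    stop("unknown region role"))
}

# anchor of a mode within its region: "a" (left edge) or "b" (right edge)
.mode_anchor <- function(kind, role) {
  if (role == "leftinf") return("b")
  if (kind == "exp_pos") "b" else "a"
}

#' Characteristic decay rates of a homogeneous membrane region
#'
#' Roots of the characteristic polynomial of the Euler-Lagrange system for a
#' homogeneous region. Deformations decay away from a perturbation as
#' exp(-|Re(lambda)| x); the smallest magnitude sets the lateral decay length
#' of membrane deformations (about 1 nm for typical parameters).
#'
#' @param upper `phase_params` of the upper monolayer (or `NULL` for a
#'   peptide strip region).
#' @param lower `phase_params` of the lower monolayer.
#' @param sys `system_constants`.
#' @return complex vector of all characteristic roots, zero roots included
#'   with their multiplicity.
#' @examples
#' p <- default_parameter_set()
#' characteristic_roots(p$disordered, p$disordered, p$system)
#' @export
characteristic_roots <- function(upper, lower, sys) {
  rs <- .region_system(upper, lower, sys)
  c(rs$roots_pos, -rs$roots_pos, rep(0 + 0i, rs$char$m0))
}
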