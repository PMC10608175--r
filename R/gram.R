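# Closed-form energy integrals of basis-mode pairs over a region.
#
# Every basis function is a sum of terms P(u) exp(lambda u) with u measured
# from the region edge where the term is largest, so all integrands are O(1).
# The energy cross integral of two terms is a polynomial-times-exponential
# integral, evaluated by stable closed forms. For the (generic) case where
# all exponential modes are pure exponentials, the polynomial coefficient
# vectors of all pair products are width-independent and are precomputed once
# per region type; only scalar exponential integrals remain per solve.

# integral of t^k exp(mu t) over [0, T], vectorized over mu; returns
# length(mu) x (K+1) complex matrix
.IkT <- function(mu, T, K) {
  n <- length(mu)
  z <- mu * T
  small <- Mod(z) < 1e-3
  I <- matrix(0 + 0i, n, K + 1L)
  e <- exp(z)
  js <- 0:8
  for (k in 0:K) {
    ser <- rep(0 + 0i, n)
    for (j in js) ser <- ser + z^j / (factorial(j) * (k + j + 1))
    ser <- T^(k + 1) * ser
    rec <- if (k == 0L) (e - 1) / mu else (T^k * e - k * I[, k]) / mu
    I[, k + 1L] <- ifelse(small, ser, rec)
  }
  I
}

# integral of t^k exp(mu t) over [0, Inf), Re(mu) < 0
.IkInf <- function(mu, K) {
  n <- length(mu)
  I <- matrix(0 + 0i, n, K + 1L)
  for (k in 0:K) I[, k + 1L] <- factorial(k) / (-mu)^(k + 1L)
  I
}

# coefficients of P(t + s) given coefficients of P(u)
.pshift <- function(cf, s) {
  d <- length(cf) - 1L
  if (d == 0L) return(cf)
  q <- rep(0 + 0i, d + 1L)
  for (m in 0:d) for (k in 0:m) {
    q[k + 1L] <- q[k + 1L] + cf[m + 1L] * choose(m, k) * s^(m - k)
  }
  q
}
.pshift_mat <- function(J, s) {
  if (ncol(J) == 1L) return(J)
  t(apply(J, 1L, .pshift, s = s))
}

# generic single pair integral (used for Jordan chains and as an
# independent slow path in consistency checks)
.pair_entry_generic <- function(lam1, J1, anch1, lam2, J2, anch2, Q, T, ztol) {
  if (is.infinite(T)) {
    mu <- lam1 + lam2
    QJ2 <- Q %*% J2
    K1 <- ncol(J1); K2 <- ncol(J2)
    r <- rep(0 + 0i, K1 + K2 - 1L)
    for (p in seq_len(nrow(Q))) r <- r + .pmul(J1[p, ], QJ2[p, ])
    if (Re(mu) < -1e-12) {
      return(sum(r * .IkInf(mu, length(r) - 1L)[1L, ]))
    }
    if (max(Mod(r)) < ztol) return(0 + 0i)
    stop("non-integrable mode pair on a semi-infinite region")
  }
  J1s <- if (anch1 == "b") .pshift_mat(J1, -T) else J1
  J2s <- if (anch2 == "b") .pshift_mat(J2, -T) else J2
  QJ2 <- Q %*% J2s
  r <- rep(0 + 0i, ncol(J1s) + ncol(J2s) - 1L)
  for (p in seq_len(nrow(Q))) r <- r + .pmul(J1s[p, ], QJ2[p, ])
  mu <- lam1 + lam2
  cpe <- -(lam1 * (anch1 == "b") + lam2 * (anch2 == "b"))
  K <- length(r) - 1L
  if (Re(mu) * T <= 500) {
    sum(exp(cpe * T) * r * .IkT(mu, T, K)[1L, ])
  } else {
    # integrate from the right edge to avoid overflow: r(T - s)
    rt <- rep(0 + 0i, K + 1L)
    for (k in 0:K) for (j in 0:k) {
      rt[j + 1L] <- rt[j + 1L] + r[k + 1L] * choose(k, j) * T^(k - j) * (-1)^j
    }
    sum(exp((cpe + mu) * T) * rt * .IkT(-mu, T, K)[1L, ])
  }
}

# width-independent pair structure for a region type and role
.pair_structure <- function(rs, role) {
  cached <- rs$pstruct[[role]]
  if (!is.null(cached)) return(cached)
  modes <- .role_modes(rs, role)
  nm <- length(modes)
  Q <- rs$Q
  ztol <- 1e-8 * max(abs(Q))
  # transformed term lists
  tinfo <- vector("list", nm)
  for (i in seq_len(nm)) {
    anch <- .mode_anchor(modes[[i]]$kind, role)
    terms <- modes[[i]]$terms
    if (role == "leftinf") {
      # rewrite in the mirrored coordinate s = b - x (pure exponentials only)
      terms <- lapply(terms, function(t) {
        tt <- t
        if (ncol(t$J) > 1L) {
          for (m in seq_len(ncol(t$J)))
            tt$J[, m] <- t$J[, m] * (-1)^(m - 1L)
        }
        tt$lam <- -t$lam
        tt
      })
      anch <- "a"
    }
    if (role == "rightinf") anch <- "a"
    tinfo[[i]] <- list(terms = terms, anch = anch,
                       generic = rs$has_chains && role == "finite" &&
                         anch == "b" &&
                         any(vapply(terms, function(t) ncol(t$J) > 1L, NA)))
  }
  Kmax <- 0L
  mu <- complex(0); cpe <- complex(0); pid <- integer(0)
  rlist <- list()
  gen_pairs <- list()
  for (i in seq_len(nm)) for (j in i:nm) {
    ti <- tinfo[[i]]; tj <- tinfo[[j]]
    if (ti$generic || tj$generic) {
      gen_pairs[[length(gen_pairs) + 1L]] <- c(i, j)
      next
    }
    for (s in ti$terms) for (t in tj$terms) {
      QJt <- Q %*% t$J
      r <- rep(0 + 0i, ncol(s$J) + ncol(t$J) - 1L)
      for (p in seq_len(nrow(Q))) r <- r + .pmul(s$J[p, ], QJt[p, ])
      mu <- c(mu, s$lam + t$lam)
      cpe <- c(cpe, -(s$lam * (ti$anch == "b") + t$lam * (tj$anch == "b")))
      pid <- c(pid, (j - 1L) * nm + i)
      rlist[[length(rlist) + 1L]] <- r
      Kmax <- max(Kmax, length(r) - 1L)
    }
  }
  rmat <- matrix(0 + 0i, length(rlist), Kmax + 1L)
  for (k in seq_along(rlist)) rmat[k, seq_along(rlist[[k]])] <- rlist[[k]]
  ps <- list(nm = nm, mu = mu, cpe = cpe, pid = pid, rmat = rmat,
             Kmax = Kmax, tinfo = tinfo, gen_pairs = gen_pairs, ztol = ztol,
             role = role)
  if (role != "finite") {
    # width-independent: evaluate once
    ok <- Re(ps$mu) < -1e-12
    vals <- rep(0 + 0i, length(ps$mu))
    if (any(ok)) {
      Ik <- .IkInf(ps$mu[ok], Kmax)
      vals[ok] <- rowSums(ps$rmat[ok, , drop = FALSE] * Ik)
    }
    if (any(!ok)) {
      bad <- !ok & apply(ps$rmat, 1L, function(r) max(Mod(r))) >= ztol
      if (any(bad))
        stop("non-integrable mode pair on a semi-infinite region")
    }
    G <- matrix(0, nm, nm)
    agg <- rowsum(Re(vals), ps$pid)
    idx <- as.integer(rownames(agg))
    G[idx] <- agg[, 1L]
    G <- G + t(G) - diag(diag(G), nm)
    ps$G <- G
  }
  rs$pstruct[[role]] <- ps
  ps
}

# Gram matrix of a region instance
.region_gram <- function(rs, role, T) {
  ps <- .pair_structure(rs, role)
  if (role != "finite") return(ps$G)
  big <- Re(ps$mu) * T > 500
  mu_eval <- ps$mu
  mu_eval[big] <- -1  # placeholder; recomputed below
  Ik <- .IkT(mu_eval, T, ps$Kmax)
  vals <- exp(ps$cpe * T) * rowSums(ps$rmat * Ik)
  if (any(big)) {
    for (k in which(big)) {
      r <- ps$rmat[k, ]
      K <- ps$Kmax
      rt <- rep(0 + 0i, K + 1L)
      for (m in 0:K) for (j in 0:m) {
        rt[j + 1L] <- rt[j + 1L] + r[m + 1L] * choose(m, j) * T^(m - j) * (-1)^j
      }
      vals[k] <- sum(exp((ps$cpe[k] + ps$mu[k]) * T) * rt *
                       .IkT(-ps$mu[k], T, K)[1L, ])
    }
  }
  nm <- ps$nm
  G <- matrix(0, nm, nm)
  agg <- rowsum(Re(vals), ps$pid)
  idx <- as.integer(rownames(agg))
  G[idx] <- agg[, 1L]
  # generic pairs (Jordan chains)
  if (length(ps$gen_pairs)) {
    Q <- rs$Q
    for (pr in ps$gen_pairs) {
      i <- pr[1L]; j <- pr[2L]
      ti <- ps$tinfo[[i]]; tj <- ps$tinfo[[j]]
      v <- 0 + 0i
      for (s in ti$terms) for (t in tj$terms) {
        v <- v + .pair_entry_generic(s$lam, s$J, ti$anch, t$lam, t$J, tj$anch,
                                     Q, T, ps$ztol)
      }
      G[(j - 1L) * nm + i] <- Re(v)
    }
  }
  G + t(G) - diag(diag(G), nm)
}

# linear energy term (nonzero only when the region's flat-state gradient g
# has nonzero derivative components, e.g. nonzero spontaneous curvature)
.region_linvec <- function(rs, role, T) {
  ps <- .pair_structure(rs, role)
  modes <- .role_modes(rs, role)
  nm <- length(modes)
  if (rs$g_zero) return(numeric(nm))
  g <- rs$g
  out <- numeric(nm)
  for (i in seq_len(nm)) {
    ti <- ps$tinfo[[i]]
    v <- 0 + 0i
    for (s in ti$terms) {
      Js <- if (ti$anch == "b" && !is.infinite(T)) .pshift_mat(s$J, -T) else s$J
      r <- rep(0 + 0i, ncol(Js))
      for (p in seq_along(g)) if (g[p] != 0) r <- r + g[p] * Js[p, ]
      if (is.infinite(T)) {
        if (Re(s$lam) < -1e-12) {
          v <- v + sum(r * .IkInf(s$lam, length(r) - 1L)[1L, ])
        } else if (max(Mod(r)) >= ps$ztol) {
          stop("non-integrable linear term on a semi-infinite region")
        }
      } else {
        cpe <- -s$lam * (ti$anch == "b")
        v <- v + sum(exp(cpe * T) * r * .IkT(s$lam, T, length(r) - 1L)[1L, ])
      }
    }
    out[i] <- Re(v)
  }
  out
}

# basis jet values at a region edge ("a" = left, "b" = right);
# rows = modes, columns = jet slots
.edge_values <- function(rs, role, T, edge) {
  modes <- .role_modes(rs, role)
  nm <- length(modes)
  V <- matrix(0, nm, rs$nslots)
  for (i in seq_len(nm)) {
    anch <- .mode_anchor(modes[[i]]$kind, role)
    u <- if (role == "finite") {
      if (edge == anch) 0 else if (edge == "b") T else -T
    } else 0  # semi-infinite regions are only evaluated at their finite edge
    for (t in modes[[i]]$terms) {
      ex <- exp(t$lam * u)
      if (ncol(t$J) == 1L) {
        V[i, ] <- V[i, ] + Re(ex * t$J[, 1L])
      } else {
        for (p in seq_len(rs$nslots))
          V[i, p] <- V[i, p] + Re(ex * .pval(t$J[p, ], u))
      }
    }
  }
  colnames(V) <- rs$slots
  V
}

# field values (not jets) of the deviation at local coordinates
# (relative to the region's left edge for finite/rightinf, right edge for
# leftinf regions)
.eval_fields <- function(rs, role, T, C, tloc) {
  modes <- .role_modes(rs, role)
  out <- matrix(0, length(tloc), rs$nf)
  colnames(out) <- names(rs$fields)
  for (i in seq_along(modes)) {
    if (C[i] == 0) next
    anch <- .mode_anchor(modes[[i]]$kind, role)
    u <- if (role == "finite" && anch == "b") tloc - T else tloc
    for (t in modes[[i]]$terms) {
      ex <- exp(t$lam * u)
      for (f in seq_len(rs$nf)) {
        out[, f] <- out[, f] + C[i] * Re(ex * .pval(t$J[rs$fields[[f]][1L], ], u))
      }
    }
  }
  out
}
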