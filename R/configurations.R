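# Scenario builders: piecewise phase assignment of both monolayers plus
# peptide strips, assembled into the boundary-value problem statement.

# --- interval-set helpers (2-column matrices [a, b], possibly infinite) ----
.iv_norm <- function(m) {
  if (is.null(m) || !length(m)) return(matrix(numeric(0), 0, 2))
  m <- matrix(as.numeric(m), ncol = 2)
  m <- m[m[, 2] > m[, 1], , drop = FALSE]
  if (!nrow(m)) return(matrix(numeric(0), 0, 2))
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    k <- nrow(out)
    if (m[i, 1] <= out[k, 2] + 1e-12) {
      out[k, 2] <- max(out[k, 2], m[i, 2])
    } else out <- rbind(out, m[i, ])
  }
  out
}
.iv_member <- function(m, x) {
  if (!nrow(m)) return(rep(FALSE, length(x)))
  vapply(x, function(xx) any(m[, 1] <= xx & xx < m[, 2]), NA)
}
.iv_overlap_len <- function(m, a, b) {
  if (!nrow(m)) return(0)
  sum(pmax(0, pmin(m[, 2], b) - pmax(m[, 1], a)))
}

#' Director jump imposed by a rigid amphipathic helix
#'
#' Geometric estimate of the discontinuity of the director x-projection
#' across the strip occupied by an adsorbed amphipathic peptide:
#' \eqn{\Delta n_x = \Delta L / \sqrt{(\Delta L/2)^2 + (h/2)^2}}, assuming
#' the boundary directors point towards the center of the hydrophobic region
#' beneath the helix.
#'
#' @param delta_L helix diameter, nm.
#' @param h hydrophobic thickness of the monolayer hosting the peptide, nm.
#' @return dimensionless jump of the director x-projection.
#' @examples
#' director_jump(1.3, 1.3)  # sqrt(2)
#' @export
director_jump <- function(delta_L, h) {
  stopifnot(delta_L >= 0, h > 0)
  if (delta_L == 0) return(0)
  delta_L / sqrt((delta_L / 2)^2 + (h / 2)^2)
}

#' Director jump of a peptide straddling the phase boundary
#'
#' Convex combination of the pure-phase jumps weighted by the fraction
#' `delta` of the peptide located in the liquid-disordered phase.
#'
#' @param delta fraction of the strip in the disordered phase, in `[0, 1]`.
#' @param jump_s director jump in the disordered (surrounding) phase.
#' @param jump_d director jump in the ordered (domain) phase.
#' @return interpolated director jump.
#' @export
mixed_director_jump <- function(delta, jump_s, jump_d) {
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) ||
      delta < 0 || delta > 1)
    stop("parameter validation: 'delta' must be in [0, 1]", call. = FALSE)
  delta * jump_s + (1 - delta) * jump_d
}

#' Assemble a membrane configuration
#'
#' Low-level constructor: given the liquid-ordered set of each monolayer and
#' the peptide strips on the upper leaflet, builds the region decomposition,
#' computes each strip's disordered fraction `delta` geometrically from its
#' overlap with the upper-monolayer Ld set, and tallies the misregistered
#' width (regions where two lipid monolayers of different phase face each
#' other; strips are not charged).
#'
#' @param upper_lo,lower_lo two-column matrices of intervals (nm, may be
#'   infinite) occupied by the ordered phase in each monolayer.
#' @param peptide_X numeric vector of peptide right-edge coordinates X (nm);
#'   each peptide occupies `[X - delta_L, X]` on the upper leaflet.
#' @param params `parameter_set`.
#' @param include_misregistration include the misregistration penalty in the
#'   reported total energy.
#' @return object of class `membrane_config`.
#' @export
membrane_configuration <- function(upper_lo, lower_lo, peptide_X = numeric(0),
                                   params = default_parameter_set(),
                                   include_misregistration = TRUE,
                                   rigid_lower_under_peptide = FALSE) {
  upper_lo <- .iv_norm(upper_lo)
  lower_lo <- .iv_norm(lower_lo)
  dL <- params$peptide$delta_L

  strips <- NULL
  if (length(peptide_X)) {
    peptide_X <- sort(peptide_X)
    x1 <- peptide_X - dL
    x2 <- peptide_X
    if (any(x1[-1] < x2[-length(x2)] + 1e-3))
      stop("configuration error: overlapping or touching peptide strips",
           call. = FALSE)
    jump_s <- director_jump(dL, params$disordered$h)
    jump_d <- director_jump(dL, params$ordered$h)
    delta <- vapply(seq_along(x1), function(i)
      1 - .iv_overlap_len(upper_lo, x1[i], x2[i]) / dL, 0)
    delta <- pmin(1, pmax(0, delta))
    dn <- vapply(delta, mixed_director_jump, 0, jump_s = jump_s,
                 jump_d = jump_d)
    strips <- data.frame(x1 = x1, x2 = x2, X0 = (x1 + x2) / 2,
                         delta = delta, dn = dn)
  }

  edges <- c(upper_lo[is.finite(upper_lo)], lower_lo[is.finite(lower_lo)])
  if (!is.null(strips)) edges <- c(edges, strips$x1, strips$x2)
  edges <- sort(unique(edges))
  # merge nearly coincident breakpoints: a sliver region much narrower than
  # any deformation length carries negligible energy but makes the stiff
  # exponential modes of the two edges numerically collinear
  if (length(edges) > 1)
    edges <- edges[c(TRUE, diff(edges) > 1e-3)]
  # strip edges must survive deduplication exactly
  if (!is.null(strips)) {
    for (v in c(strips$x1, strips$x2))
      edges[which.min(abs(edges - v))] <- v
    edges <- sort(unique(edges))
  }

  mid <- if (length(edges)) {
    c(edges[1] - 1, (edges[-length(edges)] + edges[-1]) / 2,
      edges[length(edges)] + 1)
  } else 0
  in_strip <- function(x) {
    if (is.null(strips)) return(rep(FALSE, length(x)))
    vapply(x, function(xx) any(strips$x1 < xx & xx < strips$x2), NA)
  }
  up <- ifelse(in_strip(mid), NA,
               ifelse(.iv_member(upper_lo, mid), "ordered", "disordered"))
  lo <- ifelse(.iv_member(lower_lo, mid), "ordered", "disordered")

  if (is.na(up[1]) || is.na(up[length(up)]))
    stop("configuration error: peptide strip extends to infinity", call. = FALSE)
  if (up[1] != lo[1] || up[length(up)] != lo[length(lo)])
    stop("configuration error: monolayer phases mismatch at infinity ",
         "(infinite misregistration)", call. = FALSE)

  regions <- lapply(seq_along(mid), function(i)
    list(upper = up[i], lower = lo[i]))

  widths <- if (length(edges) > 1) diff(edges) else numeric(0)
  inner <- seq_along(mid)[-c(1, length(mid))]
  mis_w <- 0
  if (length(inner))
    mis_w <- sum(widths[!is.na(up[inner]) & up[inner] != lo[inner]])

  cfg <- list(breaks = edges, regions = regions, strips = strips,
              params = params, misreg_width = mis_w,
              include_misregistration = include_misregistration,
              rigid_lower_under_peptide = rigid_lower_under_peptide,
              upper_lo = upper_lo, lower_lo = lower_lo)
  class(cfg) <- "membrane_config"
  cfg
}

#' @export
print.membrane_config <- function(x, ...) {
  cat("<membrane_config>\n")
  cat(sprintf("  %d regions, breakpoints: %s\n", length(x$regions),
              paste(signif(x$breaks, 4), collapse = ", ")))
  if (!is.null(x$strips))
    cat(sprintf("  peptides at X = %s (delta = %s)\n",
                paste(signif(x$strips$x2, 4), collapse = ", "),
                paste(signif(x$strips$delta, 3), collapse = ", ")))
  cat(sprintf("  misregistered width: %.4g nm\n", x$misreg_width))
  invisible(x)
}

#' Single Lo/Ld domain boundary with monolayer shift
#'
#' The ordered phase occupies the left half-line: the lower-monolayer edge is
#' at x = 0 and the upper-monolayer edge at x = L, so L > 0 means the upper
#' ordered monolayer extends farther toward +x. An optional adsorbed peptide
#' is placed on the upper leaflet with its right edge at `peptide_X`.
#'
#' @param L relative monolayer shift, nm.
#' @param params `parameter_set`.
#' @param peptide_X optional peptide right-edge coordinate, nm.
#' @param include_misregistration include the `0.016 |L|` penalty.
#' @return `membrane_config`.
#' @export
single_boundary <- function(L, params = default_parameter_set(),
                            peptide_X = NULL,
                            include_misregistration = TRUE, ...) {
  membrane_configuration(
    upper_lo = matrix(c(-Inf, L), 1),
    lower_lo = matrix(c(-Inf, 0), 1),
    peptide_X = if (is.null(peptide_X)) numeric(0) else peptide_X,
    params = params,
    include_misregistration = include_misregistration, ...
  )
}

#' Isolated peptide in a homogeneous membrane
#'
#' @param phase `"disordered"` (default) or `"ordered"` homogeneous bilayer.
#' @param peptide_X peptide right-edge coordinate, nm.
#' @inheritParams single_boundary
#' @return `membrane_config`.
#' @export
peptide_in_phase <- function(phase = c("disordered", "ordered"),
                             params = default_parameter_set(),
                             peptide_X = 0, ...) {
  phase <- match.arg(phase)
  lo <- if (phase == "ordered") matrix(c(-Inf, Inf), 1) else
    matrix(numeric(0), 0, 2)
  membrane_configuration(upper_lo = lo, lower_lo = lo, peptide_X = peptide_X,
                         params = params, ...)
}

#' Two liquid-ordered domains separated by a disordered gap
#'
#' The domains' facing edges sit at x = 0 and x = D, where D is the
#' edge-to-edge distance between the nearest (protruding) monolayer edges of
#' the two domains, whichever leaflet protrudes. Each domain carries its own
#' monolayer shift: a positive shift means the domain is larger in the upper
#' leaflet (the facing edge at 0 or D belongs to the upper monolayer and the
#' lower-monolayer edge recedes from the gap by |L|); a negative shift means
#' the domain is larger in the lower leaflet (the facing edge belongs to the
#' lower monolayer and the upper edge recedes). With this convention the
#' z-mirror symmetry of the energy makes the no-peptide interaction profile
#' independent of the shift-sign combination, as it must be. Optional
#' peptides sit on the upper leaflet near the facing boundaries.
#'
#' @param D edge-to-edge distance between the facing domain edges, nm.
#' @param L_left,L_right monolayer shifts of the two domains, nm (positive =
#'   domain larger in the upper leaflet).
#' @param peptide_X numeric vector (length 0, 1 or 2) of peptide right-edge
#'   coordinates, nm.
#' @inheritParams single_boundary
#' @return `membrane_config`.
#' @export
domain_pair <- function(D, L_left = 0, L_right = 0,
                        params = default_parameter_set(),
                        peptide_X = numeric(0),
                        include_misregistration = TRUE, ...) {
  if (D < 0) stop("D must be >= 0")
  membrane_configuration(
    upper_lo = rbind(c(-Inf, if (L_left >= 0) 0 else L_left),
                     c(if (L_right >= 0) D else D - L_right, Inf)),
    lower_lo = rbind(c(-Inf, if (L_left >= 0) -L_left else 0),
                     c(if (L_right >= 0) D + L_right else D, Inf)),
    peptide_X = peptide_X,
    params = params,
    include_misregistration = include_misregistration, ...
  )
}

#' Non-equivalent boundary topologies of a domain pair
#'
#' Enumerates the sign combinations of the two monolayer shifts that give
#' energetically distinct configurations for a given peptide occupancy.
#' `"upper"` marks a domain larger in the upper leaflet. With one peptide
#' (placed at the right domain's facing boundary) all four combinations are
#' distinct; with two peptides, mirror-image combinations coincide and three
#' remain; with no peptides all four are energy-equivalent (and are still
#' listed).
#'
#' @param peptide_count 0, 1 or 2 peptides at the facing boundaries.
#' @return data frame with columns `left`, `right` (`"upper"`/`"lower"`),
#'   `peptides` and `label`.
#' @export
boundary_topologies <- function(peptide_count = 0) {
  stopifnot(peptide_count %in% 0:2)
  combos <- expand.grid(left = c("upper", "lower"),
                        right = c("upper", "lower"),
                        stringsAsFactors = FALSE)
  if (peptide_count == 2) {
    # reflection maps (left, right) -> (right, left): drop one mixed combo
    combos <- combos[!(combos$left == "lower" & combos$right == "upper"), ]
  }
  combos$peptides <- peptide_count
  combos$label <- paste0(substr(toupper(combos$left), 1, 1),
                         substr(toupper(combos$right), 1, 1),
                         "-", peptide_count, "p")
  rownames(combos) <- NULL
  combos
}
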