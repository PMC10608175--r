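# Configuration loading and result serialization.
#
# Config files are flat YAML key-value mappings with explicit unit suffixes
# (the mixing of mN/m and kBT/nm^2 in the literature makes silent unit errors
# the main failure mode). Unknown keys are rejected; omitted keys take the
# package defaults; higher-order moduli omitted from a config are derived
# from kt and h, and user-supplied values inconsistent with their own kt, h
# by more than 5% are kept but flagged with a warning.

.config_keys <- function() {
  phase_keys <- c("h_nm", "km_kBT", "kt_kBT_per_nm2", "kA_kBT_per_nm2",
                  "J0_per_nm", "kc_kBT", "kgr_kBT_nm2", "B_kBT_per_nm",
                  "C_kBT_nm")
  c(paste0("ordered.", phase_keys), paste0("disordered.", phase_keys),
    "system.sigma_mN_per_m", "system.misregistration_kBT_per_nm2",
    "system.temperature_K", "peptide.delta_L_nm", "peptide.Lp_nm")
}

#' Load a parameter configuration file
#'
#' Reads a flat YAML key-value file (keys like `ordered.h_nm`,
#' `system.sigma_mN_per_m`), validates it, fills omitted keys with the
#' package defaults and derives omitted higher-order moduli.
#'
#' @param path path to a YAML file; `NULL` returns the full default set.
#' @return a `parameter_set`.
#' @export
load_config <- function(path = NULL) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    raw <- yaml::read_yaml(path)
    if (length(raw)) {
      flat <- unlist(raw)  # accepts flat dotted keys or nested maps
      unknown <- setdiff(names(flat), .config_keys())
      if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
      vals <- as.list(flat)
    }
  }
  gv <- function(key, default) {
    v <- vals[[key]]
    if (is.null(v)) return(default)
    v <- suppressWarnings(as.numeric(v))
    if (is.na(v)) stop("config key ", key, " is not numeric", call. = FALSE)
    v
  }
  sys <- system_constants(
    sigma_mN_per_m = gv("system.sigma_mN_per_m", 0.1),
    misregistration_density = gv("system.misregistration_kBT_per_nm2", 0.016),
    temperature = gv("system.temperature_K", 300)
  )
  mk_phase <- function(lbl, h0, km0) {
    pre <- paste0(lbl, ".")
    h <- gv(paste0(pre, "h_nm"), h0)
    kt <- gv(paste0(pre, "kt_kBT_per_nm2"), 12)
    kA <- gv(paste0(pre, "kA_kBT_per_nm2"), 30)
    der <- derive_higher_moduli(kt, h)
    higher <- list(kc = NULL, kgr = NULL, B = NULL, C = NULL)
    for (nm_ in names(higher)) {
      key <- paste0(pre, switch(nm_, kc = "kc_kBT", kgr = "kgr_kBT_nm2",
                                B = "B_kBT_per_nm", C = "C_kBT_nm"))
      if (!is.null(vals[[key]])) {
        v <- gv(key, NA)
        if (abs(v - der[[nm_]]) > 0.05 * max(abs(der[[nm_]]), 1e-12))
          warning(sprintf("config key %s = %g differs by >5%% from the value %g derived from kt and h; using the supplied value",
                          key, v, der[[nm_]]), call. = FALSE)
        higher[[nm_]] <- v
      }
    }
    phase_parameters(lbl, h = h, km = gv(paste0(pre, "km_kBT"), km0),
                     kt = kt, kA = kA, J0 = gv(paste0(pre, "J0_per_nm"), 0),
                     kc = higher$kc, kgr = higher$kgr, B = higher$B,
                     C = higher$C,
                     alpha0 = spontaneous_stretching(sys$sigma, kA))
  }
  ps <- list(
    ordered = mk_phase("ordered", 1.8, 20),
    disordered = mk_phase("disordered", 1.3, 10),
    system = sys,
    peptide = peptide_parameters(delta_L = gv("peptide.delta_L_nm", 1.3),
                                 Lp = gv("peptide.Lp_nm", 3.5))
  )
  class(ps) <- "parameter_set"
  ps
}

#' Write an energy profile to a delimited table with a JSON sidecar
#'
#' Writes a tab-separated table (abscissa in nm, energy in kB*T/nm, full
#' precision) and a machine-readable sidecar `<path>.summary.json` holding
#' the abscissa name, reference energy and located extrema.
#'
#' @param profile an `energy_profile`.
#' @param path output path of the table.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "energy_profile"))
  if (!length(profile$grid)) stop("empty profile", call. = FALSE)
  df <- as.data.frame(profile)
  names(df) <- c(paste0(profile$abscissa, "_nm"), "energy_kBT_per_nm")
  dfc <- data.frame(lapply(df, function(col) format(col, digits = 17)))
  names(dfc) <- names(df)
  utils::write.table(dfc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- list(abscissa = profile$abscissa,
               reference_kBT_per_nm = profile$reference,
               n_points = length(profile$grid))
  if (!is.null(profile$extrema)) summ$extrema <- profile$extrema
  keep <- !vapply(profile$details, is.list, NA)
  if (any(keep)) summ$details <- profile$details[keep]
  jsonlite::write_json(summ, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read back a profile written by [write_profile()]
#'
#' @param path path of the table written by [write_profile()].
#' @return an `energy_profile` (extrema restored from the sidecar when
#'   present).
#' @export
read_profile <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  abscissa <- sub("_nm$", "", names(df)[1])
  side <- paste0(path, ".summary.json")
  ref <- 0; ext <- NULL
  if (file.exists(side)) {
    summ <- jsonlite::read_json(side, simplifyVector = TRUE)
    ref <- summ$reference_kBT_per_nm
    if (!is.null(summ$extrema)) ext <- as.data.frame(summ$extrema)
  }
  energy_profile(abscissa, df[[1]], df[[2]], reference = ref, extrema = ext)
}

#' Regenerate the package's headline result set
#'
#' Runs the four scan drivers at the default parameters and writes all
#' profile tables, shape tables and a consolidated JSON summary of the
#' headline numbers (line-tension minima, joint peptide+shift minima,
#' peptide well depth and crossing barrier, and fusion barriers at 0/1/2
#' peptides over all boundary topologies). Deterministic: repeated runs
#' produce identical files.
#'
#' @param out_dir output directory (created if needed).
#' @param params `parameter_set`.
#' @param D_step D-grid step for the fusion scans, nm.
#' @param L_step grid step for the line-tension scan, nm.
#' @return named list of written file paths, invisibly.
#' @export
regenerate_paper_outputs <- function(out_dir = "memelastic-results",
                                     params = default_parameter_set(),
                                     D_step = 0.25, L_step = 0.1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  summary <- list()

  lt <- line_tension_vs_shift(seq(-5, 5, by = L_step), params)
  paths$line_tension <- file.path(out_dir, "line_tension_vs_shift.tsv")
  write_profile(lt, paths$line_tension)
  summary$line_tension_minima <- lt$extrema

  for (L0 in c(2.3, -2.3)) {
    pp <- peptide_domain_profile(L0, params = params)
    nm_ <- sprintf("peptide_profile_L0_%+.1f", L0)
    paths[[nm_]] <- file.path(out_dir, paste0(sub("\\+", "p", sub("-", "m", nm_)),
                                              ".tsv"))
    write_profile(pp, paths[[nm_]])
    summary[[nm_]] <- pp$details[c("well_depth", "well_X", "crossing_barrier",
                                   "barrier_X")]
  }

  jm <- list(positive = joint_minimum_peptide_shift(params, "positive"),
             negative = joint_minimum_peptide_shift(params, "negative"))
  summary$joint_minima <- jm

  Dg <- c(seq(D_step, 8, by = D_step), seq(8.5, 15, by = 0.5),
          seq(16, 40, by = 2), seq(44, 120, by = 4))
  barriers <- list()
  for (npep in 0:2) {
    topos <- boundary_topologies(npep)
    for (i in seq_len(nrow(topos))) {
      tp <- topos[i, ]
      prof <- interaction_profile(tp, params, D_grid = Dg)
      fb <- fusion_barrier(prof)
      key <- tp$label
      paths[[key]] <- file.path(out_dir, paste0("interaction_", key, ".tsv"))
      write_profile(prof, paths[[key]])
      barriers[[key]] <- list(barrier_kBT_per_nm = fb$barrier,
                              D_barrier_nm = fb$D_barrier)
      if (npep == 0) break  # all 0-peptide topologies are energy-equivalent
    }
  }
  summary$fusion_barriers <- barriers

  shp <- membrane_shape(solve_equilibrium(single_boundary(2.3, params)))
  paths$shape <- file.path(out_dir, "shape_single_boundary_L2.3.tsv")
  shpc <- data.frame(lapply(shp, function(col) format(col, digits = 17)))
  utils::write.table(shpc, paths$shape, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(paths)
}
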