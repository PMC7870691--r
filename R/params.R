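#' Default parameter registry
#'
#' Builds the full parameter set of the model: constituent mass fractions,
#' passive Gasser-Ogden-Holzapfel (GOH) material constants, smooth-muscle
#' contractile constants, deposition prestretches, acute damage constants,
#' day-scale remodeling rates, agent/calcium/crossbridge kinetics, reduced
#' vessel geometry and numerical settings. Units are MPa, mm, N, day, s and
#' molar throughout.
#'
#' Every entry carries a provenance code in `attr(, "provenance")`:
#' 1 = exact literature value, 2 = representative literature value,
#' 3 = manually fitted, 4 = fitted within a literature order of magnitude,
#' 5 = estimated.
#'
#' @return A named, nested list of class `vh_params`.
#' @export
#' @examples
#' p <- default_params()
#' p$remodeling$K_ec   # endothelial healing rate, 1/day
default_params <- function() {
  p <- list(
    densities = list(
      rho0_elas = 0.35,  # homeostatic elastin mass fraction (-)
      rho0_coll = 0.30,  # homeostatic collagen mass fraction, both families (-)
      rho0_csmc = 0.30,  # homeostatic contractile SMC fraction (-)
      rho0_ssmc = 0.05   # homeostatic synthetic SMC fraction (-)
    ),
    passive = list(
      C10   = 0.04,      # elastin neo-Hookean stiffness (MPa)
      k1    = 1.0,       # collagen fiber stiffness (MPa)
      k2    = 1.5,       # collagen exponential parameter (-)
      kappa = 0.1,       # fiber dispersion, 0 <= kappa <= 1/3 (-)
      alpha = pi / 8     # fiber angle vs circumferential (rad)
    ),
    smc = list(
      mu_csmc = 0.42,    # active stiffness-like parameter (MPa)
      kappa_c = 1.55     # crossbridge driving-stress scale (MPa)
    ),
    prestretch = list(
      g_ax   = 1.67,     # elastin axial deposition stretch (-)
      g_coll = 1.1       # collagen fiber deposition stretch (-)
    ),
    damage = list(
      m_csmc     = 1.0,  # contractile SMC damage constant (-)
      m_coll_dmg = 20.0, # collagen damage constant (-)
      m_ec       = 0.38  # endothelial death threshold on beta (-)
    ),
    remodeling = list(
      K_qh    = log(2) / 100, # homeostatic collagen decay (1/day)
      K_m     = 26.64,        # mechanical collagen production gain (-)
      K_pl    = 4.0,          # synthetic SMC proliferation rate (1/day)
      K_ec    = 0.08,         # endothelial healing rate (1/day)
      K_dd    = 1.6,          # SMC (de)differentiation rate (1/day)
      K_ic    = 0.01,         # inflammation-driven proliferation (1/day)
      dt_day  = 1.0,          # remodeling time step (day)
      variant = "original"    # original | no_redifferentiation |
                              # mech_independent_production
    ),
    contractility = list(
      k3         = 0.4,     # attachment rate, phosphorylated (1/s)
      k4         = 0.1,     # detachment rate, phosphorylated (1/s)
      k7         = 0.01,    # latch detachment rate (1/s)
      k2_hom     = 0.5,     # homeostatic dephosphorylation rate (1/s)
      alpha2     = 0.1,     # max NO-driven dephosphorylation increase (1/s)
      K_CaCaM    = 1.78e-7, # phosphorylation half-activation (M)
      alpha_Ca   = 0.24,    # CaCaM formation constant (-)
      K_NO       = 8.0e-8,  # NO Hill inflection (M)
      K_PE       = 2.0e-7,  # PE Hill inflection (M)
      Ca_hom     = 2.7e-7,  # homeostatic intracellular calcium (M)
      alpha_NO   = 1.4e-7,  # max calcium removed by NO (M)
      alpha_PE   = 1.28e-7, # max calcium added by PE (M)
      ACh_amp    = 2.8e-7,  # ACh -> NO curve amplitude (M)
      ACh_offset = 8.2,     # ACh -> NO curve offset on log10 scale (-)
      ACh_shape  = 0.9,     # ACh -> NO curve shape constant (-)
      eta        = 60.0,    # filament sliding viscosity (MPa s)
      dt_s       = 0.01     # kinetic transient time step (s)
    ),
    geometry = list(
      inner_diameter = 0.65,  # diastolic inner diameter (mm)
      thickness      = 0.04,  # wall thickness (mm)
      segment_length = 0.04,  # modeled axial length (mm)
      pressure       = 0.01,  # diastolic pressure (MPa = 10 kPa)
      n_theta        = 48,    # circumferential material points (half cylinder)
      n_r            = 3,     # through-thickness material points
      n_theta_lumen  = 4001   # luminal sampling points for endothelium survival
    ),
    myograph = list(
      rod_radius         = 0.15,   # myograph rod radius (mm)
      preload_per_length = 0.0133, # preload force per axial length (N/mm)
      dose_PE            = 1e-6,   # phenylephrine dose (M)
      dose_ACh           = 1e-5,   # acetylcholine dose (M)
      dose_NO            = 1e-6    # applied NO (nitroprusside) dose (M)
    ),
    numerics = list(
      # if TRUE the filament sliding relaxes to its latch steady state in vivo
      # and the resulting basal tone enters the prestress balance; by default
      # SMCs carry no net stress at their deposition state and the latch
      # engages only ex vivo (myograph time scale)
      latch_tone_in_vivo = FALSE,
      g_elas_bracket     = c(0.05, 2.5),  # root bracket for g_elas_circ
      tol_equil          = 1e-12,         # uniroot tolerance, equilibrium solves
      prune_tol          = 1e-8           # cohort pruning threshold on m*q
    )
  )
  prov <- c(
    densities = 2, passive = 2, smc = 4, prestretch = 2, damage = 3,
    remodeling = 3, contractility = 4, geometry = 2, myograph = 2, numerics = 5
  )
  attr(p, "provenance") <- prov
  class(p) <- c("vh_params", "list")
  p
}

# keys that must be present, with positivity constraints ("pos" strictly > 0,
# "nonneg" >= 0, "unit" in [0,1], "free" unchecked)
.vh_param_schema <- function() {
  list(
    densities = c(rho0_elas = "pos", rho0_coll = "pos", rho0_csmc = "pos",
                  rho0_ssmc = "pos"),
    passive = c(C10 = "pos", k1 = "pos", k2 = "pos", kappa = "unit",
                alpha = "nonneg"),
    smc = c(mu_csmc = "pos", kappa_c = "pos"),
    prestretch = c(g_ax = "pos", g_coll = "pos"),
    damage = c(m_csmc = "pos", m_coll_dmg = "pos", m_ec = "pos"),
    remodeling = c(K_qh = "nonneg", K_m = "nonneg", K_pl = "nonneg",
                   K_ec = "nonneg", K_dd = "nonneg", K_ic = "nonneg",
                   dt_day = "pos", variant = "free"),
    contractility = c(k3 = "nonneg", k4 = "nonneg", k7 = "nonneg",
                      k2_hom = "nonneg", alpha2 = "nonneg", K_CaCaM = "pos",
                      alpha_Ca = "pos", K_NO = "pos", K_PE = "pos",
                      Ca_hom = "pos", alpha_NO = "nonneg", alpha_PE = "nonneg",
                      ACh_amp = "pos", ACh_offset = "pos", ACh_shape = "pos",
                      eta = "pos", dt_s = "pos"),
    geometry = c(inner_diameter = "pos", thickness = "pos",
                 segment_length = "pos", pressure = "nonneg", n_theta = "pos",
                 n_r = "pos", n_theta_lumen = "pos"),
    myograph = c(rod_radius = "pos", preload_per_length = "pos",
                 dose_PE = "nonneg", dose_ACh = "nonneg", dose_NO = "nonneg"),
    numerics = c(latch_tone_in_vivo = "free", g_elas_bracket = "free",
                 tol_equil = "pos", prune_tol = "pos")
  )
}

#' Validate a parameter registry
#'
#' Checks completeness (every key used by any module must be present) and
#' sign/range constraints. Errors name the offending key.
#'
#' @param p parameter list as from [default_params()] or [load_params()].
#' @return `p`, invisibly, with class `vh_params`.
#' @export
validate_params <- function(p) {
  schema <- .vh_param_schema()
  for (grp in names(schema)) {
    if (is.null(p[[grp]])) stop("parameter group missing: ", grp, call. = FALSE)
    for (key in names(schema[[grp]])) {
      v <- p[[grp]][[key]]
      if (is.null(v)) {
        stop("parameter missing: ", grp, "$", key, call. = FALSE)
      }
      cons <- schema[[grp]][[key]]
      if (cons %in% c("pos", "nonneg", "unit")) {
        if (!is.numeric(v) || anyNA(v)) {
          stop("parameter not numeric: ", grp, "$", key, call. = FALSE)
        }
        if (cons == "pos" && any(v <= 0)) {
          stop("parameter must be > 0: ", grp, "$", key, call. = FALSE)
        }
        if (cons == "nonneg" && any(v < 0)) {
          stop("parameter must be >= 0: ", grp, "$", key, call. = FALSE)
        }
        if (cons == "unit" && (any(v < 0) || any(v > 1 / 3))) {
          stop("dispersion out of [0, 1/3]: ", grp, "$", key, call. = FALSE)
        }
      }
    }
  }
  variants <- c("original", "no_redifferentiation", "mech_independent_production")
  if (!p$remodeling$variant %in% variants) {
    stop("remodeling$variant must be one of: ",
         paste(variants, collapse = ", "), call. = FALSE)
  }
  class(p) <- c("vh_params", "list")
  invisible(p)
}

#' Load a parameter registry from YAML or JSON
#'
#' @param path path to a YAML (`.yaml`/`.yml`) or JSON file. Entries present in
#'   the file override the defaults of [default_params()]; all keys are
#'   validated after merging.
#' @return validated `vh_params` list.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  p <- default_params()
  for (grp in names(raw)) {
    if (!grp %in% names(p)) stop("unknown parameter group: ", grp, call. = FALSE)
    for (key in names(raw[[grp]])) {
      if (!key %in% names(p[[grp]])) {
        stop("unknown parameter: ", grp, "$", key, call. = FALSE)
      }
      p[[grp]][[key]] <- raw[[grp]][[key]]
    }
  }
  validate_params(p)
  p
}

#' Write a parameter registry to YAML
#'
#' @param p `vh_params` list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_params <- function(p, path) {
  validate_params(p)
  q <- unclass(p)
  attr(q, "provenance") <- NULL
  yaml::write_yaml(q, path, precision = 15)
  invisible(path)
}

#' Short stable hash of a resolved configuration
#'
#' Used to stamp run artifacts so identical configurations are recognizable.
#'
#' @param p `vh_params` list.
#' @return md5 hex string.
#' @export
params_hash <- function(p) {
  q <- unclass(p)
  attr(q, "provenance") <- NULL
  txt <- jsonlite::toJSON(q, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}

#' @method print vh_params
#' @export
print.vh_params <- function(x, ...) {
  cat("<vh_params> model parameter registry\n")
  for (grp in names(x)) {
    keys <- names(x[[grp]])
    cat(sprintf("  %-13s %s\n", grp, paste(keys, collapse = ", ")))
  }
  invisible(x)
}
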