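# Structured run configuration (YAML): force field, mass model, integrator,
# ensemble and io sections with unit-carrying keys, validated with
# actionable messages.  Pressure is given in GPa and converted at parse
# time; time steps are fs.

#' Read and validate a run configuration file
#'
#' The file is YAML with sections `forcefield`, `mass_model`, `integrator`,
#' `ensemble` and `io`.  See the package vignette for the recognized keys
#' and their units.
#'
#' @param path Path to the YAML configuration.
#' @return Named list with validated sections; `integrator` is an
#'   [integrator_config()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading configuration files requires the 'yaml' package")
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  need <- function(sec, key, default = NULL) {
    v <- raw[[sec]][[key]]
    if (is.null(v)) {
      if (is.null(default))
        stop(sprintf("config error: missing key '%s' in section '%s'",
                     key, sec))
      v <- default
    }
    v
  }
  ff_type <- need("forcefield", "type", "n2")
  ff <- switch(
    ff_type,
    n2 = n2_force_field(
      r0 = need("forcefield", "r0", 1.0977),
      Kr = need("forcefield", "Kr", 138.331),
      eps = need("forcefield", "eps", 0.003456),
      rm = need("forcefield", "rm", 3.614),
      cutoff = need("forcefield", "cutoff", 10),
      shift = need("forcefield", "shift", TRUE)),
    toy = toy_force_field(
      bond_k = need("forcefield", "bond_k"),
      bond_r0 = need("forcefield", "bond_r0"),
      angle_k = need("forcefield", "angle_k", numeric(0)),
      angle_0 = need("forcefield", "angle_0", numeric(0)),
      eps = need("forcefield", "eps", 0.005),
      rm = need("forcefield", "rm", 3.5),
      cutoff = need("forcefield", "cutoff", 9),
      shift = need("forcefield", "shift", TRUE)),
    stop("config error: forcefield type must be 'n2' or 'toy', got '",
         ff_type, "'"))
  mm <- raw$mass_model
  if (is.null(mm)) mm <- list(type = "constant")
  if (is.null(mm$type))
    stop("config error: mass_model section needs a 'type'")
  cfg <- integrator_config(
    dt = need("integrator", "dt"),
    W = need("integrator", "W", 20),
    P = need("ensemble", "P", 1e-4),
    uniform_scaling = need("integrator", "uniform_scaling", TRUE),
    fix_cell = need("integrator", "fix_cell", FALSE),
    fp_tol = need("integrator", "fp_tol", 1e-12),
    fp_max_iter = need("integrator", "fp_max_iter", 30),
    newton_tol = need("integrator", "newton_tol", 1e-12),
    newton_max_iter = need("integrator", "newton_max_iter", 10))
  list(forcefield = ff, mass_model = mm, integrator = cfg,
       ensemble = list(T_init = need("ensemble", "T_init", 0),
                       P_GPa = need("ensemble", "P", 1e-4)),
       io = list(stride = need("io", "stride", 1),
                 seed = need("io", "seed", 1)))
}

#' Instantiate the mass model described by a configuration section
#'
#' @param mm Named list (the `mass_model` section of [read_run_config()]).
#' @param top An [topology()].
#' @param x0 Reference Cartesian positions (needed by the
#'   internal-coordinate model).
#' @param hessian0 Reference Cartesian Hessian (internal-coordinate model).
#' @return A mass model object.
#' @export
config_mass_model <- function(mm, top, x0 = NULL, hessian0 = NULL) {
  switch(
    mm$type,
    constant = constant_mass_model(top),
    repartitioned = constant_mass_model(top, repartition = TRUE),
    diatomic = {
      m <- mean(top$masses)
      diatomic_mass_model(
        m_trans = if (!is.null(mm$m_trans)) mm$m_trans else m,
        m_rot = if (!is.null(mm$m_rot)) mm$m_rot else m,
        m_vib = if (!is.null(mm$m_vib)) mm$m_vib else m)
    },
    internal = {
      if (is.null(x0) || is.null(hessian0))
        stop(paste0("config error: the internal-coordinate mass model needs",
                    " a reference structure and Hessian"))
      internal_hessian_mass_model(
        top, x0, hessian0,
        w = if (!is.null(mm$w)) mm$w else 0.5,
        Mp = if (!is.null(mm$Mp)) mm$Mp else "physical",
        zero_offdiag = isTRUE(mm$zero_offdiag))
    },
    stop("config error: unknown mass_model type '", mm$type, "'"))
}
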