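# Model B: constant-pressure (Darcy) cake filtration plus one-dimensional
# advection-dispersion washing of the saturated cake.

#' Filtration setup for the Darcy model
#'
#' @param pressure_drop_mbar Driving pressure, mbar (converted to Pa
#'   internally).
#' @param filter_area Filter area, m^2 (from the configured port geometry,
#'   see [port_geometry()]).
#' @param liquid_viscosity Pa s.
#' @param specific_cake_resistance m/kg; if `NULL`, estimated with
#'   [kozeny_carman_resistance()] from the particle inputs.
#' @param medium_resistance Filter-medium resistance, 1/m (default 1e6).
#' @param solids_mass_per_filtrate_volume kg dry solids deposited per m^3 of
#'   filtrate, computed by [simulate_isolation_b()] when chaining.
#' @param porosity Cake void fraction in (0, 1).
#' @param particle_d50 Volume-median particle size, m.
#' @param sphericity Particle sphericity (default 1).
#' @param crystal_density kg/m^3.
#' @return `filtration_setup` object.
#' @export
filtration_setup <- function(pressure_drop_mbar, filter_area,
                             liquid_viscosity,
                             specific_cake_resistance = NULL,
                             medium_resistance = 1e6,
                             solids_mass_per_filtrate_volume = NULL,
                             porosity = 0.5, particle_d50 = NULL,
                             sphericity = 1, crystal_density = 1293) {
  dp <- pressure_drop_mbar * 100  # mbar -> Pa
  if (dp <= 0) stop_fmt("pressure drop must be > 0")
  if (filter_area <= 0 || liquid_viscosity <= 0)
    stop_fmt("filter_area and liquid_viscosity must be > 0")
  if (porosity <= 0 || porosity >= 1) stop_fmt("porosity must be in (0, 1)")
  if (is.null(specific_cake_resistance)) {
    if (is.null(particle_d50))
      stop_fmt("give specific_cake_resistance or particle_d50")
    specific_cake_resistance <- kozeny_carman_resistance(
      particle_d50, sphericity, porosity, crystal_density)
  }
  structure(list(pressure_drop = dp, filter_area = filter_area,
                 liquid_viscosity = liquid_viscosity,
                 specific_cake_resistance = specific_cake_resistance,
                 medium_resistance = medium_resistance,
                 solids_mass_per_filtrate_volume =
                   solids_mass_per_filtrate_volume,
                 porosity = porosity, particle_d50 = particle_d50,
                 sphericity = sphericity,
                 crystal_density = crystal_density),
            class = "filtration_setup")
}

#' Kozeny--Carman specific cake resistance
#'
#' For a bed of (poly)spherical particles,
#' `alpha = 180 (1 - eps) / (rho_c phi^2 d^2 eps^3)` (m/kg): a fallback when
#' no empirically fitted resistance is available. Strictly decreasing in
#' particle size and porosity.
#'
#' @param d50 Particle size, m.
#' @param sphericity Dimensionless in (0, 1].
#' @param porosity Void fraction in (0, 1).
#' @param crystal_density kg/m^3.
#' @return Specific cake resistance, m/kg.
#' @export
kozeny_carman_resistance <- function(d50, sphericity = 1, porosity,
                                     crystal_density) {
  if (d50 <= 0 || sphericity <= 0 || crystal_density <= 0)
    stop_fmt("all Kozeny-Carman inputs must be > 0")
  if (porosity <= 0 || porosity >= 1) stop_fmt("porosity must be in (0, 1)")
  180 * (1 - porosity) /
    (crystal_density * sphericity^2 * d50^2 * porosity^3)
}

#' Constant-pressure cake filtration (Darcy)
#'
#' Closed-form constant-pressure filtration:
#' `t(V) = mu alpha w V^2 / (2 A^2 dP) + mu R_m V / (A dP)`,
#' with cake resistance building up in proportion to the filtrate volume.
#' The flow rate `dV/dt = A^2 dP / (mu (alpha w V + R_m A))` is positive and
#' monotone non-increasing.
#'
#' @param setup A [filtration_setup()] (with
#'   `solids_mass_per_filtrate_volume` set).
#' @param target_volume Filtrate volume to collect, m^3.
#' @param n_points Points on the reported flow curve.
#' @return List: `time` (s), `flow_curve` (data frame `t`, `V`, `dVdt`).
#' @export
constant_pressure_filtration <- function(setup, target_volume,
                                         n_points = 101) {
  stopifnot(inherits(setup, "filtration_setup"))
  if (target_volume <= 0) stop_fmt("target_volume must be > 0")
  w <- setup$solids_mass_per_filtrate_volume
  if (is.null(w)) stop_fmt("solids_mass_per_filtrate_volume is not set")
  mu <- setup$liquid_viscosity; A <- setup$filter_area
  dP <- setup$pressure_drop; al <- setup$specific_cake_resistance
  Rm <- setup$medium_resistance
  t_of_V <- function(V) mu * al * w * V^2 / (2 * A^2 * dP) +
    mu * Rm * V / (A * dP)
  V <- seq(0, target_volume, length.out = n_points)
  dVdt <- A^2 * dP / (mu * (al * w * V + Rm * A))
  list(time = t_of_V(target_volume),
       flow_curve = data.frame(t = t_of_V(V), V = V, dVdt = dVdt))
}

#' Cylindrical filtration-port geometry
#'
#' The filter area and cake height derive from a configurable cylindrical
#' port; defaults are placeholders for a small lab dead-end filtration port
#' and should be set to the real equipment dimensions.
#'
#' @param diameter_m Port internal diameter, m (default 0.025).
#' @return List: `diameter_m`, `area_m2`.
#' @export
port_geometry <- function(diameter_m = 0.025) {
  if (diameter_m <= 0) stop_fmt("diameter must be > 0")
  list(diameter_m = diameter_m, area_m2 = pi * (diameter_m / 2)^2)
}

#' Dispersion-wash setup
#'
#' @param axial_dispersion_coefficient Axial dispersion coefficient D_L,
#'   m^2/s (default 1e-9).
#' @param cake_height Cake height, m.
#' @param superficial_velocity Wash superficial velocity, m/s.
#' @param porosity Cake void fraction.
#' @param n_cells Spatial grid cells (default 200, minimum 10).
#' @param cfl Courant number cap (default 0.5); the time step also honours
#'   the diffusive stability limit.
#' @return `dispersion_wash_setup` object.
#' @export
dispersion_wash_setup <- function(axial_dispersion_coefficient = 1e-9,
                                  cake_height, superficial_velocity,
                                  porosity, n_cells = 200, cfl = 0.5) {
  if (axial_dispersion_coefficient <= 0) stop_fmt("D_L must be > 0")
  if (cake_height <= 0 || superficial_velocity <= 0)
    stop_fmt("cake_height and superficial_velocity must be > 0")
  if (n_cells < 10) stop_fmt("need >= 10 grid cells")
  if (cfl <= 0 || cfl > 0.9) stop_fmt("cfl must be in (0, 0.9]")
  structure(list(D_L = axial_dispersion_coefficient,
                 cake_height = cake_height,
                 superficial_velocity = superficial_velocity,
                 porosity = porosity, n_cells = as.integer(n_cells),
                 cfl = cfl),
            class = "dispersion_wash_setup")
}

# Advect-disperse one scalar through the cake for a given wash volume
# (in units of pore volumes). Finite-volume explicit upwind advection with
# central dispersion; flux-form, so mass is conserved to rounding.
# Returns list(profile, effluent_mass_fraction_removed)
advect_scalar <- function(c0_profile, pore_volumes, setup,
                          inlet_value = 0) {
  N <- setup$n_cells
  L <- setup$cake_height
  dz <- L / N
  u <- setup$superficial_velocity / setup$porosity  # interstitial
  D <- setup$D_L
  t_end <- pore_volumes * L / u
  dt_adv <- setup$cfl * dz / u
  dt_dif <- if (D > 0) 0.4 * dz^2 / D else Inf
  dt <- min(dt_adv, dt_dif)
  nsteps <- max(1L, ceiling(t_end / dt))
  dt <- t_end / nsteps
  cc <- c0_profile
  out_mass <- 0   # per unit void cross-section (integral of u*c dt)
  for (s in seq_len(nsteps)) {
    # interior interface fluxes (advective upwind + dispersive central)
    cl <- cc[-N]; cr <- cc[-1]
    flux <- u * cl - D * (cr - cl) / dz
    f_in <- u * inlet_value            # Danckwerts total-flux inlet
    f_out <- u * cc[N]                 # free outflow (advective only)
    cc <- cc - (dt / dz) * (c(flux, f_out) - c(f_in, flux))
    out_mass <- out_mass + f_out * dt
  }
  list(profile = cc, out_per_area = out_mass,
       inlet_per_area = u * inlet_value * t_end)
}

#' Advection--dispersion washing of a saturated cake (model B)
#'
#' Solves, for each dissolved species, the one-dimensional
#' advection--dispersion equation
#' `dc/dt = D_L d2c/dz2 - u dc/dz`
#' over the cake height with a Danckwerts-type total-flux inlet at the wash
#' composition and free outflow at the filter medium (explicit upwind
#' advection, central dispersion, CFL-limited time step). The effluent is
#' integrated into per-wash filtrate streams; the cake-average residual gives
#' removal and washing yield. In the `D_L -> 0` limit the effluent reduces to
#' a plug-flow step at one pore volume, within grid tolerance.
#'
#' @param setup A [dispersion_wash_setup()].
#' @param cake Wet-cake [stream()] from the phase split.
#' @param spec A [wash_spec()] (amounts in cake void volumes = pore volumes).
#' @param curves Optional named list of [binary_curve()]s (`"api"` +
#'   impurities). When supplied, dissolution/precipitation risks are
#'   evaluated per wash on the cake-average composition; `NULL` mimics a
#'   solubility-blind simulator (no gradient solubility, no flags).
#' @param cryst_solvent,wash_solvent Solvent names spanning the gradient
#'   (needed only when `curves` is given).
#' @param feed Optional [feed_suspension()] for feed-relative percentages.
#' @return `isolation_result` with model = "B".
#' @export
dispersion_wash <- function(setup, cake, spec, curves = NULL,
                            cryst_solvent = NULL, wash_solvent = NULL,
                            feed = NULL) {
  stopifnot(inherits(setup, "dispersion_wash_setup"),
            inherits(cake, "stream"), inherits(spec, "wash_spec"))
  imp_names <- names(cake$impurities) %||% character(0)
  liq_mass <- cake$api_dissolved + sum(cake$solvents) + sum(cake$impurities)
  if (liq_mass <= 0) stop_fmt("cake carries no liquid phase")
  if (!is.null(curves)) {
    cryst_solvent <- canon_name(cryst_solvent)
    wash_solvent <- canon_name(wash_solvent)
    for (nm in c("api", imp_names))
      if (is.null(curves[[nm]]))
        stop_fmt("no binary solubility curve supplied for solute '%s'", nm)
  }
  N <- setup$n_cells
  # per-species mass-fraction profiles over the cake liquid (uniform start)
  species <- c("api", imp_names, names(cake$solvents))
  conc0 <- c(api = cake$api_dissolved / liq_mass,
             cake$impurities / liq_mass, cake$solvents / liq_mass)
  prof <- lapply(stats::setNames(species, species),
                 function(nm) rep(conc0[[nm]], N))
  initial_dissolved_api <- cake$api_dissolved
  flags <- list(
    api_dissolution = list(fired = FALSE, wash = NA_integer_,
                           step = NA_integer_),
    impurity_precipitation = stats::setNames(
      lapply(imp_names, function(i)
        list(fired = FALSE, wash = NA_integer_, step = NA_integer_)),
      imp_names))
  filtrates <- list()
  checkpoints <- list()
  cum_vv <- 0
  cell_liq <- liq_mass / N   # liquid mass per cell (constant saturation)
  record <- function(label, cum_vv) {
    resid <- vapply(species, function(nm) sum(prof[[nm]]) * cell_liq,
                    numeric(1))
    basis_imp <- if (!is.null(feed)) feed$dissolved_impurity_masses else
      cake$impurities
    removal <- vapply(imp_names, function(i) {
      if (basis_imp[[i]] <= 0) return(NA_real_)   # impurity-free: n/a
      impurity_removal_percent(basis_imp[[i]], min(resid[[i]],
                                                   basis_imp[[i]]))
    }, numeric(1))
    api_in_cake <- cake$api_solid + resid[["api"]]
    api_basis <- if (!is.null(feed))
      feed$solid_api_mass + feed$dissolved_api_mass else
        cake$api_solid + cake$api_dissolved
    out <- data.frame(label = label, cum_void_volumes = cum_vv,
                      cum_ecv = cum_vv * setup$porosity,
                      washing_yield = 100 * api_in_cake / api_basis,
                      dissolved_api = resid[["api"]],
                      stringsAsFactors = FALSE)
    for (i in seq_along(imp_names))
      out[[paste0("removed_", imp_names[i])]] <- removal[[i]]
    out
  }
  checkpoints[[1]] <- record("start of washing", 0)
  for (j in seq_along(spec)) {
    w <- spec[[j]]
    pv <- w$amount_void_volumes
    removed <- stats::setNames(numeric(length(species)), species)
    for (nm in species) {
      inlet <- if (nm %in% names(w$composition)) w$composition[[nm]] else 0
      res <- advect_scalar(prof[[nm]], pv, setup, inlet_value = inlet)
      prof[[nm]] <- res$profile
      # effluent flux integral, rescaled from per-unit-void-area to mass:
      # one pore volume of effluent carries liq_mass of liquid
      removed[nm] <- res$out_per_area * liq_mass / setup$cake_height
    }
    filtrates[[j]] <- stream(
      api_dissolved = removed[["api"]],
      solvents = removed[names(cake$solvents)],
      impurities = if (length(imp_names)) removed[imp_names] else numeric(0))
    cum_vv <- cum_vv + pv
    if (!is.null(curves)) {
      solv_prof <- Reduce(`+`, prof[names(cake$solvents)])
      pairc <- if (cryst_solvent %in% names(prof))
        mean(prof[[cryst_solvent]]) else 0
      washc <- if (wash_solvent %in% names(prof))
        mean(prof[[wash_solvent]]) else 0
      fw <- if (pairc + washc > 0) washc / (pairc + washc) else 0
      solvent_mass <- mean(solv_prof) * liq_mass
      cap_api <- solubility_at(curves[["api"]], fw) * solvent_mass / 100
      if (!flags$api_dissolution$fired &&
          cap_api > initial_dissolved_api * (1 + 1e-12))
        flags$api_dissolution <- list(fired = TRUE, wash = j, step = NA)
      for (nm in imp_names) {
        cap <- solubility_at(curves[[nm]], fw) * solvent_mass / 100
        if (sum(prof[[nm]]) * cell_liq > cap * (1 + 1e-12) &&
            !flags$impurity_precipitation[[nm]]$fired)
          flags$impurity_precipitation[[nm]] <-
            list(fired = TRUE, wash = j, step = NA)
      }
    }
    checkpoints[[j + 1]] <- record(sprintf("after wash %d", j), cum_vv)
  }
  resid <- vapply(species, function(nm) sum(prof[[nm]]) * cell_liq,
                  numeric(1))
  final_cake <- stream(api_solid = cake$api_solid,
                       api_dissolved = resid[["api"]],
                       solvents = resid[names(cake$solvents)],
                       impurities = if (length(imp_names)) resid[imp_names]
                       else numeric(0))
  structure(list(model = "B", cake = final_cake,
                 wash_filtrates = filtrates,
                 checkpoints = do.call(rbind, checkpoints),
                 flags = flags, porosity = setup$porosity,
                 setup = setup),
            class = "isolation_result")
}

#' Full model-B isolation run
#'
#' Chains the dryland phase split, constant-pressure filtration timing, and
#' advection--dispersion washing. The wash superficial velocity is the Darcy
#' flow at the wash pressure through the fully formed cake.
#'
#' @param feed A [feed_suspension()].
#' @param fsetup A [filtration_setup()].
#' @param geometry A [port_geometry()].
#' @param spec A [wash_spec()].
#' @param curves,cryst_solvent,wash_solvent As in [dispersion_wash()];
#'   `curves = NULL` disables gradient-solubility risk evaluation.
#' @param D_L Axial dispersion coefficient, m^2/s (default 1e-9).
#' @param n_cells Grid cells (default 200).
#' @return `isolation_result` with model = "B" plus `filtration` (time and
#'   flow curve), `filtration_filtrate` and `filtration_yield`.
#' @export
simulate_isolation_b <- function(feed, fsetup, geometry = port_geometry(),
                                 spec, curves = NULL,
                                 cryst_solvent = NULL, wash_solvent = NULL,
                                 D_L = 1e-9, n_cells = 200) {
  stopifnot(inherits(feed, "feed_suspension"),
            inherits(fsetup, "filtration_setup"))
  split <- filtration_phase_split(feed, fsetup$porosity, "dryland")
  A <- geometry$area_m2
  cake_volume_m3 <- (feed$solid_api_mass / feed$crystal_density) * 1e-6 /
    (1 - fsetup$porosity)
  cake_height <- cake_volume_m3 / A
  filtrate_mass <- stream_mass(split$filtrate)
  filtrate_volume_m3 <- filtrate_mass / split$ml_density * 1e-6
  if (filtrate_volume_m3 <= 0)
    stop_fmt("no filtrate to remove before dryland")
  fsetup$solids_mass_per_filtrate_volume <-
    (feed$solid_api_mass / 1000) / filtrate_volume_m3
  filt <- constant_pressure_filtration(fsetup, filtrate_volume_m3)
  # wash velocity: Darcy flow at the wash pressure through the full cake
  w_c <- (feed$solid_api_mass / 1000) / A  # kg/m^2
  u_sup <- fsetup$pressure_drop /
    (fsetup$liquid_viscosity *
       (fsetup$specific_cake_resistance * w_c + fsetup$medium_resistance))
  wsetup <- dispersion_wash_setup(
    axial_dispersion_coefficient = D_L, cake_height = cake_height,
    superficial_velocity = u_sup, porosity = fsetup$porosity,
    n_cells = n_cells)
  res <- dispersion_wash(wsetup, split$cake, spec, curves = curves,
                         cryst_solvent = cryst_solvent,
                         wash_solvent = wash_solvent, feed = feed)
  res$filtration <- filt
  res$filtration_filtrate <- split$filtrate
  res$filtration_yield <- 100 *
    (split$cake$api_solid + split$cake$api_dissolved) /
    (feed$solid_api_mass + feed$dissolved_api_mass)
  res$feed <- feed
  res$void_volume_mL <- split$void_volume_mL
  res
}
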