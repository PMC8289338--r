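# Stages 8-9, model A: filtration as a phase split to dryland/breakthrough,
# then discretized ideal-displacement washing with risk flags.

#' Component stream (cake, filtrate or suspension phase)
#'
#' @param api_solid,api_dissolved API masses, g.
#' @param solvents Named numeric vector of solvent masses, g.
#' @param impurities Named numeric vector of dissolved impurity masses, g.
#' @param impurities_solid Named numeric vector of precipitated impurity
#'   masses, g (defaults to zero).
#' @return `stream` object.
#' @export
stream <- function(api_solid = 0, api_dissolved = 0,
                   solvents = numeric(0), impurities = numeric(0),
                   impurities_solid = NULL) {
  if (is.null(impurities_solid))
    impurities_solid <- stats::setNames(rep(0, length(impurities)),
                                        names(impurities))
  vals <- c(api_solid, api_dissolved, solvents, impurities, impurities_solid)
  if (any(vals < -1e-12)) stop_fmt("stream masses must be >= 0")
  structure(list(api_solid = max(api_solid, 0),
                 api_dissolved = max(api_dissolved, 0),
                 solvents = pmax(solvents, 0),
                 impurities = pmax(impurities, 0),
                 impurities_solid = pmax(impurities_solid, 0)),
            class = "stream")
}

#' Total mass of a stream, g
#' @param s A [stream()].
#' @export
stream_mass <- function(s) {
  s$api_solid + s$api_dissolved + sum(s$solvents) + sum(s$impurities) +
    sum(s$impurities_solid)
}

#' Mass fractions of a stream
#'
#' The API fraction lumps solid and dissolved phases; each impurity lumps
#' dissolved and precipitated.
#'
#' @param s A [stream()].
#' @return Named vector (`api`, one entry per impurity, one per solvent),
#'   summing to 1.
#' @export
mass_fractions <- function(s) {
  tot <- stream_mass(s)
  if (tot <= 0) stop_fmt("stream has zero total mass")
  imp <- s$impurities
  for (nm in names(s$impurities_solid))
    imp[nm] <- imp[nm] + s$impurities_solid[nm]
  c(api = (s$api_solid + s$api_dissolved) / tot, imp / tot,
    s$solvents / tot)
}

#' @export
print.stream <- function(x, digits = 4, ...) {
  cat(sprintf("<stream> %.4g g total\n", stream_mass(x)))
  print(round(c(api_solid = x$api_solid, api_dissolved = x$api_dissolved,
                x$solvents, x$impurities), digits))
  invisible(x)
}

#' Feed suspension (crystallizer output entering isolation)
#'
#' @param solid_api_mass Suspended API crystal mass, g.
#' @param dissolved_api_mass API dissolved in the mother liquor, g.
#' @param solvent_masses Named numeric vector, g per solvent.
#' @param dissolved_impurity_masses Named numeric vector, g per impurity.
#' @param crystal_density API crystal density, g/mL.
#' @param solvent_densities Named numeric vector, g/mL (must cover every
#'   solvent that appears in the feed or washes).
#' @param solute_densities Optional named densities for dissolved species
#'   (default: `crystal_density` for all), used in the ideal-mixing
#'   mother-liquor density.
#' @return `feed_suspension` object.
#' @export
feed_suspension <- function(solid_api_mass, dissolved_api_mass,
                            solvent_masses, dissolved_impurity_masses,
                            crystal_density, solvent_densities,
                            solute_densities = NULL) {
  if (solid_api_mass <= 0) stop_fmt("solid_api_mass must be > 0")
  if (dissolved_api_mass < 0 || any(solvent_masses < 0) ||
      any(dissolved_impurity_masses < 0))
    stop_fmt("feed masses must be >= 0")
  if (crystal_density <= 0) stop_fmt("crystal_density must be > 0")
  names(solvent_masses) <- canon_name(names(solvent_masses))
  names(solvent_densities) <- canon_name(names(solvent_densities))
  if (!all(names(solvent_masses) %in% names(solvent_densities)))
    stop_fmt("solvent_densities must cover every feed solvent")
  if (is.null(solute_densities))
    solute_densities <- stats::setNames(
      rep(crystal_density, 1 + length(dissolved_impurity_masses)),
      c("api", names(dissolved_impurity_masses)))
  structure(list(solid_api_mass = solid_api_mass,
                 dissolved_api_mass = dissolved_api_mass,
                 solvent_masses = solvent_masses,
                 dissolved_impurity_masses = dissolved_impurity_masses,
                 crystal_density = crystal_density,
                 solvent_densities = solvent_densities,
                 solute_densities = solute_densities),
            class = "feed_suspension")
}

feed_as_stream <- function(feed) {
  stream(api_solid = feed$solid_api_mass,
         api_dissolved = feed$dissolved_api_mass,
         solvents = feed$solvent_masses,
         impurities = feed$dissolved_impurity_masses)
}

#' Mass fractions of the feed suspension
#'
#' @param feed A [feed_suspension()].
#' @return Named fraction vector as in [mass_fractions()] (`api` combines
#'   the solid and dissolved phases).
#' @export
feed_mass_fractions <- function(feed) {
  stopifnot(inherits(feed, "feed_suspension"))
  mass_fractions(feed_as_stream(feed))
}

# ideal-mixing mother-liquor density: mass-weighted average of pure-component
# densities over the liquid phase
ml_density <- function(feed) {
  m <- c(feed$dissolved_api_mass, feed$solvent_masses,
         feed$dissolved_impurity_masses)
  d <- c(feed$solute_densities[["api"]],
         feed$solvent_densities[names(feed$solvent_masses)],
         feed$solute_densities[names(feed$dissolved_impurity_masses)])
  sum(m * d) / sum(m)
}

#' Cake void volume, mL
#'
#' `void = (solid mass / crystal density) * porosity / (1 - porosity)`:
#' the solids define the cake skeleton, the porosity its liquid-holding
#' voidage.
#'
#' @param solid_api_mass g.
#' @param crystal_density g/mL.
#' @param porosity Void fraction in (0, 1).
#' @export
cake_void_volume <- function(solid_api_mass, crystal_density, porosity) {
  if (porosity <= 0 || porosity >= 1) stop_fmt("porosity must be in (0, 1)")
  (solid_api_mass / crystal_density) * porosity / (1 - porosity)
}

#' Split the feed into wet cake and filtrate (filtration as a phase split)
#'
#' Filtration is modeled as a pure separation: all solids report to the cake;
#' the cake retains liquid equal to its void volume times the saturation
#' times the mother-liquor density, and both liquid portions carry identical
#' species mass fractions. `dryland` leaves the cake fully saturated
#' (saturation 1); `breakthrough` uses the supplied residual saturation < 1.
#'
#' @param feed A [feed_suspension()].
#' @param porosity Cake void fraction in (0, 1).
#' @param endpoint `"dryland"` or `"breakthrough"`.
#' @param residual_saturation Saturation in (0, 1]; used for breakthrough.
#' @return List: `cake`, `filtrate` ([stream()]s), `void_volume_mL`,
#'   `cake_liquid_mass`, `ml_density`.
#' @export
filtration_phase_split <- function(feed, porosity,
                                   endpoint = c("dryland", "breakthrough"),
                                   residual_saturation = 1.0) {
  stopifnot(inherits(feed, "feed_suspension"))
  endpoint <- match.arg(endpoint)
  if (residual_saturation <= 0 || residual_saturation > 1)
    stop_fmt("residual_saturation must be in (0, 1]")
  S <- if (endpoint == "dryland") 1.0 else residual_saturation
  void <- cake_void_volume(feed$solid_api_mass, feed$crystal_density,
                           porosity)
  rho <- ml_density(feed)
  liq_total <- feed$dissolved_api_mass + sum(feed$solvent_masses) +
    sum(feed$dissolved_impurity_masses)
  cake_liq <- void * S * rho
  if (cake_liq > liq_total)
    stop_fmt(paste0("cake void demand (%.4g g of mother liquor) exceeds the ",
                    "available liquid (%.4g g): deficit %.4g g"),
             cake_liq, liq_total, cake_liq - liq_total)
  f <- cake_liq / liq_total
  cake <- stream(api_solid = feed$solid_api_mass,
                 api_dissolved = f * feed$dissolved_api_mass,
                 solvents = f * feed$solvent_masses,
                 impurities = f * feed$dissolved_impurity_masses)
  filtrate <- stream(api_dissolved = (1 - f) * feed$dissolved_api_mass,
                     solvents = (1 - f) * feed$solvent_masses,
                     impurities = (1 - f) * feed$dissolved_impurity_masses)
  list(cake = cake, filtrate = filtrate, void_volume_mL = void,
       cake_liquid_mass = cake_liq, ml_density = rho)
}

#' Wash specification
#'
#' @param ... One wash step per argument, each built with [wash_step()].
#' @return `wash_spec` object (ordered list of washes).
#' @export
wash_spec <- function(...) {
  washes <- list(...)
  stopifnot(all(vapply(washes, inherits, logical(1), "wash_step")))
  structure(washes, class = "wash_spec")
}

#' One wash step
#'
#' @param amount_void_volumes Wash amount, in cake void volumes (> 0).
#'   Reported "ECV" values are void volumes times porosity, matching the
#'   equivalent-cake-volume convention of the bundled case study.
#' @param composition Named mass fractions over solvents, summing to 1.
#' @param n_steps Discretization steps per wash (default 10: each tranche is
#'   one tenth of the wash mass).
#' @return `wash_step` object.
#' @export
wash_step <- function(amount_void_volumes, composition, n_steps = 10) {
  if (amount_void_volumes <= 0) stop_fmt("wash amount must be > 0")
  if (abs(sum(composition) - 1) > 1e-9)
    stop_fmt("wash composition must sum to 1")
  if (any(composition < 0)) stop_fmt("wash composition fractions must be >= 0")
  names(composition) <- canon_name(names(composition))
  structure(list(amount_void_volumes = amount_void_volumes,
                 composition = composition, n_steps = as.integer(n_steps)),
            class = "wash_step")
}

#' Impurity removal percentage
#'
#' @param feed_impurity Impurity mass in the feed stream, g (> 0).
#' @param residual_impurity Impurity mass remaining in the cake, g.
#' @return `100 * (feed - residual) / feed`.
#' @export
impurity_removal_percent <- function(feed_impurity, residual_impurity) {
  if (feed_impurity <= 0) stop_fmt("feed impurity mass must be > 0")
  if (residual_impurity < -1e-12)
    stop_fmt("negative residual impurity mass")
  if (residual_impurity > feed_impurity * (1 + 1e-9))
    stop_fmt("residual impurity (%.4g g) exceeds feed impurity (%.4g g)",
             residual_impurity, feed_impurity)
  100 * (feed_impurity - residual_impurity) / feed_impurity
}

#' Ideal displacement washing of a saturated cake (model A)
#'
#' Discretizes each wash into `n_steps` equal-mass tranches. Per tranche:
#' (i) the tranche displaces an equal mass of the *remaining original mother
#' liquor* to the filtrate at its pre-mixing composition (ideal plug
#' displacement); once the original liquor is exhausted, tranches displace
#' the current, fully mixed cake liquid; (ii) the tranche then mixes fully
#' with the cake liquid; (iii) solute solubilities at the new
#' crystallization/wash composition are read from the binary curves. The API
#' dissolution flag fires when the equilibrium dissolvable API exceeds the
#' amount dissolved at the end of filtration; an impurity precipitation flag
#' fires when a dissolved impurity exceeds its solubility limit, and the
#' precipitated excess is retained in the cake (worst case) and stops being
#' washable.
#'
#' @param cake Wet-cake [stream()] from [filtration_phase_split()].
#' @param spec A [wash_spec()].
#' @param curves Named list of [binary_curve()]s keyed by solute name
#'   (`"api"` plus each impurity).
#' @param initial_dissolved Named vector of post-filtration dissolved masses
#'   (`api` plus impurities); defaults to the cake's own dissolved phase.
#' @param cryst_solvent,wash_solvent Names of the two solvents spanning the
#'   binary gradient.
#' @param solvent_densities Named densities g/mL (for converting wash void
#'   volumes to masses).
#' @param void_volume_mL Cake void volume (from the phase split).
#' @param porosity Cake porosity (for ECV reporting only).
#' @param feed Optional [feed_suspension()]; when given, removal and yield
#'   percentages are reported relative to the whole feed, and the filtration
#'   filtrate should be accounted by the caller ([simulate_isolation_a()]
#'   does).
#' @return `isolation_result` (see [simulate_isolation_a()]).
#' @export
displacement_wash <- function(cake, spec, curves, initial_dissolved = NULL,
                              cryst_solvent, wash_solvent,
                              solvent_densities, void_volume_mL, porosity,
                              feed = NULL) {
  stopifnot(inherits(cake, "stream"), inherits(spec, "wash_spec"))
  cryst_solvent <- canon_name(cryst_solvent)
  wash_solvent <- canon_name(wash_solvent)
  names(solvent_densities) <- canon_name(names(solvent_densities))
  imp_names <- names(cake$impurities) %||% character(0)
  for (nm in c("api", imp_names))
    if (is.null(curves[[nm]]))
      stop_fmt("no binary solubility curve supplied for solute '%s'", nm)
  liq_solv <- cake$solvents
  # make sure every wash solvent has a slot and a density
  for (w in spec) {
    unknown <- setdiff(names(w$composition), names(solvent_densities))
    if (length(unknown))
      stop_fmt("wash composition names unknown solvent '%s' (no density)",
               unknown[1])
    for (nm in setdiff(names(w$composition), names(liq_solv)))
      liq_solv[nm] <- 0
  }
  liq_api <- cake$api_dissolved
  liq_imp <- cake$impurities
  prec_imp <- cake$impurities_solid
  if (is.null(initial_dissolved))
    initial_dissolved <- c(api = liq_api, liq_imp)
  # original mother-liquor accounting (pre-mixing displacement basis)
  M0 <- liq_api + sum(liq_solv) + sum(liq_imp)
  R <- M0
  w0 <- c(api = liq_api, liq_solv, liq_imp) / M0
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
  record <- function(label, cum_vv) {
    resid_imp <- liq_imp + prec_imp
    basis_imp <- if (!is.null(feed)) feed$dissolved_impurity_masses else
      cake$impurities + cake$impurities_solid
    removal <- vapply(imp_names, function(i) {
      if (basis_imp[[i]] <= 0) return(NA_real_)   # impurity-free: n/a
      impurity_removal_percent(basis_imp[[i]], resid_imp[[i]])
    }, numeric(1))
    api_in_cake <- cake$api_solid + liq_api
    api_basis <- if (!is.null(feed))
      feed$solid_api_mass + feed$dissolved_api_mass else
        cake$api_solid + cake$api_dissolved
    out <- data.frame(label = label, cum_void_volumes = cum_vv,
                      cum_ecv = cum_vv * porosity,
                      washing_yield = 100 * api_in_cake / api_basis,
                      dissolved_api = liq_api,
                      stringsAsFactors = FALSE)
    for (i in seq_along(imp_names))
      out[[paste0("removed_", imp_names[i])]] <- removal[[i]]
    out
  }
  checkpoints[[1]] <- record("start of washing", 0)
  for (j in seq_along(spec)) {
    w <- spec[[j]]
    rho_wash <- sum(w$composition * solvent_densities[names(w$composition)])
    wash_mass <- w$amount_void_volumes * void_volume_mL * rho_wash
    tau <- wash_mass / w$n_steps
    fil_api <- 0; fil_solv <- stats::setNames(rep(0, length(liq_solv)),
                                              names(liq_solv))
    fil_imp <- stats::setNames(rep(0, length(imp_names)), imp_names)
    for (k in seq_len(w$n_steps)) {
      # (i) displacement to filtrate
      d1 <- min(tau, R)
      if (d1 > 0) {
        take <- w0 * d1
        take["api"] <- min(take[["api"]], liq_api)
        for (nm in imp_names) take[nm] <- min(take[[nm]], liq_imp[[nm]])
        for (nm in names(liq_solv))
          take[nm] <- min(take[[nm]], liq_solv[[nm]])
        liq_api <- liq_api - take[["api"]]
        fil_api <- fil_api + take[["api"]]
        for (nm in names(liq_solv)) {
          liq_solv[nm] <- liq_solv[[nm]] - take[[nm]]
          fil_solv[nm] <- fil_solv[[nm]] + take[[nm]]
        }
        for (nm in imp_names) {
          liq_imp[nm] <- liq_imp[[nm]] - take[[nm]]
          fil_imp[nm] <- fil_imp[[nm]] + take[[nm]]
        }
        R <- R - d1
        d2 <- tau - sum(take)
      } else d2 <- tau
      cur <- liq_api + sum(liq_solv) + sum(liq_imp)
      if (d2 > 1e-15 && cur > 0) {
        d2 <- min(d2, cur)
        frac <- d2 / cur
        fil_api <- fil_api + frac * liq_api
        fil_solv <- fil_solv + frac * liq_solv
        fil_imp <- fil_imp + frac * liq_imp
        liq_api <- liq_api * (1 - frac)
        liq_solv <- liq_solv * (1 - frac)
        liq_imp <- liq_imp * (1 - frac)
      }
      # (ii) tranche mixes into the cake liquid
      add <- tau * w$composition
      liq_solv[names(add)] <- liq_solv[names(add)] + add
      # (iii) solubility evaluation at the post-mixing composition
      pair_mass <- if (cryst_solvent %in% names(liq_solv))
        liq_solv[[cryst_solvent]] else 0
      wash_side <- if (wash_solvent %in% names(liq_solv))
        liq_solv[[wash_solvent]] else 0
      denom <- pair_mass + wash_side
      fw <- if (denom > 0) wash_side / denom else 0
      solvent_mass <- sum(liq_solv)
      cap_api <- solubility_at(curves[["api"]], fw) * solvent_mass / 100
      if (!flags$api_dissolution$fired &&
          cap_api > initial_dissolved[["api"]] * (1 + 1e-12)) {
        flags$api_dissolution <- list(fired = TRUE, wash = j, step = k)
      }
      for (nm in imp_names) {
        cap <- solubility_at(curves[[nm]], fw) * solvent_mass / 100
        if (liq_imp[[nm]] > cap * (1 + 1e-12)) {
          if (!flags$impurity_precipitation[[nm]]$fired)
            flags$impurity_precipitation[[nm]] <-
              list(fired = TRUE, wash = j, step = k)
          excess <- liq_imp[[nm]] - cap
          prec_imp[nm] <- prec_imp[[nm]] + excess
          liq_imp[nm] <- cap
        }
      }
    }
    cum_vv <- cum_vv + w$amount_void_volumes
    filtrates[[j]] <- stream(api_dissolved = fil_api, solvents = fil_solv,
                             impurities = fil_imp)
    checkpoints[[j + 1]] <- record(sprintf("after wash %d", j), cum_vv)
  }
  final_cake <- stream(api_solid = cake$api_solid, api_dissolved = liq_api,
                       solvents = liq_solv, impurities = liq_imp,
                       impurities_solid = prec_imp)
  structure(list(model = "A", cake = final_cake,
                 wash_filtrates = filtrates,
                 checkpoints = do.call(rbind, checkpoints),
                 flags = flags, porosity = porosity,
                 void_volume_mL = void_volume_mL),
            class = "isolation_result")
}

#' Full model-A isolation run (filtration + displacement washing)
#'
#' Chains [filtration_phase_split()] (dryland by default) and
#' [displacement_wash()]; removal and yield percentages are relative to the
#' feed stream.
#'
#' @inheritParams displacement_wash
#' @inheritParams filtration_phase_split
#' @return `isolation_result`: list with `cake` (final [stream()]),
#'   `filtration_filtrate`, `wash_filtrates` (one [stream()] per wash),
#'   `checkpoints` (data frame: label, cumulative void volumes, cumulative
#'   ECV = void volumes x porosity, washing yield %, removal % per impurity),
#'   `filtration_yield`, `flags` (first-firing wash/step per risk), and the
#'   phase-split geometry.
#' @export
simulate_isolation_a <- function(feed, porosity, spec, curves,
                                 cryst_solvent, wash_solvent,
                                 endpoint = "dryland",
                                 residual_saturation = 1.0) {
  split <- filtration_phase_split(feed, porosity, endpoint,
                                  residual_saturation)
  res <- displacement_wash(split$cake, spec, curves,
                           initial_dissolved = NULL,
                           cryst_solvent = cryst_solvent,
                           wash_solvent = wash_solvent,
                           solvent_densities = feed$solvent_densities,
                           void_volume_mL = split$void_volume_mL,
                           porosity = porosity, feed = feed)
  res$filtration_filtrate <- split$filtrate
  res$filtration_yield <- 100 *
    (split$cake$api_solid + split$cake$api_dissolved) /
    (feed$solid_api_mass + feed$dissolved_api_mass)
  res$feed <- feed
  res$ml_density <- split$ml_density
  res
}

#' @export
print.isolation_result <- function(x, ...) {
  cat(sprintf("<isolation_result> model %s\n", x$model))
  if (!is.null(x$filtration_yield))
    cat(sprintf("  filtration yield: %.2f %%\n", x$filtration_yield))
  print(x$checkpoints, digits = 4, row.names = FALSE)
  if (isTRUE(x$flags$api_dissolution$fired))
    cat(sprintf("  FLAG: API dissolution risk (wash %d, step %d)\n",
                x$flags$api_dissolution$wash, x$flags$api_dissolution$step))
  for (nm in names(x$flags$impurity_precipitation)) {
    f <- x$flags$impurity_precipitation[[nm]]
    if (isTRUE(f$fired))
      cat(sprintf("  FLAG: %s precipitation risk (wash %d, step %d)\n",
                  nm, f$wash, f$step))
  }
  invisible(x)
}

#' @export
summary.isolation_result <- function(object, ...) {
  last <- object$checkpoints[nrow(object$checkpoints), , drop = FALSE]
  cat(sprintf("model %s: final checkpoint '%s' at %.2f ECV\n",
              object$model, last$label, last$cum_ecv))
  rem <- last[, grep("^removed_", names(last)), drop = FALSE]
  for (nm in names(rem))
    cat(sprintf("  %s: %.2f %%\n", sub("^removed_", "removal ", nm), rem[[nm]]))
  cat(sprintf("  washing yield: %.2f %%\n", last$washing_yield))
  invisible(object)
}
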