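# Stages 5-6: wash-solvent filtering and Pareto ranking.

wash_flags <- c("BP_MP_NEAR_WASH_T", "DENSITY_INVERSION",
                "API_MORE_SOLUBLE_THAN_CRYST", "IMMISCIBLE", "ICH_REJECT",
                "THRESHOLD_FAIL", "GSK_FAIL")

#' Wash-filter configuration
#'
#' Mirrors the threshold panel of the screening tool: every filter can be
#' enabled independently by setting its bound (`NULL` disables it). The
#' defaults are the published filter-3/filter-4 limits; unknown property
#' values pass any filter they cannot be evaluated against except the ICH
#' filter, which fails unknowns when `strict_ich = TRUE`.
#'
#' @param wash_temperature Washing temperature, C (default 22).
#' @param bp_mp_exclusion_margin Exclude solvents whose boiling or melting
#'   point lies within this many degrees of the wash temperature (default 10).
#' @param density_ratio_max Max wash/crystallization density ratio before a
#'   layer-inversion flag (default 1.3).
#' @param mp_max Max melting point, C (filter-3 default 0).
#' @param bp_range Allowed boiling-point range, C (default `c(60, 130)`).
#' @param viscosity_max Max viscosity, Pa s (default 0.09).
#' @param vapor_pressure_max Max vapour pressure, Pa (default 10000).
#' @param ich_min_class Minimum ICH class to pass (default 3: only low-risk
#'   class 3 solvents pass the strictest filter).
#' @param gsk_min_score All six GSK scores must exceed this (default 3, i.e.
#'   scores of 4 or more on every axis).
#' @param require_miscible Flag solvents not fully miscible with the
#'   crystallization solvent (default TRUE).
#' @param strict_ich Fail solvents with unknown ICH class (default FALSE).
#' @return `wash_filter_config` object.
#' @export
wash_filter_config <- function(wash_temperature = 22,
                               bp_mp_exclusion_margin = 10,
                               density_ratio_max = 1.3,
                               mp_max = 0, bp_range = c(60, 130),
                               viscosity_max = 0.09,
                               vapor_pressure_max = 10000,
                               ich_min_class = 3, gsk_min_score = 3,
                               require_miscible = TRUE, strict_ich = FALSE) {
  if (!is.null(bp_range) && (length(bp_range) != 2 || bp_range[1] > bp_range[2]))
    stop_fmt("bp_range must be an ordered (low, high) pair")
  structure(list(wash_temperature = wash_temperature,
                 bp_mp_exclusion_margin = bp_mp_exclusion_margin,
                 density_ratio_max = density_ratio_max,
                 mp_max = mp_max, bp_range = bp_range,
                 viscosity_max = viscosity_max,
                 vapor_pressure_max = vapor_pressure_max,
                 ich_min_class = ich_min_class,
                 gsk_min_score = gsk_min_score,
                 require_miscible = require_miscible,
                 strict_ich = strict_ich),
            class = "wash_filter_config")
}

#' Wash-solvent candidate
#'
#' @param solvent A [solvent()] object.
#' @param api_solubility API solubility in this solvent, g/100 g.
#' @param impurity_solubilities Named numeric vector, g/100 g per impurity.
#' @param miscible_with_cryst Logical; fully miscible with the
#'   crystallization solvent?
#' @return `wash_candidate` object with an (initially empty) flag set.
#' @export
wash_candidate <- function(solvent, api_solubility, impurity_solubilities,
                           miscible_with_cryst = TRUE) {
  stopifnot(inherits(solvent, "solvent"))
  if (api_solubility < 0 || any(impurity_solubilities < 0))
    stop_fmt("solubilities must be >= 0 for '%s'", solvent$name)
  if (is.null(names(impurity_solubilities)))
    stop_fmt("impurity_solubilities must be named")
  structure(list(solvent = solvent, api_solubility = api_solubility,
                 impurity_solubilities = impurity_solubilities,
                 miscible_with_cryst = isTRUE(miscible_with_cryst),
                 flags = character(0), delta_class = NULL),
            class = "wash_candidate")
}

add_flag <- function(cand, flag) {
  stopifnot(flag %in% wash_flags)
  cand$flags <- union(cand$flags, flag)
  cand
}

#' Classify a wash solvent by its impurity-vs-API solubility gap
#'
#' The gap `x = impurity solubility - API solubility` (g compound / 100 g
#' solvent) drives how effectively washing can purify the cake without
#' dissolving product. Classes (left-closed intervals):
#' 1: `0 <= x < 1`; 2: `1 <= x < 10`; 3: `10 <= x < 20`; 4: `x >= 20`.
#' Negative `x` means the impurity is less soluble than the API and cannot be
#' fully washed out; the recommendation then depends on the impurity load
#' (molar ratio threshold 2%).
#'
#' @param api_sol,imp_sol Solubilities, g/100 g.
#' @param impurity_molar_ratio Impurity molar ratio, % (may be `NA`).
#' @return List: `class` (1..4 or `"NEGATIVE"`),
#'   `recommended_wash_volumes` (text).
#' @export
delta_solubility_class <- function(api_sol, imp_sol,
                                   impurity_molar_ratio = NA_real_) {
  if (api_sol < 0 || imp_sol < 0) stop_fmt("solubilities must be >= 0")
  x <- imp_sol - api_sol
  if (x < 0) {
    rec <- if (!is.na(impurity_molar_ratio) && impurity_molar_ratio >= 2)
      "revise crystallization or use >5-6 cake volumes"
    else ">=3 equivalent cake volumes"
    return(list(class = "NEGATIVE", delta = x,
                recommended_wash_volumes = rec))
  }
  cls <- if (x < 1) 1L else if (x < 10) 2L else if (x < 20) 3L else 4L
  list(class = cls, delta = x,
       recommended_wash_volumes = "1.5-2 equivalent cake volumes (general practice)")
}

#' Apply hard compatibility filters (warning flags)
#'
#' Adds warning flags without removing any candidate:
#' `BP_MP_NEAR_WASH_T` (boiling or melting point within the margin of the
#' wash temperature), `DENSITY_INVERSION` (wash denser than
#' `density_ratio_max` times the crystallization solvent: layer-inversion
#' risk), `API_MORE_SOLUBLE_THAN_CRYST` (product would dissolve
#' preferentially in the wash), `IMMISCIBLE`, and `ICH_REJECT` (class 1).
#' Unknown properties pass; an unknown ICH class fails only in strict mode.
#'
#' @param candidates List of [wash_candidate()].
#' @param cryst_solvent The crystallization [solvent()].
#' @param cryst_api_sol API solubility in the crystallization solvent,
#'   g/100 g.
#' @param config A [wash_filter_config()].
#' @return The candidates, flags updated.
#' @export
apply_hard_filters <- function(candidates, cryst_solvent, cryst_api_sol,
                               config = wash_filter_config()) {
  stopifnot(inherits(cryst_solvent, "solvent"))
  lapply(candidates, function(cand) {
    s <- cand$solvent
    tw <- config$wash_temperature
    m <- config$bp_mp_exclusion_margin
    near <- function(v) !is.na(v) && abs(v - tw) < m
    if (near(s$boiling_point) || near(s$melting_point))
      cand <- add_flag(cand, "BP_MP_NEAR_WASH_T")
    if (!is.na(s$density) && !is.na(cryst_solvent$density) &&
        s$density > config$density_ratio_max * cryst_solvent$density)
      cand <- add_flag(cand, "DENSITY_INVERSION")
    if (cand$api_solubility > cryst_api_sol)
      cand <- add_flag(cand, "API_MORE_SOLUBLE_THAN_CRYST")
    if (config$require_miscible && !cand$miscible_with_cryst)
      cand <- add_flag(cand, "IMMISCIBLE")
    ich <- s$ich_class
    if ((!is.na(ich) && ich == 1L) || (is.na(ich) && config$strict_ich))
      cand <- add_flag(cand, "ICH_REJECT")
    cand
  })
}

#' Apply physicochemical and safety/sustainability threshold filters
#'
#' `THRESHOLD_FAIL` when any enabled bound among `mp_max`, `bp_range`,
#' `viscosity_max`, `vapor_pressure_max` is violated; `GSK_FAIL` when the ICH
#' class is below `ich_min_class` or any of the six GSK guide scores is at or
#' below `gsk_min_score`. Unknown values pass (ICH: strict mode fails them).
#'
#' @inheritParams apply_hard_filters
#' @return The candidates, flags updated.
#' @export
apply_threshold_filters <- function(candidates,
                                    config = wash_filter_config()) {
  lapply(candidates, function(cand) {
    s <- cand$solvent
    viol <- function(v, test) !is.na(v) && test(v)
    thr <- FALSE
    if (!is.null(config$mp_max))
      thr <- thr || viol(s$melting_point, function(v) v >= config$mp_max)
    if (!is.null(config$bp_range))
      thr <- thr || viol(s$boiling_point,
                         function(v) v < config$bp_range[1] ||
                           v > config$bp_range[2])
    if (!is.null(config$viscosity_max))
      thr <- thr || viol(s$viscosity, function(v) v >= config$viscosity_max)
    if (!is.null(config$vapor_pressure_max))
      thr <- thr || viol(s$vapor_pressure,
                         function(v) v >= config$vapor_pressure_max)
    if (thr) cand <- add_flag(cand, "THRESHOLD_FAIL")
    gf <- FALSE
    if (!is.null(config$ich_min_class)) {
      ich <- s$ich_class
      if (!is.na(ich) && ich < config$ich_min_class) gf <- TRUE
      if (is.na(ich) && config$strict_ich) gf <- TRUE
    }
    if (!is.null(config$gsk_min_score)) {
      gs <- s$gsk_scores
      if (any(!is.na(gs) & gs <= config$gsk_min_score)) gf <- TRUE
    }
    if (gf) cand <- add_flag(cand, "GSK_FAIL")
    cand
  })
}

#' Apply the staged filter levels 1-4
#'
#' Level 1 applies no filtering; level 2 adds the compatibility flags
#' (miscibility, density inversion, relative API solubility, ICH class 1);
#' level 3 adds the physicochemical thresholds; level 4 adds the ICH/GSK
#' sustainability limits. Flags are monotone: a higher level never removes a
#' flag set by a lower one.
#'
#' @inheritParams apply_hard_filters
#' @param level Integer 1..4.
#' @return Candidates with flags for the requested level.
#' @export
apply_filter_level <- function(candidates, level, cryst_solvent,
                               cryst_api_sol, config = wash_filter_config()) {
  stopifnot(level %in% 1:4)
  if (level >= 2)
    candidates <- apply_hard_filters(candidates, cryst_solvent,
                                     cryst_api_sol, config)
  if (level >= 3) {
    cfg3 <- config
    cfg3$ich_min_class <- NULL
    cfg3$gsk_min_score <- NULL
    candidates <- apply_threshold_filters(candidates, cfg3)
  }
  if (level == 4)
    candidates <- apply_threshold_filters(candidates, config)
  candidates
}

# dominance: a dominates b iff a is <= on API, >= on every impurity, and
# strictly better somewhere (API minimized, impurities maximized)
dominates <- function(a, b) {
  ge <- a$impurity_solubilities >= b$impurity_solubilities
  le_api <- a$api_solubility <= b$api_solubility
  strict <- a$api_solubility < b$api_solubility ||
    any(a$impurity_solubilities > b$impurity_solubilities)
  le_api && all(ge) && strict
}

#' Non-dominated (Pareto) ranking of wash candidates
#'
#' Multi-objective sorting in the NSGA-II sense, used purely as a
#' deterministic non-dominated sorter over the finite candidate list (no
#' genetic search): objectives are minimize API solubility and maximize each
#' impurity solubility. Candidates carrying any warning flag are excluded
#' before sorting. Within a front, candidates are ordered by descending mean
#' impurity solubility, then ascending API solubility, then name (a
#' deterministic stand-in for crowding distance).
#'
#' @param candidates List of [wash_candidate()] sharing one impurity set.
#' @return `wash_ranking`: list with `fronts` (list of candidate-name
#'   character vectors), `ranking` (data frame with front, api_solubility,
#'   mean impurity solubility), `flagged` (data frame name/flags of excluded
#'   candidates).
#' @export
pareto_rank <- function(candidates) {
  stopifnot(all(vapply(candidates, inherits, logical(1), "wash_candidate")))
  if (length(candidates) > 1) {
    sets <- lapply(candidates, function(c) sort(names(c$impurity_solubilities)))
    if (!all(vapply(sets, identical, logical(1), sets[[1]])))
      stop_fmt("all candidates must share the same impurity set")
    candidates <- lapply(candidates, function(c) {
      c$impurity_solubilities <- c$impurity_solubilities[sets[[1]]]
      c
    })
  }
  flagged <- Filter(function(c) length(c$flags) > 0, candidates)
  pool <- Filter(function(c) length(c$flags) == 0, candidates)
  flagged_df <- data.frame(
    name = vapply(flagged, function(c) c$solvent$name, character(1)),
    flags = vapply(flagged, function(c) paste(c$flags, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE)
  if (!length(pool)) {
    warning("no wash candidates remain after flag removal")
    return(structure(list(fronts = list(),
                          ranking = data.frame(),
                          flagged = flagged_df),
                     class = "wash_ranking"))
  }
  n <- length(pool)
  # fast non-dominated sorting (domination counts + dominated sets)
  dom_count <- integer(n)
  dom_sets <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(pool[[i]], pool[[j]]))
        dom_sets[[i]] <- c(dom_sets[[i]], j)
      else if (dominates(pool[[j]], pool[[i]]))
        dom_count[i] <- dom_count[i] + 1L
    }
  }
  front_of <- integer(n)
  current <- which(dom_count == 0L)
  f <- 0L
  while (length(current)) {
    f <- f + 1L
    front_of[current] <- f
    nxt <- integer(0)
    for (i in current) {
      for (j in dom_sets[[i]]) {
        dom_count[j] <- dom_count[j] - 1L
        if (dom_count[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- nxt
  }
  df <- data.frame(
    name = vapply(pool, function(c) c$solvent$name, character(1)),
    front = front_of,
    api_solubility = vapply(pool, function(c) c$api_solubility, numeric(1)),
    mean_impurity_solubility =
      vapply(pool, function(c) mean(c$impurity_solubilities), numeric(1)),
    stringsAsFactors = FALSE)
  ord <- order(df$front, -df$mean_impurity_solubility, df$api_solubility,
               df$name)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df$rank <- seq_len(nrow(df))
  fronts <- split(df$name, df$front)
  structure(list(fronts = unname(fronts), ranking = df, flagged = flagged_df),
            class = "wash_ranking")
}

#' @export
print.wash_ranking <- function(x, ...) {
  cat(sprintf("<wash_ranking> %d ranked in %d fronts, %d flagged out\n",
              nrow(x$ranking), length(x$fronts), nrow(x$flagged)))
  if (nrow(x$ranking)) print(x$ranking, digits = 4)
  invisible(x)
}

#' Advisory drying-friendliness score
#'
#' Solvents that are easy to strip during drying have low boiling point, low
#' enthalpy of vaporization and high vapour pressure. The score is
#' `z(Vp) - z(Tb) - z(dHvap)` with z-scores over the candidate pool; higher
#' is more drying-friendly. Advisory only (no printed bound exists), as is
#' the mother-liquor/wash viscosity ratio also reported.
#'
#' @param candidates List of [wash_candidate()].
#' @param cryst_solvent Optional crystallization [solvent()] for the
#'   viscosity ratio.
#' @return Data frame: name, drying_score, viscosity_ratio.
#' @export
drying_friendliness <- function(candidates, cryst_solvent = NULL) {
  getp <- function(p) vapply(candidates,
                             function(c) c$solvent[[p]] %||% NA_real_,
                             numeric(1))
  z <- function(v) {
    if (all(is.na(v)) || stats::sd(v, na.rm = TRUE) == 0 ||
        is.na(stats::sd(v, na.rm = TRUE)))
      return(rep(0, length(v)))
    (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  }
  vp <- z(getp("vapor_pressure")); tb <- z(getp("boiling_point"))
  hv <- z(getp("enthalpy_vaporization"))
  score <- ifelse(is.na(vp), 0, vp) - ifelse(is.na(tb), 0, tb) -
    ifelse(is.na(hv), 0, hv)
  visc <- getp("viscosity")
  vr <- if (!is.null(cryst_solvent) && !is.na(cryst_solvent$viscosity))
    visc / cryst_solvent$viscosity else rep(NA_real_, length(visc))
  data.frame(name = vapply(candidates, function(c) c$solvent$name,
                           character(1)),
             drying_score = score, viscosity_ratio = vr,
             stringsAsFactors = FALSE)
}
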