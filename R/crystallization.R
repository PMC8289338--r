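# Stages 1-4: crystallization solvent ranking by yield and solvent use.

#' Crystallization candidate
#'
#' @param solvent A [solvent()] object or a bare solvent name.
#' @param hot_loading g API dissolved per g solvent at the dissolution
#'   temperature (supplied by the user; dissolution-temperature solubilities
#'   are inputs, not predicted here).
#' @param cold_solubility g API per g solvent at the isolation temperature.
#' @param solvent_mass Solvent mass, g (default 100 g, the basis on which the
#'   bundled case-study ranking is tabulated).
#' @return `cryst_candidate` object.
#' @export
cryst_candidate <- function(solvent, hot_loading, cold_solubility,
                            solvent_mass = 100) {
  if (is.character(solvent)) solvent <- solvent(name = solvent)
  stopifnot(inherits(solvent, "solvent"))
  if (!is.finite(hot_loading) || !is.finite(cold_solubility))
    stop_fmt("hot_loading and cold_solubility must be finite")
  if (cold_solubility < 0 || hot_loading < cold_solubility)
    stop_fmt("need hot_loading >= cold_solubility >= 0 for '%s'", solvent$name)
  if (solvent_mass <= 0) stop_fmt("solvent_mass must be > 0")
  structure(list(solvent = solvent, hot_loading = hot_loading,
                 cold_solubility = cold_solubility,
                 solvent_mass = solvent_mass),
            class = "cryst_candidate")
}

#' Crystallization yield, returned mass and solvent ratio
#'
#' Cooling-crystallization mass balance on a fixed solvent mass: the mass of
#' API returned as crystals is the drop in dissolved loading between the
#' dissolution and isolation temperatures times the solvent mass.
#'
#' @param candidate A [cryst_candidate()].
#' @return List: `return_mass` (g), `yield` (%,
#'   `100 * (hot - cold) / hot`), `solvent_ratio` (g solvent per g product;
#'   `Inf` when nothing crystallizes).
#' @examples
#' # 0.5647 g/g hot, 0.1544 g/g at isolation, 100 g solvent:
#' crystallization_yield(cryst_candidate("ethanol", 0.5647, 0.1544, 100))
#' @export
crystallization_yield <- function(candidate) {
  stopifnot(inherits(candidate, "cryst_candidate"))
  hot <- candidate$hot_loading
  if (hot == 0) stop_fmt("hot_loading is zero for '%s'", candidate$solvent$name)
  ret <- (hot - candidate$cold_solubility) * candidate$solvent_mass
  list(return_mass = ret,
       yield = 100 * (hot - candidate$cold_solubility) / hot,
       solvent_ratio = if (ret > 0) candidate$solvent_mass / ret else Inf)
}

#' Ranking grid for crystallization solvents
#'
#' A 3 x 3 grid of yield bands (rows) by solvent-consumption bands (columns).
#' Categories are numbered 1..9 row-major from (best yield, least solvent);
#' the preference order interleaves columns before dropping a yield band
#' (1, 4, 7, 2, 5, 8, 3, 6, 9 by default), i.e. a lower-yield/low-solvent
#' option beats a high-yield/high-solvent one. The printed workflow gives the
#' ordering rule and the suspension limits; the numeric band edges here are
#' configurable defaults.
#'
#' @param yield_band_edges Descending yield thresholds (%); default
#'   `c(90, 70)` giving bands `[90,100]`, `[70,90)`, `[0,70)` (left-closed at
#'   the printed edge).
#' @param volume_band_edges Ascending solvent-ratio thresholds (g solvent/g
#'   product); default `c(10, 20)` giving `(0,10)`, `[10,20)`, `[20,Inf)`.
#' @param category_order Permutation of 1..9, most preferred first.
#' @param colors Character vector of length 9, colour per category.
#' @return `ranking_grid` object.
#' @export
ranking_grid <- function(yield_band_edges = c(90, 70),
                         volume_band_edges = c(10, 20),
                         category_order = c(1, 4, 7, 2, 5, 8, 3, 6, 9),
                         colors = c("green", "green", "orange",
                                    "green", "orange", "red",
                                    "orange", "red", "red")) {
  if (is.unsorted(rev(yield_band_edges), strictly = TRUE))
    stop_fmt("yield_band_edges must be strictly decreasing")
  if (is.unsorted(volume_band_edges, strictly = TRUE))
    stop_fmt("volume_band_edges must be strictly increasing")
  if (!identical(sort(as.integer(category_order)), 1:9))
    stop_fmt("category_order must be a permutation of 1..9")
  stopifnot(length(colors) == 9)
  structure(list(yield_band_edges = yield_band_edges,
                 volume_band_edges = volume_band_edges,
                 category_order = as.integer(category_order),
                 colors = colors),
            class = "ranking_grid")
}

#' Assign a yield/solvent-ratio pair to a grid category
#'
#' Bands are left-closed at their printed edges: a yield exactly at an edge
#' falls in the better band; a solvent ratio exactly at an edge falls in the
#' worse band (consistent with "less than x g/g" phrasing).
#'
#' @param yield Percent, in `[0, 100]`.
#' @param solvent_ratio g solvent per g product, > 0 (may be `Inf`).
#' @param grid A [ranking_grid()].
#' @return List: `category` (1..9), `color`.
#' @export
assign_category <- function(yield, solvent_ratio, grid = ranking_grid()) {
  stopifnot(inherits(grid, "ranking_grid"))
  if (is.na(yield) || yield < 0 || yield > 100)
    stop_fmt("yield must be in [0, 100]")
  if (is.na(solvent_ratio) || solvent_ratio <= 0)
    stop_fmt("solvent_ratio must be > 0")
  yband <- sum(yield < grid$yield_band_edges)          # 0 = best
  vband <- sum(solvent_ratio >= grid$volume_band_edges) # 0 = best
  cat <- 3L * vband + yband + 1L
  list(category = cat, color = grid$colors[cat])
}

#' Rank crystallization solvents
#'
#' Applies the safety and suspension-density constraints, then orders the
#' survivors by grid category preference:
#' \itemize{
#'   \item ICH class 1 solvents are excluded outright; class 2 solvents are
#'     retained but annotated as not favourable.
#'   \item Candidates below `min_ratio` g solvent per g product (too dense a
#'     suspension to mix; it tends toward a paste) are excluded.
#'   \item Candidates above `max_ratio` (too dilute, excessive solvent use)
#'     are demoted: kept and flagged, ranked after all undemoted candidates.
#' }
#' Ties within a category break by descending yield, then ascending solvent
#' ratio, then name.
#'
#' @param candidates List of [cryst_candidate()].
#' @param grid A [ranking_grid()].
#' @param min_ratio,max_ratio Suspension-density limits, g solvent / g API
#'   product (defaults 3.5 and 10).
#' @return `cryst_ranking`: list with `ranking` (data frame: name, yield,
#'   return_mass, solvent_ratio, category, color, demoted, ich_note) and
#'   `excluded` (data frame: name, reason).
#' @export
rank_crystallization_solvents <- function(candidates, grid = ranking_grid(),
                                          min_ratio = 3.5, max_ratio = 10) {
  if (!length(candidates)) stop_fmt("no crystallization candidates supplied")
  stopifnot(all(vapply(candidates, inherits, logical(1), "cryst_candidate")))
  rows <- lapply(candidates, function(cc) {
    y <- crystallization_yield(cc)
    data.frame(name = cc$solvent$name,
               ich_class = cc$solvent$ich_class %||% NA_integer_,
               yield = y$yield, return_mass = y$return_mass,
               solvent_ratio = y$solvent_ratio, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  excl_reason <- rep(NA_character_, nrow(df))
  excl_reason[!is.na(df$ich_class) & df$ich_class == 1L] <-
    "ICH class 1 (hazardous): rejected"
  too_dense <- is.na(excl_reason) & df$solvent_ratio < min_ratio
  excl_reason[too_dense] <- sprintf(
    "suspension too dense: %.3g g solvent/g API < %.3g",
    df$solvent_ratio[too_dense], min_ratio)
  keep <- is.na(excl_reason)
  ranked <- df[keep, , drop = FALSE]
  excluded <- data.frame(name = df$name[!keep], reason = excl_reason[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(ranked)) {
    cats <- t(vapply(seq_len(nrow(ranked)), function(i) {
      a <- assign_category(ranked$yield[i], ranked$solvent_ratio[i], grid)
      c(a$category, match(a$category, grid$category_order))
    }, numeric(2)))
    ranked$category <- as.integer(cats[, 1])
    ranked$color <- grid$colors[ranked$category]
    ranked$demoted <- ranked$solvent_ratio > max_ratio
    ranked$ich_note <- ifelse(!is.na(ranked$ich_class) & ranked$ich_class == 2L,
                              "ICH class 2: not favorable", "")
    ord <- order(ranked$demoted, cats[, 2], -ranked$yield,
                 ranked$solvent_ratio, ranked$name)
    ranked <- ranked[ord, , drop = FALSE]
    rownames(ranked) <- NULL
    ranked$rank <- seq_len(nrow(ranked))
  }
  structure(list(ranking = ranked, excluded = excluded, grid = grid,
                 min_ratio = min_ratio, max_ratio = max_ratio),
            class = "cryst_ranking")
}

#' @export
print.cryst_ranking <- function(x, ...) {
  cat(sprintf("<cryst_ranking> %d ranked, %d excluded (min %.2g, max %.2g g/g)\n",
              nrow(x$ranking), nrow(x$excluded), x$min_ratio, x$max_ratio))
  if (nrow(x$ranking))
    print(x$ranking[, c("rank", "name", "yield", "solvent_ratio",
                        "category", "color", "demoted")], digits = 4)
  if (nrow(x$excluded)) {
    cat("excluded:\n")
    print(x$excluded)
  }
  invisible(x)
}
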