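# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive results by the most direct route
# (pairwise enumeration, hand mass balances) rather than calling the package
# internals they check.

# Pareto fronts by repeated peeling of the non-dominated set, with dominance
# written out longhand (minimize api, maximize each impurity).
oracle_pareto_fronts <- function(api, imp) {
  # api: numeric vector; imp: matrix (candidates x impurities)
  n <- length(api)
  remaining <- seq_len(n)
  front <- integer(n)
  f <- 0L
  dom <- function(i, j) {
    better_eq <- api[i] <= api[j] && all(imp[i, ] >= imp[j, ])
    strictly <- api[i] < api[j] || any(imp[i, ] > imp[j, ])
    better_eq && strictly
  }
  while (length(remaining)) {
    f <- f + 1L
    nd <- remaining[vapply(remaining, function(i)
      !any(vapply(remaining, function(j) j != i && dom(j, i), logical(1))),
      logical(1))]
    front[nd] <- f
    remaining <- setdiff(remaining, nd)
  }
  front
}

# Exhaustive pairwise comparator for the crystallization ranking: candidate a
# ranks before b iff (not demoted, demoted), else better category-order
# position, else higher yield, else lower ratio, else name.
oracle_cryst_order <- function(df, grid) {
  pos <- match(df$category, grid$category_order)
  key <- order(df$demoted, pos, -df$yield, df$solvent_ratio, df$name)
  df$name[key]
}

toy_solvent <- function(name, ...) solvent(name = name, ...)

# small two-solvent feed for mass-balance tests
toy_feed <- function(solid = 10, dissolved_api = 2, cryst_mass = 50,
                     imp = c(impA = 0.4, impB = 0.2)) {
  feed_suspension(
    solid_api_mass = solid, dissolved_api_mass = dissolved_api,
    solvent_masses = c(alcohol = cryst_mass),
    dissolved_impurity_masses = imp,
    crystal_density = 1.3,
    solvent_densities = c(alcohol = 0.8, alkane = 0.7))
}

toy_curves <- function(s0_api = 6, s1_api = 0.01, s0_imp = 30,
                       s1_imp = 0.05, imp = c("impA", "impB")) {
  mk <- function(a, b) binary_curve(data.frame(wash_fraction = c(0, 1),
                                               solubility = c(a, b)),
                                    interpolation = "log_linear")
  out <- c(list(api = mk(s0_api, s1_api)),
           stats::setNames(lapply(imp, function(i) mk(s0_imp, s1_imp)), imp))
  out
}

# species (API + impurity) conservation: wash streams add solvents but never
# solutes, so feed solute masses must equal cake + all filtrates
expect_species_conserved <- function(feed, result, tol = 1e-9) {
  streams <- c(list(result$cake), result$wash_filtrates)
  if (!is.null(result$filtration_filtrate))
    streams <- c(streams, list(result$filtration_filtrate))
  total <- function(get) sum(vapply(streams, get, numeric(1)))
  fed <- feed$solid_api_mass + feed$dissolved_api_mass
  got <- total(function(s) s$api_solid + s$api_dissolved)
  expect_equal(got, fed, tolerance = tol)
  getel <- function(v, nm) if (nm %in% names(v)) v[[nm]] else 0
  for (nm in names(feed$dissolved_impurity_masses)) {
    got <- total(function(s) getel(s$impurities, nm) +
                   getel(s$impurities_solid, nm))
    expect_equal(got, feed$dissolved_impurity_masses[[nm]], tolerance = tol)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

erfc_ref <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)
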