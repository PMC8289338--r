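#' @keywords internal
"_PACKAGE"

# ---- internal helpers -------------------------------------------------------

#' Canonical solvent-name key: lower case, collapsed whitespace
#' @noRd
canon_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

gsk_axes <- c("waste", "environment", "health", "flammability",
              "reactivity", "life_cycle")

# ---- Solvent / SolventTable -------------------------------------------------

#' Create a solvent record
#'
#' Holds the physicochemical and safety attributes used throughout the
#' screening workflow. Unknown attributes are stored as `NA` and (with the
#' exception of the ICH class in strict mode) pass any filter they cannot be
#' evaluated against.
#'
#' @param name Solvent name (matched case-insensitively after whitespace
#'   normalisation throughout the package).
#' @param density Density at ambient temperature, g/mL.
#' @param viscosity Dynamic viscosity, Pa s.
#' @param melting_point,boiling_point Degrees Celsius.
#' @param vapor_pressure Vapour pressure at ambient temperature, Pa.
#' @param enthalpy_vaporization kJ/mol.
#' @param ich_class ICH residual-solvent class, 1 (avoid) to 3 (low risk),
#'   or `NA` if the solvent is not classified.
#' @param gsk_scores Named numeric vector of the six GSK solvent-guide scores
#'   (`waste`, `environment`, `health`, `flammability`, `reactivity`,
#'   `life_cycle`), each an integer 1--10 or `NA`.
#' @param legislation_flag Optional logical legislation/EHS flag.
#' @return An object of class `solvent` (a named list).
#' @export
solvent <- function(name, density = NA_real_, viscosity = NA_real_,
                    melting_point = NA_real_, boiling_point = NA_real_,
                    vapor_pressure = NA_real_,
                    enthalpy_vaporization = NA_real_,
                    ich_class = NA_integer_,
                    gsk_scores = stats::setNames(rep(NA_real_, 6), gsk_axes),
                    legislation_flag = NA) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name)))
    stop_fmt("solvent 'name' must be a non-empty string")
  num1 <- function(x, what, positive = FALSE) {
    x <- as.numeric(x)
    if (length(x) != 1L) stop_fmt("'%s' must be length 1", what)
    if (!is.na(x) && positive && x <= 0)
      stop_fmt("'%s' must be > 0 (got %g) for solvent '%s'", what, x, name)
    x
  }
  density <- num1(density, "density", positive = TRUE)
  viscosity <- num1(viscosity, "viscosity", positive = TRUE)
  melting_point <- num1(melting_point, "melting_point")
  boiling_point <- num1(boiling_point, "boiling_point")
  if (!is.na(melting_point) && !is.na(boiling_point) &&
      melting_point >= boiling_point)
    stop_fmt("melting_point must be below boiling_point for solvent '%s'", name)
  vapor_pressure <- num1(vapor_pressure, "vapor_pressure", positive = TRUE)
  enthalpy_vaporization <- num1(enthalpy_vaporization, "enthalpy_vaporization")
  ich_class <- as.integer(ich_class)
  if (!is.na(ich_class) && !(ich_class %in% 1:3))
    stop_fmt("ich_class must be 1, 2 or 3 for solvent '%s'", name)
  gs <- stats::setNames(rep(NA_real_, 6), gsk_axes)
  if (!is.null(gsk_scores) && length(gsk_scores)) {
    if (is.null(names(gsk_scores)) && length(gsk_scores) == 6L)
      names(gsk_scores) <- gsk_axes
    bad <- setdiff(names(gsk_scores), gsk_axes)
    if (length(bad)) stop_fmt("unknown GSK axis: %s", paste(bad, collapse = ", "))
    gs[names(gsk_scores)] <- as.numeric(gsk_scores)
  }
  if (any(!is.na(gs) & (gs < 1 | gs > 10)))
    stop_fmt("GSK scores must lie in [1, 10] for solvent '%s'", name)
  structure(list(name = name, density = density, viscosity = viscosity,
                 melting_point = melting_point, boiling_point = boiling_point,
                 vapor_pressure = vapor_pressure,
                 enthalpy_vaporization = enthalpy_vaporization,
                 ich_class = ich_class, gsk_scores = gs,
                 legislation_flag = legislation_flag),
            class = "solvent")
}

#' @export
print.solvent <- function(x, ...) {
  cat(sprintf("<solvent> %s\n", x$name))
  cat(sprintf("  density %s g/mL, viscosity %s Pa.s, mp %s C, bp %s C\n",
              format(x$density), format(x$viscosity),
              format(x$melting_point), format(x$boiling_point)))
  cat(sprintf("  Vp %s Pa, dHvap %s kJ/mol, ICH class %s\n",
              format(x$vapor_pressure), format(x$enthalpy_vaporization),
              format(x$ich_class)))
  invisible(x)
}

#' Assemble a solvent table
#'
#' @param solvents List of [solvent()] objects.
#' @param provenance Free-text provenance note.
#' @return `solvent_table`: list with elements `solvents` (named by canonical
#'   name) and `provenance`.
#' @export
solvent_table <- function(solvents, provenance = "") {
  if (!length(solvents)) stop_fmt("solvent table must contain >= 1 solvent")
  stopifnot(all(vapply(solvents, inherits, logical(1), "solvent")))
  keys <- canon_name(vapply(solvents, `[[`, character(1), "name"))
  if (anyDuplicated(keys))
    stop_fmt("duplicate solvent names: %s",
             paste(unique(keys[duplicated(keys)]), collapse = ", "))
  names(solvents) <- keys
  structure(list(solvents = solvents, provenance = provenance),
            class = "solvent_table")
}

#' @export
length.solvent_table <- function(x) length(x$solvents)

#' @export
print.solvent_table <- function(x, ...) {
  cat(sprintf("<solvent_table> %d solvents", length(x)))
  if (nzchar(x$provenance)) cat(" |", x$provenance)
  cat("\n")
  invisible(x)
}

#' Look up a solvent by name (case/whitespace-insensitive)
#' @param table A `solvent_table`.
#' @param name Solvent name.
#' @return The matching [solvent()] object.
#' @export
get_solvent <- function(table, name) {
  stopifnot(inherits(table, "solvent_table"))
  s <- table$solvents[[canon_name(name)]]
  if (is.null(s)) stop_fmt("solvent '%s' not found in table", name)
  s
}

#' Convert a solvent table to a data frame
#' @param x A `solvent_table`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @export
as.data.frame.solvent_table <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  rows <- lapply(x$solvents, function(s) {
    d <- data.frame(name = s$name, density = s$density,
                    viscosity = s$viscosity,
                    melting_point = s$melting_point,
                    boiling_point = s$boiling_point,
                    vapor_pressure = s$vapor_pressure,
                    enthalpy_vaporization = s$enthalpy_vaporization,
                    ich_class = s$ich_class,
                    stringsAsFactors = FALSE)
    for (ax in gsk_axes) d[[paste0("gsk_", ax)]] <- s$gsk_scores[[ax]]
    d$legislation_flag <- s$legislation_flag
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- CSV readers / writers --------------------------------------------------

#' Read a solvent-property CSV
#'
#' Expected header: `name` (mandatory) plus any of `density`, `viscosity`,
#' `melting_point`, `boiling_point`, `vapor_pressure`,
#' `enthalpy_vaporization`, `ich_class`, `gsk_waste`, `gsk_environment`,
#' `gsk_health`, `gsk_flammability`, `gsk_reactivity`, `gsk_life_cycle`,
#' `legislation_flag`. Empty cells mean "unknown" and are kept as `NA`,
#' never zero-filled.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A [solvent_table()].
#' @export
read_solvent_table <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE,
                         na.strings = c("", "NA"))
  if (!"name" %in% names(raw))
    stop_fmt("solvent table '%s' lacks the mandatory 'name' column", path)
  numcols <- c("density", "viscosity", "melting_point", "boiling_point",
               "vapor_pressure", "enthalpy_vaporization", "ich_class",
               paste0("gsk_", gsk_axes))
  parse_num <- function(col) {
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad))
      stop_fmt("non-numeric value '%s' in column '%s', row %d of %s",
               raw[[col]][bad[1]], col, bad[1] + 1L, path)
    v
  }
  vals <- lapply(stats::setNames(numcols, numcols), parse_num)
  leg <- if ("legislation_flag" %in% names(raw))
    as.logical(raw$legislation_flag) else rep(NA, nrow(raw))
  solvents <- lapply(seq_len(nrow(raw)), function(i) {
    gs <- vapply(gsk_axes, function(ax) vals[[paste0("gsk_", ax)]][i],
                 numeric(1))
    solvent(name = raw$name[i], density = vals$density[i],
            viscosity = vals$viscosity[i],
            melting_point = vals$melting_point[i],
            boiling_point = vals$boiling_point[i],
            vapor_pressure = vals$vapor_pressure[i],
            enthalpy_vaporization = vals$enthalpy_vaporization[i],
            ich_class = vals$ich_class[i], gsk_scores = gs,
            legislation_flag = leg[i])
  })
  solvent_table(solvents, provenance = path)
}

#' Write a solvent table to CSV
#'
#' Round-trips with [read_solvent_table()]: unknown values become empty cells.
#'
#' @param table A `solvent_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_solvent_table <- function(table, path) {
  df <- as.data.frame(table)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- solubility tables ------------------------------------------------------

#' Convert between solubility units
#'
#' The package's canonical internal unit is g solute per 100 g solvent;
#' g solute per g solvent is accepted at the boundary.
#'
#' @param value Non-negative solubility value(s).
#' @param from,to One of `"g_per_100g"` or `"g_per_g"`.
#' @return Converted value(s). Round trips are exact to floating point.
#' @examples
#' convert_solubility(2.73, "g_per_100g", "g_per_g")  # 0.0273
#' @export
convert_solubility <- function(value, from = c("g_per_100g", "g_per_g"),
                               to = c("g_per_100g", "g_per_g")) {
  from <- match.arg(from); to <- match.arg(to)
  value <- as.numeric(value)
  if (any(!is.na(value) & value < 0))
    stop_fmt("solubility must be >= 0")
  if (from == to) return(value)
  if (from == "g_per_100g") value / 100 else value * 100
}

#' Read a solubility CSV
#'
#' Expected columns: `solute`, `solvent`, `temperature_C`, `solubility` and
#' optionally `units` (per-row `g_per_100g`/`g_per_g`; the `units` argument is
#' the default applied where the column is absent). Values are normalised to
#' g/100 g internally.
#'
#' @param path CSV path.
#' @param units Default unit of the `solubility` column.
#' @return A `solubility_table`: data frame with columns `solute`, `solvent`,
#'   `temperature_C`, `solubility_g_per_100g`.
#' @export
read_solubility_table <- function(path, units = c("g_per_100g", "g_per_g")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("solute", "solvent", "solubility")
  tcol <- if ("temperature_C" %in% names(raw)) "temperature_C" else "temperature"
  if (!all(need %in% names(raw)) || !tcol %in% names(raw))
    stop_fmt("solubility table '%s' must have columns solute, solvent, temperature_C, solubility",
             path)
  u <- if ("units" %in% names(raw)) raw$units else rep(units, nrow(raw))
  sol <- as.numeric(raw$solubility)
  sol <- ifelse(u == "g_per_g", sol * 100, sol)
  solubility_table(raw$solute, raw$solvent, as.numeric(raw[[tcol]]), sol)
}

#' Build a solubility table from vectors (g/100 g internal unit)
#'
#' @param solute,solvent Character vectors.
#' @param temperature_C Numeric, degrees Celsius.
#' @param solubility_g_per_100g Numeric, g solute / 100 g solvent.
#' @return `solubility_table` data frame.
#' @export
solubility_table <- function(solute, solvent, temperature_C,
                             solubility_g_per_100g) {
  df <- data.frame(solute = canon_name(solute), solvent = canon_name(solvent),
                   temperature_C = as.numeric(temperature_C),
                   solubility_g_per_100g = as.numeric(solubility_g_per_100g),
                   stringsAsFactors = FALSE)
  if (any(is.na(df$solubility_g_per_100g)))
    stop_fmt("non-numeric solubility value")
  if (any(df$solubility_g_per_100g < 0))
    stop_fmt("negative solubility for (%s, %s)",
             df$solute[df$solubility_g_per_100g < 0][1],
             df$solvent[df$solubility_g_per_100g < 0][1])
  key <- paste(df$solute, df$solvent, df$temperature_C, sep = "|")
  if (anyDuplicated(key))
    stop_fmt("duplicate (solute, solvent, temperature) entry: %s",
             key[duplicated(key)][1])
  class(df) <- c("solubility_table", "data.frame")
  df
}

#' Look up one solubility value
#'
#' @param table A `solubility_table`.
#' @param solute,solvent Names (case-insensitive).
#' @param temperature_C Temperature; if `NULL` and the (solute, solvent) pair
#'   is present at a single temperature, that record is used.
#' @param default Value returned when absent (default: error).
#' @return Solubility, g/100 g.
#' @export
lookup_solubility <- function(table, solute, solvent, temperature_C = NULL,
                              default = NULL) {
  hit <- table$solute == canon_name(solute) &
    table$solvent == canon_name(solvent)
  if (!is.null(temperature_C)) hit <- hit & table$temperature_C == temperature_C
  n <- sum(hit)
  if (n == 0L) {
    if (!is.null(default)) return(default)
    stop_fmt("no solubility record for (%s, %s)", solute, solvent)
  }
  if (n > 1L)
    stop_fmt("ambiguous solubility for (%s, %s): give temperature_C",
             solute, solvent)
  table$solubility_g_per_100g[hit]
}

#' Write a solubility table to CSV (canonical units)
#' @param table A `solubility_table`.
#' @param path Output path.
#' @export
write_solubility_table <- function(table, path) {
  df <- as.data.frame(table)
  df$units <- "g_per_100g"
  names(df)[names(df) == "solubility_g_per_100g"] <- "solubility"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- fixture generation -----------------------------------------------------

#' Generate a reproducible synthetic screening table
#'
#' Emulates a large solvent-screening list: physicochemical properties are
#' drawn from uniform/log-uniform ranges that straddle every filter threshold
#' used in the wash-selection stage (boiling point 30--250 C, density
#' 0.6--1.6 g/mL, viscosity 1e-4--0.2 Pa s, vapour pressure 10--1e5 Pa, ICH
#' class 1--3, GSK scores 1--10), so each filter has both passing and failing
#' solvents by construction. Solubilities are log-uniform over
#' [1e-3, 50] g/100 g.
#'
#' @param seed Integer seed; fixed seed gives identical output.
#' @param n_solvents Number of solvents (>= 2).
#' @param n_solutes Number of solutes (first one is treated as the API by the
#'   workflow fixtures).
#' @return List with elements `solvents` ([solvent_table()]) and
#'   `solubilities` ([solubility_table()] at 22 C).
#' @export
generate_fixture_table <- function(seed, n_solvents = 20, n_solutes = 3) {
  if (n_solvents < 2) stop_fmt("n_solvents must be >= 2")
  set.seed(as.integer(seed))
  runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))
  bp <- stats::runif(n_solvents, 30, 250)
  mp <- bp - stats::runif(n_solvents, 40, 220)
  solvents <- lapply(seq_len(n_solvents), function(i) {
    solvent(name = sprintf("fixture-solvent-%02d", i),
            density = stats::runif(1, 0.6, 1.6),
            viscosity = runif_log(1, 1e-4, 0.2),
            melting_point = mp[i], boiling_point = bp[i],
            vapor_pressure = runif_log(1, 10, 1e5),
            enthalpy_vaporization = stats::runif(1, 25, 70),
            ich_class = sample(1:3, 1),
            gsk_scores = stats::setNames(sample(1:10, 6, replace = TRUE),
                                         gsk_axes))
  })
  # guarantee at least one violation of each wash filter and one ICH class 1
  solvents[[1]]$ich_class <- 1L
  solvents[[1]]$boiling_point <- 25        # within 10 C of a 22 C wash
  solvents[[1]]$melting_point <- -60
  solvents[[2]]$density <- 1.6             # density-inversion candidate
  solvents[[2]]$viscosity <- 0.15          # viscosity threshold violation
  solvents[[2]]$vapor_pressure <- 5e4      # vapour-pressure violation
  if (n_solvents >= 3) solvents[[3]]$ich_class <- 3L
  tab <- solvent_table(solvents,
                       provenance = sprintf("synthetic fixture, seed %d", seed))
  grid <- expand.grid(solute = sprintf("fixture-solute-%d", seq_len(n_solutes)),
                      solvent = vapply(solvents, `[[`, character(1), "name"),
                      stringsAsFactors = FALSE)
  sol <- solubility_table(grid$solute, grid$solvent,
                          rep(22, nrow(grid)),
                          runif_log(nrow(grid), 1e-3, 50))
  list(solvents = tab, solubilities = sol)
}
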