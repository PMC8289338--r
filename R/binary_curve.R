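# Stage 6: solubility along the crystallization -> wash composition gradient.

#' Build a binary solubility curve
#'
#' Represents the solubility of one solute as the liquid composition moves
#' from pure crystallization solvent (wash mass fraction 0) to pure wash
#' solvent (fraction 1). An interior maximum on such a curve signals API
#' dissolution risk during washing.
#'
#' @param knots Data frame or 2-column matrix of
#'   (`wash_fraction` in `[0, 1]`, `solubility` g/100 g) pairs, strictly
#'   increasing in fraction and including both endpoints 0 and 1.
#' @param interpolation `"shape_preserving_cubic"` (default; monotone
#'   Fritsch--Carlson piecewise cubic, introduces no new local extrema
#'   between knots) or `"log_linear"` (linear in log-solubility, natural for
#'   sparse antisolvent data; requires strictly positive solubilities).
#' @param solute,cryst_solvent,wash_solvent Optional labels.
#' @return `binary_curve` object, evaluable with [solubility_at()].
#' @export
binary_curve <- function(knots,
                         interpolation = c("shape_preserving_cubic",
                                           "log_linear"),
                         solute = "", cryst_solvent = "", wash_solvent = "") {
  interpolation <- match.arg(interpolation)
  knots <- as.data.frame(knots)
  if (ncol(knots) < 2) stop_fmt("knots must have two columns")
  names(knots)[1:2] <- c("wash_fraction", "solubility")
  f <- as.numeric(knots$wash_fraction); s <- as.numeric(knots$solubility)
  if (length(f) < 2) stop_fmt("need at least 2 knots")
  if (is.unsorted(f, strictly = TRUE))
    stop_fmt("knot wash fractions must be strictly increasing")
  if (f[1] != 0 || f[length(f)] != 1)
    stop_fmt("knots must include the endpoints 0 and 1")
  if (any(s < 0)) stop_fmt("knot solubilities must be >= 0")
  if (interpolation == "log_linear" && any(s <= 0))
    stop_fmt("log_linear interpolation needs strictly positive solubilities")
  fun <- switch(interpolation,
    shape_preserving_cubic = {
      if (length(unique(s)) == 1L) {
        k <- s[1]; function(x) rep(k, length(x))
      } else {
        sf <- stats::splinefun(f, s, method = "monoH.FC")
        function(x) pmax(0, sf(x))
      }
    },
    log_linear = {
      af <- stats::approxfun(f, log(s))
      function(x) exp(af(x))
    })
  structure(list(knots = data.frame(wash_fraction = f, solubility = s),
                 interpolation = interpolation, fun = fun,
                 solute = solute, cryst_solvent = cryst_solvent,
                 wash_solvent = wash_solvent),
            class = "binary_curve")
}

#' Evaluate a binary solubility curve
#'
#' @param curve A [binary_curve()].
#' @param wash_fraction Numeric in `[0, 1]` (mass fraction of wash solvent in
#'   the solvent blend).
#' @return Solubility, g/100 g; exact at knots.
#' @export
solubility_at <- function(curve, wash_fraction) {
  stopifnot(inherits(curve, "binary_curve"))
  if (any(is.na(wash_fraction)) ||
      any(wash_fraction < 0 | wash_fraction > 1))
    stop_fmt("wash_fraction must lie in [0, 1]")
  curve$fun(wash_fraction)
}

#' Detect an interior solubility maximum (dissolution risk)
#'
#' Evaluates the curve on a fixed 1001-point grid over `[0, 1]` and reports
#' whether the interior maximum exceeds both endpoint values by a relative
#' tolerance. A solvent pair whose API curve shows such a maximum risks
#' dissolving product mid-wash; pairs without one are safe in this respect.
#'
#' @param curve A [binary_curve()].
#' @param rel_tol Relative tolerance over the endpoints (default 1e-6).
#' @return List: `has_interior_maximum` (logical), `location` (fraction or
#'   `NA`), `maximum` (value at that location).
#' @export
detect_maximum <- function(curve, rel_tol = 1e-6) {
  stopifnot(inherits(curve, "binary_curve"))
  grid <- seq(0, 1, length.out = 1001)
  v <- solubility_at(curve, grid)
  endmax <- max(v[1], v[1001])
  i <- which.max(v)
  hit <- i > 1 && i < 1001 && v[i] > endmax * (1 + rel_tol)
  list(has_interior_maximum = hit,
       location = if (hit) grid[i] else NA_real_,
       maximum = if (hit) v[i] else NA_real_)
}

#' @export
print.binary_curve <- function(x, ...) {
  cat(sprintf("<binary_curve> %s in %s -> %s (%s, %d knots)\n",
              x$solute, x$cryst_solvent, x$wash_solvent,
              x$interpolation, nrow(x$knots)))
  invisible(x)
}

#' @export
plot.binary_curve <- function(x, n = 201, ...) {
  g <- seq(0, 1, length.out = n)
  graphics::plot(g, solubility_at(x, g), type = "l",
                 xlab = "wash solvent mass fraction",
                 ylab = "solubility (g/100 g)",
                 main = sprintf("%s: %s -> %s", x$solute, x$cryst_solvent,
                                x$wash_solvent), ...)
  graphics::points(x$knots$wash_fraction, x$knots$solubility, pch = 19)
  invisible(x)
}

#' Read binary curves from CSV
#'
#' Columns: `solute`, `cryst_solvent`, `wash_solvent`, `wash_fraction`,
#' `solubility_g_per_100g`. One curve per (solute, solvent-pair) group.
#'
#' @param path CSV path.
#' @param interpolation Passed to [binary_curve()].
#' @return Named list of `binary_curve` objects, keyed
#'   `solute|cryst|wash` (canonical names).
#' @export
read_binary_curves <- function(path,
                               interpolation = "shape_preserving_cubic") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("solute", "cryst_solvent", "wash_solvent", "wash_fraction",
            "solubility_g_per_100g")
  if (!all(need %in% names(df)))
    stop_fmt("curve file '%s' must have columns %s", path,
             paste(need, collapse = ", "))
  key <- paste(canon_name(df$solute), canon_name(df$cryst_solvent),
               canon_name(df$wash_solvent), sep = "|")
  out <- lapply(split(df, key), function(d) {
    d <- d[order(d$wash_fraction), ]
    binary_curve(d[, c("wash_fraction", "solubility_g_per_100g")],
                 interpolation = interpolation,
                 solute = d$solute[1], cryst_solvent = d$cryst_solvent[1],
                 wash_solvent = d$wash_solvent[1])
  })
  out
}
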