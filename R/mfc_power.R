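# Microbial fuel cell polarization: current/power density curves, maximum
# power density (MPD), and a Thevenin-model internal-resistance diagnostic.

#' Construct a polarization sweep
#'
#' External-resistance/voltage pairs recorded while sweeping the load of a
#' sediment MFC, plus the projected anode area that normalizes densities.
#'
#' @param external_resistance ohms, > 0
#' @param voltage volts, >= 0, same length
#' @param anode_area m^2, > 0
#' @param sample_id identifier
#' @return object of class `polarization_sweep`
#' @export
polarization_sweep <- function(external_resistance, voltage, anode_area,
                               sample_id = "mfc") {
  stopifnot(length(external_resistance) == length(voltage))
  if (length(voltage) < 1) stop("empty sweep", call. = FALSE)
  if (any(external_resistance <= 0)) {
    stop("external resistances must be > 0 ohm", call. = FALSE)
  }
  if (any(voltage < 0)) stop("voltages must be >= 0 V", call. = FALSE)
  if (anode_area <= 0) stop("anode area must be > 0 m^2", call. = FALSE)
  structure(list(external_resistance = external_resistance,
                 voltage = voltage, anode_area = anode_area,
                 sample_id = sample_id),
            class = "polarization_sweep")
}

#' Current-density / power-density curve
#'
#' Per sweep point: I = V / R_ext, current density I/A (A m^-2), power
#' density V I / A reported in uW m^-2.
#'
#' @param sweep a [polarization_sweep()]
#' @return data.frame with `resistance`, `voltage`, `current_density`
#'   (A m^-2) and `power_density` (uW m^-2)
#' @export
power_density_curve <- function(sweep) {
  stopifnot(inherits(sweep, "polarization_sweep"))
  current <- sweep$voltage / sweep$external_resistance
  data.frame(resistance = sweep$external_resistance, voltage = sweep$voltage,
             current_density = current / sweep$anode_area,
             power_density = sweep$voltage * current / sweep$anode_area * 1e6)
}

#' Maximum power density of a sweep
#'
#' Empirical maximum of the power-density curve over the recorded points (no
#' interpolation, matching a plot-based reading); ties go to the larger
#' external resistance.
#'
#' @param sweep a [polarization_sweep()]
#' @return list with `mpd` (uW m^-2), `resistance_at_max` (ohm),
#'   `current_density_at_max` (A m^-2)
#' @export
max_power_density <- function(sweep) {
  curve <- power_density_curve(sweep)
  best <- max(curve$power_density)
  at <- which(curve$power_density == best)
  at <- at[which.max(curve$resistance[at])]
  list(mpd = best, resistance_at_max = curve$resistance[at],
       current_density_at_max = curve$current_density[at])
}

#' Thevenin-model internal resistance estimate
#'
#' Least-squares fit of V = Voc R / (R + Rint) to the sweep, a quality
#' diagnostic for synthetic and field sweeps. Also checks that voltage is
#' monotone nonincreasing as the load resistance decreases, as a healthy
#' polarization curve should be.
#'
#' @param sweep a [polarization_sweep()], >= 3 points
#' @return list with `voc` (V), `rint` (ohm), `converged`, `flags`
#' @export
estimate_internal_resistance <- function(sweep) {
  stopifnot(inherits(sweep, "polarization_sweep"))
  r <- sweep$external_resistance
  v <- sweep$voltage
  if (length(r) < 3) stop("need >= 3 sweep points", call. = FALSE)
  flags <- character(0)
  ord <- order(r, decreasing = TRUE)
  if (is.unsorted(rev(v[ord]))) {
    # voltage should fall as R falls; noise can break this mildly
    if (any(diff(v[ord]) > 0.05 * max(v))) flags <- c(flags, "nonmonotone_voltage")
  }
  if (stats::sd(v) == 0 && v[1] == 0) {
    return(list(voc = 0, rint = NA_real_, converged = FALSE,
                flags = c(flags, "degenerate_sweep")))
  }
  start <- list(voc = max(v) * 1.05 + 1e-6, rint = stats::median(r))
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ voc * r / (r + rint), start = start,
                      lower = c(voc = 0, rint = 1e-9),
                      data = data.frame(r = r, v = v)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(voc = NA_real_, rint = NA_real_, converged = FALSE,
                flags = c(flags, "fit_failed")))
  }
  est <- stats::coef(fit)
  list(voc = unname(est["voc"]), rint = unname(est["rint"]),
       converged = TRUE, flags = flags)
}
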