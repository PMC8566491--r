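#' Measured flow curve of a liquid sample
#'
#' Container for a steady-shear flow curve: shear rate / shear stress pairs
#' measured on a rotational rheometer. Rates must be strictly positive and
#' strictly increasing, stresses strictly positive, with at least three
#' points so that a two-parameter power law can be fitted meaningfully.
#'
#' @param shear_rate Numeric vector of shear rates (1/s).
#' @param shear_stress Numeric vector of shear stresses (Pa), same length.
#' @param temperature Measurement temperature in degrees C (metadata only;
#'   no temperature correction is ever applied). Default 40, mouth
#'   temperature.
#' @param label Optional sample label.
#' @return An object of class `flow_curve`: a list with fields
#'   `shear_rate`, `shear_stress`, `temperature`, `label`.
#' @seealso [fit_power_law()], [read_flow_curve()], [generate_flow_curve()]
#' @export
#' @examples
#' fc <- flow_curve(c(0.1, 1, 10), c(0.02, 0.05, 0.15))
flow_curve <- function(shear_rate, shear_stress, temperature = 40,
                       label = "") {
  if (!is.numeric(shear_rate) || !is.numeric(shear_stress))
    stop("shear_rate and shear_stress must be numeric", call. = FALSE)
  if (length(shear_rate) != length(shear_stress))
    stop("shear_rate and shear_stress must have equal length", call. = FALSE)
  if (length(shear_rate) < 3L)
    stop("a flow curve needs at least 3 points", call. = FALSE)
  if (anyNA(shear_rate) || anyNA(shear_stress))
    stop("flow curve contains missing values", call. = FALSE)
  if (any(shear_rate <= 0))
    stop("all shear rates must be strictly positive", call. = FALSE)
  if (any(shear_stress <= 0))
    stop("all shear stresses must be strictly positive", call. = FALSE)
  if (any(diff(shear_rate) <= 0))
    stop("shear rates must be strictly increasing", call. = FALSE)
  structure(
    list(shear_rate = as.numeric(shear_rate),
         shear_stress = as.numeric(shear_stress),
         temperature = as.numeric(temperature)[1],
         label = as.character(label)[1]),
    class = "flow_curve")
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf("<flow_curve> %s: %d points, rates %.3g-%.3g 1/s, %g degC\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$shear_rate), min(x$shear_rate), max(x$shear_rate),
              x$temperature))
  invisible(x)
}

#' Read a flow curve from a delimited text file
#'
#' Expects a header with columns `shear_rate` and `shear_stress` (an
#' optional `temperature` column is used as metadata). Field separator is
#' inferred from the file extension (`.tsv`/`.txt` = tab, otherwise comma).
#'
#' @param path Path to a CSV/TSV file holding one curve.
#' @param label Sample label; defaults to the file name without extension.
#' @return A [flow_curve()] object.
#' @export
read_flow_curve <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("shear_rate", "shear_stress")
  if (!all(need %in% names(df)))
    stop("file must have columns shear_rate, shear_stress", call. = FALSE)
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  temp <- if ("temperature" %in% names(df)) df$temperature[1] else 40
  flow_curve(df$shear_rate, df$shear_stress, temperature = temp,
             label = label)
}

#' Power-law (Ostwald-de Waele) fluid
#'
#' The constitutive law sigma = kappa * gamma_dot^n, with consistency
#' parameter `kappa` (Pa s^n) and flow index `n` (dimensionless). `n = 1`
#' recovers a Newtonian fluid of viscosity `kappa`; `n < 1` is
#' shear-thinning.
#'
#' @param kappa Consistency parameter, Pa s^n; must be > 0.
#' @param n Flow index; must be > 0.
#' @param label Optional sample label.
#' @return An object of class `power_law_fluid`.
#' @export
#' @examples
#' water_like <- power_law_fluid(kappa = 0.001, n = 1)
power_law_fluid <- function(kappa, n, label = "") {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa <= 0)
    stop("kappa must be a single positive number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("n must be a single positive number", call. = FALSE)
  structure(list(kappa = as.numeric(kappa), n = as.numeric(n),
                 label = as.character(label)[1]),
            class = "power_law_fluid")
}

#' @export
print.power_law_fluid <- function(x, ...) {
  cat(sprintf("<power_law_fluid> %s: kappa = %.4g Pa s^n, n = %.3g%s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$kappa, x$n, if (x$n == 1) " (Newtonian)" else ""))
  if (!is.null(attr(x, "r_squared")))
    cat(sprintf("  fitted on %d points, R^2 = %.5f\n",
                attr(x, "n_points"), attr(x, "r_squared")))
  invisible(x)
}

#' Fit a power law to a flow curve
#'
#' Ordinary least squares on log-transformed data: log(sigma) regressed on
#' log(gamma_dot). This weights all decades of shear rate equally, which is
#' appropriate for flow curves spanning several orders of magnitude of rate.
#' kappa is recovered as exp(intercept), n as the slope; the choice of log
#' base is internal and does not affect the estimates.
#'
#' The fitted object carries the attributes `r_squared`, `n_points`,
#' `rate_range` (the shear-rate window actually used, which is whatever the
#' input provides) and `log_loss` (residual sum of squares in natural-log
#' space, the quantity minimised).
#'
#' @param curve A [flow_curve()].
#' @return A [power_law_fluid()] with fit attributes.
#' @export
#' @examples
#' fc <- flow_curve(c(0.1, 1, 10, 100), 0.5 * c(0.1, 1, 10, 100)^0.3)
#' fit_power_law(fc)
fit_power_law <- function(curve) {
  if (!inherits(curve, "flow_curve"))
    curve <- do.call(flow_curve, as.list(curve)) # revalidate plain lists
  lx <- log(curve$shear_rate)
  ly <- log(curve$shear_stress)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  kappa <- exp(fit$coefficients[[1]])
  n <- fit$coefficients[[2]]
  rss <- sum(fit$residuals^2)
  tss <- sum((ly - mean(ly))^2)
  out <- power_law_fluid(kappa, n, label = curve$label)
  attr(out, "r_squared") <- if (tss > 0) 1 - rss / tss else 1
  attr(out, "n_points") <- length(lx)
  attr(out, "rate_range") <- range(curve$shear_rate)
  attr(out, "log_loss") <- rss
  out
}

#' Shear stress of a power-law fluid at a given shear rate
#'
#' Evaluates sigma = kappa * gamma_dot^n. Vectorised over `gamma_dot`.
#'
#' @param fluid A [power_law_fluid()].
#' @param gamma_dot Shear rate(s), 1/s; must be > 0.
#' @return Shear stress(es) in Pa.
#' @export
stress_at_rate <- function(fluid, gamma_dot) {
  stopifnot(inherits(fluid, "power_law_fluid"))
  if (!is.numeric(gamma_dot) || length(gamma_dot) == 0 ||
      any(!is.finite(gamma_dot)) || any(gamma_dot <= 0))
    stop("gamma_dot must be strictly positive", call. = FALSE)
  fluid$kappa * gamma_dot^fluid$n
}

#' Apparent (shear-rate dependent) viscosity of a power-law fluid
#'
#' Evaluates eta = kappa * gamma_dot^(n - 1) = stress / rate. For `n < 1`
#' this decreases with rate (shear-thinning); for `n = 1` it is the constant
#' Newtonian viscosity kappa.
#'
#' @inheritParams stress_at_rate
#' @return Apparent viscosity(ies) in Pa s.
#' @export
apparent_viscosity <- function(fluid, gamma_dot) {
  stopifnot(inherits(fluid, "power_law_fluid"))
  if (!is.numeric(gamma_dot) || length(gamma_dot) == 0 ||
      any(!is.finite(gamma_dot)) || any(gamma_dot <= 0))
    stop("gamma_dot must be strictly positive", call. = FALSE)
  fluid$kappa * gamma_dot^(fluid$n - 1)
}

#' Serialise a fitted power law
#'
#' Writes the record (label, kappa, n, r_squared, n_points) as one-row CSV
#' or as JSON, inferred from the file extension.
#'
#' @param fit A fitted [power_law_fluid()] from [fit_power_law()].
#' @param path Output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_power_law_fit <- function(fit, path) {
  stopifnot(inherits(fit, "power_law_fluid"))
  rec <- list(label = fit$label, kappa = fit$kappa, n = fit$n,
              r_squared = attr(fit, "r_squared"),
              n_points = attr(fit, "n_points"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  }
  invisible(path)
}
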