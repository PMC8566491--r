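#' Biophysical parameters of the tongue-palate system
#'
#' Bundles the constants describing how a liquid bolus is held and sheared
#' in the mouth during a thickness assessment. Defaults are the measured
#' literature values for low-viscosity liquid foods: lingual normal force
#' 500 mN, tongue speed 15 cm/s, a tablespoon bolus of 4 mL spread over a
#' contact disk of radius 2.5 cm (measured by licking a piece of paper),
#' assessment time 1.2 s, tongue radius of curvature 5 cm, tongue modulus
#' 3 kPa (soft tissue, in the reported 2.5-10 kPa range), palate modulus
#' 40 MPa (bony, reported 30-50 MPa), and a contact angle of 30 degrees
#' (metadata only -- wetting is used solely to argue that all samples start
#' from the same initial condition).
#'
#' The initial gap `h0` is derived as `V0 / (pi R^2)` (bolus volume over
#' contact-disk area) unless supplied explicitly, in which case the
#' volume-consistency invariant is skipped and a warning is issued.
#'
#' @param F_N Lingual normal force, N (>= 0; zero load means no squeezing).
#' @param V Lateral tongue speed, m/s.
#' @param V0 Bolus volume, m^3.
#' @param R Radius of the liquid contact disk on the tongue, m.
#' @param h0 Initial tongue-palate gap, m, or `NULL` to derive from
#'   `V0/(pi R^2)`.
#' @param t_assess Assessment (residence) time, s.
#' @param R_tongue Radius of curvature of the tongue, m.
#' @param E_tongue Young's modulus of the tongue, Pa.
#' @param E_palate Young's modulus of the palate, Pa; must exceed
#'   `E_tongue`.
#' @param theta Contact angle on the tongue surface, degrees (metadata).
#' @return An object of class `oral_parameters`.
#' @seealso [initial_gap()], [hertz_deformation()],
#'   [parallel_plate_validity()]
#' @export
#' @examples
#' p <- oral_parameters()
#' p$h0 * 1000  # initial gap in mm, about 2
oral_parameters <- function(F_N = 0.5, V = 0.15, V0 = 4e-6, R = 0.025,
                            h0 = NULL, t_assess = 1.2, R_tongue = 0.05,
                            E_tongue = 3e3, E_palate = 4e7, theta = 30) {
  num1 <- function(x, nm, min_exclusive = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(nm, " must be a single finite number", call. = FALSE)
    if (min_exclusive && x <= 0)
      stop(nm, " must be strictly positive", call. = FALSE)
    if (!min_exclusive && x < 0)
      stop(nm, " must be non-negative", call. = FALSE)
    as.numeric(x)
  }
  F_N <- num1(F_N, "F_N", min_exclusive = FALSE)
  V <- num1(V, "V"); V0 <- num1(V0, "V0"); R <- num1(R, "R")
  t_assess <- num1(t_assess, "t_assess")
  R_tongue <- num1(R_tongue, "R_tongue")
  E_tongue <- num1(E_tongue, "E_tongue")
  E_palate <- num1(E_palate, "E_palate")
  theta <- num1(theta, "theta")
  if (E_tongue >= E_palate)
    stop("E_tongue must be smaller than E_palate", call. = FALSE)
  h0_derived <- is.null(h0)
  if (h0_derived) {
    h0 <- initial_gap(V0, R)
  } else {
    h0 <- num1(h0, "h0")
    if (abs(h0 * pi * R^2 - V0) > 1e-12 * V0)
      warning("h0 overridden: gap is no longer consistent with the bolus ",
              "volume (h0 * pi * R^2 != V0)", call. = FALSE)
  }
  structure(list(F_N = F_N, V = V, V0 = V0, R = R, h0 = h0,
                 t_assess = t_assess, R_tongue = R_tongue,
                 E_tongue = E_tongue, E_palate = E_palate, theta = theta,
                 h0_derived = h0_derived),
            class = "oral_parameters")
}

#' @rdname oral_parameters
#' @export
default_oral_parameters <- function() oral_parameters()

#' @export
print.oral_parameters <- function(x, ...) {
  cat("<oral_parameters>\n")
  cat(sprintf("  F_N = %g N, V = %g m/s, V0 = %g mL, R = %g cm\n",
              x$F_N, x$V, x$V0 * 1e6, x$R * 100))
  cat(sprintf("  h0 = %.3g mm%s, t_assess = %g s\n", x$h0 * 1000,
              if (x$h0_derived) " (= V0 / pi R^2)" else " (user override)",
              x$t_assess))
  cat(sprintf("  R_tongue = %g cm, E_tongue = %g kPa, E_palate = %g MPa, theta = %g deg\n",
              x$R_tongue * 100, x$E_tongue / 1e3, x$E_palate / 1e6, x$theta))
  invisible(x)
}

#' Initial tongue-palate gap from bolus volume and contact radius
#'
#' The bolus of volume `V0` trapped under a contact disk of radius `R`
#' forms a liquid cylinder of height `h0 = V0 / (pi R^2)`; with the default
#' tablespoon volume (4 mL) and licking-test radius (2.5 cm) this is about
#' 2 mm.
#'
#' @param V0 Bolus volume, m^3; > 0.
#' @param R Contact-disk radius, m; > 0.
#' @return Gap height in m.
#' @export
initial_gap <- function(V0, R) {
  if (!is.numeric(V0) || !is.numeric(R) || any(!is.finite(c(V0, R))) ||
      any(c(V0, R) <= 0))
    stop("V0 and R must be strictly positive", call. = FALSE)
  V0 / (pi * R^2)
}

#' Hertz-type deformation of the tongue under the lingual load
#'
#' Indentation depth of a soft sphere (the tongue, radius of curvature
#' `R_tongue`, modulus `E_tongue`) pressed against the rigid palate with
#' normal force `F_N`:
#' \deqn{\delta = \left(\frac{9 F_N^2}{16\, R_{tongue} E_{tongue}^2}\right)^{1/3}.}
#' With the default parameters (0.5 N, 5 cm, 3 kPa) this gives about 7 mm,
#' small compared with the tongue size, which is what justifies treating
#' the tongue-palate system as two parallel plates.
#'
#' @param F_N Normal (lingual) force, N; >= 0 (zero load gives zero
#'   deformation).
#' @param R_tongue Tongue radius of curvature, m; > 0.
#' @param E_tongue Tongue Young's modulus, Pa; > 0.
#' @return Deformation depth in m.
#' @export
hertz_deformation <- function(F_N, R_tongue, E_tongue) {
  if (!is.numeric(F_N) || any(!is.finite(F_N)) || any(F_N < 0))
    stop("F_N must be non-negative", call. = FALSE)
  if (!is.numeric(R_tongue) || !is.numeric(E_tongue) ||
      any(!is.finite(c(R_tongue, E_tongue))) ||
      any(c(R_tongue, E_tongue) <= 0))
    stop("R_tongue and E_tongue must be strictly positive", call. = FALSE)
  (9 * F_N^2 / (16 * R_tongue * E_tongue^2))^(1 / 3)
}

#' Hertzian contact radius from indentation depth
#'
#' Standard contact-mechanics relation `a = sqrt(delta * R_tongue)` between
#' the indentation depth and the radius of the flattened contact area. With
#' delta = 7 mm and R_tongue = 5 cm this gives about 2 cm, consistent with
#' the independently measured licking radius of 2-2.5 cm.
#'
#' @param delta Indentation depth, m; > 0.
#' @param R_tongue Tongue radius of curvature, m; > 0.
#' @return Contact radius in m.
#' @export
contact_radius <- function(delta, R_tongue) {
  if (!is.numeric(delta) || !is.numeric(R_tongue) ||
      any(!is.finite(c(delta, R_tongue))) || any(c(delta, R_tongue) <= 0))
    stop("delta and R_tongue must be strictly positive", call. = FALSE)
  sqrt(delta * R_tongue)
}

#' Check the parallel-plate idealisation
#'
#' The squeeze-flow model treats tongue and palate as two rigid parallel
#' plates. That holds when (i) the Hertz deformation of the tongue is small
#' compared with its radius of curvature and (ii) the tongue is much softer
#' than the palate (modulus ratio below 1e-2), so that all compliance sits
#' in the tongue and elasto-hydrodynamic coupling can be neglected.
#'
#' @param params An [oral_parameters()] object.
#' @return A list with `delta` (m), `contact_radius` (m), `geometry_ok`
#'   (delta < R_tongue) and `stiffness_ok` (E_tongue/E_palate < 1e-2).
#' @export
parallel_plate_validity <- function(params) {
  stopifnot(inherits(params, "oral_parameters"))
  delta <- hertz_deformation(params$F_N, params$R_tongue, params$E_tongue)
  a <- if (delta > 0) contact_radius(delta, params$R_tongue) else 0
  list(delta = delta,
       contact_radius = a,
       geometry_ok = delta < params$R_tongue,
       stiffness_ok = params$E_tongue / params$E_palate < 1e-2)
}

# flat key = value config I/O -------------------------------------------

.oral_fields <- c("F_N", "V", "V0", "R", "h0", "t_assess", "R_tongue",
                  "E_tongue", "E_palate", "theta")

#' Write oral parameters to a flat key-value config file
#'
#' One `key = value` pair per line, keys exactly the field names, SI units.
#' `h0` is written only when it was user-overridden, so a round trip
#' preserves the derived-vs-explicit distinction.
#'
#' @param params An [oral_parameters()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_oral_config <- function(params, path) {
  stopifnot(inherits(params, "oral_parameters"))
  keys <- .oral_fields
  if (params$h0_derived) keys <- setdiff(keys, "h0")
  lines <- vapply(keys, function(k)
    sprintf("%s = %s", k, format(params[[k]], digits = 17)), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read oral parameters from a flat key-value config file
#'
#' Unknown keys are rejected. Missing keys fall back to the package
#' defaults; explicit overrides passed through `...` take precedence over
#' the file.
#'
#' @param path Config file path.
#' @param ... Named overrides applied on top of the file values.
#' @return An [oral_parameters()] object.
#' @export
read_oral_config <- function(path, ...) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- as.numeric(vapply(kv, `[[`, "", 2L))
  unknown <- setdiff(keys, .oral_fields)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- stats::setNames(as.list(vals), keys)
  args[names(list(...))] <- list(...)
  do.call(oral_parameters, args)
}
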