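#' Planar musculoskeletal knee model
#'
#' Builds a simplified sagittal-plane knee: a revolute joint driven by
#' seven Hill-type muscles with rigid tendons, polynomial moment arms and
#' affine normalized-fiber-length maps, plus shank inertial parameters,
#' viscous joint damping and soft joint-range stops.
#'
#' Sign convention, stated once and used everywhere: knee angle increases
#' with flexion (0 degrees = fully extended); joint torques are
#' flexion-positive, so extensor activity produces negative torque and
#' drives the angle toward 0.  Moment arms in the parameter file are signed
#' anatomically (extensors positive, flexors negative).
#'
#' @param params Path to a YAML parameter file, or a pre-parsed parameter
#'   list with the same structure; `NULL` loads the packaged defaults.
#' @return An object of class `knee_model`.
#' @export
knee_model <- function(params = NULL) {
  if (is.null(params))
    params <- system.file("extdata", "knee_params_default.yaml",
                          package = "synergylab", mustWork = TRUE)
  if (is.character(params)) params <- yaml::read_yaml(params)
  stopifnot(is.list(params), !is.null(params$muscles), !is.null(params$limb))
  if (!setequal(names(params$muscles), knee_muscles))
    stopf("parameter file must define the 7 canonical muscles")
  limb <- params$limb
  for (f in c("mass_kg", "inertia_kgm2", "com_m"))
    if (limb[[f]] <= 0) stopf("limb `%s` must be > 0", f)
  if (limb$damping_nms_per_rad < 0) stopf("limb damping must be >= 0")

  mus <- params$muscles[knee_muscles]
  model <- structure(
    list(muscles = mus, limb = limb,
         version = params$version %||% "unversioned"),
    class = "knee_model")
  ## Audit the anatomical sign convention over the working range.
  for (th in c(0, 20, 60, 90)) {
    r <- moment_arms(model, th)
    if (any(r[c("RF", "VL", "VM")] <= 0))
      stopf("extensor moment arm not positive at %g deg", th)
    if (any(r[c("Se", "BF", "MG")] >= 0))
      stopf("flexor moment arm not negative at %g deg", th)
  }
  ## Static torque grid used by the fast settle path: per-muscle active
  ## torque per unit activation and total passive torque vs angle.
  grid <- seq(-15, 135, by = 0.25)
  act <- matrix(0, nrow = 7L, ncol = length(grid),
                dimnames = list(knee_muscles, NULL))
  pas <- numeric(length(grid))
  for (i in seq_along(grid)) {
    r <- moment_arms(model, grid[i])
    for (m in seq_len(7L)) {
      p <- mus[[m]]
      lt <- fiber_length_norm(p, grid[i])
      act[m, i] <- p$fmax_n * fl_gauss(lt, p$fl_width) * r[m]
      pas[i] <- pas[i] + p$fmax_n * fp_exp(lt, p$kpe, p$e0_strain) * r[m]
    }
  }
  model$static_grid <- list(theta = grid, active = act, passive = pas)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.knee_model <- function(x, ...) {
  cat(sprintf("<knee_model> v%s: 7 muscles, limb %.2f kg / %.2f kg m^2, range [%g, %g] deg\n",
              x$version, x$limb$mass_kg, x$limb$inertia_kgm2,
              x$limb$range_deg[1], x$limb$range_deg[2]))
  invisible(x)
}

## Signed moment arms (m) of all muscles at a knee angle (deg).
moment_arms <- function(model, knee_angle) {
  vapply(model$muscles, function(p) {
    cf <- as.numeric(p$moment_arm_poly_m)
    sum(cf * knee_angle^(seq_along(cf) - 1))
  }, numeric(1))
}

## Normalized fiber length of one muscle at a knee angle (affine map).
fiber_length_norm <- function(p, knee_angle) {
  cf <- as.numeric(p$fiberlen_affine)
  cf[1] + if (length(cf) > 1) cf[2] * knee_angle else 0
}

## Hill-model factor curves.
fl_gauss <- function(lt, width) exp(-((lt - 1) / width)^2)

fp_exp <- function(lt, kpe, e0) {
  ifelse(lt > 1, (exp(kpe * (lt - 1) / e0) - 1) / (exp(kpe) - 1), 0)
}

fv_hill <- function(vnorm, shape = 0.25, ecc_max = 1.4, ecc_shape = 0.08) {
  ifelse(vnorm >= 0,
         pmax(0, (1 - vnorm) / (1 + vnorm / shape)),
         (1 + ecc_max * (-vnorm) / ecc_shape) / (1 + (-vnorm) / ecc_shape))
}

#' Hill-type muscle force
#'
#' Computes the musculotendon force `F = Fmax * (a * fL * fV + fP)`:
#' active force scaled by a Gaussian force-length curve (peak 1 at
#' normalized fiber length 1), a hyperbolic force-velocity factor (1 at
#' zero velocity, saturating above 1 when lengthening) and an exponential
#' passive curve that engages above optimal length.  The tendon is rigid,
#' so fiber length follows directly from knee angle.
#'
#' @param a Activation in `[0, 1]`.
#' @param params One muscle's parameter list (an element of
#'   `knee_model()$muscles`).
#' @param knee_angle Knee angle in degrees.
#' @param fiber_velocity Fiber shortening velocity in m/s (shortening
#'   positive).
#' @return Force in newtons (nonnegative).
#' @export
muscle_force <- function(a, params, knee_angle, fiber_velocity = 0) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a < 0 || a > 1)
    stopf("activation must be a scalar in [0, 1]")
  lt <- fiber_length_norm(params, knee_angle)
  vnorm <- fiber_velocity / (params$vmax_l0_per_s * params$l0_m)
  fl <- fl_gauss(lt, params$fl_width)
  fv <- fv_hill(vnorm, params$fv_shape, params$fv_ecc_max,
                params$fv_ecc_shape)
  fp <- fp_exp(lt, params$kpe, params$e0_strain)
  max(0, params$fmax_n * (a * fl * fv + fp))
}

## Extension-positive muscle-driven torque, exact (not gridded), at zero
## or given angular velocity (deg/s).
tau_extension <- function(model, activations, knee_angle, omega = 0) {
  tau <- 0
  for (m in seq_len(7L)) {
    p <- model$muscles[[m]]
    r <- sum(as.numeric(p$moment_arm_poly_m) *
               knee_angle^(seq_along(p$moment_arm_poly_m) - 1))
    cf <- as.numeric(p$fiberlen_affine)
    dlt <- if (length(cf) > 1) cf[2] else 0
    ## fiber shortening velocity: extensor fibers lengthen with flexion
    vfib <- -dlt * p$l0_m * omega
    tau <- tau + muscle_force(activations[m], p, knee_angle, vfib) * r
  }
  tau
}

## Soft joint-stop torque (flexion-positive) outside the joint range.
stop_torque <- function(limb, theta) {
  k <- limb$stop_stiffness_nm_per_deg
  lo <- limb$range_deg[1]; hi <- limb$range_deg[2]
  ifelse(theta < lo, k * (lo - theta),
         ifelse(theta > hi, -k * (theta - hi), 0))
}

## Gravity torque (flexion-positive) on the shank about the knee.
gravity_torque <- function(limb, theta) {
  limb$mass_kg * limb$gravity_ms2 * limb$com_m * sin(theta * pi / 180)
}

#' Net muscle-driven knee torque
#'
#' Flexion-positive net joint torque from muscle forces, gravity and
#' passive fiber terms: `tau = -sum(F_m * r_m) + tau_gravity` with
#' anatomically signed moment arms, so extensor-dominant activation yields
#' negative torque (extension, angle driven toward 0).
#'
#' @param activations Numeric vector of 7 activations in `[0, 1]` (an
#'   [activation_vector()] or plain numeric in canonical order).
#' @param state A [model_state()] (knee angle deg, angular velocity deg/s).
#' @param model A [knee_model()].
#' @return Torque in newton metres, flexion-positive.
#' @export
knee_torque <- function(activations, state, model) {
  stopifnot(inherits(model, "knee_model"))
  a <- as.numeric(activations)
  if (length(a) != 7L || any(!is.finite(a)) || any(a < 0 | a > 1))
    stopf("activations must be 7 values in [0, 1]")
  -tau_extension(model, a, state$angle, state$velocity) +
    gravity_torque(model$limb, state$angle)
}

#' Kinematic state of the knee joint
#'
#' @param angle Knee flexion angle in degrees (0 = fully extended).
#' @param velocity Angular velocity in deg/s (flexion-positive).
#' @return An object of class `model_state`.
#' @export
model_state <- function(angle, velocity = 0) {
  assert_scalar_num(angle, "angle")
  assert_scalar_num(velocity, "velocity")
  structure(list(angle = angle, velocity = velocity), class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf("<model_state> angle %.3f deg, velocity %.3f deg/s\n",
              x$angle, x$velocity))
  invisible(x)
}
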