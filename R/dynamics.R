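## Net flexion-positive static torque at angle theta under constant
## activations and external torque (no velocity terms).
static_net_torque <- function(model, activations, theta, external_torque) {
  -tau_extension(model, activations, theta, 0) +
    gravity_torque(model$limb, theta) +
    stop_torque(model$limb, theta) + external_torque
}

## Same, vectorized over the model's precomputed angle grid.
static_net_torque_grid <- function(model, activations, external_torque) {
  g <- model$static_grid
  tau_ext <- as.numeric(crossprod(model$static_grid$active,
                                  as.numeric(activations))) + g$passive
  -tau_ext + gravity_torque(model$limb, g$theta) +
    stop_torque(model$limb, g$theta) + external_torque
}

## Fast settle path: locate static equilibria by sign changes on the grid,
## refine with uniroot, and return the stable equilibrium nearest the
## initial angle.  Stability means net torque decreasing through the root
## (a restoring torque); if only unstable roots exist the nearest is
## returned, flagged unsettled.
settle_static <- function(model, activations, external_torque, theta0) {
  ## already at equilibrium (includes torque-free plateaus): stay put
  if (abs(static_net_torque(model, activations, theta0,
                            external_torque)) < 1e-9)
    return(list(angle = theta0, settled = TRUE))
  fg <- static_net_torque_grid(model, activations, external_torque)
  grid <- model$static_grid$theta
  sc <- which(fg[-1] * fg[-length(fg)] <= 0)
  sc <- sc[fg[sc] != 0 | fg[sc + 1] != 0]
  if (!length(sc)) {
    ## net torque one-signed over the whole extended grid: saturate
    return(list(angle = if (fg[1] > 0) max(grid) else min(grid),
                settled = FALSE))
  }
  roots <- vapply(sc, function(i) {
    stats::uniroot(function(th)
      static_net_torque(model, activations, th, external_torque),
      lower = grid[i], upper = grid[i + 1],
      f.lower = fg[i], f.upper = fg[i + 1], tol = 1e-7)$root
  }, numeric(1))
  stable <- fg[sc + 1] < fg[sc]
  cand <- if (any(stable)) roots[stable] else roots
  list(angle = cand[which.min(abs(cand - theta0))], settled = any(stable))
}

#' Advance the knee state by one time step
#'
#' Semi-implicit Euler update of (angle, velocity) under the net torque:
#' muscle-driven torque, external torque, viscous damping and soft
#' joint-range stops.
#'
#' @param state A [model_state()].
#' @param activations 7 activations in `[0, 1]`.
#' @param model A [knee_model()].
#' @param external_torque External torque in N m, flexion-positive (a
#'   counter torque opposing extension is positive).
#' @param dt Time step in seconds, in `(0, 0.01]`.
#' @return The updated `model_state`.
#' @export
step_state <- function(state, activations, model, external_torque = 0, dt = 0.002) {
  stopifnot(inherits(state, "model_state"), inherits(model, "knee_model"))
  if (!is.finite(state$angle) || !is.finite(state$velocity))
    stopf("non-finite state")
  if (dt <= 0 || dt > 0.01) stopf("`dt` must be in (0, 0.01]")
  limb <- model$limb
  tau <- knee_torque(activations, state, model) + external_torque +
    stop_torque(limb, state$angle) -
    limb$damping_nms_per_rad * state$velocity * pi / 180
  alpha <- tau / limb$inertia_kgm2 * 180 / pi   # deg/s^2
  v <- state$velocity + alpha * dt
  model_state(state$angle + v * dt, v)
}

#' Settle the limb under constant inputs
#'
#' Finds the resting state of the limb under fixed activations and external
#' torque.  `method = "dynamic"` integrates the damped dynamics from
#' `state` until the angular speed stays below `settle_tol` for 0.5 s
#' continuously (or `t_max` is reached); `method = "static"` solves the
#' static torque balance directly by root finding on the joint range and
#' returns the stable equilibrium nearest the initial angle.  The two
#' agree for this damped single-joint system; the static path is orders of
#' magnitude faster and is the default for torque measurement and fitness
#' evaluation.
#'
#' @inheritParams step_state
#' @param state Initial [model_state()].
#' @param t_max Maximum integration time in seconds (dynamic method).
#' @param settle_tol Angular-speed tolerance in deg/s (dynamic method).
#' @param method `"dynamic"` or `"static"`.
#' @return A `model_state` with attributes `settled` (logical) and
#'   `elapsed` (simulated seconds; 0 for the static path).
#' @export
settle <- function(activations, model, external_torque = 0,
                   state = model_state(60), t_max = 10, settle_tol = 1,
                   method = c("dynamic", "static"), dt = 0.002) {
  method <- match.arg(method)
  stopifnot(inherits(state, "model_state"))
  if (t_max <= 0) stopf("`t_max` must be > 0")
  a <- as.numeric(activations)
  if (length(a) != 7L || any(!is.finite(a)) || any(a < 0 | a > 1))
    stopf("activations must be 7 values in [0, 1]")

  if (method == "static") {
    eq <- settle_static(model, a, external_torque, state$angle)
    out <- model_state(eq$angle, 0)
    attr(out, "settled") <- eq$settled
    attr(out, "elapsed") <- 0
    return(out)
  }

  hold_needed <- 0.5
  hold <- 0
  s <- state
  elapsed <- 0
  while (elapsed < t_max) {
    s <- step_state(s, a, model, external_torque, dt)
    elapsed <- elapsed + dt
    hold <- if (abs(s$velocity) < settle_tol) hold + dt else 0
    if (hold >= hold_needed) break
  }
  attr(s, "settled") <- hold >= hold_needed
  attr(s, "elapsed") <- elapsed
  s
}

#' Balancing (counter) torque measurement
#'
#' Measures the muscle-driven knee torque at a target angle the way the
#' virtual experiment does: starting from zero, a counter torque opposing
#' the muscle-driven torque is increased in steps of `increment`; each time,
#' the limb is settled under activations plus counter torque from the
#' target angle.  Once the settled angle crosses back over the target, the
#' counter torque is refined by bisection until the settled angle is within
#' `tol` of the target (and the torque bracket is tight).  At equilibrium
#' the counter torque magnitude equals the muscle-driven torque.
#'
#' @inheritParams settle
#' @param target_angle Target knee angle in degrees.
#' @param increment Coarse counter-torque increment in N m.
#' @param tol Angle tolerance in degrees.
#' @param max_iter Iteration cap over increments plus bisection steps.
#' @return An object of class `torque_measurement`: `balancing_torque`
#'   (N m, magnitude), `direction` (+1 when the counter torque flexes,
#'   i.e. muscles drive extension), `settled_angle`, `iterations`,
#'   `converged`.
#' @export
balancing_torque <- function(activations, target_angle, model,
                             increment = 1, tol = 0.5,
                             method = c("static", "dynamic"),
                             max_iter = 1000) {
  method <- match.arg(method)
  stopifnot(inherits(model, "knee_model"))
  assert_scalar_num(target_angle, "target_angle")
  if (increment <= 0) stopf("`increment` must be > 0")
  lo_r <- model$limb$range_deg[1]; hi_r <- model$limb$range_deg[2]
  if (target_angle < lo_r || target_angle > hi_r)
    stopf("target angle outside joint range [%g, %g]", lo_r, hi_r)

  settle_at <- function(ext) {
    s <- settle(activations, model, external_torque = ext,
                state = model_state(target_angle), method = method)
    s$angle
  }
  iter <- 0L
  th0 <- settle_at(0); iter <- iter + 1L
  if (abs(th0 - target_angle) <= tol && abs(th0 - target_angle) < 1e-6) {
    return(structure(list(balancing_torque = 0, direction = 0,
                          settled_angle = th0, iterations = iter,
                          converged = TRUE),
                     class = "torque_measurement"))
  }
  ## muscles drive extension -> settled below target -> flexing counter (+)
  dir <- if (th0 < target_angle) +1 else -1
  ext <- 0; th <- th0
  crossed <- FALSE
  while (iter < max_iter) {
    ext_next <- ext + dir * increment
    th_next <- settle_at(ext_next); iter <- iter + 1L
    if ((dir > 0 && th_next >= target_angle) ||
        (dir < 0 && th_next <= target_angle)) {
      crossed <- TRUE
      lo <- ext; hi <- ext_next
      break
    }
    ext <- ext_next; th <- th_next
  }
  if (!crossed)
    return(structure(list(balancing_torque = abs(ext), direction = dir,
                          settled_angle = th, iterations = iter,
                          converged = FALSE),
                     class = "torque_measurement"))
  ## bisection: settled angle is monotone in the counter torque on the
  ## stable branch; tighten both the angle and the torque bracket
  repeat {
    mid <- (lo + hi) / 2
    th_mid <- settle_at(mid); iter <- iter + 1L
    if ((dir > 0 && th_mid >= target_angle) ||
        (dir < 0 && th_mid <= target_angle)) hi <- mid else lo <- mid
    tight <- abs(hi - lo) <= max(1e-3, 1e-4 * abs(hi))
    if ((abs(th_mid - target_angle) <= tol && tight) || iter >= max_iter)
      break
  }
  est <- (lo + hi) / 2
  th_est <- settle_at(est); iter <- iter + 1L
  structure(list(balancing_torque = abs(est), direction = dir,
                 settled_angle = th_est,
                 iterations = iter,
                 converged = abs(th_est - target_angle) <= tol),
            class = "torque_measurement")
}

#' @export
print.torque_measurement <- function(x, ...) {
  cat(sprintf("<torque_measurement> %.3f N m (%s), settled %.3f deg, %d iters, %s\n",
              x$balancing_torque,
              if (x$direction >= 0) "extension-opposing" else "flexion-opposing",
              x$settled_angle, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
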