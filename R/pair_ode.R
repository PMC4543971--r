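# Pair-approximation moment equations of the adaptive two-type SIS model.
#
# The hierarchy of motif equations is truncated at pairs with the standard
# closure [X_u Y_v Z_w] = [X_u Y_v][Y_v Z_w]/[Y_v] (ordered convention, no
# subtraction of the focal link).  In the ordered convention the symmetry
# bookkeeping factors of the unordered presentation disappear; see
# moment_state.R for the layout.

.EPS_DENOM <- 1e-12

# right-hand side on the raw named vector; works for real and complex input
# (complex-step differentiation relies on the purely arithmetic form).
# Straight-line scalar code: this is the innermost kernel of Newton,
# continuation and integration.
.moment_rhs_raw <- function(x, params) {
  beta <- params$beta; mu <- params$mu; omega <- params$omega
  psa <- params$psi_a; psb <- params$psi_b

  Ia <- x[["I_a"]]; Ib <- x[["I_b"]]
  Sa <- params$p_a - Ia; Sb <- params$p_b - Ib
  SSaa <- x[["SS_aa"]]; SSab <- x[["SS_ab"]]; SSbb <- x[["SS_bb"]]
  SIaa <- x[["SI_aa"]]; SIab <- x[["SI_ab"]]
  SIba <- x[["SI_ba"]]; SIbb <- x[["SI_bb"]]
  IIaa <- x[["II_aa"]]; IIab <- x[["II_ab"]]; IIbb <- x[["II_bb"]]

  Ga <- SIaa + SIab
  Gb <- SIba + SIbb
  # guarded mean infected-neighbour pressure per susceptible of each type;
  # when S_u vanishes so do all pair densities anchored on S_u, so zeroing
  # the ratio keeps the extinct plane exactly invariant in floating point.
  Wa <- if (Re(Sa) < .EPS_DENOM) 0 else Ga / Sa
  Wb <- if (Re(Sb) < .EPS_DENOM) 0 else Gb / Sb
  Stot <- Sa + Sb
  rs <- if (Re(Stot) < .EPS_DENOM) 0 else omega / Stot

  bpa <- beta * psa; bpb <- beta * psb

  out <- c(
    I_a = -mu * Ia + bpa * Ga,
    I_b = -mu * Ib + bpb * Gb,
    SS_aa = 2 * mu * SIaa - 2 * bpa * SSaa * Wa + rs * 2 * Ga * Sa,
    SS_ab = mu * (SIab + SIba) - SSab * (bpb * Wb + bpa * Wa) +
      rs * (Ga * Sb + Gb * Sa),
    SS_bb = 2 * mu * SIbb - 2 * bpb * SSbb * Wb + rs * 2 * Gb * Sb,
    SI_aa = mu * IIaa - (mu + bpa + omega) * SIaa +
      bpa * SSaa * Wa - bpa * SIaa * Wa,
    SI_ab = mu * IIab - (mu + bpa + omega) * SIab +
      bpb * SSab * Wb - bpa * SIab * Wa,
    SI_ba = mu * IIab - (mu + bpb + omega) * SIba +
      bpa * SSab * Wa - bpb * SIba * Wb,
    SI_bb = mu * IIbb - (mu + bpb + omega) * SIbb +
      bpb * SSbb * Wb - bpb * SIbb * Wb,
    II_aa = -2 * mu * IIaa + 2 * bpa * SIaa + 2 * bpa * SIaa * Wa,
    II_ab = -2 * mu * IIab + bpa * SIab + bpb * SIba +
      bpa * SIab * Wa + bpb * SIba * Wb,
    II_bb = -2 * mu * IIbb + 2 * bpb * SIbb + 2 * bpb * SIbb * Wb)
  out
}

#' Time derivative of the moment-closure system
#'
#' Evaluates the pair-approximation right-hand side: recovery at rate `mu`,
#' transmission along susceptible-infected pairs at rate `beta * psi_u`
#' (with `u` the type of the susceptible end), rewiring of
#' susceptible-infected pairs at rate `omega` towards a uniformly chosen
#' susceptible partner, and triplet-mediated external infection closed at
#' the pair level.  The total ordered link density is conserved exactly.
#'
#' @param state a [moment_state()].
#' @param params a [model_params()].
#' @return named numeric vector of the 12 time derivatives.
#' @export
moment_rhs <- function(state, params) {
  x <- as.numeric(state[MOMENT_NAMES])
  names(x) <- MOMENT_NAMES
  .moment_rhs_raw(as.list(x), params)
}

#' Pair-approximation triplet closure
#'
#' Closes the density of ordered triplet chains `X_u - Y_v - Z_w` as
#' `[X_u Y_v] [Y_v Z_w] / [Y_v]` (ordered convention).  When the middle-node
#' fraction vanishes the chain density is returned as 0; any pair density
#' anchored on an empty class vanishes at least as fast, so this is the
#' continuous extension.
#'
#' @param xy_density,yz_density ordered pair densities sharing the middle
#'   class.
#' @param y_fraction node fraction of the middle class.
#' @return closed triplet density.
#' @examples
#' closure_triplet(4, 2, 0.5)  # 16
#' @export
closure_triplet <- function(xy_density, yz_density, y_fraction) {
  if (y_fraction < .EPS_DENOM) return(0)
  xy_density * yz_density / y_fraction
}

#' Disease-free moment states
#'
#' With no infected nodes every moment derivative vanishes, whatever the
#' susceptible-susceptible link configuration: the extinct states form a
#' plane parametrized by the SS densities.  The default configuration is the
#' random-mixing (Erdos-Renyi) point `SS[u][v] = <k> p_u p_v`.
#'
#' @param params a [model_params()].
#' @param ss_config optional ordered SS triple `(SS_aa, SS_ab, SS_bb)` with
#'   `SS_aa + 2 SS_ab + SS_bb = mean_degree`.
#' @return a [moment_state()] on the extinct plane.
#' @export
disease_free_state <- function(params, ss_config = NULL) {
  k <- params$mean_degree
  if (is.null(ss_config)) {
    ss_config <- c(k * params$p_a^2, k * params$p_a * params$p_b,
                   k * params$p_b^2)
  } else {
    if (length(ss_config) != 3L || any(ss_config < 0))
      stop("ss_config must be three non-negative densities", call. = FALSE)
    tot <- ss_config[1] + 2 * ss_config[2] + ss_config[3]
    if (abs(tot - k) > 1e-8 * max(1, k))
      stop("ss_config violates link conservation: ordered total ", tot,
           " != mean degree ", k, call. = FALSE)
  }
  moment_state(I_a = 0, I_b = 0,
               SS_aa = ss_config[1], SS_ab = ss_config[2],
               SS_bb = ss_config[3],
               SI_aa = 0, SI_ab = 0, SI_ba = 0, SI_bb = 0,
               II_aa = 0, II_ab = 0, II_bb = 0)
}

#' Integrate the moment equations
#'
#' Stiff-capable adaptive integration (lsoda).  Tight tolerances are the
#' default because the conservation laws are monitored rather than enforced:
#' the drift of the ordered link total over the run is checked against
#' `10 * rtol * mean_degree`.  Small negative undershoots (above `-atol`)
#' are clipped to zero and counted in the `clipped` attribute.
#'
#' @param state0 initial [moment_state()].
#' @param params a [model_params()].
#' @param t_max final time.
#' @param n_out number of output times (including 0).
#' @param rtol,atol relative and absolute solver tolerances.
#' @return data.frame with column `time` followed by the 12 moment
#'   variables; attributes `clipped` (count of clipped undershoots) and
#'   `conservation_drift` (max absolute drift of the ordered link total).
#' @export
integrate_moments <- function(state0, params, t_max, n_out = 201,
                              rtol = 1e-10, atol = 1e-12) {
  x0 <- as.numeric(state0[MOMENT_NAMES])
  names(x0) <- MOMENT_NAMES
  deriv <- function(t, y, parms) {
    list(as.numeric(.moment_rhs_raw(as.list(y), params)))
  }
  times <- seq(0, t_max, length.out = n_out)
  sol <- deSolve::ode(y = x0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("moment integration failed at t = ", max(sol[, "time"]),
         call. = FALSE)
  out <- as.data.frame(unclass(sol))
  vals <- as.matrix(out[MOMENT_NAMES])
  undershoot <- vals < 0
  clipped <- sum(undershoot & vals >= -atol)
  if (any(vals < -atol))
    warning("negative moment values beyond -atol (min ", min(vals), ")")
  vals[undershoot & vals >= -atol] <- 0
  out[MOMENT_NAMES] <- vals
  drift <- max(abs(vals %*% MOMENT_LINK_COEF[MOMENT_NAMES] -
                     link_density_total(state0)))
  if (drift > 10 * rtol * max(1, params$mean_degree))
    warning("link-conservation drift ", drift, " exceeds budget")
  attr(out, "clipped") <- clipped
  attr(out, "conservation_drift") <- drift
  out
}

# linear solve with a minimum-norm fallback: without rewiring (omega = 0)
# the per-type-pair link totals are individually conserved, which leaves the
# reduced Jacobian rank-deficient on purpose; the pseudoinverse step then
# converges to the steady state on the conserved leaf of the initial guess.
.lin_solve <- function(A, b) {
  out <- tryCatch(solve(A, b), error = function(e) NULL)
  if (!is.null(out) && all(is.finite(out))) return(out)
  sv <- svd(A)
  keep <- sv$d > 1e-10 * max(sv$d)
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep]))
}

# --- reduced (independent) coordinates ------------------------------------
# SS_bb is eliminated through the ordered link-conservation law; all Newton
# and continuation computations run in the remaining 11 coordinates.

.REDUCED_NAMES <- setdiff(MOMENT_NAMES, "SS_bb")

reduce_state <- function(state) {
  x <- as.numeric(state[MOMENT_NAMES])
  names(x) <- MOMENT_NAMES
  x[.REDUCED_NAMES]
}

expand_state <- function(y, params) {
  x <- numeric(12)
  names(x) <- MOMENT_NAMES
  x[.REDUCED_NAMES] <- y[.REDUCED_NAMES]
  coef <- MOMENT_LINK_COEF[.REDUCED_NAMES]
  x[["SS_bb"]] <- params$mean_degree - sum(coef * y[.REDUCED_NAMES])
  moment_state(x, check = FALSE)
}

.reduced_rhs <- function(y, params, beta = NULL) {
  if (!is.null(beta)) params$beta <- beta
  full <- expand_state(y, params)
  as.numeric(.moment_rhs_raw(as.list(unclass(full)),
                             params))[match(.REDUCED_NAMES, MOMENT_NAMES)]
}

#' Jacobian of the moment system
#'
#' Machine-precision derivatives by complex-step differentiation of the
#' purely arithmetic right-hand side (no subtractive cancellation, step
#' `1e-20`).  `reduced = TRUE` returns the 11x11 Jacobian in the independent
#' coordinates (SS_bb eliminated by conservation, chain rule applied);
#' otherwise the raw 12x12 matrix.
#'
#' @param state a [moment_state()].
#' @param params a [model_params()].
#' @param reduced return the 11x11 independent-coordinate Jacobian.
#' @return square numeric matrix with dimension names.
#' @export
moment_jacobian <- function(state, params, reduced = TRUE) {
  x <- as.numeric(state[MOMENT_NAMES])
  names(x) <- MOMENT_NAMES
  h <- 1e-20
  J <- matrix(0, 12, 12, dimnames = list(MOMENT_NAMES, MOMENT_NAMES))
  for (j in seq_len(12)) {
    xc <- as.list(x)
    xc[[j]] <- complex(real = x[[j]], imaginary = h)
    J[, j] <- Im(.moment_rhs_raw(xc, params)) / h
  }
  if (!reduced) return(J)
  keep <- .REDUCED_NAMES
  coef <- MOMENT_LINK_COEF[keep]
  Jr <- J[keep, keep, drop = FALSE]
  # SS_bb = <k> - sum(coef * y): chain rule for the eliminated column
  Jr - outer(J[keep, "SS_bb"], coef)
}

# derivative of the reduced rhs w.r.t. beta, by complex step
.reduced_rhs_dbeta <- function(y, params, beta) {
  h <- 1e-20
  p2 <- params
  p2$beta <- complex(real = beta, imaginary = h)
  full <- expand_state(y, params)
  xs <- as.numeric(unclass(full))
  names(xs) <- MOMENT_NAMES
  d <- Im(.moment_rhs_raw(as.list(xs), p2)) / h
  d[match(.REDUCED_NAMES, MOMENT_NAMES)]
}

#' Newton solver for moment steady states
#'
#' Damped Newton iteration on the 11 independent coordinates (conservation
#' eliminated structurally, so every iterate satisfies the link total
#' exactly).  Convergence requires the max-norm residual of the reduced
#' right-hand side below `tol`.
#'
#' @param guess starting [moment_state()].
#' @param params a [model_params()].
#' @param tol residual tolerance (max-norm).
#' @param max_iter Newton iteration cap.
#' @return converged [moment_state()] with attributes `residual` and
#'   `iterations`.
#' @export
find_steady_state <- function(guess, params, tol = 1e-10, max_iter = 50) {
  y <- reduce_state(guess)
  f <- .reduced_rhs(y, params)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) {
      out <- expand_state(y, params)
      attr(out, "residual") <- max(abs(f))
      attr(out, "iterations") <- it - 1L
      return(out)
    }
    J <- moment_jacobian(expand_state(y, params), params, reduced = TRUE)
    step <- .lin_solve(J, -f)
    if (any(!is.finite(step)))
      stop("singular Jacobian in Newton iteration (residual ",
           max(abs(f)), ")", call. = FALSE)
    lambda <- 1
    repeat {
      y_new <- y + lambda * step
      f_new <- .reduced_rhs(y_new, params)
      if (max(abs(f_new)) < max(abs(f)) || lambda < 1 / 64) break
      lambda <- lambda / 2
    }
    y <- y_new
    f <- f_new
  }
  if (max(abs(f)) < tol) {
    out <- expand_state(y, params)
    attr(out, "residual") <- max(abs(f))
    attr(out, "iterations") <- max_iter
    return(out)
  }
  stop("Newton iteration did not converge; last residual ", max(abs(f)),
       call. = FALSE)
}

#' Endemic steady state by relaxation plus Newton polish
#'
#' Integrates from a lightly infected random-mixing state until the dynamics
#' is close to an attractor, then polishes with [find_steady_state()].
#' Returns NULL when the trajectory collapses to the extinct plane (no
#' endemic attractor reached from this initial condition).
#'
#' @param params a [model_params()].
#' @param i0 initial prevalence split across types proportionally.
#' @param t_relax relaxation horizon before the Newton polish.
#' @return endemic [moment_state()] or NULL.
#' @export
endemic_state <- function(params, i0 = 0.2, t_relax = 2e4) {
  s0 <- initial_moment_state(params, i0)
  tr <- integrate_moments(s0, params, t_max = t_relax, n_out = 51,
                          rtol = 1e-8, atol = 1e-10)
  xT <- moment_state(as.numeric(tr[nrow(tr), MOMENT_NAMES]), check = FALSE)
  if (xT[["I_a"]] + xT[["I_b"]] < 1e-6) return(NULL)
  st <- find_steady_state(xT, params)
  if (st[["I_a"]] + st[["I_b"]] < 1e-6) return(NULL)
  st
}

#' Random-mixing moment state at a given prevalence
#'
#' Product-form state: infection assigned independently of type and degree,
#' links distributed as `<k>` times the product of endpoint-class fractions.
#' This is the pair-level image of a fresh Erdos-Renyi network with randomly
#' assigned epidemic states.
#'
#' @param params a [model_params()].
#' @param prevalence total infected fraction, split across types in
#'   proportion to `p_a`, `p_b`.
#' @return a [moment_state()].
#' @export
initial_moment_state <- function(params, prevalence) {
  stopifnot(prevalence >= 0, prevalence <= 1)
  k <- params$mean_degree
  I <- c(a = params$p_a, b = params$p_b) * prevalence
  S <- c(a = params$p_a, b = params$p_b) - I
  moment_state(
    I_a = I[["a"]], I_b = I[["b"]],
    SS_aa = k * S[["a"]]^2, SS_ab = k * S[["a"]] * S[["b"]],
    SS_bb = k * S[["b"]]^2,
    SI_aa = k * S[["a"]] * I[["a"]], SI_ab = k * S[["a"]] * I[["b"]],
    SI_ba = k * S[["b"]] * I[["a"]], SI_bb = k * S[["b"]] * I[["b"]],
    II_aa = k * I[["a"]]^2, II_ab = k * I[["a"]] * I[["b"]],
    II_bb = k * I[["b"]]^2)
}
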