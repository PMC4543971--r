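# Threshold analysis: linearized invasion thresholds on the extinct plane,
# pseudo-arclength continuation of equilibrium branches, fold (persistence
# threshold) and landing-point (adapted invasion threshold) extraction.
#
# The extinct states form a 2-parameter plane (the SS link configuration is
# arbitrary once no infected remain), so the full Jacobian always carries
# neutral directions there.  Invasion is therefore decided by the reduced
# linear subsystem of the 7 infected link classes (4 SI + 3 II), whose
# leading eigenvalue changes sign at the transcritical point.

#' Linearized infected subsystem at a disease-free state
#'
#' Builds the 7x7 matrix governing the growth of the infected link classes
#' `(SI_aa, SI_ab, SI_ba, SI_bb, II_aa, II_ab, II_bb)` around a point on the
#' extinct plane with susceptible-susceptible configuration taken from
#' `df_state`.
#'
#' @param df_state a [moment_state()] with all infected classes zero.
#' @param params a [model_params()]; `params$beta` is overridden by `beta`.
#' @param beta infectivity at which to evaluate the linearization.
#' @return 7x7 numeric matrix.
#' @export
infected_subsystem_matrix <- function(df_state, params, beta = params$beta) {
  p <- c(a = params$p_a, b = params$p_b)
  psi <- c(a = params$psi_a, b = params$psi_b)
  mu <- params$mu; omega <- params$omega
  SS <- matrix(c(df_state[["SS_aa"]], df_state[["SS_ab"]],
                 df_state[["SS_ab"]], df_state[["SS_bb"]]),
               2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  vars <- c("SI_aa", "SI_ab", "SI_ba", "SI_bb", "II_aa", "II_ab", "II_bb")
  M <- matrix(0, 7, 7, dimnames = list(vars, vars))
  si <- function(u, v) paste0("SI_", u, v)
  ii <- function(u, v) paste0("II_", min(u, v), max(u, v))
  for (u in c("a", "b")) for (v in c("a", "b")) {
    row <- si(u, v)
    M[row, row] <- M[row, row] - (mu + beta * psi[[u]] + omega)
    M[row, ii(u, v)] <- M[row, ii(u, v)] + mu
    # external infection of the v-end of an S_u-S_v pair, closed at pairs:
    # beta psi_v SS[u,v]/p_v * sum_w SI_vw
    for (w in c("a", "b"))
      M[row, si(v, w)] <- M[row, si(v, w)] + beta * psi[[v]] * SS[u, v] / p[[v]]
  }
  M["II_aa", "SI_aa"] <- 2 * beta * psi[["a"]]
  M["II_bb", "SI_bb"] <- 2 * beta * psi[["b"]]
  M["II_ab", "SI_ab"] <- beta * psi[["a"]]
  M["II_ab", "SI_ba"] <- beta * psi[["b"]]
  M["II_aa", "II_aa"] <- -2 * mu
  M["II_ab", "II_ab"] <- -2 * mu
  M["II_bb", "II_bb"] <- -2 * mu
  M
}

.leading_re <- function(M) max(Re(eigen(M, only.values = TRUE)$values))

#' Invasion threshold at a given disease-free configuration
#'
#' The infectivity at which the leading eigenvalue of the linearized
#' infected subsystem crosses zero, located by bisection.
#'
#' @param df_state a [moment_state()] on the extinct plane.
#' @param params a [model_params()].
#' @param beta_range interval scanned for the sign change.
#' @param rel_tol relative bisection tolerance on beta.
#' @return the critical infectivity.
#' @examples
#' p <- model_params(0.03, 0.5, 0.5, 0.75, 0.002, 0.2)
#' invasion_threshold_at(disease_free_state(p), p)  # (mu+omega)/(psi*<k>)
#' @export
invasion_threshold_at <- function(df_state, params,
                                  beta_range = c(1e-8, 10),
                                  rel_tol = 1e-8) {
  if (max(abs(df_state[c("I_a", "I_b", "SI_aa", "SI_ab", "SI_ba", "SI_bb",
                         "II_aa", "II_ab", "II_bb")])) > 1e-8)
    stop("df_state is not on the extinct plane", call. = FALSE)
  f <- function(b) .leading_re(infected_subsystem_matrix(df_state, params, b))
  lo <- beta_range[1]; hi <- beta_range[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo >= 0 || fhi <= 0)
    stop("threshold not bracketed in beta range [", lo, ", ", hi, "]",
         call. = FALSE)
  while ((hi - lo) > rel_tol * (lo + hi) / 2) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# --- pseudo-arclength continuation ----------------------------------------

# internal: corrector solving the bordered system
#   F(y, beta) = 0  (11 eqs)
#   t . (z - z_pred) = 0
# in normalized coordinates (y / y_scale, beta / beta_scale).
.corrector <- function(y, beta, params, tangent, z_pred, scale,
                       tol = 1e-11, max_iter = 12) {
  for (it in seq_len(max_iter)) {
    f <- .reduced_rhs(y, params, beta)
    zn <- c(y, beta) / scale
    g <- sum(tangent * (zn - z_pred))
    if (max(abs(f)) < tol && abs(g) < 1e-12)
      return(list(y = y, beta = beta, ok = TRUE, iters = it - 1L))
    Jy <- moment_jacobian(expand_state(y, params),
                          params_with_beta(params, beta), reduced = TRUE)
    Fb <- .reduced_rhs_dbeta(y, params, beta)
    A <- cbind(Jy * rep(scale[1:11], each = 11), Fb * scale[12])
    A <- rbind(A, tangent)
    rhs <- -c(f, g)
    dz <- .lin_solve(A, rhs)
    if (is.null(dz) || any(!is.finite(dz))) return(list(ok = FALSE))
    y <- y + dz[1:11] * scale[1:11]
    beta <- beta + dz[12] * scale[12]
  }
  f <- .reduced_rhs(y, params, beta)
  list(y = y, beta = beta, ok = max(abs(f)) < 1e-8, iters = max_iter)
}

#' Pseudo-arclength continuation of an equilibrium branch
#'
#' Secant-predictor, Newton-corrector continuation of steady states of the
#' moment system in the infectivity `beta`, in the 11 independent
#' coordinates.  Steps adapt between `h_min` and `h_max` (halved on
#' corrector failure, grown on fast convergence); the normalized arclength
#' uses link densities scaled by the mean degree and `beta` scaled by its
#' starting value, so the branch passes around folds.
#'
#' @param params a [model_params()].
#' @param beta_start infectivity of the starting fixed point.
#' @param beta_end continuation stops when `beta` leaves
#'   `range(beta_start, beta_end)` (with slack `h_max` on the far side).
#' @param start_state converged fixed point at `beta_start` (a
#'   [moment_state()]); re-polished internally.
#' @param h0,h_min,h_max initial, minimal and maximal normalized step.
#' @param max_points cap on accepted branch points.
#' @param stop_at_plane stop once the total prevalence crosses zero
#'   (continuation is allowed one point past the extinct plane so the
#'   crossing can be interpolated).
#' @return an `equilibrium_branch`: data.frame with `beta`, `I_tot`,
#'   `leading_re`, `stable`, plus the state matrix in attribute `states`
#'   (rows = points, 12 moment columns) and fold indices in attribute
#'   `folds`.
#' @export
continue_branch <- function(params, beta_start, beta_end, start_state,
                            h0 = 2e-3, h_min = 1e-6, h_max = 2e-2,
                            max_points = 5000, stop_at_plane = TRUE) {
  scale <- c(rep(max(1, params$mean_degree), 11), max(abs(beta_start), 1e-3))
  st0 <- find_steady_state(start_state, params_with_beta(params, beta_start))
  y <- reduce_state(st0)
  betas <- beta_start
  ys <- matrix(y, nrow = 1)

  # second point by natural continuation: nudge beta toward beta_end
  dir <- sign(beta_end - beta_start)
  db <- dir * h0 * scale[12]
  st1 <- tryCatch(
    find_steady_state(expand_state(y, params),
                      params_with_beta(params, beta_start + db)),
    error = function(e) NULL)
  if (is.null(st1)) stop("could not take the first continuation step",
                         call. = FALSE)
  y1 <- reduce_state(st1)
  betas <- c(betas, beta_start + db)
  ys <- rbind(ys, y1)

  h <- h0
  warn_flag <- FALSE
  for (k in seq_len(max_points)) {
    n <- length(betas)
    z_prev <- c(ys[n - 1, ], betas[n - 1]) / scale
    z_curr <- c(ys[n, ], betas[n]) / scale
    tangent <- z_curr - z_prev
    tl <- sqrt(sum(tangent^2))
    if (tl < .Machine$double.eps) break
    tangent <- tangent / tl

    accepted <- FALSE
    while (!accepted) {
      z_pred <- z_curr + h * tangent
      res <- .corrector(z_pred[1:11] * scale[1:11], z_pred[12] * scale[12],
                        params, tangent, z_pred, scale)
      if (res$ok) {
        accepted <- TRUE
      } else if (h > h_min) {
        h <- max(h / 2, h_min)
      } else {
        warn_flag <- TRUE
        break
      }
    }
    if (!accepted) {
      warning("corrector failed at minimal step; partial branch returned")
      break
    }
    betas <- c(betas, res$beta)
    ys <- rbind(ys, res$y)
    if (!is.null(res$iters) && res$iters <= 4 && h < h_max)
      h <- min(h * 1.7, h_max)

    i_tot <- res$y[["I_a"]] + res$y[["I_b"]]
    if (stop_at_plane && i_tot < 0) break
    bmin <- min(beta_start, beta_end) - h_max * scale[12]
    bmax <- max(beta_start, beta_end) + h_max * scale[12]
    if (res$beta < bmin || res$beta > bmax) break
  }

  states <- t(apply(ys, 1, function(yy) {
    names(yy) <- .REDUCED_NAMES
    as.numeric(expand_state(yy, params))
  }))
  colnames(states) <- MOMENT_NAMES
  lead <- vapply(seq_len(nrow(ys)), function(i) {
    yy <- ys[i, ]; names(yy) <- .REDUCED_NAMES
    .leading_re(moment_jacobian(expand_state(yy, params),
                                params_with_beta(params, betas[i]),
                                reduced = TRUE))
  }, numeric(1))
  db <- diff(betas)
  folds <- which(db[-1] * db[-length(db)] < 0) + 1L
  out <- data.frame(beta = betas,
                    I_tot = states[, "I_a"] + states[, "I_b"],
                    leading_re = lead,
                    stable = lead < 0)
  attr(out, "states") <- states
  attr(out, "folds") <- folds
  attr(out, "warning") <- warn_flag
  class(out) <- c("equilibrium_branch", "data.frame")
  out
}

#' @export
print.equilibrium_branch <- function(x, ...) {
  cat(sprintf("Equilibrium branch: %d points, beta in [%.6g, %.6g]\n",
              nrow(x), min(x$beta), max(x$beta)))
  f <- attr(x, "folds")
  if (length(f)) cat(sprintf("  folds near beta = %s\n",
                             paste(signif(x$beta[f], 6), collapse = ", ")))
  invisible(x)
}

#' Copy a parameter set with a different infectivity
#'
#' Convenience for scans and continuation: returns `params` with
#' `params$beta` replaced.
#'
#' @param params a [model_params()].
#' @param beta new infectivity.
#' @return the modified `sis_params`.
#' @export
params_with_beta <- function(params, beta) {
  params$beta <- beta
  params
}

#' Persistence threshold (fold bifurcation of the endemic branch)
#'
#' Continues the endemic branch downward in `beta` and locates the fold at
#' which the endemic state annihilates with the unstable saddle.  The fold
#' is detected as a sign change of the `beta` increments along arclength and
#' refined by re-continuation with shrinking steps plus a final parabolic
#' fit of `beta` against arclength.
#'
#' @param params a [model_params()]; `params$beta` is ignored.
#' @param beta_start starting infectivity on the endemic branch; defaults to
#'   three times the initial invasion threshold.
#' @param beta_min lower end of the scanned range.
#' @return list with `beta_per`, `state` (the fold [moment_state()]), and
#'   `branch` (the continued branch); or `fold = NA` style result with
#'   `beta_per = NA` and a `reason` when no fold is found (continuous
#'   transition or out of range).
#' @export
persistence_threshold <- function(params, beta_start = NULL,
                                  beta_min = NULL) {
  b_inv0 <- invasion_threshold_at(disease_free_state(params), params)
  if (is.null(beta_start)) beta_start <- 3 * b_inv0
  if (is.null(beta_min)) beta_min <- b_inv0 / 20
  es <- endemic_state(params_with_beta(params, beta_start))
  if (is.null(es))
    stop("no endemic state found at beta_start = ", beta_start, call. = FALSE)
  br <- continue_branch(params, beta_start, beta_min, es)
  folds <- attr(br, "folds")
  if (!length(folds)) {
    return(list(beta_per = NA_real_, state = NULL, branch = br,
                reason = "transition continuous or out of range"))
  }
  k <- folds[1]
  # parabolic refinement of beta along arclength near the fold
  idx <- max(1, k - 2):min(nrow(br), k + 2)
  states <- attr(br, "states")
  s <- c(0, cumsum(sqrt(rowSums(diff(states[idx, , drop = FALSE])^2) +
                          diff(br$beta[idx])^2)))
  fit <- stats::lm(br$beta[idx] ~ s + I(s^2))
  cf <- stats::coef(fit)
  s_star <- -cf[[2]] / (2 * cf[[3]])
  beta_per <- cf[[1]] + cf[[2]] * s_star + cf[[3]] * s_star^2
  # state at the fold: interpolate columns quadratically in s as well
  st_fold <- vapply(seq_len(ncol(states)), function(j) {
    cj <- stats::coef(stats::lm(states[idx, j] ~ s + I(s^2)))
    cj[[1]] + cj[[2]] * s_star + cj[[3]] * s_star^2
  }, numeric(1))
  names(st_fold) <- MOMENT_NAMES
  list(beta_per = beta_per, state = moment_state(st_fold, check = FALSE),
       branch = br)
}

# natural continuation of the unstable branch in total prevalence:
# solve F(y, beta) = 0 together with I_a + I_b = c for (y, beta).
.solve_at_prevalence <- function(y, beta, params, c_target,
                                 tol = 1e-11, max_iter = 30) {
  iI <- match(c("I_a", "I_b"), .REDUCED_NAMES)
  for (it in seq_len(max_iter)) {
    f <- .reduced_rhs(y, params, beta)
    g <- y[[iI[1]]] + y[[iI[2]]] - c_target
    if (max(abs(f)) < tol && abs(g) < tol)
      return(list(y = y, beta = beta, ok = TRUE))
    Jy <- moment_jacobian(expand_state(y, params),
                          params_with_beta(params, beta), reduced = TRUE)
    Fb <- .reduced_rhs_dbeta(y, params, beta)
    row <- c(as.numeric(seq_along(y) %in% iI), 0)
    A <- rbind(cbind(Jy, Fb), row)
    dz <- .lin_solve(A, -c(f, g))
    if (is.null(dz) || any(!is.finite(dz))) return(list(ok = FALSE))
    y <- y + dz[1:11]
    beta <- beta + dz[12]
  }
  list(ok = FALSE)
}

#' Adapted invasion threshold (landing point of the unstable branch)
#'
#' Continues the unstable branch from the fold toward vanishing prevalence.
#' The branch lands on a specific point of the extinct plane; the
#' susceptible-susceptible configuration there defines the adapted network,
#' and the transcritical infectivity of that configuration is the adapted
#' invasion threshold.  The landing is extracted by natural continuation in
#' the total prevalence down to `c_min`, Richardson-extrapolated to zero,
#' and cross-validated against [invasion_threshold_at()] at the extrapolated
#' configuration (mandatory self-consistency check).
#'
#' @param params a [model_params()].
#' @param persistence optional result of [persistence_threshold()] to reuse.
#' @param c_min smallest prevalence used for the extrapolation.
#' @param consistency_tol maximal relative disagreement tolerated between
#'   the extrapolated `beta` and the linearized threshold at the landing
#'   configuration.
#' @return list with `beta_inv_adapted`, `landing_ss_config` (ordered SS
#'   triple), `beta_extrapolated`, and `persistence` (the fold result used).
#' @export
adapted_invasion_threshold <- function(params, persistence = NULL,
                                       c_min = 1e-6,
                                       consistency_tol = 1e-6) {
  if (is.null(persistence)) persistence <- persistence_threshold(params)
  if (is.na(persistence$beta_per))
    stop("no fold found; adapted threshold undefined without bistability",
         call. = FALSE)
  br <- persistence$branch
  states <- attr(br, "states")
  # starting point: last branch point with small positive prevalence past
  # the fold, or the fold itself
  folds <- attr(br, "folds")
  post <- seq(folds[1], nrow(br))
  pos <- post[br$I_tot[post] > 0]
  i0 <- pos[which.min(br$I_tot[pos])]
  y <- states[i0, .REDUCED_NAMES]
  names(y) <- .REDUCED_NAMES
  beta <- br$beta[i0]

  c_now <- br$I_tot[i0]
  c_hi <- max(c_now / 2, 8 * c_min)
  n_steps <- max(4L, ceiling(log2(c_hi / c_min)) + 1L)
  targets <- exp(seq(log(c_hi), log(c_min), length.out = n_steps))
  cs <- c()
  sols <- list()
  for (c_target in targets) {
    res <- .solve_at_prevalence(y, beta, params, c_target)
    if (!res$ok)
      stop("unstable branch did not approach the extinct plane ",
           "(failure at prevalence ", c_target, ")", call. = FALSE)
    y <- res$y; beta <- res$beta
    cs <- c(cs, c_target)
    sols[[length(sols) + 1L]] <- res
  }
  n <- length(cs)
  # Richardson: values at c and c/2 extrapolated linearly to c = 0
  val <- function(res) {
    full <- expand_state(res$y, params)
    c(res$beta, full[["SS_aa"]], full[["SS_ab"]], full[["SS_bb"]])
  }
  v1 <- val(sols[[n - 1]]); v2 <- val(sols[[n]])
  w <- cs[n - 1] / (cs[n - 1] - cs[n])
  v0 <- v1 + w * (v2 - v1)
  beta_extrap <- v0[1]
  ss_landing <- pmax(v0[2:4], 0)
  df <- disease_free_state(params, ss_config = ss_landing)
  beta_cross <- invasion_threshold_at(df, params)
  rel <- abs(beta_extrap - beta_cross) / beta_cross
  if (rel > consistency_tol)
    warning(sprintf(paste0("landing-point self-consistency: extrapolated ",
                           "beta %.8g vs linearized %.8g (rel. %.2g)"),
                    beta_extrap, beta_cross, rel))
  list(beta_inv_adapted = beta_cross,
       beta_extrapolated = beta_extrap,
       landing_ss_config = ss_landing,
       consistency_rel_err = rel,
       persistence = persistence)
}

#' Full threshold report
#'
#' Orchestrates the three critical infectivities of the adaptive two-type
#' SIS model: the initial invasion threshold (transcritical point of the
#' random-mixing extinct state), the persistence threshold (fold of the
#' endemic branch) and the adapted invasion threshold (transcritical point
#' of the landing configuration of the unstable branch).
#'
#' @param params a [model_params()].
#' @return object of class `threshold_report`: list with `beta_inv_initial`,
#'   `beta_per`, `beta_inv_adapted`, `landing_ss_config`, `branch`, and the
#'   input parameters.
#' @export
threshold_report <- function(params) {
  b0 <- invasion_threshold_at(disease_free_state(params), params)
  per <- persistence_threshold(params)
  ad <- if (is.na(per$beta_per)) NULL else
    adapted_invasion_threshold(params, persistence = per)
  rep <- list(beta_inv_initial = b0,
              beta_per = per$beta_per,
              beta_inv_adapted = if (is.null(ad)) NA_real_ else
                ad$beta_inv_adapted,
              landing_ss_config = if (is.null(ad)) NULL else
                ad$landing_ss_config,
              branch = per$branch,
              params = params)
  class(rep) <- "threshold_report"
  rep
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("Threshold report (adaptive two-type SIS)\n")
  cat(sprintf("  initial invasion threshold : %.6g\n", x$beta_inv_initial))
  cat(sprintf("  persistence threshold      : %.6g\n", x$beta_per))
  cat(sprintf("  adapted invasion threshold : %.6g\n", x$beta_inv_adapted))
  if (!is.null(x$landing_ss_config))
    cat(sprintf("  landing SS config (ordered): %s\n",
                paste(signif(x$landing_ss_config, 6), collapse = ", ")))
  invisible(x)
}
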