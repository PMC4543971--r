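#' Model parameters for the adaptive two-type SIS model
#'
#' Validates and assembles the full parameter set of the adaptive
#' susceptible-infected-susceptible model with two node types.  Type A nodes
#' are at least as susceptible as type B nodes (`psi_a >= psi_b > 0`); the
#' type composition `p_a` is fixed in time.  Rates are continuous-time Markov
#' rates in arbitrary (but consistent) time units.
#'
#' @param beta base transmission rate per susceptible-infected link; the
#'   effective rate along a link is `beta * psi_i` with `i` the type of the
#'   susceptible end.
#' @param psi_a,psi_b dimensionless susceptibility multipliers of types A
#'   and B.
#' @param p_a fraction of nodes of type A (`p_b = 1 - p_a`).
#' @param mu recovery rate per infected node.
#' @param omega rewiring rate per susceptible-infected link.
#' @param n_nodes,n_links network size N and link count K used for
#'   simulations; the mean degree `2 * n_links / n_nodes` also sets the total
#'   link density of the moment equations.
#'
#' @return An object of class `sis_params`: a named list with the arguments
#'   plus the derived `p_b`, `mean_degree` and `mean_psi`.
#' @examples
#' p <- model_params(beta = 0.032, psi_a = 0.65, psi_b = 0.05, p_a = 0.75,
#'                   mu = 0.002, omega = 0.2, n_nodes = 1e5, n_links = 1e6)
#' p$mean_degree  # 20
#' p$mean_psi     # 0.5
#' @export
model_params <- function(beta, psi_a, psi_b, p_a, mu, omega,
                         n_nodes = 1e4, n_links = 1e5) {
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  for (nm in c("beta", "psi_a", "psi_b", "p_a", "mu", "omega",
               "n_nodes", "n_links")) {
    v <- get(nm)
    stop_if(!is.numeric(v) || length(v) != 1L || !is.finite(v),
            sprintf("%s must be a single finite number", nm))
  }
  stop_if(beta < 0, "beta must be non-negative")
  stop_if(mu <= 0, "mu must be positive")
  stop_if(omega < 0, "omega must be non-negative")
  stop_if(psi_b <= 0, "psi_b must be positive")
  stop_if(psi_a < psi_b, "psi_a must be >= psi_b")
  stop_if(p_a <= 0 || p_a > 1, "p_a must lie in (0, 1]")
  stop_if(n_nodes < 2 || n_nodes != round(n_nodes),
          "n_nodes must be an integer >= 2")
  stop_if(n_links < 0 || n_links != round(n_links),
          "n_links must be a non-negative integer")
  stop_if(n_links > n_nodes * (n_nodes - 1) / 2,
          "n_links exceeds the number of possible simple-graph edges")

  p <- list(beta = beta, psi_a = psi_a, psi_b = psi_b,
            p_a = p_a, p_b = 1 - p_a, mu = mu, omega = omega,
            n_nodes = n_nodes, n_links = n_links,
            mean_degree = 2 * n_links / n_nodes,
            mean_psi = p_a * psi_a + (1 - p_a) * psi_b)
  class(p) <- "sis_params"
  p
}

#' @export
print.sis_params <- function(x, ...) {
  cat("Adaptive two-type SIS parameters\n")
  cat(sprintf("  beta = %g, mu = %g, omega = %g\n", x$beta, x$mu, x$omega))
  cat(sprintf("  psi_a = %g, psi_b = %g, p_a = %g  (<psi> = %g)\n",
              x$psi_a, x$psi_b, x$p_a, x$mean_psi))
  cat(sprintf("  N = %g, K = %g  (<k> = %g)\n",
              x$n_nodes, x$n_links, x$mean_degree))
  invisible(x)
}

#' Type composition from a target mean susceptibility
#'
#' Solves for the type-A fraction `p_a` such that the population mean
#' susceptibility `p_a * psi_a + (1 - p_a) * psi_b` equals `mean_psi`.
#' Used to build "balanced" parameter families in which heterogeneity
#' (`psi_a` vs `psi_b`) varies while the mean susceptibility is held fixed.
#'
#' @param psi_a,psi_b susceptibility multipliers, `psi_a > psi_b`.
#' @param mean_psi target mean susceptibility, strictly between `psi_b`
#'   and `psi_a`.
#' @return `p_a` in (0, 1).
#' @examples
#' solve_pa_for_mean_susceptibility(0.65, 0.05, 0.5)  # 0.75
#' @export
solve_pa_for_mean_susceptibility <- function(psi_a, psi_b, mean_psi) {
  if (!(psi_b < mean_psi && mean_psi < psi_a))
    stop("mean_psi must lie strictly between psi_b and psi_a; ",
         "no valid composition exists otherwise", call. = FALSE)
  (mean_psi - psi_b) / (psi_a - psi_b)
}

#' Swap the roles of the two node types
#'
#' Relabels A as B and vice versa: swaps `psi_a`/`psi_b` and replaces `p_a`
#' by `1 - p_a`.  The model is invariant under this relabelling when all
#' per-type quantities are swapped along with it, which makes the swapped
#' parameter set a convenient symmetry oracle.  Note the swapped set violates
#' the `psi_a >= psi_b` convention unless the model is homogeneous, so the
#' result is returned unvalidated with the same class.
#'
#' @param params a `sis_params` object.
#' @return a `sis_params` object with types relabelled.
#' @keywords internal
#' @export
swap_types <- function(params) {
  q <- params
  q$psi_a <- params$psi_b
  q$psi_b <- params$psi_a
  q$p_a <- params$p_b
  q$p_b <- params$p_a
  q
}
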