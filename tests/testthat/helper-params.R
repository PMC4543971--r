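# Shared fixtures: the study parameter set (heterogeneous susceptibility,
# slow recovery, fast rewiring) at full and desk-scaled network sizes, and
# small deterministic graphs used across files.

study_params <- function(beta = 0.032, n_nodes = 1e5, n_links = 1e6) {
  model_params(beta = beta, psi_a = 0.65, psi_b = 0.05, p_a = 0.75,
               mu = 0.002, omega = 0.2, n_nodes = n_nodes, n_links = n_links)
}

homog_params <- function(beta = 0.03, omega = 0.2, psi = 0.5,
                         n_nodes = 1e5, n_links = 1e6) {
  model_params(beta = beta, psi_a = psi, psi_b = psi, p_a = 0.75,
               mu = 0.002, omega = omega, n_nodes = n_nodes,
               n_links = n_links)
}

random_moment_state <- function(params, positive = TRUE) {
  # random strictly positive state honouring the conservation laws
  x <- runif(12, 0.05, 1)
  names(x) <- adaptivesis:::MOMENT_NAMES
  x[["I_a"]] <- runif(1, 0.05, 0.95) * params$p_a
  x[["I_b"]] <- runif(1, 0.05, 0.95) * params$p_b
  coef <- adaptivesis:::MOMENT_LINK_COEF
  link_names <- names(coef)[coef > 0]
  tot <- sum(coef[link_names] * x[link_names])
  x[link_names] <- x[link_names] * params$mean_degree / tot
  moment_state(x)
}

# one-type adaptive SIS pair approximation in the aggregated ordered
# convention (I, SS, SI, II with SS/II counting both directions); derived
# independently of the two-type right-hand side.
one_type_rhs <- function(I, SS, SI, II, beta, psi, mu, omega) {
  S <- 1 - I
  W <- if (S < 1e-12) 0 else SI / S
  c(I = -mu * I + beta * psi * SI,
    SS = 2 * mu * SI - 2 * beta * psi * SS * W + 2 * omega * SI,
    SI = mu * II - (mu + beta * psi + omega) * SI +
      beta * psi * SS * W - beta * psi * SI * W,
    II = -2 * mu * II + 2 * beta * psi * SI + 2 * beta * psi * SI * W)
}

# embed an aggregate one-type state on the product (type-symmetric)
# invariant manifold of the two-type system
embed_product_state <- function(I, SS, SI, II, p_a) {
  p <- c(a = p_a, b = 1 - p_a)
  moment_state(
    I_a = p[["a"]] * I, I_b = p[["b"]] * I,
    SS_aa = p[["a"]]^2 * SS, SS_ab = p[["a"]] * p[["b"]] * SS,
    SS_bb = p[["b"]]^2 * SS,
    SI_aa = p[["a"]]^2 * SI, SI_ab = p[["a"]] * p[["b"]] * SI,
    SI_ba = p[["b"]] * p[["a"]] * SI, SI_bb = p[["b"]]^2 * SI,
    II_aa = p[["a"]]^2 * II, II_ab = p[["a"]] * p[["b"]] * II,
    II_bb = p[["b"]]^2 * II)
}

aggregate_moment_rhs <- function(d) {
  c(I = d[["I_a"]] + d[["I_b"]],
    SS = d[["SS_aa"]] + 2 * d[["SS_ab"]] + d[["SS_bb"]],
    SI = d[["SI_aa"]] + d[["SI_ab"]] + d[["SI_ba"]] + d[["SI_bb"]],
    II = d[["II_aa"]] + 2 * d[["II_ab"]] + d[["II_bb"]])
}
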