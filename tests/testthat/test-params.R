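test_that("parameter validation accepts the study set and derives fields", {
  p <- study_params()
  expect_equal(p$mean_degree, 20)
  expect_equal(p$mean_psi, 0.5)
  expect_equal(p$p_b, 0.25)
  # homogeneous boundary psi_a == psi_b is allowed
  expect_silent(model_params(0.01, 0.5, 0.5, 0.75, 0.002, 0.2))
})

test_that("parameter invariant violations name the offending field", {
  expect_error(model_params(0.01, 0.65, 0, 0.75, 0.002, 0.2), "psi_b")
  expect_error(model_params(0.01, 0.05, 0.65, 0.75, 0.002, 0.2), "psi_a")
  expect_error(model_params(-0.01, 0.65, 0.05, 0.75, 0.002, 0.2), "beta")
  expect_error(model_params(0.01, 0.65, 0.05, 0.75, 0, 0.2), "mu")
  expect_error(model_params(0.01, 0.65, 0.05, 1.2, 0.002, 0.2), "p_a")
  expect_error(model_params(0.01, 0.65, 0.05, 0.75, 0.002, 0.2,
                            n_nodes = 5, n_links = 11), "n_links")
})

test_that("type composition solves the mean-susceptibility constraint", {
  expect_equal(solve_pa_for_mean_susceptibility(0.65, 0.05, 0.5), 0.75)
  expect_equal(solve_pa_for_mean_susceptibility(0.6, 0.4, 0.5), 0.5)
  expect_error(solve_pa_for_mean_susceptibility(0.65, 0.05, 0.05),
               "strictly between")
  expect_error(solve_pa_for_mean_susceptibility(0.65, 0.05, 0.7),
               "strictly between")
  # round trip with the mean-psi derivation in model_params
  pa <- solve_pa_for_mean_susceptibility(0.9, 0.1, 0.5)
  p <- model_params(0.01, 0.9, 0.1, pa, 0.002, 0.2)
  expect_equal(p$mean_psi, 0.5)
})

test_that("ordered/unordered conversion halves same-class pairs and inverts", {
  p <- study_params()
  df <- disease_free_state(p)
  u <- to_paper_convention(df)
  expect_equal(u[["SS_aa"]], 5.625)     # ordered 11.25 halved
  expect_equal(u[["SS_ab"]], 3.75)      # distinct classes unchanged
  # total unordered density equals K/N, ordered equals <k>
  coefu <- rep(1, 12); names(coefu) <- names(u)
  link_names <- setdiff(names(u), c("I_a", "I_b"))
  expect_equal(sum(u[link_names]), p$n_links / p$n_nodes)
  expect_equal(link_density_total(df), p$mean_degree)
  set.seed(42)
  for (i in 1:20) {
    s <- random_moment_state(p)
    expect_equal(as.numeric(from_paper_convention(to_paper_convention(s))),
                 as.numeric(s))
  }
})

test_that("type relabelling commutes with the moment equations", {
  set.seed(7)
  p <- study_params()
  q <- swap_types(p)
  for (i in 1:20) {
    s <- random_moment_state(p)
    d1 <- swap_moment_types(moment_state(moment_rhs(s, p), check = FALSE))
    d2 <- moment_rhs(swap_moment_types(s), q)
    expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-12)
  }
  # and with the linearized invasion threshold
  b1 <- invasion_threshold_at(disease_free_state(p), p)
  b2 <- invasion_threshold_at(disease_free_state(q), q)
  expect_equal(b1, b2, tolerance = 1e-9)
})
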