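test_that("homogeneous invasion threshold matches the determinant condition", {
  # hand-derived from the aggregated linearization: beta*psi*<k> = mu+omega
  p <- homog_params()
  b <- invasion_threshold_at(disease_free_state(p), p)
  expect_equal(b, (p$mu + p$omega) / (0.5 * p$mean_degree),
               tolerance = 1e-6)
  # errors when the sign change is not inside the scanned range
  expect_error(invasion_threshold_at(disease_free_state(p), p,
                                     beta_range = c(1e-8, 1e-4)),
               "not bracketed")
  expect_error(invasion_threshold_at(endemic_state(study_params(0.06)),
                                     study_params(0.06)),
               "extinct plane")
})

test_that("invasion threshold rises with rewiring, falls with connectivity", {
  b <- vapply(c(0, 0.2, 1, 5), function(om)
    invasion_threshold_at(disease_free_state(homog_params(omega = om)),
                          homog_params(omega = om)), numeric(1))
  expect_true(all(diff(b) > 0))
  bk <- vapply(c(5, 10, 20, 40), function(k) {
    p <- model_params(0.01, 0.65, 0.05, 0.75, 0.002, 0.2,
                      n_nodes = 1e4, n_links = k * 1e4 / 2)
    invasion_threshold_at(disease_free_state(p), p)
  }, numeric(1))
  expect_true(all(diff(bk) < 0))
})

test_that("continuation finds the fold and the unstable segment", {
  p <- study_params()
  per <- persistence_threshold(p)
  expect_false(is.na(per$beta_per))
  expect_gt(per$beta_per, 0)
  br <- per$branch
  # sign change of the beta increments happened along arclength
  expect_gte(length(attr(br, "folds")), 1)
  # near-singular Jacobian at the fold state
  J <- moment_jacobian(per$state, params_with_beta(p, per$beta_per),
                       reduced = TRUE)
  sv <- svd(J)$d
  expect_lt(min(sv) / max(sv), 1e-4)
  # every accepted point re-converges to itself
  states <- attr(br, "states")
  for (i in seq(1, nrow(br), length.out = 5)) {
    st <- moment_state(states[round(i), ], check = FALSE)
    re <- find_steady_state(st, params_with_beta(p, br$beta[round(i)]))
    expect_lt(max(abs(as.numeric(re) - as.numeric(st))), 1e-9)
  }
  # stable endemic segment above the fold, unstable below
  expect_true(br$stable[1])
  expect_false(is.na(per$state[["I_a"]]))
})

test_that("no fold without the adaptive feedback (homogeneous, omega = 0)", {
  p0 <- homog_params(beta = 6e-4, omega = 0)
  per <- persistence_threshold(p0)
  expect_true(is.na(per$beta_per))
  expect_match(per$reason, "continuous")
})

test_that("adapted threshold: landing point is self-consistent and ordered", {
  p <- study_params()
  ad <- adapted_invasion_threshold(p)
  expect_lt(ad$consistency_rel_err, 1e-6)
  b0 <- invasion_threshold_at(disease_free_state(p), p)
  expect_gt(ad$beta_inv_adapted, b0)
  expect_gt(ad$beta_inv_adapted, ad$persistence$beta_per)
  # landing configuration shows the self-organized heterogeneity k_b > k_a
  ss <- ad$landing_ss_config
  k_a <- (ss[1] + ss[2]) / p$p_a
  k_b <- (ss[3] + ss[2]) / p$p_b
  expect_gt(k_b / k_a, 1)
  expect_lt(k_b / k_a, p$psi_a / p$psi_b)
})

test_that("threshold report is deterministic and serializable", {
  p <- study_params(n_nodes = 1e4, n_links = 1e5)
  r1 <- threshold_report(p)
  r2 <- threshold_report(p)
  expect_identical(r1[c("beta_inv_initial", "beta_per",
                        "beta_inv_adapted", "landing_ss_config")],
                   r2[c("beta_inv_initial", "beta_per",
                        "beta_inv_adapted", "landing_ss_config")])
  js <- jsonlite::toJSON(r1[c("beta_inv_initial", "beta_per",
                              "beta_inv_adapted")], auto_unbox = TRUE)
  expect_true(jsonlite::validate(js))
})
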