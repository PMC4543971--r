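test_that("moment derivatives conserve links and freeze the extinct plane", {
  set.seed(20)
  p <- study_params()
  for (i in 1:50) {
    s <- random_moment_state(p)
    d <- moment_rhs(s, p)
    expect_lt(abs(sum(adaptivesis:::MOMENT_LINK_COEF * d)), 1e-12)
  }
  expect_equal(max(abs(moment_rhs(disease_free_state(p), p))), 0)
  # any SS split of the extinct plane is stationary
  expect_equal(max(abs(moment_rhs(
    disease_free_state(p, ss_config = c(2, 4, 10)), p))), 0)
  expect_error(disease_free_state(p, ss_config = c(1, 1, 1)),
               "conservation")
  # single-type limit puts all mass in SS_aa
  p1 <- model_params(0.01, 0.5, 0.5, 1, 0.002, 0.2)
  df1 <- disease_free_state(p1)
  expect_equal(df1[["SS_aa"]], p1$mean_degree)
  expect_equal(df1[["SS_ab"]] + df1[["SS_bb"]], 0)
})

test_that("triplet closure has the bilinear guarded form", {
  expect_equal(closure_triplet(0, 3, 0.5), 0)
  expect_equal(closure_triplet(4, 2, 0.5), 16)
  expect_equal(closure_triplet(0, 0, 0), 0)   # guard on empty middle class
  expect_equal(closure_triplet(2 * 1.5, 3, 0.5),
               1.5 * closure_triplet(2, 3, 0.5))
  expect_equal(closure_triplet(2, 3 * 2.5, 0.5),
               2.5 * closure_triplet(2, 3, 0.5))
})

test_that("with equal susceptibilities the system reduces to one type", {
  set.seed(21)
  p <- homog_params(beta = 0.015)
  for (i in 1:100) {
    I <- runif(1, 0.05, 0.9)
    SI <- runif(1, 0.1, 3); II <- runif(1, 0.1, 5)
    SS <- p$mean_degree - 2 * SI - II
    if (SS <= 0) next
    emb <- embed_product_state(I, SS, SI, II, p$p_a)
    d2 <- moment_rhs(emb, p)
    d1 <- one_type_rhs(I, SS, SI, II, p$beta, 0.5, p$mu, p$omega)
    expect_equal(aggregate_moment_rhs(d2), d1, tolerance = 1e-12)
    # the product manifold is invariant: the derivative is itself product
    expect_equal(d2[["SS_aa"]] / p$p_a^2, d2[["SS_bb"]] / p$p_b^2,
                 tolerance = 1e-9)
  }
})

test_that("complex-step Jacobian matches central finite differences", {
  set.seed(22)
  p <- study_params()
  for (i in 1:5) {
    s <- random_moment_state(p)
    J <- moment_jacobian(s, p, reduced = FALSE)
    h <- 1e-6
    Jfd <- vapply(1:12, function(j) {
      xp <- unclass(s); xm <- unclass(s)
      xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      (moment_rhs(moment_state(xp, check = FALSE), p) -
         moment_rhs(moment_state(xm, check = FALSE), p)) / (2 * h)
    }, numeric(12))
    expect_lt(max(abs(J - Jfd) / (abs(J) + 1)), 1e-6)
  }
})

test_that("integration conserves, clips undershoots, stays on the plane", {
  p <- study_params()
  df <- disease_free_state(p)
  tr0 <- integrate_moments(df, p, t_max = 1000, n_out = 11)
  for (nm in adaptivesis:::MOMENT_NAMES)
    expect_equal(tr0[[nm]], rep(df[[nm]], 11))
  # supercritical from a lightly infected state: endemic attractor
  ph <- study_params(beta = 0.06)
  tr <- integrate_moments(initial_moment_state(ph, 0.01), ph, t_max = 3e4,
                          n_out = 31)
  iT <- tr$I_a[31] + tr$I_b[31]
  expect_gt(iT, 0.1); expect_lt(iT, 1)
  expect_lt(attr(tr, "conservation_drift"), 1e-8 * 20)
  # the endemic attractor is unique: two interior starts agree
  tr2 <- integrate_moments(initial_moment_state(ph, 0.6), ph, t_max = 3e4,
                           n_out = 31)
  expect_equal(tr$I_a[31] + tr$I_b[31], tr2$I_a[31] + tr2$I_b[31],
               tolerance = 1e-6)
})

test_that("Newton steady-state solver is exact and quadratic", {
  p <- study_params(beta = 0.06)
  df <- disease_free_state(p)
  out <- find_steady_state(df, p)
  expect_equal(as.numeric(out), as.numeric(df))  # exact root unchanged
  expect_equal(attr(out, "iterations"), 0L)
  es <- endemic_state(p)
  expect_lte(attr(es, "iterations"), 5)
  expect_lt(max(abs(moment_rhs(es, p))), 1e-10)
  expect_equal(link_density_total(es), p$mean_degree, tolerance = 1e-9)
  # stability flags: endemic attractor stable, and the infected subsystem
  # at the random-mixing extinct state flips sign across the threshold
  J <- moment_jacobian(es, p, reduced = TRUE)
  expect_lt(max(Re(eigen(J, only.values = TRUE)$values)), 0)
  b_c <- invasion_threshold_at(disease_free_state(p), p)
  M_lo <- infected_subsystem_matrix(df, p, beta = 0.9 * b_c)
  M_hi <- infected_subsystem_matrix(df, p, beta = 1.1 * b_c)
  expect_lt(max(Re(eigen(M_lo, only.values = TRUE)$values)), 0)
  expect_gt(max(Re(eigen(M_hi, only.values = TRUE)$values)), 0)
})
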