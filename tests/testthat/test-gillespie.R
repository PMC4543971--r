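test_that("absorbing states produce no events", {
  set.seed(10)
  p <- study_params(n_nodes = 50, n_links = 200)
  net <- assign_initial_condition(generate_er_network(50, 200), 0.75, 0)
  run <- gillespie_run(net, p, t_max = 1000)
  expect_equal(run$n_events, 0)
  expect_true(run$extinct)
  # extinction stays absorbing: restarting from an extinct state is silent
  net1 <- assign_initial_condition(generate_er_network(50, 200), 0.75, 0.2)
  r1 <- gillespie_run(net1, model_params(0, 0.65, 0.05, 0.75, 5, 0,
                                         n_nodes = 50, n_links = 200),
                      t_max = 1e4)
  expect_true(r1$extinct)
  r2 <- gillespie_run(r1$net, p, t_max = 1000)
  expect_equal(r2$n_events, 0)
})

test_that("single-clock channels match their exponential laws", {
  # lone infected node, no transmission or rewiring: Exp(mu) lifetime
  set.seed(11)
  p1 <- model_params(0, 0.65, 0.05, 0.75, mu = 0.5, omega = 0,
                     n_nodes = 30, n_links = 60)
  net <- generate_er_network(30, 60)
  ext <- replicate(10000, {
    nn <- assign_initial_condition(net, 0.75, 1 / 30)
    gillespie_run(nn, p1, t_max = 1e6, sample_interval = 1e6)$extinction_time
  })
  se <- stats::sd(ext) / sqrt(length(ext))
  expect_lt(abs(mean(ext) - 1 / 0.5), 3 * se)

  # pure death from everyone infected: harmonic-sum mean extinction time
  set.seed(12)
  n <- 40
  pn <- model_params(0, 0.65, 0.05, 0.75, mu = 0.2, omega = 0,
                     n_nodes = n, n_links = 2 * n)
  netf <- assign_initial_condition(generate_er_network(n, 2 * n), 0.75, 1)
  ext2 <- replicate(3000,
    gillespie_run(netf, pn, t_max = 1e6,
                  sample_interval = 1e6)$extinction_time)
  expected <- sum(1 / (0.2 * seq_len(n)))
  se2 <- stats::sd(ext2) / sqrt(length(ext2))
  expect_lt(abs(mean(ext2) - expected), 3 * se2)
})

test_that("competing transmission channels split by susceptibility", {
  # path S(A) - I - S(B): first infection lands on the type-A end with
  # probability psi_a / (psi_a + psi_b)
  set.seed(13)
  # mu must be positive; make recovery slower than transmission by nine
  # orders of magnitude so the first event is an infection with certainty
  p <- model_params(beta = 1, psi_a = 0.65, psi_b = 0.05, p_a = 0.5,
                    mu = 1e-9, omega = 0, n_nodes = 3, n_links = 2)
  net <- network_state(rbind(c(1, 2), c(2, 3)), type = c(1L, 1L, 2L),
                       state = c(0L, 1L, 0L))
  n_rep <- 10000
  left <- 0
  for (r in seq_len(n_rep)) {
    run <- gillespie_run(net, p, t_max = 100, record_events = TRUE)
    first <- run$events[run$events$code == 1L, ][1, ]
    left <- left + (first$node == 1L)
  }
  p_hat <- left / n_rep
  p_true <- 0.65 / 0.70
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n_rep))
})

test_that("incremental S-I registry matches a from-scratch rebuild", {
  set.seed(14)
  p <- study_params(n_nodes = 500, n_links = 5000)
  net <- assign_initial_condition(generate_er_network(500, 5000), 0.75, 0.3)
  # debug_check audits the registry against a full rescan at every sample
  run <- gillespie_run(net, p, t_max = 2000, sample_interval = 5,
                       debug_check = TRUE)
  expect_gt(run$n_events, 1000)
  # conservation of edges and type counts through all that rewiring
  expect_equal(nrow(run$net$edges), 5000)
  expect_equal(run$net$type, net$type)
  expect_false(anyDuplicated(run$net$edges) > 0)
  # the sampled prevalence decomposes by type
  expect_equal(run$ts$prevalence, run$ts$I_a + run$ts$I_b)
  # mixture identity on per-type degrees at every sample
  expect_equal(0.75 * run$ts$k_a + 0.25 * run$ts$k_b,
               rep(20, nrow(run$ts)))
})

test_that("small-graph dynamics match the brute-force master equation", {
  # 4-node path, rewiring active: full CTMC over (edge set, states)
  p <- model_params(beta = 0.9, psi_a = 0.65, psi_b = 0.05, p_a = 0.5,
                    mu = 0.4, omega = 0.5, n_nodes = 4, n_links = 3)
  ctmc <- small_ctmc(4, 3, types = c(1L, 2L, 1L, 2L), params = p)
  edges0 <- rbind(c(1, 2), c(2, 3), c(3, 4))
  state0 <- c(0L, 1L, 0L, 0L)
  exact <- ctmc_infected_distribution(ctmc, edges0, state0, t = 2.5)
  net <- network_state(edges0, type = c(1L, 2L, 1L, 2L), state = state0)
  set.seed(15)
  n_rep <- 10000
  emp <- gillespie_infected_distribution(net, p, t = 2.5, n_rep = n_rep)
  se <- sqrt(exact * (1 - exact) / n_rep)
  expect_true(all(abs(emp - exact) <= 3 * se + 2 / n_rep))
})

test_that("stationarity protocol flags extinction and endemic outcomes", {
  set.seed(16)
  # far below threshold: dies out
  p_lo <- study_params(beta = 0.004, n_nodes = 1000, n_links = 10000)
  net <- assign_initial_condition(generate_er_network(1000, 10000),
                                  0.75, 0.01)
  res <- run_to_stationarity(net, p_lo, window_factor = 4)
  expect_true(res$summary$extinct)
  expect_equal(res$summary$prevalence, 0)
  # well endemic: persists with positive prevalence
  p_hi <- study_params(beta = 0.06, n_nodes = 1000, n_links = 10000)
  net2 <- assign_initial_condition(generate_er_network(1000, 10000),
                                   0.75, 0.5)
  res2 <- run_to_stationarity(net2, p_hi, window_factor = 4)
  expect_false(res2$summary$extinct)
  expect_gt(res2$summary$prevalence, 0.5)
})
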