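test_that("G(N,K) generation is exact in edge count and Poissonian", {
  set.seed(1)
  tri <- generate_er_network(3, 3)
  expect_equal(tri$edges, matrix(as.integer(c(1, 1, 2, 2, 3, 3)), ncol = 2))
  expect_error(generate_er_network(5, 11), "possible")
  vars <- replicate(10, {
    net <- generate_er_network(1e4, 1e5)
    deg <- tabulate(c(net$edges), nbins = 1e4)
    expect_equal(mean(deg), 20)          # exact: 2K/N
    stats::var(deg)
  })
  expect_lt(abs(mean(vars) - 20) / 20, 0.05)  # Poisson: variance ~ mean
})

test_that("initial condition hits exact counts, independently of type", {
  set.seed(2)
  net <- generate_er_network(100, 300)
  net <- assign_initial_condition(net, 0.75, 0.2)
  expect_equal(sum(net$type == 1L), 75)
  expect_equal(sum(net$state), 20)
  # prevalence 0 freezes the dynamics entirely
  p <- study_params(n_nodes = 100, n_links = 300)
  net0 <- assign_initial_condition(net, 0.75, 0)
  run <- gillespie_run(net0, p, t_max = 100)
  expect_equal(run$n_events, 0)
  # type and epidemic state are assigned independently: the infected
  # fraction among type A matches that among type B across seeds
  set.seed(3)
  diffs <- replicate(200, {
    nn <- assign_initial_condition(generate_er_network(1000, 2000), 0.5, 0.3)
    mean(nn$state[nn$type == 1L]) - mean(nn$state[nn$type == 2L])
  })
  se <- stats::sd(diffs) / sqrt(200)
  expect_lt(abs(mean(diffs)), 3 * se + 1e-12)
})

test_that("degree statistics satisfy the exact mixture identity", {
  set.seed(4)
  net <- assign_initial_condition(generate_er_network(2000, 20000), 0.75, 0)
  ds <- degree_stats(net)
  expect_equal(0.75 * ds$k_a + 0.25 * ds$k_b, 20)
  expect_lt(abs(ds$ratio - 1), 0.1)  # types independent of degree
  tri <- network_state(rbind(c(1, 2), c(2, 3), c(1, 3)),
                       type = c(1L, 1L, 2L), state = rep(0L, 3))
  dt <- degree_stats(tri)
  expect_equal(dt$k_a, 2)
  expect_equal(dt$k_b, 2)
  expect_equal(dt$ratio, 1)
  # a type with no nodes reports a missing ratio
  mono <- network_state(rbind(c(1, 2)), type = c(1L, 1L),
                        state = c(0L, 0L))
  expect_true(is.na(degree_stats(mono)$ratio))
})

test_that("rewiring respects eligibility and is a no-op when starved", {
  # star: susceptible centre 1, infected leaf 2, isolated susceptibles 3:7
  star <- network_state(rbind(c(1, 2)), type = rep(1L, 7),
                        state = c(0L, 1L, rep(0L, 5)), n_nodes = 7)
  set.seed(5)
  out <- rewire_event(star, c(1, 2))
  expect_true(attr(out, "rewired"))
  deg <- tabulate(c(out$edges), nbins = 7)
  expect_equal(deg[1], 1)               # centre keeps its degree
  expect_equal(deg[2], 0)               # infected leaf lost the link
  expect_equal(sum(deg[3:7]), 1)        # exactly one isolated node gained
  expect_true(attr(out, "new_target") %in% 3:7)

  # two-node graph: no other susceptible exists
  two <- network_state(rbind(c(1, 2)), type = c(1L, 2L), state = c(0L, 1L))
  out2 <- rewire_event(two, c(1, 2))
  expect_false(attr(out2, "rewired"))
  expect_equal(out2$edges, two$edges)

  # S end already adjacent to every susceptible: no-op
  full <- network_state(rbind(c(1, 2), c(1, 3), c(1, 4)),
                        type = rep(1L, 4), state = c(0L, 1L, 0L, 0L))
  out3 <- rewire_event(full, c(1, 2))
  expect_false(attr(out3, "rewired"))

  # handing a non-S-I link is an internal consistency error
  ss <- network_state(rbind(c(1, 2)), type = c(1L, 1L), state = c(0L, 0L))
  expect_error(rewire_event(ss, c(1, 2)), "consistency")
})

test_that("adapted restart keeps the link pattern and resets states", {
  set.seed(6)
  p <- study_params(n_nodes = 500, n_links = 2500)
  net <- assign_initial_condition(generate_er_network(500, 2500), 0.75, 0.5)
  run <- gillespie_run(net, p, t_max = 500)
  restart <- adapted_restart_state(run$net, 20)
  expect_equal(restart$edges, run$net$edges)
  expect_equal(restart$type, run$net$type)
  expect_equal(sum(restart$state), 20)
  restart2 <- adapted_restart_state(run$net, 20)
  expect_equal(restart2$edges, restart$edges)
  expect_false(identical(restart2$state, restart$state))
  expect_error(adapted_restart_state(run$net, 501), "exceeds")
})
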