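# Brute-force master-equation oracle for tiny graphs (N <= 4).
#
# Enumerates the full continuous-time Markov chain over (edge set, infection
# pattern) pairs with the exact event rules: recovery at mu per infected,
# transmission at beta * psi(type of S end) per S-I link, rewiring at omega
# per S-I link with the target uniform over eligible susceptibles (not the
# S end, not a current neighbour; none eligible = no-op).  The transient
# distribution is exp(Q t); this path shares no code with the compiled
# simulator.

small_ctmc <- function(n_nodes, n_links, types, params) {
  pairs <- t(utils::combn(n_nodes, 2))
  npairs <- nrow(pairs)
  mask_of <- function(idx) sum(2^(idx - 1))
  esets <- apply(utils::combn(npairs, n_links), 2, mask_of)
  states <- expand.grid(e = esets, s = 0:(2^n_nodes - 1))
  ns <- nrow(states)
  key <- states$e * 2^n_nodes + states$s
  lookup <- function(e, s) match(e * 2^n_nodes + s, key)
  psi <- c(params$psi_a, params$psi_b)
  Q <- matrix(0, ns, ns)
  for (k in seq_len(ns)) {
    e <- states$e[k]; s <- states$s[k]
    inf <- which(bitwAnd(s, 2^(seq_len(n_nodes) - 1)) > 0)
    sus <- setdiff(seq_len(n_nodes), inf)
    eidx <- which(bitwAnd(e, 2^(seq_len(npairs) - 1)) > 0)
    el <- pairs[eidx, , drop = FALSE]
    adj <- lapply(seq_len(n_nodes),
                  function(v) c(el[el[, 1] == v, 2], el[el[, 2] == v, 1]))
    for (v in inf) {
      j <- lookup(e, s - 2^(v - 1))
      Q[k, j] <- Q[k, j] + params$mu
    }
    for (r in seq_len(nrow(el))) {
      a <- el[r, 1]; b <- el[r, 2]
      ia <- a %in% inf; ib <- b %in% inf
      if (ia == ib) next
      sn <- if (ia) b else a
      infn <- if (ia) a else b
      j <- lookup(e, s + 2^(sn - 1))
      Q[k, j] <- Q[k, j] + params$beta * psi[types[sn]]
      elig <- setdiff(sus, c(sn, adj[[sn]]))
      if (length(elig)) {
        eid_old <- which(pairs[, 1] == min(sn, infn) &
                           pairs[, 2] == max(sn, infn))
        for (tgt in elig) {
          eid_new <- which(pairs[, 1] == min(sn, tgt) &
                             pairs[, 2] == max(sn, tgt))
          enew <- e - 2^(eid_old - 1) + 2^(eid_new - 1)
          j <- lookup(enew, s)
          Q[k, j] <- Q[k, j] + params$omega / length(elig)
        }
      }
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  n_inf <- vapply(states$s, function(s)
    sum(bitwAnd(s, 2^(seq_len(n_nodes) - 1)) > 0), numeric(1))
  list(states = states, Q = Q, pairs = pairs, n_inf = n_inf,
       mask_of = mask_of, lookup = lookup)
}

# exact distribution of the number infected at time t from a given start
ctmc_infected_distribution <- function(ctmc, edges0, state0, t) {
  n_nodes <- length(state0)
  eid <- apply(edges0, 1, function(ed) {
    which(ctmc$pairs[, 1] == min(ed) & ctmc$pairs[, 2] == max(ed))
  })
  e0 <- ctmc$mask_of(eid)
  s0 <- sum(2^(which(state0 == 1L) - 1))
  p0 <- numeric(nrow(ctmc$states))
  p0[ctmc$lookup(e0, s0)] <- 1
  pT <- as.numeric(p0 %*% as.matrix(Matrix::expm(ctmc$Q * t)))
  vapply(0:n_nodes, function(m) sum(pT[ctmc$n_inf == m]), numeric(1))
}

# empirical distribution of the number infected at time t over n_rep runs
gillespie_infected_distribution <- function(net, params, t, n_rep) {
  counts <- integer(net$n_nodes + 1)
  for (r in seq_len(n_rep)) {
    run <- gillespie_run(net, params, t_max = t, sample_interval = t,
                         stop_on_extinction = FALSE)
    k <- sum(run$net$state) + 1L
    counts[k] <- counts[k] + 1L
  }
  counts / n_rep
}
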