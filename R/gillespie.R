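# R-side drivers of the compiled Gillespie core: single runs, the
# stationarity protocol, and the simulated invasion-threshold estimator.

#' Event-driven stochastic simulation of the adaptive two-type SIS process
#'
#' Exact Gillespie simulation of the three event channels: recovery of each
#' infected node at rate `mu`, transmission along each
#' susceptible-infected link at rate `beta * psi_type(S end)`, and rewiring
#' of each susceptible-infected link at rate `omega` (the susceptible end
#' reconnects to a uniformly chosen eligible susceptible; no eligible
#' target leaves the link intact).  Reproducibility is governed by R's RNG
#' (`set.seed()`).
#'
#' @param net a [network_state()] with types and states assigned.
#' @param params a [model_params()]; the network's own size is used.
#' @param t_max simulated time horizon.
#' @param sample_interval spacing of time-series samples (> 0).
#' @param stop_on_extinction stop the event loop once no infected remain
#'   (extinction is absorbing either way; remaining samples repeat the
#'   frozen state).
#' @param debug_check re-derive the susceptible-infected link registry from
#'   scratch at every sample time and stop on any mismatch.
#' @param record_events also return the per-event log (time, channel code
#'   0 = recovery / 1 = infection / 2 = rewiring / 3 = rewiring no-op, and
#'   the acting node), capped at `max_recorded_events`.
#' @param max_recorded_events cap for the event log.
#' @return list with `ts` (data.frame: `t`, `prevalence`, `I_a`, `I_b`
#'   node fractions, per-type mean degrees `k_a`, `k_b`, `si_links` count),
#'   `net` (final [network_state()]), `n_events`, `extinct`,
#'   `extinction_time`, and optionally `events`.
#' @export
gillespie_run <- function(net, params, t_max, sample_interval = 1,
                          stop_on_extinction = TRUE, debug_check = FALSE,
                          record_events = FALSE,
                          max_recorded_events = 1e6L) {
  stopifnot(inherits(net, "sis_network"), !is.null(net$state),
            sample_interval > 0, t_max >= 0)
  res <- .gillespie_core(net$edges, net$type, net$state,
                         params$beta, params$psi_a, params$psi_b,
                         params$mu, params$omega, t_max, sample_interval,
                         stop_on_extinction, debug_check, record_events,
                         as.integer(max_recorded_events))
  n <- net$n_nodes
  s <- res$samples
  ts <- data.frame(t = s$t,
                   prevalence = (s$I_a + s$I_b) / n,
                   I_a = s$I_a / n, I_b = s$I_b / n,
                   k_a = s$k_a, k_b = s$k_b,
                   si_links = s$si_links)
  out <- list(ts = ts,
              net = network_state(res$edges, net$type, res$state,
                                  n_nodes = n),
              n_events = res$n_events,
              extinct = res$extinct,
              extinction_time = res$extinction_time)
  if (record_events) out$events <- as.data.frame(res$events)
  out
}

#' Evolve a network to epidemic stationarity
#'
#' Simulates in windows of `window_factor / mu` time units until the mean
#' prevalence of two consecutive windows agrees within two standard errors
#' (batch-means errors within each window), then averages prevalence and
#' per-type degrees over one further window.  Extinction before
#' stationarity is reported as an extinct outcome with prevalence 0.
#'
#' @param net a [network_state()] with states assigned.
#' @param params a [model_params()].
#' @param window_factor window length in units of `1 / mu`.
#' @param sample_interval sampling spacing within windows.
#' @param t_hard_max hard cap on total simulated time.
#' @return list with `net` (final network), `summary` (list: `prevalence`,
#'   `prevalence_se`, `k_a`, `k_b`, `ratio`, `extinct`, `stationary`,
#'   `t_total`) and `windows` (per-window means).
#' @export
run_to_stationarity <- function(net, params, window_factor = 50,
                                sample_interval = NULL, t_hard_max = 1e5) {
  window <- window_factor / params$mu
  if (is.null(sample_interval))
    sample_interval <- max(window / 2000, .Machine$double.eps)
  t_total <- 0
  means <- c(); ses <- c()
  prev_mean <- NA; prev_se <- NA
  stationary <- FALSE
  repeat {
    run <- gillespie_run(net, params, t_max = window,
                         sample_interval = sample_interval)
    net <- run$net
    t_total <- t_total + window
    x <- run$ts$prevalence[-1]
    nb <- 10
    bm <- tapply(x, cut(seq_along(x), nb, labels = FALSE), mean)
    m <- mean(x); se <- stats::sd(bm) / sqrt(nb)
    means <- c(means, m); ses <- c(ses, se)
    if (run$extinct) {
      return(list(net = net,
                  summary = list(prevalence = 0, prevalence_se = 0,
                                 k_a = mean(run$ts$k_a), k_b = mean(run$ts$k_b),
                                 ratio = NA_real_, extinct = TRUE,
                                 stationary = TRUE, t_total = t_total),
                  windows = data.frame(mean = means, se = ses)))
    }
    if (!is.na(prev_mean) &&
        abs(m - prev_mean) < 2 * sqrt(se^2 + prev_se^2)) {
      stationary <- TRUE
      break
    }
    if (t_total + window > t_hard_max) break
    prev_mean <- m; prev_se <- se
  }
  # averaging window
  run <- gillespie_run(net, params, t_max = window,
                       sample_interval = sample_interval)
  net <- run$net
  t_total <- t_total + window
  x <- run$ts$prevalence[-1]
  nb <- 10
  bm <- tapply(x, cut(seq_along(x), nb, labels = FALSE), mean)
  list(net = net,
       summary = list(prevalence = mean(x),
                      prevalence_se = stats::sd(bm) / sqrt(nb),
                      k_a = mean(run$ts$k_a), k_b = mean(run$ts$k_b),
                      ratio = mean(run$ts$k_b) / mean(run$ts$k_a),
                      extinct = run$extinct,
                      stationary = stationary, t_total = t_total),
       windows = data.frame(mean = c(means, mean(x)),
                            se = c(ses, stats::sd(bm) / sqrt(nb))))
}

#' Simulated invasion threshold from extinction probabilities
#'
#' Estimates, by bisection in the infectivity, the point where the
#' probability of reaching the disease-free state drops below `p_cut`
#' (default 0.05).  Each probe at a given `beta` runs `n_runs` independent
#' simulations from freshly drawn initial states; a run counts as extinct
#' when no infected remain before `t_decide` (runs are also stopped early
#' once the prevalence exceeds `i_establish`, which at these sizes is
#' always followed by establishment).
#'
#' The returned confidence bracket `ci` spans from the largest probed
#' `beta` at which every run went extinct to the smallest probed `beta`
#' with extinction probability below `p_cut`: below the transcritical point
#' establishment is impossible, so any establishment certifies that `beta`
#' exceeds it.
#'
#' @param make_initial_state function(`beta`) returning a fresh
#'   [network_state()] with initial infected assigned (its argument may be
#'   ignored).
#' @param params a [model_params()]; `beta` is overridden during the scan.
#' @param beta_range interval searched; an error is raised when the
#'   criterion is not bracketed.
#' @param n_runs runs per probed `beta` (>= 20).
#' @param p_cut extinction-probability criterion.
#' @param t_decide per-run time horizon.
#' @param i_establish prevalence above which a run is deemed established.
#' @param max_iter bisection steps.
#' @return list with `beta` (bracket midpoint), `bracket`, `ci`, and
#'   `probes` (data.frame: beta, n_runs, n_extinct).
#' @export
estimate_invasion_threshold_sim <- function(make_initial_state, params,
                                            beta_range, n_runs = 100,
                                            p_cut = 0.05, t_decide = 4000,
                                            i_establish = 0.05,
                                            max_iter = 7) {
  stopifnot(n_runs >= 20, length(beta_range) == 2, diff(beta_range) > 0)
  probes <- data.frame(beta = numeric(), n_runs = integer(),
                       n_extinct = integer())
  p_ext <- function(beta) {
    pr <- params_with_beta(params, beta)
    n_ext <- 0L
    for (r in seq_len(n_runs)) {
      net <- make_initial_state(beta)
      # run in chunks until the outcome is decided; near-threshold runs
      # that linger undecided get up to 10x the nominal horizon
      t_done <- 0
      extinct <- FALSE
      repeat {
        chunk <- t_decide / 8
        run <- gillespie_run(net, pr, t_max = chunk,
                             sample_interval = max(chunk / 50, 1e-6))
        net <- run$net
        t_done <- t_done + chunk
        if (run$extinct) { extinct <- TRUE; break }
        if (max(run$ts$prevalence) >= i_establish ||
            t_done >= 10 * t_decide)
          break
      }
      n_ext <- n_ext + extinct
    }
    probes[nrow(probes) + 1L, ] <<- list(beta, n_runs, n_ext)
    n_ext / n_runs
  }
  lo <- beta_range[1]; hi <- beta_range[2]
  if (p_ext(lo) < p_cut || p_ext(hi) >= p_cut)
    stop("threshold outside scanned range [", lo, ", ", hi, "]",
         call. = FALSE)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (p_ext(mid) >= p_cut) lo <- mid else hi <- mid
  }
  all_ext <- probes$n_extinct == probes$n_runs
  below <- probes$n_extinct / probes$n_runs < p_cut
  ci <- c(if (any(all_ext)) max(probes$beta[all_ext]) else beta_range[1],
          if (any(below)) min(probes$beta[below]) else beta_range[2])
  list(beta = (lo + hi) / 2, bracket = c(lo, hi), ci = ci, probes = probes)
}
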