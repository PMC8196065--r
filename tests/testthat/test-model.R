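test_that("derivatives vanish at fixed points and conserve tiles", {
  p <- rate_params()
  zero <- c(Ti = 0, Ta = 0, P = 0, N = 0, R = 0, W = 0, a = 0)
  expect_equal(unname(assembly_derivatives(0, zero, p)[[1]]),
               rep(0, 7))
  # no gene, no trigger, no active tiles: assembly can never start
  p0 <- rate_params(G = 0)
  s <- initial_state(p0)
  d <- assembly_derivatives(0, s, p0)[[1]]
  expect_equal(unname(d[["P"]]), 0)
  expect_equal(unname(d[["R"]]), 0)
  # tile pool conservation holds identically at random states
  set.seed(5)
  for (i in 1:1000) {
    st <- c(Ti = runif(1, 0, 500), Ta = runif(1, 0, 500),
            P = runif(1, 0, 500), N = runif(1, 0, 5),
            R = runif(1, 0, 200), W = runif(1, 0, 100),
            a = runif(1))
    d <- assembly_derivatives(0, st, p)[[1]]
    expect_lt(abs(d[["Ti"]] + d[["Ta"]] + d[["P"]] + d[["W"]]), 1e-12)
  }
  expect_error(assembly_derivatives(0, c(zero[-1], Ti = -1), p),
               "negative")
})

test_that("trajectories conserve tiles and stay non-negative", {
  p <- rate_params(H = 0.05)
  sim <- simulate_assembly(p, t_end = 900, n_points = 301)
  tot <- sim$Ti + sim$Ta + sim$P + sim$W
  expect_lt(max(abs(tot - p$T_total)) / p$T_total, 1e-6)
  expect_true(all(sim[c("Ti", "Ta", "P", "N", "R", "W", "a")] >= 0))
  expect_true(all(sim$f >= 0 & sim$f <= 1))
})

test_that("elongation-only limit matches the closed-form exponential", {
  p <- rate_params(G = 0, H = 0, k_nuc = 0, k_off = 0)
  N0 <- 5
  sim <- simulate_assembly(p, initial_state(p, active_fraction = 1,
                                            N0 = N0),
                           t_end = 100, n_points = 101)
  exact <- p$T_total * exp(-p$k_on * N0 * sim$time)
  expect_lt(max(abs(sim$Ta - exact) / pmax(exact, 1e-9)), 1e-6)
})

test_that("no gene means no assembly; more gene means faster, higher plateaus", {
  p0 <- rate_params(G = 0, H = 0)
  s0 <- simulate_assembly(p0, t_end = 600)
  expect_true(all(s0$f == 0))
  finals <- t_half <- numeric(0)
  for (G in c(7.5, 50, 100)) {
    p <- rate_params(G = G, H = 0)
    s <- simulate_assembly(p, t_end = 900, n_points = 901)
    expect_true(all(diff(s$f) > -1e-7)) # monotone without degradation
    finals <- c(finals, s$f[nrow(s)])
    t_half <- c(t_half,
                s$time[which(s$f >= s$f[nrow(s)] / 2)[1]])
  }
  expect_true(all(diff(finals) > 0))
  # doubling the gene speeds up the approach to plateau
  pa <- simulate_assembly(rate_params(G = 50, H = 0), t_end = 900,
                          n_points = 901)
  pb <- simulate_assembly(rate_params(G = 100, H = 0), t_end = 900,
                          n_points = 901)
  th <- function(s) s$time[which(s$f >= s$f[nrow(s)] / 2)[1]]
  expect_lt(th(pb), th(pa))
  expect_gt(pb$f[nrow(pb)], pa$f[nrow(pa)])
})

test_that("pre-activated tiles assemble faster at higher concentration", {
  t95 <- vapply(c(50, 250), function(Tt) {
    p <- rate_params(G = 0, H = 0, T_total = Tt)
    s <- simulate_assembly(p, initial_state(p, active_fraction = 1),
                           t_end = 2000, n_points = 2001)
    fin <- s$f[nrow(s)]
    s$time[which(s$f >= 0.95 * fin)[1]]
  }, numeric(1))
  expect_lt(t95[2], t95[1])
})

test_that("transcription against RNase H yields a tunable pulse", {
  H_grid <- c(0.025, 0.05, 0.075, 0.1)
  peaks <- halfs <- numeric(0)
  for (H in H_grid) {
    p <- rate_params(H = H)
    s <- simulate_assembly(p, t_end = 900, n_points = 901)
    m <- pulse_metrics(s)
    # eventual decline after the peak
    expect_lt(s$f[nrow(s)], 0.95 * m$peak_height)
    peaks <- c(peaks, m$peak_height)
    halfs <- c(halfs, m$t_half_rise)
  }
  expect_true(all(diff(peaks) < 0))   # more RNase H, smaller pulse
  expect_true(all(diff(halfs) > 0))   # more RNase H, delayed assembly
})

test_that("pulse metrics interpolate on simple trajectories", {
  tri <- data.frame(time = 0:10,
                    f = c(0, 0.1, 0.3, 0.5, 0.4, 0.3, 0.2, 0.15, 0.1,
                          0.05, 0))
  m <- pulse_metrics(tri, threshold = 0.25)
  expect_equal(m$peak_height, 0.5)
  expect_equal(m$t_peak, 3)
  # crossings: up between t=1 and 2 (at 0.25), down between 5 and 6
  expect_equal(m$t_half_rise, 1.75) # f = 0.25 on the rise
  expect_equal(m$duration_above, (5.5) - 1.75)
  expect_false(m$right_censored)
  mono <- data.frame(time = 0:5, f = seq(0, 0.5, 0.1))
  m2 <- pulse_metrics(mono, threshold = 0.25)
  expect_true(m2$right_censored)
  expect_equal(m2$duration_above, 5 - 2.5)
  flat <- data.frame(time = 0:5, f = rep(0.01, 6))
  m3 <- pulse_metrics(flat, threshold = 0.1)
  expect_equal(m3$duration_above, 0)
  expect_equal(m3$peak_height, 0.01)
})

test_that("parameter sweeps reproduce single runs and validate names", {
  base <- rate_params(H = 0)
  sw <- sweep_parameter(base, "G", 50, t_end = 300, n_points = 101)
  direct <- simulate_assembly(rate_params(G = 50, H = 0), t_end = 300,
                              n_points = 101)
  expect_equal(sw[[1]]$sim$f, direct$f)
  expect_error(sweep_parameter(base, "k_bogus", 1, t_end = 10),
               "valid names")
  expect_error(sweep_parameter(base, "G", numeric(0), t_end = 10),
               "non-empty")
  sG <- sweep_summary(sweep_parameter(base, "G", c(7.5, 50, 100),
                                      t_end = 900, n_points = 301), "G")
  expect_true(all(diff(sG$final_f) > 0))
})

test_that("parameter validation rejects unphysical inputs", {
  expect_error(rate_params(k_on = -1), "non-negative")
  expect_error(rate_params(n_nuc = 1), "n_nuc")
  expect_error(rate_params(w_frac = 1.5), "w_frac")
  expect_error(initial_state(rate_params(), active_fraction = 2))
})
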