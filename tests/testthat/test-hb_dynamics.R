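# graphs for a single site-partner bond following a given boolean series
series_graphs <- function(s) {
  lapply(seq_along(s), function(t) {
    g <- fake_graph(2, if (s[t]) cbind(1, 2) else NULL)
    g$frame_index <- t - 1L
    g
  })
}

test_that("persistence events are maximal uninterrupted runs", {
  # present all 10 frames: one event, censored at both ends
  ev <- trace_persistence(series_graphs(rep(TRUE, 10)), "s1")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$length, 10L)
  expect_true(ev$left_censored && ev$right_censored)
  # present 0-2, absent 3, present 4-5: two events of 3 and 2 frames
  ev2 <- trace_persistence(
    series_graphs(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)), "s1")
  expect_equal(ev2$start, c(0L, 4L))
  expect_equal(ev2$length, c(3L, 2L))
  expect_equal(ev2$left_censored, c(TRUE, FALSE))
  expect_equal(ev2$right_censored, c(FALSE, TRUE))
  # a gap tolerance of one frame bridges the single absence
  ev3 <- trace_persistence(
    series_graphs(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)), "s1",
    gap_tolerance = 1L)
  expect_equal(nrow(ev3), 1L)
  expect_equal(ev3$length, 6L)
  expect_error(trace_persistence(series_graphs(c(TRUE)), "zzz"),
               "unknown site")
})

test_that("mean run length follows the geometric law of the break rate", {
  set.seed(71)
  p_break <- 0.2
  s <- stats::runif(60000) >= p_break  # iid survival: runs ~ geometric
  ev <- trace_persistence(series_graphs(s), "s1")
  ev <- ev[!(ev$left_censored | ev$right_censored), ]
  expect_gt(nrow(ev), 5000)
  expect_lt(abs(mean(ev$length) - 1 / p_break) / (1 / p_break), 0.05)
})

test_that("residence time weights durations by occurrence probability", {
  ev <- data.frame(site = "X", partner = c("a", "b", "c"),
                   start = c(0L, 5L, 9L), length = c(2L, 2L, 4L),
                   left_censored = FALSE, right_censored = FALSE)
  rt <- residence_time(ev, frame_interval = 0.5, correction = 1)
  expect_equal(rt$mean_lifetime_ps, (8 / 3) * 0.5, tolerance = 1e-12)
  rt2 <- residence_time(ev, frame_interval = 0.5, correction = 2)
  expect_equal(rt2$mean_lifetime_ps, (8 / 3), tolerance = 1e-12)
  # the histogram formulation sum_i t_i P(t_i) coincides exactly
  h <- attr(rt, "histograms")$X
  expect_equal(sum(h$probability), 1)
  expect_equal(sum(h$duration_frames * h$probability) * 0.5,
               rt$mean_lifetime_ps)
})

test_that("the two printed residence-time formulations agree on any input", {
  set.seed(83)
  for (k in 1:25) {
    n <- sample(1:200, 1)
    ev <- data.frame(site = "S", partner = paste0("p", 1:n),
                     start = 0L, length = sample(1:30, n, replace = TRUE),
                     left_censored = FALSE, right_censored = FALSE)
    dt <- runif(1, 0.1, 2)
    corr <- sample(c(1, 2), 1)
    rt <- residence_time(ev, frame_interval = dt, correction = corr)
    h <- attr(rt, "histograms")$S
    expect_equal(rt$mean_lifetime_ps,
                 sum(h$duration_frames * h$probability) * dt * corr,
                 tolerance = 1e-12)
    expect_equal(rt$mean_lifetime_ps, mean(ev$length) * dt * corr,
                 tolerance = 1e-12)
  }
})

test_that("auto correction doubles hydrogen-mode lifetimes only", {
  s <- c(TRUE, TRUE, FALSE, TRUE)
  evh <- trace_persistence(series_graphs(s), "s1",
                           partner_mode = "hydrogen")
  evm <- trace_persistence(series_graphs(s), "s1",
                           partner_mode = "molecule")
  rth <- residence_time(evh, frame_interval = 1, correction = "auto")
  rtm <- residence_time(evm, frame_interval = 1, correction = "auto")
  expect_equal(rth$correction, 2)
  expect_equal(rtm$correction, 1)
  expect_error(residence_time(evh[0, ], correction = 1), "undefined")
})

test_that("correlation of a permanent bond is identically one", {
  cs <- hb_correlation(rep(TRUE, 50), frame_interval = 0.5)
  expect_equal(cs$value, rep(1, nrow(cs)))
  expect_equal(cs$lag_ps[1], 0)
  lt <- integrate_lifetime(cs)
  expect_equal(as.numeric(lt), max(cs$lag_ps))
})

test_that("a bond present only at the first frame decorrelates at once", {
  s <- c(TRUE, rep(FALSE, 99))
  cs <- hb_correlation(s, frame_interval = 0.5)
  expect_equal(cs$value[1], 1)
  expect_equal(cs$value[-1], rep(0, nrow(cs) - 1L))
})

test_that("FFT correlation equals the direct double-loop estimate", {
  set.seed(91)
  for (k in 1:5) {
    n <- sample(20:80, 1)
    np <- sample(1:4, 1)
    S <- matrix(runif(n * np) < 0.4, n, np)
    if (!any(S)) S[1, 1] <- TRUE
    cs <- hb_correlation(S, frame_interval = 1, max_lag = n - 1)
    direct <- vapply(0:(n - 1), function(l) {
      num <- 0
      for (p in 1:np) for (t0 in 1:(n - l))
        num <- num + S[t0, p] * S[t0 + l, p]
      (num / (np * (n - l))) / (sum(S) / (np * n))
    }, 0)
    expect_equal(cs$value, direct, tolerance = 1e-9)
  }
})

test_that("correlation decay matches the Markov chain's closed form", {
  set.seed(97)
  a <- 0.15; b <- 0.05            # unbind / bind per frame
  n <- 20000
  S <- vapply(1:8, function(p) markov_series(n, a, b), logical(n))
  cs <- hb_correlation(S, frame_interval = 1, max_lag = 30)
  pi1 <- b / (a + b)
  lam <- 1 - a - b
  analytic <- pi1 + (1 - pi1) * lam^(cs$lag_ps)
  expect_lt(max(abs(cs$value - analytic)), 0.03)
})

test_that("integrated lifetime recovers tau from an exponential decay", {
  tau <- 3.7
  lags <- seq(0, 25 * tau, by = tau / 50)
  cs <- correlation_series(lags, exp(-lags / tau))
  lt <- integrate_lifetime(cs)
  expect_lt(abs(as.numeric(lt) - tau) / tau, 0.02)
  expect_equal(attr(lt, "truncation_lag_ps"), max(lags))
  # degenerate single-lag series has no area
  expect_equal(as.numeric(integrate_lifetime(
    correlation_series(0, 1))), 0)
})

test_that("continuous persistence is shorter than intermittent lifetime
          when partners rebind", {
  set.seed(103)
  a <- 0.3; b <- 0.2              # fast rebinding
  S <- vapply(1:5, function(p) markov_series(3000, a, b), logical(3000))
  graphs <- series_graphs(S[, 1])
  cont <- residence_time(trace_persistence(graphs, "s1",
                                           partner_mode = "molecule"),
                         frame_interval = 1, correction = 1)
  interm <- integrate_lifetime(hb_correlation(S, frame_interval = 1))
  expect_lt(cont$mean_lifetime_ps, as.numeric(interm))
})

test_that("hydrogen and molecule conventions disagree by the swap rate", {
  tr <- generate_trajectory(synthetic_params(n_waters = 20, n_frames = 3000,
                                             seed = 43))
  graphs <- build_frame_graphs(tr$frames, tr$topology)
  p <- tr$params$p_unbind; q <- tr$params$q_swap
  evh <- do.call(rbind, lapply(c("O9", "O9p"), function(s)
    trace_persistence(graphs, s, partner_mode = "hydrogen")))
  attr(evh, "partner_mode") <- "hydrogen"
  rth <- residence_time(evh, frame_interval = 0.5, correction = 1)
  # hydrogen episodes end by unbind or swap: mean 1/(p + q - pq) frames
  expected <- 0.5 / (p + q - p * q)
  observed <- sum(rth$mean_lifetime_ps * rth$n_events) / sum(rth$n_events)
  expect_lt(abs(observed - expected) / expected, 0.1)
})
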