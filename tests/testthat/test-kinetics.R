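series <- function(leaders, stride = 20) {
  data.frame(mcs = seq_along(leaders) * stride, leader = leaders)
}

test_that("overtake detection honors the persistence rule", {
  # constant leader: no events
  expect_equal(nrow(detect_overtakes(series(rep(1L, 20)))), 0)
  # A (200 MCS) -> B (200 MCS): one event
  ev <- detect_overtakes(series(c(rep(1L, 10), rep(2L, 10))))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$old_leader, 1L)
  expect_equal(ev$new_leader, 2L)
  # A(200) -> B(40) -> A(200): B never persists 80 MCS, no event
  flicker <- series(c(rep(1L, 10), rep(2L, 2), rep(1L, 10)))
  expect_equal(nrow(detect_overtakes(flicker)), 0)
})

test_that("overtake detection is invariant to refining the stride", {
  leaders <- c(rep(1L, 10), rep(2L, 2), rep(1L, 4), rep(3L, 8))
  coarse <- series(leaders, stride = 20)
  fine <- series(rep(leaders, each = 2), stride = 10)
  ec <- detect_overtakes(coarse)
  ef <- detect_overtakes(fine)
  expect_equal(nrow(ec), nrow(ef))
  expect_equal(ec$new_leader, ef$new_leader)
})

test_that("overtake events match an enumeration oracle on random series", {
  set.seed(60)
  for (rep_i in 1:20) {
    leaders <- sample(1:3, 40, replace = TRUE, prob = c(.45, .45, .1))
    s <- series(leaders)
    ev <- detect_overtakes(s, persistence_mcs = 80)
    # oracle: collapse runs, keep runs of >= 4 samples (80 MCS), count
    # changes between consecutive kept runs
    r <- rle(leaders)
    kept <- r$values[r$lengths * 20 >= 80]
    oracle <- if (length(kept) > 1) sum(diff(kept) != 0) else 0
    expect_equal(nrow(ev), oracle)
  }
})

test_that("tip lifetimes scale MCS tenure to minutes", {
  lt <- tip_lifetimes(series(c(rep(1L, 3), rep(2L, 5))), mcs_seconds = 30)
  expect_equal(lt$minutes, c(3 * 20 * 0.5, 5 * 20 * 0.5))
  expect_equal(lt$truncated, c(TRUE, TRUE))
  # a tenure of 884 MCS lasts 442 minutes
  lt2 <- tip_lifetimes(data.frame(mcs = seq(4, 884, by = 4), leader = 9L),
                       mcs_seconds = 30)
  expect_equal(lt2$minutes, 442)
  # single-frame tenure at 20 MCS stride is 10 minutes
  lt3 <- tip_lifetimes(series(c(1L, 2L, 2L)))
  expect_equal(lt3$minutes[1], 10)
})

test_that("coordination angles follow the axis convention", {
  ax <- sprout_axis(c(0, 0), c(0, 10), c(0, 0), c(0, 10))  # axis = +x
  tr <- data.frame(mcs = c(0, 20, 40), cell_id = 1,
                   x = c(0, 1, 0), y = c(0, 0, 0))
  co <- coordination(tr, ax)
  expect_equal(co$theta, c(0, pi))  # along, then against the axis
  # known angles: the pooled sd matches the closed form
  angles <- c(0.1, 0.3, 0.2) * pi
  tr2 <- data.frame(mcs = seq(0, 60, 20), cell_id = 2,
                    x = cumsum(c(0, cos(angles))),
                    y = cumsum(c(0, sin(angles))))
  co2 <- coordination(tr2, ax)
  expect_equal(co2$std_anterograde, sd(angles / pi))
})

test_that("directional motility classifies and sums to 100", {
  ax <- sprout_axis(c(0, 0), c(0, 10), c(0, 0), c(0, 10))
  # all stopped
  tr <- data.frame(mcs = rep(c(0, 20), 3), cell_id = rep(1:3, each = 2),
                   x = 0, y = 0)
  expect_equal(unname(directional_motility(tr, ax)), c(0, 0, 100))
  # all moving forward one site per interval
  tr2 <- data.frame(mcs = rep(c(0, 20), 3), cell_id = rep(1:3, each = 2),
                    x = rep(c(0, 1), 3), y = 0)
  expect_equal(unname(directional_motility(tr2, ax)), c(100, 0, 0))
  # mixed set against an enumeration oracle
  set.seed(61)
  n <- 50
  tr3 <- do.call(rbind, lapply(1:n, function(i) {
    dx <- rnorm(1); dy <- rnorm(1)
    if (runif(1) < 0.3) { dx <- dx / 20; dy <- dy / 20 }
    data.frame(mcs = c(0, 20), cell_id = i, x = c(0, dx), y = c(0, dy))
  }))
  got <- directional_motility(tr3, ax)
  d <- sproutcpm:::interval_displacements(tr3)
  mag <- sqrt(d$dx^2 + d$dy^2)
  stopped <- mag < 0.5
  antero <- !stopped & d$dx > 0
  retro <- !stopped & d$dx <= 0
  expect_equal(unname(got),
               100 * c(mean(antero), mean(retro), mean(stopped)))
  expect_equal(sum(got), 100)
})

test_that("MSD fit recovers ballistic motion", {
  ax <- sprout_axis(c(0, 0), c(0, 10), c(0, 0), c(0, 10))
  v0 <- 0.02  # um/s; with 2 um sites and 30 s/MCS: 0.3 sites per 20 MCS
  tr <- do.call(rbind, lapply(1:5, function(i) {
    t_mcs <- seq(0, 400, 20)
    data.frame(mcs = t_mcs, cell_id = i, x = v0 * t_mcs * 30 / 2, y = 0)
  }))
  fit <- msd_fit(tr, ax)
  expect_lt(fit$D, 1e-8)
  expect_equal(fit$v, v0, tolerance = 1e-6)
})

test_that("MSD fit recovers diffusion of a pure random walk", {
  ax <- sprout_axis(c(0, 0), c(0, 10), c(0, 0), c(0, 10))
  set.seed(62)
  s_sites <- 0.8           # step sd in sites per 20-MCS interval
  n_tracks <- 600
  t_mcs <- seq(0, 200, 20)
  tr <- do.call(rbind, lapply(seq_len(n_tracks), function(i) {
    steps <- rnorm(length(t_mcs) - 1, 0, s_sites)
    data.frame(mcs = t_mcs, cell_id = i, x = c(0, cumsum(steps)), y = 0)
  }))
  fit <- msd_fit(tr, ax)
  # D = s^2 / (2 dt) in physical units
  D_true <- (s_sites * 2)^2 / (2 * 20 * 30)
  expect_lt(fit$v, 0.005)
  expect_lt(abs(fit$D - D_true) / D_true, 0.15)
})

test_that("MSD fit recovers drift plus diffusion within 10 percent", {
  ax <- sprout_axis(c(0, 0), c(0, 10), c(0, 0), c(0, 10))
  set.seed(63)
  s_sites <- 0.5; v0 <- 0.003  # um/s
  n_tracks <- 1e4
  nlag <- 10
  steps <- matrix(rnorm(n_tracks * nlag, 0, s_sites), n_tracks, nlag)
  xs <- t(apply(steps, 1, cumsum))
  t_mcs <- (1:nlag) * 20
  xs <- sweep(xs, 2, v0 * t_mcs * 30 / 2, "+")
  tr <- data.frame(mcs = rep(c(0, t_mcs), n_tracks),
                   cell_id = rep(seq_len(n_tracks), each = nlag + 1),
                   x = as.vector(rbind(0, t(xs))), y = 0)
  fit <- msd_fit(tr, ax)
  D_true <- (s_sites * 2)^2 / (2 * 20 * 30)
  expect_lt(abs(fit$D - D_true) / D_true, 0.10)
  expect_lt(abs(fit$v - v0) / v0, 0.05)
})

test_that("MSD fit is scale-equivariant", {
  ax <- sprout_axis(c(0, 0), c(0, 10), c(0, 0), c(0, 10))
  set.seed(64)
  t_mcs <- seq(0, 200, 20)
  tr <- do.call(rbind, lapply(1:200, function(i) {
    steps <- rnorm(length(t_mcs) - 1, 0, 0.5)
    data.frame(mcs = t_mcs, cell_id = i,
               x = c(0, cumsum(steps)) + 0.005 * t_mcs * 15, y = 0)
  }))
  f1 <- msd_fit(tr, ax)
  tr2 <- transform(tr, x = 3 * x)
  f2 <- msd_fit(tr2, ax)
  expect_equal(f2$v, 3 * f1$v, tolerance = 1e-6)
  expect_equal(f2$D, 9 * f1$D, tolerance = 1e-6)
})

test_that("MSD fit demands enough lag times", {
  ax <- sprout_axis(c(0, 0), c(0, 10), c(0, 0), c(0, 10))
  tr <- data.frame(mcs = c(0, 20), cell_id = 1, x = c(0, 1), y = 0)
  expect_error(msd_fit(tr, ax), "MSD fit undefined")
})

test_that("overtake rate normalizes by sprout count and window", {
  presence <- data.frame(sprout_id = 1:3, first_mcs = 0, last_mcs = 30000)
  ev <- data.frame(sprout_id = c(1, 2, 3), mcs = c(12000, 15000, 25000),
                   old_leader = 1, new_leader = 2)
  r <- overtake_rate(ev, presence, window = c(10000, 30000))
  expect_equal(r$rate, 1.0)
  r0 <- overtake_rate(ev[0, ], presence, window = c(10000, 30000))
  expect_equal(r0$rate, 0)
  none <- overtake_rate(ev, presence[0, ], window = c(10000, 30000))
  expect_true(is.na(none$rate))
  # randomized synthetic event sets match hand counting
  set.seed(65)
  for (i in 1:10) {
    ev2 <- data.frame(sprout_id = sample(1:3, 20, TRUE),
                      mcs = sample(0:30000, 20),
                      old_leader = 1, new_leader = 2)
    r2 <- overtake_rate(ev2, presence, window = c(10000, 30000))
    expect_equal(r2$rate,
                 sum(ev2$mcs >= 10000 & ev2$mcs <= 30000) / 3)
  }
})
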