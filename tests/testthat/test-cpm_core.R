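test_that("hamiltonian reduces to the adhesion term for a relaxed cell", {
  # 5x5 cell at its target area, no length constraint, J(cell, ECM) = 1
  J <- j_table(cell_cell = 0.5, cell_ecm = 1)
  st <- single_cell_state(n = 15, w = 5, target_area = 25,
                          params = cpm_params(J = J))
  # count unordered Moore-neighbor pairs across the cell boundary
  pairs <- 0
  for (r in 1:15) for (c in 1:15) {
    if (st$labels[r, c] == 0L) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > 15 || c2 < 1 || c2 > 15) next
      if (st$labels[r2, c2] == 0L) pairs <- pairs + 1
    }
  }
  expect_equal(hamiltonian(st), pairs * 1)
})

test_that("hamiltonian of an empty lattice is zero", {
  labels <- matrix(0L, 10, 10)
  cells <- data.frame(id = integer(), kind = character(),
                      genotype = character(), target_area = numeric())
  st <- cpm_state(labels, cells)
  expect_equal(hamiltonian(st), 0)
})

test_that("area constraint contributes (A - a)^2 per cell", {
  J0 <- j_table(cell_cell = 0, cell_ecm = 0)
  st <- single_cell_state(n = 11, w = 3, target_area = 10,
                          params = cpm_params(J = J0, lambda_size = 1))
  expect_equal(hamiltonian(st), (10 - 9)^2)
})

test_that("states with a label lacking a cell record are rejected", {
  labels <- matrix(0L, 5, 5)
  labels[2, 2] <- 7L
  cells <- data.frame(id = 1L, kind = "stalk", genotype = "WT",
                      target_area = 1)
  expect_error(cpm_state(labels, cells), "without a cell record")
})

test_that("delta_h_copy matches exhaustive Hamiltonian re-evaluation", {
  # randomized proposals on a scrambled lattice, with and without the
  # length constraint; oracle = full recomputation before/after
  for (lamlen in c(0, 0.5)) {
    set.seed(101)
    st <- three_cell_state(lambda_length = lamlen)
    st <- run_mcs(st, 5)
    n_checked <- 0
    offsets <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
    offsets <- offsets[rowSums(abs(offsets)) > 0, ]
    for (i in 1:400) {
      src <- c(sample(2:19, 1), sample(2:19, 1))
      tgt <- src + offsets[sample(nrow(offsets), 1), ]
      if (any(tgt < 2) || any(tgt > 19)) next
      if (st$labels[src[1], src[2]] == st$labels[tgt[1], tgt[2]]) next
      dh <- delta_h_copy(st, src, tgt)
      h0 <- hamiltonian(st)
      st2 <- st
      st2$labels[tgt[1], tgt[2]] <- st2$labels[src[1], src[2]]
      st2 <- sproutcpm:::refresh_geometry(st2)
      h1 <- hamiltonian(st2)
      core <- dh
      # remove the connectivity penalty (not part of the Hamiltonian)
      if (core > st$params$connectivity_penalty / 2)
        core <- core - st$params$connectivity_penalty
      expect_equal(core, h1 - h0, tolerance = 1e-9)
      n_checked <- n_checked + 1
    }
    expect_gt(n_checked, 50)
  }
})

test_that("a copy that locally splits a cell carries the penalty", {
  # cell 1 is a 1-wide strip; overwriting its middle site disconnects
  # the two halves locally
  labels <- matrix(0L, 9, 9)
  labels[5, 3:7] <- 1L
  cells <- data.frame(id = 1L, kind = "stalk", genotype = "WT",
                      target_area = 5)
  st <- cpm_state(labels, cells)
  dh <- delta_h_copy(st, src = c(4, 5), tgt = c(5, 5))  # ECM -> middle
  expect_gt(dh, st$params$connectivity_penalty / 2)
  # with the penalty disabled the same copy is cheap
  st$params$connectivity <- FALSE
  dh2 <- delta_h_copy(st, src = c(4, 4), tgt = c(5, 5))
  expect_lt(dh2, st$params$connectivity_penalty / 2)
})

test_that("vacuous copies signal a no-op", {
  st <- three_cell_state()
  expect_true(is.na(delta_h_copy(st, c(4, 4), c(4, 5))))
})

test_that("accept_copy follows the Boltzmann rule", {
  p <- cpm_params()
  expect_true(accept_copy(-2, p))
  expect_true(accept_copy(0, p))
  # empirical acceptance at dh = mu over many draws: within 3 SE of e^-1
  set.seed(7)
  n <- 1e5
  acc <- mean(runif(n) < exp(-1 / p$mu))
  se <- sqrt(exp(-1) * (1 - exp(-1)) / n)
  expect_lt(abs(acc - exp(-1)), 3 * se)
})

test_that("run_mcs conserves lattice sites and is seed-deterministic", {
  set.seed(3)
  st <- three_cell_state()
  total0 <- sum(st$cells$area) + sum(st$labels == 0L)
  st2 <- run_mcs(st, 10)
  expect_equal(sum(st2$cells$area) + sum(st2$labels == 0L), total0)
  expect_identical(tabulate(st2$labels[st2$labels > 0], 3),
                   as.integer(st2$cells$area))
  set.seed(99); a <- run_mcs(three_cell_state(), 10)
  set.seed(99); b <- run_mcs(three_cell_state(), 10)
  expect_identical(a$labels, b$labels)
})

test_that("the area constraint holds a single cell near its target", {
  set.seed(21)
  st <- single_cell_state(n = 21, w = 7, target_area = 49,
                          params = cpm_params(lambda_size = 1))
  areas <- numeric(50)
  for (k in 1:50) {
    st <- run_mcs(st, 20)
    areas[k] <- st$cells$area[1]
  }
  expect_true(all(abs(areas - 49) <= 10))
  expect_lt(abs(mean(areas) - 49), 3)
})

test_that("connectivity penalty keeps cells connected over time", {
  set.seed(31)
  st <- three_cell_state()
  for (k in 1:20) {
    st <- run_mcs(st, 10)
    for (id in 1:3) {
      mask <- st$labels == id
      if (!any(mask)) next
      comp <- sproutcpm:::count_components(mask)
      expect_identical(comp, 1L)
    }
  }
})

test_that("elongation constraint drives the measured length toward L", {
  set.seed(41)
  st <- single_cell_state(n = 41, w = 7, target_area = 49,
                          params = cpm_params(lambda_length = 0.5,
                                              target_length = 20))
  l0 <- st$cells$length[1]
  lens <- numeric(30)
  for (k in 1:30) {
    st <- run_mcs(st, 20)
    lens[k] <- st$cells$length[1]
  }
  expect_gt(mean(tail(lens, 10)), l0 + 5)
  expect_lt(abs(mean(tail(lens, 10)) - 20), 6)
})

test_that("cell length estimation follows the ellipse convention", {
  # 1 x 9 row: exact second moment of a 1 x 9 rectangle is 81/12
  row9 <- cbind(1, 1:9)
  expect_equal(estimate_cell_length(row9), 4 * sqrt(81 / 12),
               tolerance = 1e-9)
  # n x n square: isotropic, length 4 * n / sqrt(12)
  sq <- as.matrix(expand.grid(1:6, 1:6))
  expect_equal(estimate_cell_length(sq), 4 * 6 / sqrt(12), tolerance = 1e-9)
  # rotation by 90 degrees leaves the estimate unchanged
  rot <- cbind(row9[, 2], -row9[, 1])
  expect_equal(estimate_cell_length(rot), estimate_cell_length(row9))
  expect_error(estimate_cell_length(matrix(numeric(), 0, 2)), "empty")
})
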