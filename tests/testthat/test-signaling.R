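test_that("contact map matches a brute-force bond count", {
  set.seed(17)
  st <- three_cell_state()
  st <- run_mcs(st, 5)
  labels <- st$labels
  cm <- compute_contact_map(labels)
  # brute force over all 4-neighbor bonds
  H <- nrow(labels); W <- ncol(labels)
  P <- numeric(3); pair <- matrix(0, 3, 3)
  for (r in 1:H) for (c in 1:W) {
    for (d in list(c(0, 1), c(1, 0))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 > H || c2 > W) next
      a <- labels[r, c]; b <- labels[r2, c2]
      if (a == b) next
      if (a > 0) P[a] <- P[a] + 1
      if (b > 0) P[b] <- P[b] + 1
      if (a > 0 && b > 0) {
        pair[min(a, b), max(a, b)] <- pair[min(a, b), max(a, b)] + 1
      }
    }
  }
  expect_equal(cm$membrane, P)
  for (k in seq_len(nrow(cm$pairs)))
    expect_equal(cm$pairs$links[k], pair[cm$pairs$i[k], cm$pairs$j[k]])
  # symmetry of weights and the membrane bound
  expect_equal(cm$W, t(cm$W))
  agg <- tapply(c(cm$pairs$links, cm$pairs$links),
                c(cm$pairs$i, cm$pairs$j), sum)
  for (id in names(agg))
    expect_lte(agg[[id]], cm$membrane[as.integer(id)])
})

test_that("isolated cells have empty neighborhoods and full membrane", {
  st <- single_cell_state(n = 11, w = 3)
  cm <- compute_contact_map(st$labels)
  expect_equal(nrow(cm$pairs), 0)
  expect_equal(cm$membrane[1], 12)  # 4 sides x 3 sites
  expect_equal(contact_neighbors(cm)[[1]], NULL)
})

test_that("two abutting rectangles have symmetric contact sizes", {
  labels <- matrix(0L, 10, 10)
  labels[3:6, 2:5] <- 1L
  labels[3:6, 6:9] <- 2L
  cm <- compute_contact_map(labels)
  expect_equal(cm$pairs$links, 4)
  expect_equal(cm$W[1, 2], cm$W[2, 1])
})

test_that("an isolated cell relaxes to the contact-free fixed point", {
  p <- signaling_params()
  cmap <- structure(list(membrane = 12, pairs = data.frame(
    i = integer(), j = integer(), links = numeric()),
    W = matrix(0, 1, 1)), class = "contact_map")
  s <- cbind(D = 2, N = 2, S = 1, R = 1, A = 0)
  for (i in 1:30000) s <- step_dll4_notch(s, cmap, p)
  fp <- sproutcpm:::isolated_fixed_point(p)
  expect_equal(as.numeric(s[1, "S"]), 0, tolerance = 1e-6)
  expect_equal(as.numeric(s[1, "D"]), unname(fp["D"]), tolerance = 1e-3)
  expect_equal(as.numeric(s[1, "N"]), unname(fp["N"]), tolerance = 1e-3)
})

test_that("Euler trajectories match a high-order reference integrator", {
  skip_if_not_installed("deSolve")
  p <- signaling_params()
  cm <- two_cell_contacts()
  gen <- c("WT", "VEGFR2_HAPLOID")
  set.seed(4)
  s0 <- signaling_init(gen, p)
  t_total <- 3000
  rhs <- signaling_rhs_desolve(2, cm, p, gen, vegf = TRUE)
  ref <- deSolve::ode(y = as.vector(s0), times = c(0, t_total), func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  ref_end <- matrix(ref[2, -1], 2, 5)
  s_dt3 <- euler_fine(s0, cm, p, gen, TRUE, t_total, 3)
  s_dt1.5 <- euler_fine(s0, cm, p, gen, TRUE, t_total, 1.5)
  err3 <- max(abs(s_dt3 - ref_end))
  err1.5 <- max(abs(s_dt1.5 - ref_end))
  expect_lt(err3, 0.01)
  # halving dt roughly halves the global Euler error
  expect_lt(err1.5, 0.65 * err3)
})

test_that("symmetric two-cell systems stay exactly symmetric", {
  p <- signaling_params()
  cm <- two_cell_contacts()
  s <- cbind(D = c(1.5, 1.5), N = c(0.5, 0.5), S = c(0, 0),
             R = c(1.9, 1.9), A = c(0.8, 0.8))
  for (i in 1:5000) s <- signaling_step(s, cm, p, c("WT", "WT"))
  expect_identical(s[1, ], s[2, ])
})

test_that("a small Dll4 perturbation breaks symmetry (lateral inhibition)", {
  p <- signaling_params()
  cm <- two_cell_contacts()
  s <- cbind(D = c(1.51, 1.49), N = c(0.5, 0.5), S = c(0, 0),
             R = c(0, 0), A = c(0, 0))
  for (i in 1:60000) s <- step_dll4_notch(s, cm, p)
  # one high-Dll4/low-NICD cell and one low-Dll4/high-NICD cell
  expect_gt(abs(diff(s[, "S"])), 0.5)
  hi_D <- which.max(s[, "D"])
  expect_equal(which.min(s[, "S"]), hi_D)
})

test_that("trans weights are invariant under swapping cell indices", {
  set.seed(23)
  st <- three_cell_state(); st <- run_mcs(st, 3)
  cm <- compute_contact_map(st$labels)
  expect_equal(cm$W, t(cm$W))
})

test_that("VEGF extension reduces to Dll4-Notch when V_ext = 0", {
  p <- signaling_params(V_ext = 0)
  cm <- two_cell_contacts()
  gen <- c("WT", "WT")
  s <- cbind(D = c(1.4, 1.6), N = c(0.5, 0.5), S = c(0.1, 0.2),
             R = c(1, 1), A = c(0, 0))
  s_full <- signaling_step(s, cm, p, gen, vegf = TRUE)
  s_dn <- step_dll4_notch(s, cm, p)
  # identical D/N/S dynamics (Hill(0) = 0); activity stays at zero
  expect_equal(s_full[, c("D", "N", "S")], s_dn[, c("D", "N", "S")])
  expect_equal(as.numeric(s_full[, "A"]), c(0, 0))
  # a cell with residual activity sees it decay when V_ext = 0
  s2 <- cbind(D = 1, N = 0.5, S = 0.1, R = 1, A = 0.5)
  cm1 <- structure(list(membrane = 10, pairs = data.frame(
    i = integer(), j = integer(), links = numeric()),
    W = matrix(0, 1, 1)), class = "contact_map")
  s2b <- step_vegf_extension(s2, cm1, p, "WT")
  expect_lt(s2b[1, "A"], 0.5)
})

test_that("haploid steady-state VEGFR2 is exactly half of wild type", {
  p <- signaling_params()
  cm <- two_cell_contacts(w = 0)  # no trans-signaling, S stays ~0
  gen <- c("WT", "VEGFR2_HAPLOID")
  s <- cbind(D = c(0, 0), N = c(0, 0), S = c(0, 0), R = c(0, 0),
             A = c(0, 0))
  for (i in 1:40000) {
    s <- step_vegf_extension(s, cm, p, gen)
    s[, "S"] <- 0
  }
  R_wt_expected <- (p$beta_Rc + p$beta_R) / p$gamma_R
  expect_equal(as.numeric(s[1, "R"]), R_wt_expected, tolerance = 1e-3)
  expect_equal(as.numeric(s[2, "R"]), R_wt_expected / 2, tolerance = 1e-3)
  expect_error(step_vegf_extension(s, cm, p, c("WT", "mutant")),
               "unknown genotype")
})

test_that("even rings alternate and odd rings are frustrated", {
  p <- signaling_params()
  set.seed(31)
  for (n in c(6, 12)) {
    cm <- ring_contacts(n)
    s <- signaling_init(rep("WT", n), p)
    for (i in 1:60000) s <- signaling_step(s, cm, p, rep("WT", n),
                                           vegf = FALSE)
    kinds <- assign_phenotypes(s, p)
    # perfect alternation: no adjacent pair with the same phenotype
    same <- kinds == kinds[c(2:n, 1)]
    expect_false(any(same))
  }
  # odd ring: at least one adjacent pair must share a fate
  n <- 7
  cm <- ring_contacts(n)
  s <- signaling_init(rep("WT", n), p)
  for (i in 1:60000) s <- signaling_step(s, cm, p, rep("WT", n),
                                         vegf = FALSE)
  kinds <- assign_phenotypes(s, p)
  expect_true(any(kinds == kinds[c(2:n, 1)]))
})

test_that("genotype effect: WT steady VEGFR2 exceeds the haploid's", {
  p <- signaling_params()
  cm <- two_cell_contacts()
  gen <- c("WT", "VEGFR2_HAPLOID")
  set.seed(6)
  s <- signaling_init(gen, p)
  for (i in 1:40000) s <- signaling_step(s, cm, p, gen)
  expect_gt(s[1, "R"], s[2, "R"])
})

test_that("phenotype assignment thresholds NICD with stalk at the boundary", {
  p <- signaling_params(nicd_threshold = 1)
  s <- cbind(D = c(0, 0, 0), N = c(0, 0, 0), S = c(0, 1, 2),
             R = c(0, 0, 0), A = c(0, 0, 0))
  expect_equal(assign_phenotypes(s, p), c("tip", "stalk", "stalk"))
})

test_that("NICD threshold calibration splits bimodal levels", {
  x <- c(rep(0.1, 10), rep(0.9, 10))
  expect_equal(calibrate_nicd_threshold(x), 0.5)
  expect_error(calibrate_nicd_threshold(rep(0.3, 10)), "degenerate")
  # two-cell lateral-inhibition steady state separates cleanly
  p <- signaling_params()
  cm <- two_cell_contacts()
  s <- cbind(D = c(1.51, 1.49), N = c(0.5, 0.5), S = c(0, 0),
             R = c(0, 0), A = c(0, 0))
  for (i in 1:60000) s <- step_dll4_notch(s, cm, p)
  thr <- calibrate_nicd_threshold(s[, "S"])
  expect_gt(thr, min(s[, "S"]))
  expect_lt(thr, max(s[, "S"]))
})

test_that("negative Euler overshoots are clipped and counted", {
  p <- signaling_params(ode_dt = 1e6)  # absurd step to force overshoot
  cmap <- structure(list(membrane = 10, pairs = data.frame(
    i = integer(), j = integer(), links = numeric()),
    W = matrix(0, 1, 1)), class = "contact_map")
  s <- cbind(D = 0.01, N = 0.01, S = 5, R = 0.01, A = 0.01)
  s2 <- step_dll4_notch(s, cmap, p)
  expect_true(all(s2 >= 0))
  expect_gt(attr(s2, "n_clipped"), 0)
})
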