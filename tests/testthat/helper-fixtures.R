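# shared fixture builders (all fixtures are generated in code)

# small state with three rectangular cells on a 20x20 lattice
three_cell_state <- function(lambda_length = 0, target_length = 10,
                             params = NULL) {
  labels <- matrix(0L, 20, 20)
  labels[3:8, 3:8] <- 1L
  labels[10:15, 4:9] <- 2L
  labels[5:10, 12:17] <- 3L
  cells <- data.frame(id = 1:3, kind = c("tip", "stalk", "stalk"),
                      genotype = "WT", target_area = 36)
  if (is.null(params))
    params <- cpm_params(lambda_length = lambda_length,
                         target_length = target_length)
  cpm_state(labels, cells, params)
}

# single square cell of side w centered in an n x n lattice
single_cell_state <- function(n = 15, w = 5, target_area = w^2,
                              params = cpm_params()) {
  labels <- matrix(0L, n, n)
  lo <- (n - w) %/% 2 + 1
  labels[lo:(lo + w - 1), lo:(lo + w - 1)] <- 1L
  cells <- data.frame(id = 1L, kind = "stalk", genotype = "WT",
                      target_area = target_area)
  cpm_state(labels, cells, params)
}

# contact map for two cells in mutual contact with given weight
two_cell_contacts <- function(w = 0.25, membrane = 10, links = 5) {
  structure(list(membrane = rep(membrane, 2),
                 pairs = data.frame(i = 1L, j = 2L, links = links),
                 W = matrix(c(0, w, w, 0), 2, 2)),
            class = "contact_map")
}

# ring contact graph of n cells, constant trans weight between neighbors
ring_contacts <- function(n, w = 0.0625, membrane = 20) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    W[i, j] <- W[j, i] <- w
  }
  structure(list(membrane = rep(membrane, n),
                 pairs = data.frame(i = seq_len(n), j = seq_len(n) %% n + 1L,
                                    links = 5),
                 W = W), class = "contact_map")
}

# straight horizontal bar mask
bar_mask <- function(H = 40, W = 120, width = 6, len = 100) {
  m <- matrix(0L, H, W)
  r0 <- (H - width) %/% 2 + 1
  c0 <- (W - len) %/% 2 + 1
  m[r0:(r0 + width - 1), c0:(c0 + len - 1)] <- 1L
  m
}

# Y-shaped mask: a trunk splitting into two arms, all of given widths
y_mask <- function(trunk = 40, arm = 30, width = 6, H = 110, W = 110) {
  m <- matrix(0L, H, W)
  cx <- W %/% 2
  jy <- 60
  m[(jy):(jy + trunk), (cx - width %/% 2):(cx + width %/% 2)] <- 1L
  for (k in 0:arm) {
    # two arms going up-left and up-right at 45 degrees
    m[jy - k, (cx - k - width %/% 2):(cx - k + width %/% 2)] <- 1L
    m[jy - k, (cx + k - width %/% 2):(cx + k + width %/% 2)] <- 1L
  }
  m
}

# deterministic reference Euler at fine dt used as a poor-man's check;
# high-accuracy oracle integration uses deSolve in the tests themselves
euler_fine <- function(states, contacts, params, genotypes, vegf, t_total,
                       dt_fine) {
  p <- params
  p$ode_dt <- dt_fine
  steps <- round(t_total / dt_fine)
  for (i in seq_len(steps))
    states <- signaling_step(states, contacts, p, genotypes, vegf)
  states
}

# deSolve right-hand side of the full signaling system for n cells
signaling_rhs_desolve <- function(n, contacts, params, genotypes, vegf) {
  function(t, y, parms) {
    states <- matrix(y, n, 5,
                     dimnames = list(NULL, c("D", "N", "S", "R", "A")))
    d <- sproutcpm:::deriv_dll4_notch(states, contacts, params)
    if (vegf)
      d <- d + sproutcpm:::deriv_vegf(states, contacts, params, genotypes)
    list(as.vector(d))
  }
}
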