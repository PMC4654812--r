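#' VEGF-Dll4-Notch signaling parameters
#'
#' Rate constants of the per-cell ODE network. Each cell i carries Dll4
#' (`D`), Notch (`N`), NICD (`S`), VEGFR2 (`R`) and VEGF signaling
#' activity (`A`), all in dimensionless model units; rates are per second.
#' Trans-signaling between cells i and j is weighted by the shared
#' membrane fraction `|P_ij|^2 / (|P_i| |P_j|)` and scaled by `1/d^2`;
#' cis-inhibition couples D and N within a cell through `1/k_c`.
#'
#' NICD is produced by a Hill function (`alpha_S`, `k_S`, `n_S`) of the
#' weighted trans input and decays at `gamma_S`. Dll4 has constitutive
#' (`beta_Dc`) and NICD-repressed (`beta_D`, exponent `m_D`) production,
#' decay `gamma_D`, cis and trans losses, and - with VEGF - an extra
#' production term `alpha_D * A^n_D / (k_D + A^n_D)`. Notch has
#' constitutive production `beta_N`, decay `gamma_N` and the same loss
#' terms. VEGFR2 production (`beta_Rc` constitutive, `beta_R` repressed by
#' NICD with exponent `m_R`) is halved for the `VEGFR2_HAPLOID` genotype.
#' VEGF activity follows a Hill function (`alpha_A`, `k_A`, `n_A`) of the
#' VEGF concentration perceived at the membrane (`R_i * V_ext` under a
#' uniform external field).
#'
#' Defaults are calibrated so that lateral inhibition produces alternating
#' (salt-and-pepper) tip/stalk patterns and, with VEGF, Dll4 and VEGFR2
#' levels correlate, giving wild-type cells a tip-fate advantage over
#' haploids.
#'
#' @param nicd_threshold NICD level separating the tip (below) from the
#'   stalk (at or above) phenotype; see [calibrate_nicd_threshold()].
#' @param ode_dt Euler time step in seconds.
#' @param iters_per_mcs Euler substeps per Monte Carlo step.
#' @param V_ext uniform external VEGF level.
#' @param ... other rate constants, see Details.
#' @return an object of class `signaling_params`.
#' @export
signaling_params <- function(alpha_S = 0.008, k_S = 0.01, n_S = 2,
                             gamma_S = 0.002,
                             beta_Dc = 2e-4, beta_D = 0.0036, m_D = 2,
                             gamma_D = 0.002,
                             beta_N = 0.002, gamma_N = 0.002,
                             k_c = 500, k_t = 500, d = 1,
                             alpha_A = 0.002, k_A = 1, n_A = 2,
                             gamma_A = 0.002,
                             beta_Rc = 2e-4, beta_R = 0.0036, m_R = 2,
                             gamma_R = 0.002,
                             alpha_D_vegf = 0.004, k_D = 0.25, n_D = 2,
                             V_ext = 1, nicd_threshold = 1,
                             ode_dt = 3, iters_per_mcs = 10L, ...) {
  p <- c(as.list(environment()), list(...))
  rates <- c("alpha_S", "gamma_S", "beta_Dc", "beta_D", "gamma_D",
             "beta_N", "gamma_N", "alpha_A", "gamma_A", "beta_Rc",
             "beta_R", "gamma_R", "alpha_D_vegf")
  stopifnot(all(unlist(p[rates]) >= 0),
            p$n_S >= 1, p$m_D >= 1, p$n_A >= 1, p$m_R >= 1, p$n_D >= 1,
            p$k_c > 0, p$k_t > 0, p$d > 0, p$ode_dt > 0)
  p$iters_per_mcs <- as.integer(p$iters_per_mcs)
  structure(p, class = "signaling_params")
}

#' Compute the cell-contact map of a lattice
#'
#' Membrane and contact sizes by boundary-link counting in the
#' 4-neighborhood: `membrane[i]` is the number of lattice bonds between a
#' site of cell i and any site outside cell i, and the contact size
#' between cells i and j is the number of bonds between their sites
#' (symmetric by construction, and the contacts of a cell never exceed its
#' membrane size).
#'
#' @param labels integer label matrix (0 = ECM).
#' @param ncell number of cells (defaults to `max(labels)`).
#' @return an object of class `contact_map`: list with `membrane` (numeric
#'   vector indexed by cell id), `pairs` (data frame `i`, `j`, `links`
#'   with `i < j`) and `W`, the dense symmetric matrix of trans weights
#'   `|P_ij|^2 / (|P_i| |P_j|)`.
#' @export
compute_contact_map <- function(labels, ncell = max(labels)) {
  storage.mode(labels) <- "integer"
  ncell <- max(as.integer(ncell), 0L)
  raw <- .contact_map_cpp(labels, ncell)
  membrane <- raw$membrane
  pairs <- data.frame(i = raw$i, j = raw$j, links = raw$links)
  W <- matrix(0, ncell, ncell)
  if (nrow(pairs)) {
    w <- pairs$links^2 / (membrane[pairs$i] * membrane[pairs$j])
    W[cbind(pairs$i, pairs$j)] <- w
    W[cbind(pairs$j, pairs$i)] <- w
  }
  structure(list(membrane = membrane, pairs = pairs, W = W),
            class = "contact_map")
}

#' Neighbor sets from a contact map
#'
#' @param contacts a [compute_contact_map()] result.
#' @return list of integer neighbor-id vectors, indexed by cell id.
#' @export
contact_neighbors <- function(contacts) {
  n <- length(contacts$membrane)
  nb <- vector("list", n)
  for (k in seq_len(nrow(contacts$pairs))) {
    i <- contacts$pairs$i[k]; j <- contacts$pairs$j[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

#' Initial signaling state
#'
#' All cells start at the homogeneous steady state of the contact-free
#' system (no trans-signaling: NICD at zero, Dll4 and Notch at their
#' cis-coupled fixed point, VEGFR2 and VEGF activity at their genotype's
#' fixed point for `S = 0`), perturbed by multiplicative Gaussian noise to
#' break the symmetry that lateral inhibition then amplifies.
#'
#' @param genotypes character vector ("WT" or "VEGFR2_HAPLOID"), one per
#'   cell.
#' @param params a [signaling_params()].
#' @param noise_sd standard deviation of the multiplicative noise (0.01 =
#'   1 percent).
#' @return numeric matrix with one row per cell and columns
#'   `D`, `N`, `S`, `R`, `A`.
#' @export
signaling_init <- function(genotypes, params, noise_sd = 0.01) {
  n <- length(genotypes)
  fp <- isolated_fixed_point(params)
  g <- ifelse(genotypes == "VEGFR2_HAPLOID", 0.5, 1)
  R0 <- g * (params$beta_Rc + params$beta_R) / params$gamma_R
  V <- R0 * params$V_ext
  A0 <- params$alpha_A * hill(V, params$k_A, params$n_A) / params$gamma_A
  states <- cbind(D = rep(fp["D"], n), N = rep(fp["N"], n),
                  S = rep(0, n), R = R0, A = A0)
  states * (1 + noise_sd * matrix(rnorm(n * 5), n, 5))
}

hill <- function(x, k, n) {
  xn <- x^n
  xn / (k + xn)
}

# cis-coupled fixed point of the isolated (contact-free) cell at S = 0
isolated_fixed_point <- function(params) {
  p <- params
  D <- (p$beta_Dc + p$beta_D) / p$gamma_D
  N <- p$beta_N / p$gamma_N
  for (it in 1:200) {
    Dn <- (p$beta_Dc + p$beta_D) / (p$gamma_D + N / p$k_c)
    Nn <- p$beta_N / (p$gamma_N + Dn / p$k_c)
    if (abs(Dn - D) + abs(Nn - N) < 1e-12) { D <- Dn; N <- Nn; break }
    D <- Dn; N <- Nn
  }
  c(D = D, N = N)
}

# time derivatives of the Dll4/Notch/NICD subsystem (trans input via W)
deriv_dll4_notch <- function(states, contacts, params) {
  p <- params
  D <- states[, "D"]; N <- states[, "N"]; S <- states[, "S"]
  WD <- as.vector(contacts$W %*% D)  # sum_j D_j w_ij
  WN <- as.vector(contacts$W %*% N)  # sum_j N_j w_ij
  trans_in <- N * WD / p$d^2
  dS <- p$alpha_S * hill(trans_in, p$k_S, p$n_S) - p$gamma_S * S
  dD <- p$beta_Dc + p$beta_D / (1 + S^p$m_D) - p$gamma_D * D -
    D * N / p$k_c - D * WN / (p$k_t * p$d^2)
  dN <- p$beta_N - p$gamma_N * N - N * D / p$k_c -
    N * WD / (p$k_t * p$d^2)
  cbind(D = dD, N = dN, S = dS, R = 0, A = 0)
}

# time derivatives of the VEGF extension: VEGFR2, VEGF activity, and the
# VEGF-driven extra Dll4 production
deriv_vegf <- function(states, contacts, params, genotypes) {
  p <- params
  S <- states[, "S"]; R <- states[, "R"]; A <- states[, "A"]
  bad <- setdiff(unique(genotypes), c("WT", "VEGFR2_HAPLOID"))
  if (length(bad)) stop("unknown genotype: ", paste(bad, collapse = ", "))
  g <- ifelse(genotypes == "VEGFR2_HAPLOID", 0.5, 1)
  dR <- g * (p$beta_Rc + p$beta_R / (1 + S^p$m_R)) - p$gamma_R * R
  V_perceived <- R * p$V_ext  # uniform field: membrane average is R*V
  dA <- p$alpha_A * hill(V_perceived, p$k_A, p$n_A) - p$gamma_A * A
  dD <- p$alpha_D_vegf * hill(A, p$k_D, p$n_D)
  cbind(D = dD, N = 0, S = 0, R = dR, A = dA)
}

clip_states <- function(states) {
  neg <- states < 0
  if (any(neg)) {
    states[neg] <- 0
    attr(states, "n_clipped") <- sum(neg)
  } else attr(states, "n_clipped") <- 0L
  states
}

#' One Euler step of the Dll4-Notch-NICD subsystem
#'
#' Forward Euler with step `ode_dt` of the lateral-inhibition network with
#' cis-inhibition, trans terms weighted by the shared membrane fractions.
#' Negative overshoots are clipped to zero (count in attribute
#' `n_clipped`).
#'
#' @param states matrix as returned by [signaling_init()].
#' @param contacts a [compute_contact_map()] for the same cells.
#' @param params a [signaling_params()].
#' @return the updated state matrix.
#' @export
step_dll4_notch <- function(states, contacts, params) {
  if (nrow(states) != length(contacts$membrane))
    stop("signaling states and contact map describe different cell sets")
  clip_states(states + params$ode_dt * deriv_dll4_notch(states, contacts, params))
}

#' One Euler step of the VEGF extension
#'
#' Updates VEGFR2 and VEGF signaling activity and adds the VEGF-driven
#' Dll4 production. With `V_ext = 0`, activity decays to zero and the
#' system reduces to pure Dll4-Notch signaling.
#'
#' @inheritParams step_dll4_notch
#' @param genotypes character vector ("WT" or "VEGFR2_HAPLOID").
#' @return the updated state matrix.
#' @export
step_vegf_extension <- function(states, contacts, params, genotypes) {
  clip_states(states + params$ode_dt *
                deriv_vegf(states, contacts, params, genotypes))
}

#' One full Euler step (both subsystems from the same state)
#'
#' @inheritParams step_vegf_extension
#' @param vegf logical; include the VEGF extension.
#' @return the updated state matrix.
#' @export
signaling_step <- function(states, contacts, params, genotypes,
                           vegf = TRUE) {
  d <- deriv_dll4_notch(states, contacts, params)
  if (vegf) d <- d + deriv_vegf(states, contacts, params, genotypes)
  clip_states(states + params$ode_dt * d)
}

#' Signaling substeps for one Monte Carlo step
#'
#' Applies `iters_per_mcs` Euler substeps with the contact map held fixed
#' (the lattice is frozen within an MCS's signaling update).
#'
#' @inheritParams signaling_step
#' @return the updated state matrix with attribute `n_clipped`.
#' @export
signaling_mcs <- function(states, contacts, params, genotypes,
                          vegf = TRUE) {
  nclip <- 0L
  for (i in seq_len(params$iters_per_mcs)) {
    states <- signaling_step(states, contacts, params, genotypes, vegf)
    nclip <- nclip + attr(states, "n_clipped")
  }
  attr(states, "n_clipped") <- nclip
  states
}

#' Assign tip/stalk phenotypes from NICD levels
#'
#' A cell differentiates into a tip cell when its NICD level lies below
#' the threshold, and into a stalk cell otherwise (the boundary value is
#' assigned to stalk).
#'
#' @param states signaling state matrix.
#' @param params a [signaling_params()].
#' @return character vector of kinds ("tip"/"stalk").
#' @export
assign_phenotypes <- function(states, params) {
  ifelse(states[, "S"] < params$nicd_threshold, "tip", "stalk")
}

#' Calibrate the NICD phenotype threshold
#'
#' Given steady-state NICD levels from a calibration run, splits them into
#' the two modes of the expected bimodal (tip-low / stalk-high)
#' distribution by the optimal two-cluster partition in one dimension and
#' returns the midpoint between the two cluster means. Fails with a
#' diagnostic when the distribution is not bimodal (cluster separation
#' smaller than twice the pooled within-cluster spread).
#'
#' @param steady_states numeric vector of NICD levels.
#' @return scalar threshold.
#' @export
calibrate_nicd_threshold <- function(steady_states) {
  x <- sort(as.numeric(steady_states))
  n <- length(x)
  if (n < 2 || diff(range(x)) == 0)
    stop("NICD calibration failed: degenerate (unimodal) level distribution")
  best <- NULL
  for (k in 1:(n - 1)) {
    lo <- x[1:k]; hi <- x[(k + 1):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (is.null(best) || ss < best$ss)
      best <- list(ss = ss, k = k, m1 = mean(lo), m2 = mean(hi),
                   s1 = if (k > 1) sd(lo) else 0,
                   s2 = if (n - k > 1) sd(hi) else 0)
  }
  pooled <- sqrt(mean(c(best$s1, best$s2)^2))
  if (!is.finite(pooled)) pooled <- 0
  if ((best$m2 - best$m1) < 2 * pooled)
    stop(sprintf(paste0("NICD calibration failed: no bimodal separation ",
                        "(cluster means %.4g and %.4g, pooled spread %.4g)"),
                 best$m1, best$m2, pooled))
  (best$m1 + best$m2) / 2
}
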