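#' Interfacial energy table
#'
#' Builds the symmetric J lookup table over the kinds ECM, tip and stalk.
#' Higher J means weaker adhesion across that interface. The ECM-ECM entry
#' is zero by convention (it never contributes: identical labels carry no
#' interfacial energy, and distinct ECM regions do not exist).
#'
#' @param cell_cell adhesion energy between any two cells (tip or stalk).
#' @param cell_ecm adhesion energy between a cell and the matrix.
#' @return a 3x3 named symmetric matrix.
#' @export
j_table <- function(cell_cell = 0.4, cell_ecm = 0.6) {
  J <- matrix(cell_cell, 3, 3, dimnames = list(KIND_LEVELS, KIND_LEVELS))
  J["ECM", ] <- cell_ecm
  J[, "ECM"] <- cell_ecm
  J["ECM", "ECM"] <- 0
  J
}

#' Cellular Potts model parameters
#'
#' @param J symmetric 3x3 interfacial-energy table (see [j_table()]).
#' @param lambda_size weight of the area constraint.
#' @param lambda_length weight of the length constraint (0 disables it; the
#'   contact-inhibition model runs with 0, the elongation model with > 0).
#'   Applies to cells only, never to the ECM.
#' @param target_length target cell length in lattice sites.
#' @param mu Cellular Potts temperature; copies raising the energy by
#'   `dh` are accepted with probability `exp(-dh / mu)`.
#' @param connectivity_penalty energy added to a copy that would locally
#'   split the retracting cell into disconnected pieces.
#' @param connectivity logical; enable the local-connectivity penalty.
#' @param mcs_seconds wall-clock seconds represented by one Monte Carlo
#'   step (30 s).
#' @param site_um lattice spacing in micrometers (2 um per site).
#' @return an object of class `cpm_params`.
#' @export
cpm_params <- function(J = j_table(), lambda_size = 1, lambda_length = 0,
                       target_length = 0, mu = 1,
                       connectivity_penalty = 1e5, connectivity = TRUE,
                       mcs_seconds = 30, site_um = 2) {
  stopifnot(is.matrix(J), nrow(J) == 3, ncol(J) == 3,
            isTRUE(all.equal(J, t(J))),
            mu > 0, lambda_size >= 0, lambda_length >= 0,
            connectivity_penalty > 0)
  structure(list(J = J, lambda_size = lambda_size,
                 lambda_length = lambda_length,
                 target_length = target_length, mu = mu,
                 connectivity_penalty = connectivity_penalty,
                 connectivity = connectivity, mcs_seconds = mcs_seconds,
                 site_um = site_um),
            class = "cpm_params")
}

#' Create a simulation state
#'
#' Bundles the label lattice, the per-cell record table and the model
#' parameters. Every nonzero label occurring in `labels` must have a row in
#' `cells`; bookkeeping fields (area, centroid, length) are derived from the
#' lattice.
#'
#' @param labels integer matrix of cell identifiers, 0 = ECM.
#' @param cells data frame with columns `id`, `kind` ("tip" or "stalk"),
#'   `genotype` ("WT" or "VEGFR2_HAPLOID"), `target_area`, and optionally
#'   `lambda_length` and `target_length` (defaults taken from `params`).
#' @param params a [cpm_params()] object.
#' @param chem optional [chem_field()] matched to the lattice.
#' @return an object of class `cpm_state`.
#' @export
cpm_state <- function(labels, cells, params = cpm_params(), chem = NULL) {
  storage.mode(labels) <- "integer"
  stopifnot(is.data.frame(cells), all(c("id", "kind") %in% names(cells)))
  cells$id <- as.integer(cells$id)
  if (any(cells$id < 1L) || anyDuplicated(cells$id))
    stop("cell ids must be distinct positive integers")
  n <- nrow(cells)
  if (is.null(cells$genotype)) cells$genotype <- rep("WT", n)
  if (is.null(cells$target_area)) stop("cells$target_area is required")
  if (is.null(cells$lambda_length))
    cells$lambda_length <- rep(params$lambda_length, n)
  if (is.null(cells$target_length))
    cells$target_length <- rep(params$target_length, n)
  if (any(cells$kind == "ECM")) stop("kind ECM is reserved for label 0")
  present <- sort(unique(labels[labels > 0L]))
  if (!all(present %in% cells$id))
    stop("labels present in the lattice without a cell record: ",
         paste(setdiff(present, cells$id), collapse = ", "))
  cells <- cells[order(cells$id), , drop = FALSE]
  if (!identical(cells$id, seq_len(nrow(cells))))
    stop("cell ids must be 1..ncell (dense labeling)")
  state <- structure(list(labels = labels, cells = cells, params = params,
                          chem = chem, time_mcs = 0L),
                     class = "cpm_state")
  refresh_geometry(state)
}

#' @export
print.cpm_state <- function(x, ...) {
  cat(sprintf("<cpm_state> %d x %d lattice, %d cells (%d alive), t = %d MCS\n",
              nrow(x$labels), ncol(x$labels), nrow(x$cells),
              sum(x$cells$area > 0), x$time_mcs))
  invisible(x)
}

# recompute per-cell area, centroid and length from the lattice
refresh_geometry <- function(state) {
  labels <- state$labels
  ncell <- nrow(state$cells)
  a <- tabulate(labels[labels > 0L], nbins = ncell)
  state$cells$area <- a
  cr <- cc <- ll <- rep(NA_real_, ncell)
  if (ncell > 0) {
    idx <- which(labels > 0L)
    if (length(idx)) {
      lab <- labels[idx]
      rows <- (idx - 1L) %% nrow(labels) + 1L
      cols <- (idx - 1L) %/% nrow(labels) + 1L
      cr[] <- rowsum_safe(rows, lab, ncell) / pmax(a, 1)
      cc[] <- rowsum_safe(cols, lab, ncell) / pmax(a, 1)
      for (i in which(a > 0)) {
        s <- which(labels == i, arr.ind = TRUE)
        ll[i] <- estimate_cell_length(s)
      }
    }
  }
  cr[a == 0] <- NA_real_
  cc[a == 0] <- NA_real_
  ll[a == 0] <- 0
  state$cells$centroid_row <- cr
  state$cells$centroid_col <- cc
  state$cells$length <- ll
  state
}

rowsum_safe <- function(x, group, nbins) {
  out <- numeric(nbins)
  s <- rowsum(as.numeric(x), group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

site_kind_codes <- function(state) {
  codes <- c(0L, kind_code(state$cells$kind))
  matrix(codes[state$labels + 1L], nrow(state$labels), ncol(state$labels))
}

#' Total Hamiltonian energy of a state
#'
#' Reference (full) evaluation of the Cellular Potts energy: interfacial
#' energy summed once over every unordered pair of 2nd-order (Moore)
#' neighbor sites with distinct labels, plus the quadratic area constraint
#' over all cells, plus the quadratic length constraint for cells with a
#' positive length weight. Used as the exhaustive oracle against which the
#' incremental [delta_h_copy()] is validated.
#'
#' @param state a [cpm_state()].
#' @return scalar energy.
#' @export
hamiltonian <- function(state) {
  labels <- state$labels
  kinds <- site_kind_codes(state)
  J <- state$params$J
  H <- nrow(labels); W <- ncol(labels)
  adh <- 0
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (sft in shifts) {
    dr <- sft[1]; dc <- sft[2]
    r1 <- seq_len(H - dr); c1 <- if (dc >= 0) seq_len(W - dc) else seq.int(1 - dc, W)
    r2 <- r1 + dr; c2 <- c1 + dc
    la <- labels[r1, c1, drop = FALSE]; lb <- labels[r2, c2, drop = FALSE]
    ka <- kinds[r1, c1, drop = FALSE]; kb <- kinds[r2, c2, drop = FALSE]
    diff <- la != lb
    if (any(diff)) adh <- adh + sum(J[cbind(ka[diff] + 1L, kb[diff] + 1L)])
  }
  area_term <- state$params$lambda_size *
    sum((state$cells$target_area - state$cells$area)^2)
  len_term <- 0
  for (i in seq_len(nrow(state$cells))) {
    lam <- state$cells$lambda_length[i]
    if (lam > 0) {
      l <- if (state$cells$area[i] > 0)
        estimate_cell_length(which(labels == i, arr.ind = TRUE)) else 0
      len_term <- len_term + lam * (state$cells$target_length[i] - l)^2
    }
  }
  adh + area_term + len_term
}

#' Energy change of a proposed copy
#'
#' Local (incremental) energy change of copying the label at `src` onto the
#' adjacent site `tgt`: adhesion, area and length deltas plus the
#' connectivity penalty when the copy would locally split the retracting
#' cell. Chemotaxis biases are not included here; see [chemotaxis_bias()].
#' Equals the difference of full Hamiltonians for the non-penalty part.
#'
#' @param state a [cpm_state()].
#' @param src,tgt integer length-2 vectors `(row, col)`, 1-based; `tgt`
#'   must be a Moore neighbor of `src`.
#' @return scalar energy change, or `NA_real_` when the copy is vacuous
#'   (identical labels at source and target).
#' @export
delta_h_copy <- function(state, src, tgt) {
  stopifnot(length(src) == 2, length(tgt) == 2)
  if (max(abs(src - tgt)) != 1L)
    stop("target must be a Moore neighbor of source")
  if (state$labels[src[1], src[2]] == state$labels[tgt[1], tgt[2]])
    return(NA_real_)
  p <- state$params
  .delta_h_cpp(state$labels, kind_code(state$cells$kind),
               as.numeric(state$cells$target_area),
               as.numeric(state$cells$lambda_length),
               as.numeric(state$cells$target_length),
               unname(p$J), p$lambda_size, p$connectivity_penalty,
               p$connectivity, src[1], src[2], tgt[1], tgt[2])
}

#' Metropolis acceptance of a copy attempt
#'
#' A copy lowering the energy (or leaving it unchanged) is always accepted;
#' a copy raising it by `dh` is accepted with Boltzmann probability
#' `exp(-dh / mu)`. Draws from R's global RNG.
#'
#' @param delta_h energy change of the attempt.
#' @param params a [cpm_params()] (only `mu` is used).
#' @return logical.
#' @export
accept_copy <- function(delta_h, params) {
  if (delta_h <= 0) return(TRUE)
  runif(1) < exp(-delta_h / params$mu)
}

#' Run Monte Carlo steps
#'
#' Performs `n_mcs` Monte Carlo steps; each MCS makes as many copy attempts
#' as there are lattice sites, picking a random source site and a random
#' Moore neighbor as target. The lattice border is frozen ECM: attempts
#' touching it are rejected. When the state carries a chemoattractant field
#' and `chemotaxis` is given, the chemotactic bias enters every attempt and
#' the field advances by `steps_per_mcs` diffusion steps after each MCS.
#'
#' @param state a [cpm_state()].
#' @param n_mcs number of Monte Carlo steps.
#' @param chemotaxis optional [chemotaxis_params()].
#' @return the updated state (bookkeeping refreshed, `time_mcs` advanced).
#' @export
run_mcs <- function(state, n_mcs = 1L, chemotaxis = NULL) {
  p <- state$params
  ncell <- nrow(state$cells)
  lambda_c <- numeric(ncell)
  contact_inhibition <- FALSE
  do_field <- !is.null(state$chem) && !is.null(chemotaxis)
  if (!is.null(chemotaxis)) {
    lambda_c <- unname(chemotaxis$lambda_c[state$cells$kind])
    lambda_c[is.na(lambda_c)] <- 0
    contact_inhibition <- chemotaxis$contact_inhibition
  }
  if (is.null(state$chem)) {
    chem_mat <- matrix(0, nrow(state$labels), ncol(state$labels))
    fpar <- list(alpha = 0, eps = 0, D = 0, dt = 1, dx = 1, steps_per_mcs = 0L)
  } else {
    chem_mat <- state$chem$c
    fpar <- state$chem[c("alpha", "eps", "D", "dt", "dx", "steps_per_mcs")]
  }
  out <- .run_mcs_cpp(state$labels, kind_code(state$cells$kind),
                      as.numeric(state$cells$target_area),
                      as.numeric(state$cells$lambda_length),
                      as.numeric(state$cells$target_length),
                      unname(p$J), p$lambda_size, p$mu,
                      p$connectivity_penalty, p$connectivity,
                      lambda_c, contact_inhibition, chem_mat, do_field,
                      fpar$alpha, fpar$eps, fpar$D, fpar$dt, fpar$dx,
                      as.integer(fpar$steps_per_mcs), as.integer(n_mcs))
  state$labels <- out$labels
  if (!is.null(state$chem)) state$chem$c <- out$chem
  state$cells$area <- out$area
  state$cells$centroid_row <- out$centroid_row
  state$cells$centroid_col <- out$centroid_col
  state$cells$length <- out$length
  state$time_mcs <- state$time_mcs + as.integer(n_mcs)
  state
}

# number of 8-connected components of a logical mask (internal)
count_components <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(0L)
  H <- nrow(mask)
  remaining <- rep(TRUE, length(idx))
  names(remaining) <- idx
  pos <- setNames(seq_along(idx), idx)
  comp <- 0L
  while (any(remaining)) {
    comp <- comp + 1L
    queue <- idx[which(remaining)[1]]
    remaining[as.character(queue)] <- FALSE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %% H + 1L; c <- (cur - 1L) %/% H + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > H || c2 < 1 || c2 > ncol(mask)) next
        k <- (c2 - 1L) * H + r2
        kk <- as.character(k)
        if (!is.na(remaining[kk]) && remaining[kk]) {
          remaining[kk] <- FALSE
          queue <- c(queue, k)
        }
      }
    }
  }
  comp
}

#' Estimate a cell's length from its inertia tensor
#'
#' The length is taken from the largest eigenvalue of the cell's
#' second-moment (covariance) tensor about its centroid using the ellipse
#' convention `l = 4 * sqrt(lambda_max / a)` (with the tensor in summed
#' form; equivalently four times the standard deviation along the major
#' axis). Each site contributes a 1/12 unit-square spread so a single site
#' has the extent of one site.
#'
#' @param member_sites two-column matrix of `(row, col)` site coordinates.
#' @return scalar length in lattice sites.
#' @export
estimate_cell_length <- function(member_sites) {
  if (is.null(dim(member_sites)))
    member_sites <- matrix(member_sites, ncol = 2)
  n <- nrow(member_sites)
  if (n == 0) stop("cannot estimate the length of an empty cell")
  r <- member_sites[, 1]; c <- member_sites[, 2]
  crr <- mean(r^2) - mean(r)^2 + 1 / 12
  ccc <- mean(c^2) - mean(c)^2 + 1 / 12
  crc <- mean(r * c) - mean(r) * mean(c)
  lmax <- 0.5 * ((crr + ccc) + sqrt((crr - ccc)^2 + 4 * crc^2))
  4 * sqrt(max(lmax, 0))
}
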