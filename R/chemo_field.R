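#' Secreted chemoattractant field
#'
#' Scalar concentration grid co-registered with the Cellular Potts lattice.
#' The field obeys `dc/dt = alpha * [cell] - eps * [ECM] * c + D * lap(c)`:
#' cells secrete at rate `alpha`, the signal decays at rate `eps` in the
#' matrix only, and diffuses everywhere. Solved by explicit forward Euler
#' with a 5-point Laplacian and zero-flux boundaries; the explicit-scheme
#' stability bound `D * dt / dx^2 <= 0.25` is asserted at construction.
#'
#' Defaults give a diffusion length `sqrt(D / eps)` of about 24 um (12
#' sites), i.e. gradients spanning one to a few cell diameters.
#'
#' @param nrow,ncol grid dimensions (must match the lattice).
#' @param alpha secretion rate (1/s).
#' @param eps decay rate (1/s).
#' @param D diffusion coefficient (m^2/s).
#' @param dt time step of the field solver (s).
#' @param dx lattice spacing (m).
#' @param steps_per_mcs field steps taken between consecutive MCS.
#' @param c0 initial concentration (scalar or matrix).
#' @return an object of class `chem_field`.
#' @export
chem_field <- function(nrow, ncol, alpha = 1.8e-4, eps = 1.8e-4,
                       D = 1e-13, dt = 2, dx = 2e-6, steps_per_mcs = 15L,
                       c0 = 0) {
  stopifnot(alpha >= 0, eps >= 0, D >= 0, dt > 0, dx > 0)
  cfl <- D * dt / dx^2
  if (cfl > 0.25)
    stop(sprintf("explicit scheme unstable: D*dt/dx^2 = %.3g > 0.25", cfl))
  cmat <- if (is.matrix(c0)) c0 else matrix(c0, nrow, ncol)
  stopifnot(nrow(cmat) == nrow, ncol(cmat) == ncol, all(cmat >= 0))
  structure(list(c = cmat, alpha = alpha, eps = eps, D = D, dt = dt,
                 dx = dx, steps_per_mcs = as.integer(steps_per_mcs)),
            class = "chem_field")
}

#' One explicit finite-difference step of the chemoattractant field
#'
#' @param field a [chem_field()].
#' @param labels integer label matrix (0 = ECM) of the same shape.
#' @param nsteps number of consecutive steps to take.
#' @return the updated field.
#' @export
step_field <- function(field, labels, nsteps = 1L) {
  stopifnot(identical(dim(field$c), dim(labels)))
  field$c <- .field_steps_cpp(field$c, labels, field$alpha, field$eps,
                              field$D, field$dt, field$dx,
                              as.integer(nsteps))
  field
}

#' Advance the field by one Monte Carlo step worth of diffusion
#'
#' Applies exactly `steps_per_mcs` single steps, the coupling cadence used
#' between consecutive MCS of the Potts dynamics.
#'
#' @inheritParams step_field
#' @return the updated field.
#' @export
run_field_mcs <- function(field, labels) {
  step_field(field, labels, nsteps = field$steps_per_mcs)
}

#' Chemotaxis parameters
#'
#' @param lambda_c named vector of chemotactic strengths per cell kind,
#'   e.g. `c(tip = 10, stalk = 10)`.
#' @param contact_inhibition logical; when `TRUE` the chemotactic bias acts
#'   only at cell-ECM interfaces (copies between two cell sites feel no
#'   bias), the defining assumption of the contact-inhibition model.
#' @return an object of class `chemotaxis_params`.
#' @export
chemotaxis_params <- function(lambda_c = c(tip = 10, stalk = 10),
                              contact_inhibition = TRUE) {
  stopifnot(all(lambda_c >= 0), !is.null(names(lambda_c)))
  structure(list(lambda_c = lambda_c,
                 contact_inhibition = isTRUE(contact_inhibition)),
            class = "chemotaxis_params")
}

#' Chemotactic bias of a copy attempt
#'
#' Returns `lambda_c * (c(src) - c(tgt))` so that extensions toward higher
#' concentration lower the effective energy. With contact inhibition on,
#' copies that are not at a cell-ECM interface receive no bias. The
#' strength is looked up for the active cell's kind: the source cell when a
#' cell extends, the target cell when the ECM advances into a cell.
#'
#' @param field a [chem_field()].
#' @param src,tgt `(row, col)` site coordinates, 1-based.
#' @param src_kind,tgt_kind cell kinds at the two sites ("ECM", "tip" or
#'   "stalk").
#' @param params a [chemotaxis_params()].
#' @return scalar bias energy.
#' @export
chemotaxis_bias <- function(field, src, tgt, src_kind, tgt_kind, params) {
  if (src_kind == "ECM" && tgt_kind == "ECM") return(0)
  if (params$contact_inhibition && src_kind != "ECM" && tgt_kind != "ECM")
    return(0)
  active <- if (src_kind != "ECM") src_kind else tgt_kind
  lc <- unname(params$lambda_c[active])
  if (is.na(lc)) lc <- 0
  lc * (field$c[src[1], src[2]] - field$c[tgt[1], tgt[2]])
}
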