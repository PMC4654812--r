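#' Sprout elongation axis
#'
#' The axis runs from the start position (mean of the branch-node
#' positions at the first and last frame of the sprout's existence) to the
#' end position (mean of the tip positions at those frames). The
#' start-to-end direction defines anterograde motion.
#'
#' @param B_first,B_last `(row, col)` branch-node positions.
#' @param E_first,E_last `(row, col)` tip (end-node) positions.
#' @return an object of class `sprout_axis` with `start`, `end` and the
#'   unit direction `u`.
#' @export
sprout_axis <- function(B_first, E_first, B_last, E_last) {
  start <- (as.numeric(B_first) + as.numeric(B_last)) / 2
  end <- (as.numeric(E_first) + as.numeric(E_last)) / 2
  if (all(start == end)) stop("degenerate sprout axis: start equals end")
  u <- (end - start) / sqrt(sum((end - start)^2))
  structure(list(start = start, end = end, u = u), class = "sprout_axis")
}

# run-length encode a per-sprout leader series sampled on a fixed stride
leader_runs <- function(leader_series, stride = NULL) {
  stopifnot(all(c("mcs", "leader") %in% names(leader_series)))
  ls <- leader_series[order(leader_series$mcs), , drop = FALSE]
  if (is.null(stride))
    stride <- if (nrow(ls) > 1) min(diff(ls$mcs)) else 20
  r <- rle(ls$leader)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(leader = r$values,
             start_mcs = ls$mcs[starts], end_mcs = ls$mcs[ends],
             n_samples = r$lengths,
             duration_mcs = r$lengths * stride)
}

#' Detect tip-cell overtake events
#'
#' An overtake is the replacement of a sprout's leader cell by another
#' cell where both the outgoing and the incoming leader hold the tip
#' position for at least `persistence_mcs` consecutive MCS (40 min at 30
#' s/MCS); shorter tenures are treated as protrusion flickers and produce
#' no event.
#'
#' @param leader_series data frame with columns `mcs` and `leader`
#'   (sampled on a fixed stride dividing `persistence_mcs`), one sprout.
#' @param persistence_mcs persistence requirement in MCS.
#' @param sprout_id optional identifier copied into the events.
#' @return data frame of events: `sprout_id`, `mcs` (first sample of the
#'   incoming tenure), `old_leader`, `new_leader`.
#' @export
detect_overtakes <- function(leader_series, persistence_mcs = 80,
                             sprout_id = NA) {
  runs <- leader_runs(leader_series)
  qual <- runs[runs$duration_mcs >= persistence_mcs, , drop = FALSE]
  out <- data.frame(sprout_id = numeric(), mcs = numeric(),
                    old_leader = integer(), new_leader = integer())
  if (nrow(qual) < 2) return(out)
  for (k in 2:nrow(qual)) {
    if (qual$leader[k] != qual$leader[k - 1]) {
      out <- rbind(out, data.frame(sprout_id = sprout_id,
                                   mcs = qual$start_mcs[k],
                                   old_leader = qual$leader[k - 1],
                                   new_leader = qual$leader[k]))
    }
  }
  out
}

#' Mean overtake rate per sprout
#'
#' Divides the number of overtakes inside the analysis window by the
#' number of sprouts present in the window, expressed per 20,000 MCS.
#'
#' @param events events data frame (from [detect_overtakes()], possibly
#'   pooled over sprouts).
#' @param sprout_presence data frame with one row per sprout and columns
#'   `sprout_id`, `first_mcs`, `last_mcs` (the sprout's observed span).
#' @param window length-2 numeric, analysis window in MCS.
#' @return list with `rate` (overtakes per sprout per 20,000 MCS),
#'   `n_events` and `n_sprouts`.
#' @export
overtake_rate <- function(events, sprout_presence,
                          window = c(10000, 30000)) {
  present <- sprout_presence$last_mcs >= window[1] &
    sprout_presence$first_mcs <= window[2]
  n_sprouts <- sum(present)
  if (n_sprouts == 0)
    return(list(rate = NA_real_, n_events = 0L, n_sprouts = 0L))
  n_events <- if (nrow(events))
    sum(events$mcs >= window[1] & events$mcs <= window[2]) else 0L
  scale <- 20000 / (window[2] - window[1])
  list(rate = n_events / n_sprouts * scale, n_events = n_events,
       n_sprouts = n_sprouts)
}

#' Tip-cell lifetimes
#'
#' Durations of contiguous leader tenures, in minutes (0.5 min per MCS at
#' the default time scaling). Tenures truncated by the sprout's birth or
#' death (first and last run) are included and flagged.
#'
#' @param leader_series per-sprout leader series (`mcs`, `leader`).
#' @param mcs_seconds seconds per MCS.
#' @return data frame with `leader`, `minutes`, `truncated`.
#' @export
tip_lifetimes <- function(leader_series, mcs_seconds = 30) {
  runs <- leader_runs(leader_series)
  if (!nrow(runs))
    return(data.frame(leader = integer(), minutes = numeric(),
                      truncated = logical()))
  data.frame(leader = runs$leader,
             minutes = runs$duration_mcs * mcs_seconds / 60,
             truncated = seq_len(nrow(runs)) %in% c(1L, nrow(runs)))
}

# per-interval displacement table: one row per (cell, interval)
interval_displacements <- function(tracks) {
  stopifnot(all(c("mcs", "cell_id", "x", "y") %in% names(tracks)))
  tracks <- tracks[order(tracks$cell_id, tracks$mcs), , drop = FALSE]
  out <- do.call(rbind, lapply(split(tracks, tracks$cell_id), function(tr) {
    n <- nrow(tr)
    if (n < 2) return(NULL)
    data.frame(cell_id = tr$cell_id[-1], mcs = tr$mcs[-1],
               dx = diff(tr$x), dy = diff(tr$y))
  }))
  if (is.null(out))
    out <- data.frame(cell_id = integer(), mcs = numeric(),
                      dx = numeric(), dy = numeric())
  rownames(out) <- NULL
  out
}

#' Coordination of cell movement with the sprout axis
#'
#' For every per-interval displacement the angle theta in `[0, pi]` with
#' the sprout elongation direction is computed; zero displacements are
#' excluded. The pooled standard deviation of `theta / pi` is reported
#' separately for anterograde (`theta < pi/2`) and retrograde
#' (`theta > pi/2`) samples.
#'
#' @param tracks data frame `mcs`, `cell_id`, `x`, `y` (site units; `x` =
#'   column, `y` = row).
#' @param axis a [sprout_axis()].
#' @return list with `theta` (all angles), `std_anterograde`,
#'   `std_retrograde`.
#' @export
coordination <- function(tracks, axis) {
  d <- interval_displacements(tracks)
  mag <- sqrt(d$dx^2 + d$dy^2)
  keep <- mag > 0
  # axis$u is (row, col) = (y, x)
  cosang <- (d$dy * axis$u[1] + d$dx * axis$u[2])[keep] / mag[keep]
  cosang <- pmin(pmax(cosang, -1), 1)
  theta <- acos(cosang)
  ant <- theta[theta < pi / 2]
  ret <- theta[theta > pi / 2]
  list(theta = theta,
       std_anterograde = if (length(ant) > 1) sd(ant / pi) else NA_real_,
       std_retrograde = if (length(ret) > 1) sd(ret / pi) else NA_real_)
}

#' Directional motility percentages
#'
#' Classifies every per-interval sample: displacements smaller than
#' `stopped_threshold` lattice sites are stopped; otherwise the sign of
#' the axial projection decides anterograde versus retrograde. The three
#' percentages sum to 100.
#'
#' @inheritParams coordination
#' @param stopped_threshold displacement magnitude below which a cell
#'   counts as stopped (lattice sites).
#' @return named numeric vector `anterograde`, `retrograde`, `stopped`.
#' @export
directional_motility <- function(tracks, axis, stopped_threshold = 0.5) {
  d <- interval_displacements(tracks)
  if (!nrow(d)) return(c(anterograde = NA, retrograde = NA, stopped = NA))
  mag <- sqrt(d$dx^2 + d$dy^2)
  proj <- d$dy * axis$u[1] + d$dx * axis$u[2]
  cls <- ifelse(mag < stopped_threshold, "stopped",
                ifelse(proj > 0, "anterograde", "retrograde"))
  n <- length(cls)
  c(anterograde = 100 * sum(cls == "anterograde") / n,
    retrograde = 100 * sum(cls == "retrograde") / n,
    stopped = 100 * sum(cls == "stopped") / n)
}

#' Fit the mean squared displacement of a biased random walk
#'
#' Positions are orthogonally projected on the sprout axis; each cell's
#' squared displacement from the start of its track is averaged per lag
#' and the curve `MSD(t) = 2 D t + (v t)^2` is fitted by non-negative
#' least squares. Units: micrometers and seconds via `site_um` (2 um per
#' site) and `mcs_seconds` (30 s per MCS).
#'
#' @inheritParams coordination
#' @param site_um micrometers per lattice site.
#' @param mcs_seconds seconds per MCS.
#' @param min_lags minimum number of usable lag times.
#' @return list with `D` (um^2/s), `v` (um/s), `msd` (lag table) and
#'   `cov` (approximate covariance of `(D, v^2)` from the linear fit).
#' @export
msd_fit <- function(tracks, axis, site_um = 2, mcs_seconds = 30,
                    min_lags = 3L) {
  tracks <- tracks[order(tracks$cell_id, tracks$mcs), , drop = FALSE]
  per_cell <- split(tracks, tracks$cell_id)
  sq <- list()
  for (tr in per_cell) {
    if (nrow(tr) < 2) next
    s <- (tr$y - axis$start[1]) * axis$u[1] +
      (tr$x - axis$start[2]) * axis$u[2]
    lag <- tr$mcs - tr$mcs[1]
    sq[[length(sq) + 1]] <- data.frame(lag = lag[-1],
                                       sd2 = (s[-1] - s[1])^2)
  }
  if (!length(sq)) stop("no usable tracks for the MSD fit")
  allsq <- do.call(rbind, sq)
  msd <- aggregate(sd2 ~ lag, data = allsq, FUN = mean)
  ncount <- aggregate(sd2 ~ lag, data = allsq, FUN = length)
  msd$n <- ncount$sd2
  usable <- msd[msd$n >= 2, , drop = FALSE]
  if (nrow(usable) < min_lags)
    stop("MSD fit undefined: fewer than ", min_lags,
         " lag times with at least two samples")
  t_s <- usable$lag * mcs_seconds
  y <- usable$sd2 * site_um^2
  # dividing the curve by t turns MSD = 2Dt + (vt)^2 into the straight
  # line MSD/t = 2D + v^2 t, which also stabilizes the variance across
  # lags (large drift-dominated lags would otherwise swamp D)
  X <- cbind(2, t_s)
  fit <- pracma::lsqnonneg(X, y / t_s)
  coef <- fit$x
  resid <- y / t_s - X %*% coef
  dof <- max(nrow(X) - 2, 1)
  sigma2 <- sum(resid^2) / dof
  covm <- tryCatch(sigma2 * solve(crossprod(X)),
                   error = function(e) matrix(NA_real_, 2, 2))
  list(D = coef[1], v = sqrt(max(coef[2], 0)),
       msd = data.frame(lag_mcs = usable$lag, t_s = t_s, msd_um2 = y,
                        n = usable$n),
       cov = covm)
}
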