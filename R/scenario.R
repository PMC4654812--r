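#' Scenario configuration
#'
#' Assembles a complete experiment definition: model variant, signaling
#' mode, differential tip/stalk behavior, mosaic mixing ratio, durations
#' and all parameter blocks. Presets fix the lattice scale:
#' `"paper"` (400 x 400 lattice, spheroid radius 45, 30,000 MCS, analysis
#' window 10,000-30,000), `"desk"` (200 x 200, radius 25, 6,000 MCS,
#' window 2,000-6,000) for batch runs on a single core, and `"mini"`
#' (140 x 140, radius 18, 3,000 MCS, window 1,000-3,000) for quick
#' exploration and unit tests.
#'
#' @param model_variant `"contact_inhibition"` (chemotaxis restricted to
#'   cell-ECM interfaces) or `"cell_elongation"` (unrestricted chemotaxis
#'   plus a cell length constraint).
#' @param preset `"paper"`, `"desk"` or `"mini"`.
#' @param signaling `"off"`, `"dll4_notch"` or `"vegf_dll4_notch"`.
#' @param behavior_mode `"uniform"`, `"differential_adhesion"` or
#'   `"differential_chemosensitivity"`.
#' @param mosaic_ratio fraction of wild-type cells (1 = pure WT).
#' @param seeds integer vector of random seeds, one simulation each.
#' @param ... overrides for any config field (`duration_mcs`, `window`,
#'   `sample_stride`, `lattice`, `spheroid_radius`, `cell_width`, `cpm`,
#'   `chemotaxis`, `field`, `signaling_params`, `morph`,
#'   `persistence_mcs`).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(model_variant = c("contact_inhibition",
                                              "cell_elongation"),
                            preset = c("desk", "paper", "mini"),
                            signaling = c("off", "dll4_notch",
                                          "vegf_dll4_notch"),
                            behavior_mode = c("uniform",
                                              "differential_adhesion",
                                              "differential_chemosensitivity"),
                            mosaic_ratio = 1.0, seeds = 1L, ...) {
  model_variant <- match.arg(model_variant)
  preset <- match.arg(preset)
  signaling <- match.arg(signaling)
  behavior_mode <- match.arg(behavior_mode)
  stopifnot(mosaic_ratio >= 0, mosaic_ratio <= 1, length(seeds) >= 1,
            !anyDuplicated(seeds))
  scale <- switch(preset,
                  paper = list(lattice = 400L, spheroid_radius = 45,
                               duration_mcs = 30000L,
                               window = c(10000, 30000)),
                  desk = list(lattice = 200L, spheroid_radius = 25,
                              duration_mcs = 6000L, window = c(2000, 6000)),
                  mini = list(lattice = 140L, spheroid_radius = 18,
                              duration_mcs = 3000L, window = c(1000, 3000)))
  variant <- model_variant_defaults(model_variant)
  cfg <- list(model_variant = model_variant, preset = preset,
              signaling = signaling, behavior_mode = behavior_mode,
              mosaic_ratio = mosaic_ratio, seeds = as.integer(seeds),
              duration_mcs = scale$duration_mcs, window = scale$window,
              sample_stride = 20L, lattice = scale$lattice,
              spheroid_radius = scale$spheroid_radius, cell_width = 7L,
              cpm = variant$cpm, chemotaxis = variant$chemotaxis,
              field = list(alpha = 1.8e-4, eps = 1.8e-4, D = 1e-13,
                           dt = 2, dx = 2e-6, steps_per_mcs = 15L),
              signaling_params = signaling_params(),
              morph = variant$morph, persistence_mcs = 80)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  stopifnot(cfg$duration_mcs >= cfg$window[2],
            cfg$window[1] < cfg$window[2])
  bundle <- apply_behavior_mode(cfg$behavior_mode, cfg$cpm, cfg$chemotaxis)
  cfg$cpm <- bundle$cpm
  cfg$chemotaxis <- bundle$chemotaxis
  structure(cfg, class = "scenario_config")
}

#' Base parameter sets of the two sprouting variants
#'
#' Returns the calibrated default Potts, chemotaxis and morphometry
#' parameters of a model variant (energies on the `mu = 1` scale; see the
#' methods vignette for the calibration rationale).
#'
#' @param variant `"contact_inhibition"` or `"cell_elongation"`.
#' @return list with `cpm`, `chemotaxis` and `morph` blocks.
#' @export
model_variant_defaults <- function(variant = "contact_inhibition") {
  if (variant == "contact_inhibition") {
    list(cpm = cpm_params(J = j_table(cell_cell = 1.2, cell_ecm = 0.4),
                          lambda_size = 1, lambda_length = 0),
         chemotaxis = chemotaxis_params(lambda_c = c(tip = 5, stalk = 5),
                                        contact_inhibition = TRUE),
         morph = morph_params(r = 4, t = 4, p = 10, m = 10))
  } else {
    list(cpm = cpm_params(J = j_table(cell_cell = 0.8, cell_ecm = 0.4),
                          lambda_size = 1, lambda_length = 1,
                          target_length = 40),
         chemotaxis = chemotaxis_params(lambda_c = c(tip = 10, stalk = 10),
                                        contact_inhibition = FALSE),
         morph = morph_params(r = 2, t = 5, p = 25, m = 15))
  }
}

#' Install a differential tip/stalk behavior mode
#'
#' `"differential_adhesion"` gives tip cells reduced adhesion:
#' `J(stalk, stalk) = 0.2`, `J(tip, tip) = J(stalk, tip) = 0.8`,
#' `J(cell, ECM) = 1`. `"differential_chemosensitivity"` makes tip cells
#' less sensitive to the chemoattractant (`lambda_c` 5 for tips, 10 for
#' stalks) with uniform adhesion (`J` 0.4 between cells, 0.6 to the ECM).
#' `"uniform"` leaves the base parameters untouched.
#'
#' @param mode behavior mode name.
#' @param cpm a [cpm_params()].
#' @param chemotaxis a [chemotaxis_params()].
#' @return list with updated `cpm` and `chemotaxis`.
#' @export
apply_behavior_mode <- function(mode, cpm, chemotaxis) {
  if (mode == "uniform") return(list(cpm = cpm, chemotaxis = chemotaxis))
  if (mode == "differential_adhesion") {
    J <- cpm$J
    J["stalk", "stalk"] <- 0.2
    J["tip", "tip"] <- 0.8
    J["tip", "stalk"] <- J["stalk", "tip"] <- 0.8
    J["ECM", "stalk"] <- J["stalk", "ECM"] <- 1
    J["ECM", "tip"] <- J["tip", "ECM"] <- 1
    cpm$J <- J
  } else if (mode == "differential_chemosensitivity") {
    J <- cpm$J
    J["stalk", "stalk"] <- J["tip", "tip"] <- 0.4
    J["tip", "stalk"] <- J["stalk", "tip"] <- 0.4
    J["ECM", "stalk"] <- J["stalk", "ECM"] <- 0.6
    J["ECM", "tip"] <- J["tip", "ECM"] <- 0.6
    cpm$J <- J
    chemotaxis$lambda_c <- c(tip = 5, stalk = 10)
  } else stop("unknown behavior mode: ", mode)
  list(cpm = cpm, chemotaxis = chemotaxis)
}

#' Initialize a spheroid of square cells
#'
#' Tiles a disc of the given radius with square cells of `cell_width`
#' sites. Cells clipped by the disc boundary are retained when at least
#' half of their full area lies inside; the sites of smaller fragments
#' are absorbed into the nearest retained cell. Genotypes are assigned
#' independently: wild type with probability `mosaic_ratio`, otherwise
#' Vegfr2 heterozygous.
#'
#' @param lattice lattice side length (sites); the spheroid is centered.
#' @param radius spheroid radius in sites.
#' @param cell_width cell side length in sites.
#' @param mosaic_ratio wild-type fraction.
#' @param params a [cpm_params()] for the returned state.
#' @param chem optional [chem_field()] to attach.
#' @return a [cpm_state()] with all cells of kind "stalk".
#' @export
init_spheroid <- function(lattice, radius = 45, cell_width = 7,
                          mosaic_ratio = 1, params = cpm_params(),
                          chem = NULL) {
  H <- W <- as.integer(lattice)
  ctr <- (H + 1) / 2
  if (radius + cell_width + 2 > ctr)
    stop("spheroid does not fit in the lattice with a margin")
  coords <- expand.grid(row = seq_len(H), col = seq_len(W))
  inside <- (coords$row - ctr)^2 + (coords$col - ctr)^2 <= radius^2
  sites <- coords[inside, ]
  br <- floor((sites$row - (ctr - radius)) / cell_width)
  bc <- floor((sites$col - (ctr - radius)) / cell_width)
  bkey <- paste(br, bc)
  counts <- table(bkey)
  full <- cell_width^2
  kept <- names(counts)[counts >= ceiling(full / 2)]
  if (!length(kept)) stop("spheroid too small to hold a single cell")
  keymap <- setNames(seq_along(kept), kept)
  labels <- matrix(0L, H, W)
  assigned <- bkey %in% kept
  labels[cbind(sites$row[assigned], sites$col[assigned])] <-
    keymap[bkey[assigned]]
  # absorb fragment sites into the nearest retained cell (by block center)
  if (any(!assigned)) {
    centers_r <- tapply(sites$row[assigned], keymap[bkey[assigned]], mean)
    centers_c <- tapply(sites$col[assigned], keymap[bkey[assigned]], mean)
    frag <- which(!assigned)
    for (f in frag) {
      d2 <- (centers_r - sites$row[f])^2 + (centers_c - sites$col[f])^2
      labels[sites$row[f], sites$col[f]] <-
        as.integer(names(d2)[which.min(d2)])
    }
  }
  ncell <- length(kept)
  genotype <- ifelse(runif(ncell) < mosaic_ratio, "WT", "VEGFR2_HAPLOID")
  cells <- data.frame(id = seq_len(ncell), kind = "stalk",
                      genotype = genotype, target_area = full)
  cpm_state(labels, cells, params = params, chem = chem)
}

# --- sprout detection and cross-frame identity tracking -------------------

# detect sprouts on one frame: skeleton graph, leaders, member lists
detect_frame_sprouts <- function(labels, morph, contacts = NULL) {
  g <- network_to_graph(labels > 0, morph)
  # branchless skeletons (common at reduced spheroid scale) still carry
  # two sprout tips: each segment end is scored against the opposite end
  spr <- graph_sprouts(g, allow_segments = TRUE)
  out <- list()
  if (!nrow(spr)) return(out)
  if (is.null(contacts)) contacts <- compute_contact_map(labels)
  adj <- adjacency_pairs_8(labels)
  for (k in seq_len(nrow(spr))) {
    B <- c(spr$B_row[k], spr$B_col[k])
    E <- c(spr$E_row[k], spr$E_col[k])
    leader <- identify_leader(labels, B, E, adj = adj)
    if (is.na(leader)) next
    members <- sprout_members(NULL, leader, contacts = contacts)
    out[[length(out) + 1]] <- list(B = B, E = E, leader = leader,
                                   members = members)
  }
  out
}

# match the sprouts of a new frame against recently seen sprouts by
# member overlap (intersection over the smaller member set, >= 50%); a
# sprout identity survives up to two consecutive unseen frames before it
# is closed, absorbing skeletonization flicker
match_sprouts <- function(registry, frame_sprouts, mcs, max_miss = 2L) {
  prev <- Filter(function(s) s$active, registry$sprouts)
  prev_ids <- vapply(prev, function(s) s$id, 0L)
  used <- logical(length(prev))
  for (fs in frame_sprouts) {
    best <- 0; best_k <- NA_integer_
    for (k in seq_along(prev)) {
      if (used[k]) next
      ov <- length(intersect(fs$members, prev[[k]]$members)) /
        min(length(fs$members), length(prev[[k]]$members))
      if (ov > best) { best <- ov; best_k <- k }
    }
    if (!is.na(best_k) && best >= 0.5) {
      used[best_k] <- TRUE
      id <- prev_ids[best_k]
      s <- registry$sprouts[[id]]
      s$last_mcs <- mcs; s$B_last <- fs$B; s$E_last <- fs$E
      s$members <- fs$members
      s$leader_series <- rbind(s$leader_series,
                               data.frame(mcs = mcs, leader = fs$leader))
      s$member_frames[[as.character(mcs)]] <- fs$members
      s$seen <- TRUE; s$miss <- 0L
      registry$sprouts[[id]] <- s
    } else {
      id <- registry$next_id
      registry$next_id <- id + 1L
      registry$sprouts[[id]] <- list(
        id = id, active = TRUE, seen = TRUE, miss = 0L,
        first_mcs = mcs, last_mcs = mcs,
        B_first = fs$B, E_first = fs$E, B_last = fs$B, E_last = fs$E,
        members = fs$members,
        leader_series = data.frame(mcs = mcs, leader = fs$leader),
        member_frames = setNames(list(fs$members), as.character(mcs)))
    }
  }
  for (k in seq_along(registry$sprouts)) {
    s <- registry$sprouts[[k]]
    if (isTRUE(s$active) && !isTRUE(s$seen)) {
      s$miss <- s$miss + 1L
      if (s$miss > max_miss) s$active <- FALSE
    }
    s$seen <- FALSE
    registry$sprouts[[k]] <- s
  }
  registry
}

#' Run a scenario
#'
#' Runs one simulation per seed: spheroid initialization, the per-MCS loop
#' (Potts copies with chemotaxis, chemoattractant diffusion, optional
#' signaling substeps and phenotype assignment), center-of-mass sampling
#' every `sample_stride` MCS, sprout detection with cross-frame identity
#' tracking, and the kinetics analyses on the configured window.
#'
#' @param config a [scenario_config()].
#' @param out_dir optional directory; when given, per-seed label and field
#'   snapshots (TIFF + JSON sidecar), track and event tables (CSV) and the
#'   summary (JSON) are written with config-hash provenance.
#' @param snapshot_every write a snapshot every this many MCS (default:
#'   only the final frame).
#' @param progress print per-seed progress.
#' @return an object of class `scenario_result`: list with `tracks`,
#'   `events`, `sprouts`, `final` (per-cell end state), `summary` and
#'   `config`.
#' @export
run_scenario <- function(config, out_dir = NULL, snapshot_every = NULL,
                         progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  per_seed <- lapply(config$seeds, function(seed) {
    if (progress) message("seed ", seed)
    run_one_seed(config, seed, out_dir = out_dir,
                 snapshot_every = snapshot_every)
  })
  names(per_seed) <- paste0("seed_", config$seeds)
  tracks <- do.call(rbind, lapply(per_seed, `[[`, "tracks"))
  events <- do.call(rbind, lapply(per_seed, `[[`, "events"))
  sprouts <- do.call(rbind, lapply(per_seed, `[[`, "sprout_table"))
  final <- do.call(rbind, lapply(per_seed, `[[`, "final"))
  rownames(tracks) <- rownames(events) <- rownames(sprouts) <-
    rownames(final) <- NULL
  summary <- summarize_scenario(per_seed, config)
  res <- structure(list(tracks = tracks, events = events, sprouts = sprouts,
                        final = final, per_seed = per_seed,
                        summary = summary, config = config),
                   class = "scenario_result")
  if (!is.null(out_dir)) write_scenario_outputs(res, out_dir)
  res
}

run_one_seed <- function(config, seed, out_dir = NULL,
                         snapshot_every = NULL) {
  set.seed(seed)
  f <- config$field
  chem <- chem_field(config$lattice, config$lattice, alpha = f$alpha,
                     eps = f$eps, D = f$D, dt = f$dt, dx = f$dx,
                     steps_per_mcs = f$steps_per_mcs)
  state <- init_spheroid(config$lattice, config$spheroid_radius,
                         config$cell_width, config$mosaic_ratio,
                         params = config$cpm, chem = chem)
  ncell <- nrow(state$cells)
  genotypes <- state$cells$genotype
  sig_on <- config$signaling != "off"
  vegf_on <- config$signaling == "vegf_dll4_notch"
  sparams <- config$signaling_params
  sig <- NULL
  if (sig_on) {
    sig <- signaling_init(genotypes, sparams)
    state$cells$kind <- assign_phenotypes(sig, sparams)
  }
  stride <- config$sample_stride
  n_frames <- config$duration_mcs %/% stride
  registry <- list(sprouts = list(), next_id = 1L)
  track_rows <- vector("list", n_frames + 1L)
  sig_rows <- if (sig_on) vector("list", n_frames + 1L) else NULL
  sample_frame <- function(frame_idx, mcs) {
    alive <- state$cells$area > 0
    track_rows[[frame_idx]] <<- data.frame(
      seed = seed, mcs = mcs, cell_id = state$cells$id[alive],
      x = state$cells$centroid_col[alive],
      y = state$cells$centroid_row[alive])
    contacts <- compute_contact_map(state$labels, ncell)
    fs <- detect_frame_sprouts(state$labels, config$morph, contacts)
    registry <<- match_sprouts(registry, fs, mcs)
    if (sig_on) {
      sig_rows[[frame_idx]] <<- data.frame(
        seed = seed, mcs = mcs, cell_id = state$cells$id[alive],
        D = sig[alive, "D"], N = sig[alive, "N"], S = sig[alive, "S"],
        R = sig[alive, "R"], A = sig[alive, "A"],
        kind = state$cells$kind[alive], genotype = genotypes[alive])
    }
  }
  sample_frame(1L, 0L)
  for (frame in seq_len(n_frames)) {
    if (sig_on) {
      for (i in seq_len(stride)) {
        state <- run_mcs(state, 1L, chemotaxis = config$chemotaxis)
        contacts <- compute_contact_map(state$labels, ncell)
        sig <- signaling_mcs(sig, contacts, sparams, genotypes,
                             vegf = vegf_on)
        state$cells$kind <- assign_phenotypes(sig, sparams)
      }
    } else {
      state <- run_mcs(state, stride, chemotaxis = config$chemotaxis)
    }
    mcs <- frame * stride
    sample_frame(frame + 1L, mcs)
    if (!is.null(out_dir) && !is.null(snapshot_every) &&
        mcs %% snapshot_every == 0) {
      write_snapshot(state, file.path(out_dir,
                                      sprintf("seed%d_mcs%06d", seed, mcs)))
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_snapshot(state, file.path(out_dir, sprintf("seed%d_final", seed)))
  }
  tracks <- do.call(rbind, track_rows)
  analysis <- analyze_seed(registry, tracks, config, seed)
  final <- data.frame(seed = seed, cell_id = state$cells$id,
                      kind = state$cells$kind, genotype = genotypes,
                      area = state$cells$area,
                      is_final_leader = state$cells$id %in%
                        analysis$final_leaders)
  c(analysis,
    list(tracks = tracks, final = final, state = state,
         signaling_series = if (sig_on) do.call(rbind, sig_rows) else NULL))
}

# per-seed kinetics: overtakes, lifetimes, coordination, motility, MSD
analyze_seed <- function(registry, tracks, config, seed) {
  sprouts <- registry$sprouts
  window <- config$window
  sprout_table <- do.call(rbind, lapply(sprouts, function(s) {
    data.frame(seed = seed, sprout_id = s$id, first_mcs = s$first_mcs,
               last_mcs = s$last_mcs, n_frames = nrow(s$leader_series),
               final_leader = tail(s$leader_series$leader, 1))
  }))
  if (is.null(sprout_table))
    sprout_table <- data.frame(seed = integer(), sprout_id = integer(),
                               first_mcs = numeric(), last_mcs = numeric(),
                               n_frames = integer(),
                               final_leader = integer())
  events <- do.call(rbind, lapply(sprouts, function(s) {
    ev <- detect_overtakes(s$leader_series, config$persistence_mcs,
                           sprout_id = s$id)
    if (nrow(ev)) ev$seed <- seed
    ev
  }))
  if (is.null(events))
    events <- data.frame(sprout_id = integer(), mcs = numeric(),
                         old_leader = integer(), new_leader = integer(),
                         seed = integer())
  lifetimes <- do.call(rbind, lapply(sprouts, function(s) {
    lt <- tip_lifetimes(s$leader_series, config$cpm$mcs_seconds)
    if (nrow(lt)) { lt$sprout_id <- s$id; lt$seed <- seed }
    lt
  }))
  rate <- overtake_rate(events, sprout_table, window)
  # kinetics over sprout-member tracks; per-sprout axis
  proj_rows <- list(); theta_all <- numeric(); motil_raw <- list()
  for (s in sprouts) {
    ax <- tryCatch(sprout_axis(s$B_first, s$E_first, s$B_last, s$E_last),
                   error = function(e) NULL)
    if (is.null(ax)) next
    frames <- as.numeric(names(s$member_frames))
    mem_tracks <- do.call(rbind, lapply(seq_along(frames), function(i) {
      tr <- tracks[tracks$mcs == frames[i] &
                     tracks$cell_id %in% s$member_frames[[i]], ,
                   drop = FALSE]
      tr
    }))
    if (is.null(mem_tracks) || nrow(mem_tracks) < 2) next
    co <- coordination(mem_tracks, ax)
    theta_all <- c(theta_all, co$theta)
    motil_raw[[length(motil_raw) + 1]] <-
      list(tracks = mem_tracks, axis = ax)
    # projected tracks for the pooled MSD (x = axial position, y = 0)
    sproj <- (mem_tracks$y - ax$start[1]) * ax$u[1] +
      (mem_tracks$x - ax$start[2]) * ax$u[2]
    proj_rows[[length(proj_rows) + 1]] <-
      data.frame(mcs = mem_tracks$mcs,
                 cell_id = paste0("s", s$id, "c", mem_tracks$cell_id),
                 x = sproj, y = 0)
  }
  motility <- if (length(motil_raw)) {
    disp <- do.call(rbind, lapply(motil_raw, function(mr) {
      d <- interval_displacements(mr$tracks)
      d$proj <- d$dy * mr$axis$u[1] + d$dx * mr$axis$u[2]
      d
    }))
    mag <- sqrt(disp$dx^2 + disp$dy^2)
    cls <- ifelse(mag < 0.5, "stopped",
                  ifelse(disp$proj > 0, "anterograde", "retrograde"))
    c(anterograde = 100 * mean(cls == "anterograde"),
      retrograde = 100 * mean(cls == "retrograde"),
      stopped = 100 * mean(cls == "stopped"))
  } else c(anterograde = NA, retrograde = NA, stopped = NA)
  msd <- NULL
  if (length(proj_rows)) {
    ptr <- do.call(rbind, proj_rows)
    dummy_axis <- structure(list(start = c(0, 0), end = c(0, 1),
                                 u = c(0, 1)), class = "sprout_axis")
    msd <- tryCatch(msd_fit(ptr, dummy_axis,
                            site_um = config$cpm$site_um,
                            mcs_seconds = config$cpm$mcs_seconds),
                    error = function(e) NULL)
  }
  # occupancy is scored on the sprouts alive at the end of the run; the
  # tail window (last tenth of the run, at least five sampling frames)
  # absorbs skeleton flicker at reduced scale, where the strictly-final
  # frame may carry no sprout record at all
  final_cut <- config$duration_mcs -
    max(5 * config$sample_stride, config$duration_mcs / 10)
  final_leaders <- unlist(lapply(sprouts, function(s) {
    if (s$last_mcs >= final_cut) tail(s$leader_series$leader, 1) else NULL
  }))
  ant <- theta_all[theta_all < pi / 2]
  ret <- theta_all[theta_all > pi / 2]
  list(sprout_table = sprout_table, events = events,
       lifetimes = lifetimes, rate = rate,
       std_theta_anterograde = if (length(ant) > 1) sd(ant / pi) else NA,
       std_theta_retrograde = if (length(ret) > 1) sd(ret / pi) else NA,
       motility = motility, msd = msd, final_leaders = final_leaders,
       registry = registry)
}

summarize_scenario <- function(per_seed, config) {
  rates <- vapply(per_seed, function(x) x$rate$rate, 0)
  lifetimes <- unlist(lapply(per_seed, function(x) {
    if (!is.null(x$lifetimes) && nrow(x$lifetimes)) x$lifetimes$minutes
    else numeric()
  }))
  Ds <- vapply(per_seed,
               function(x) if (!is.null(x$msd)) x$msd$D else NA_real_, 0)
  vs <- vapply(per_seed,
               function(x) if (!is.null(x$msd)) x$msd$v else NA_real_, 0)
  mot <- do.call(rbind, lapply(per_seed, `[[`, "motility"))
  list(overtake_rate_mean = mean(rates, na.rm = TRUE),
       overtake_rate_sd = sd(rates[!is.na(rates)]),
       overtake_rates = rates,
       tip_lifetime_mean_min = if (length(lifetimes))
         mean(lifetimes, na.rm = TRUE) else NA_real_,
       tip_lifetime_sd_min = if (length(lifetimes) > 1)
         sd(lifetimes, na.rm = TRUE) else NA_real_,
       dispersion_um2_s = mean(Ds, na.rm = TRUE),
       elongation_velocity_um_s = mean(vs, na.rm = TRUE),
       std_theta_anterograde =
         mean(vapply(per_seed, `[[`, 0, "std_theta_anterograde"),
              na.rm = TRUE),
       std_theta_retrograde =
         mean(vapply(per_seed, `[[`, 0, "std_theta_retrograde"),
              na.rm = TRUE),
       motility = if (!is.null(mot)) colMeans(mot, na.rm = TRUE) else NULL,
       n_sprouts = sum(vapply(per_seed,
                              function(x) x$rate$n_sprouts, 0L)),
       n_events = sum(vapply(per_seed,
                             function(x) x$rate$n_events, 0L)))
}

#' Wild-type sprout-tip occupancy with a binomial null
#'
#' Counts the sprouts whose final leader cell is wild type and computes
#' the upper-tail binomial probability of observing at least that many
#' under random mixing at the initial mixing ratio.
#'
#' @param leader_genotypes character vector, final leader genotype per
#'   sprout (pooled over seeds).
#' @param mixing_ratio initial wild-type fraction.
#' @return list with `n_sprouts`, `k_wt_led`, `percentage`, `p_binomial`.
#' @export
wt_tip_occupancy <- function(leader_genotypes, mixing_ratio) {
  n <- length(leader_genotypes)
  if (n == 0) stop("occupancy undefined: no sprouts at the final frame")
  k <- sum(leader_genotypes == "WT")
  list(n_sprouts = n, k_wt_led = k, percentage = 100 * k / n,
       p_binomial = pbinom(k - 1, n, mixing_ratio, lower.tail = FALSE))
}

#' Tip-differentiation fractions by genotype
#'
#' Fraction of each genotype's cells (in the whole population, not only at
#' sprout tips) carrying the tip phenotype.
#'
#' @param kinds character vector of cell kinds ("tip"/"stalk").
#' @param genotypes character vector of genotypes, same length.
#' @return named list `frac_wt_tip`, `frac_haploid_tip` (`NA` when a
#'   genotype is absent).
#' @export
tip_differentiation_fraction <- function(kinds, genotypes) {
  stopifnot(length(kinds) == length(genotypes))
  frac <- function(g) {
    sel <- genotypes == g
    if (!any(sel)) return(NA_real_)
    mean(kinds[sel] == "tip")
  }
  list(frac_wt_tip = frac("WT"),
       frac_haploid_tip = frac("VEGFR2_HAPLOID"))
}
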