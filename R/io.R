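#' Write a label-matrix snapshot
#'
#' Writes the label lattice as a single-channel 16-bit TIFF plus a JSON
#' sidecar mapping each cell identifier to its kind and genotype. When the
#' state carries a chemoattractant field, it is written alongside as a
#' 32-bit float TIFF (values scaled to `[0, 1]`; the scale factor is
#' recorded in the sidecar).
#'
#' @param state a [cpm_state()].
#' @param basename path prefix; `.tif`, `.json` and `_field.tif` are
#'   appended.
#' @return the basename, invisibly.
#' @export
write_snapshot <- function(state, basename) {
  dir.create(dirname(basename), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(state$labels / 65535, paste0(basename, ".tif"),
                  bits.per.sample = 16)
  sidecar <- list(cells = data.frame(id = state$cells$id,
                                     kind = state$cells$kind,
                                     genotype = state$cells$genotype),
                  time_mcs = state$time_mcs)
  if (!is.null(state$chem)) {
    cmax <- max(state$chem$c, 1e-300)
    tiff::writeTIFF(state$chem$c / cmax, paste0(basename, "_field.tif"),
                    bits.per.sample = 32)
    sidecar$field_scale <- cmax
  }
  jsonlite::write_json(sidecar, paste0(basename, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(basename)
}

#' Read a label-matrix snapshot
#'
#' @param basename path prefix used by [write_snapshot()].
#' @return list with `labels` (integer matrix), `cells` (data frame) and,
#'   when present, `chem` (numeric matrix, rescaled).
#' @export
read_snapshot <- function(basename) {
  img <- tiff::readTIFF(paste0(basename, ".tif"))
  labels <- matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
  sidecar <- jsonlite::read_json(paste0(basename, ".json"),
                                 simplifyVector = TRUE)
  out <- list(labels = labels, cells = sidecar$cells,
              time_mcs = sidecar$time_mcs)
  fpath <- paste0(basename, "_field.tif")
  if (file.exists(fpath)) {
    f <- tiff::readTIFF(fpath)
    out$chem <- f * sidecar$field_scale
  }
  out
}

# flatten a scenario config into namespaced key/value pairs
flatten_config <- function(config) {
  out <- list()
  push <- function(key, val) out[[key]] <<- val
  for (nm in names(config)) {
    v <- config[[nm]]
    if (nm == "cpm") {
      J <- v$J
      for (a in rownames(J)) for (b in colnames(J))
        if (a <= b) push(paste0("cpm.J.", a, ".", b), unname(J[a, b]))
      for (f in c("lambda_size", "lambda_length", "target_length", "mu",
                  "connectivity_penalty", "connectivity", "mcs_seconds",
                  "site_um"))
        push(paste0("cpm.", f), v[[f]])
    } else if (nm == "chemotaxis") {
      for (k in names(v$lambda_c))
        push(paste0("chemotaxis.lambda_c.", k), unname(v$lambda_c[k]))
      push("chemotaxis.contact_inhibition", v$contact_inhibition)
    } else if (nm == "field") {
      for (f in names(v)) push(paste0("field.", f), v[[f]])
    } else if (nm == "signaling_params") {
      for (f in names(v)) push(paste0("signaling.", f), v[[f]])
    } else if (nm == "morph") {
      for (f in c("r", "t", "p", "m")) push(paste0("morph.", f), v[[f]])
    } else if (nm == "window") {
      push("window.start", v[1]); push("window.end", v[2])
    } else if (nm == "seeds") {
      push("seeds", as.integer(v))
    } else {
      push(nm, v)
    }
  }
  out
}

#' Write a scenario configuration to a YAML file
#'
#' Flat namespaced keys covering every model symbol (interfacial energies,
#' constraint weights, field rates, all signaling constants, morphometry
#' and analysis parameters).
#'
#' @param config a [scenario_config()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(flatten_config(config), path)
  invisible(path)
}

#' Read a scenario configuration from a YAML file
#'
#' Unknown keys are rejected.
#'
#' @param path YAML file written by [write_run_config()] (or hand-edited).
#' @return a [scenario_config()].
#' @export
read_run_config <- function(path) {
  kv <- yaml::read_yaml(path)
  base <- scenario_config()
  known <- names(flatten_config(base))
  unknown <- setdiff(names(kv), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  g <- function(key, default) if (!is.null(kv[[key]])) kv[[key]] else default
  Jcc <- g("cpm.J.stalk.stalk", 0.4)
  JcE <- g("cpm.J.ECM.stalk", 0.6)
  cpm <- cpm_params(J = j_table(Jcc, JcE),
                    lambda_size = g("cpm.lambda_size", 1),
                    lambda_length = g("cpm.lambda_length", 0),
                    target_length = g("cpm.target_length", 0),
                    mu = g("cpm.mu", 1),
                    connectivity_penalty = g("cpm.connectivity_penalty", 1e5),
                    connectivity = g("cpm.connectivity", TRUE),
                    mcs_seconds = g("cpm.mcs_seconds", 30),
                    site_um = g("cpm.site_um", 2))
  J <- cpm$J
  for (a in rownames(J)) for (b in colnames(J)) {
    key <- if (a <= b) paste0("cpm.J.", a, ".", b) else
      paste0("cpm.J.", b, ".", a)
    if (!is.null(kv[[key]])) J[a, b] <- J[b, a] <- kv[[key]]
  }
  J["ECM", "ECM"] <- 0
  cpm$J <- J
  chemo <- chemotaxis_params(
    lambda_c = c(tip = g("chemotaxis.lambda_c.tip", 10),
                 stalk = g("chemotaxis.lambda_c.stalk", 10)),
    contact_inhibition = g("chemotaxis.contact_inhibition", TRUE))
  sp_keys <- names(flatten_config(base))
  sig_args <- list()
  for (key in names(kv)) {
    if (startsWith(key, "signaling."))
      sig_args[[sub("^signaling\\.", "", key)]] <- kv[[key]]
  }
  sparams <- do.call(signaling_params, sig_args)
  scenario_config(
    model_variant = g("model_variant", "contact_inhibition"),
    preset = g("preset", "desk"),
    signaling = g("signaling", "off"),
    behavior_mode = g("behavior_mode", "uniform"),
    mosaic_ratio = g("mosaic_ratio", 1),
    seeds = as.integer(g("seeds", 1L)),
    duration_mcs = g("duration_mcs", base$duration_mcs),
    window = c(g("window.start", base$window[1]),
               g("window.end", base$window[2])),
    sample_stride = g("sample_stride", 20L),
    lattice = g("lattice", base$lattice),
    spheroid_radius = g("spheroid_radius", base$spheroid_radius),
    cell_width = g("cell_width", 7L),
    cpm = cpm, chemotaxis = chemo, signaling_params = sparams,
    field = list(alpha = g("field.alpha", 1.8e-4),
                 eps = g("field.eps", 1.8e-4),
                 D = g("field.D", 1e-13), dt = g("field.dt", 2),
                 dx = g("field.dx", 2e-6),
                 steps_per_mcs = g("field.steps_per_mcs", 15L)),
    morph = morph_params(g("morph.r", base$morph$r),
                         g("morph.t", base$morph$t),
                         g("morph.p", base$morph$p),
                         g("morph.m", base$morph$m)),
    persistence_mcs = g("persistence_mcs", 80))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

write_scenario_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(res$config)
  header <- sprintf("# config_hash: %s", hash)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(header, con)
    write.csv(df, con, row.names = FALSE)
    close(con)
  }
  wr(res$tracks, "tracks.csv")
  wr(res$events, "events.csv")
  wr(res$sprouts, "sprouts.csv")
  wr(res$final, "final_cells.csv")
  summ <- res$summary
  summ$config_hash <- hash
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_run_config(res$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Read a track table written by [run_scenario()]
#'
#' @param path `tracks.csv` path (provenance header tolerated).
#' @return data frame.
#' @export
read_tracks <- function(path) {
  read.csv(path, comment.char = "#")
}
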