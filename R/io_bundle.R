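BUNDLE_SCHEMA_VERSION <- "1.0"

EVENT_COLUMNS <- c("trial_id", "block_id", "phase", "task", "matched_task",
                   "seq_id", "s1_freq", "s2_freq", "t_led", "t_grasp",
                   "t_s1", "t_s2", "tone_duration", "t_end", "p_s1", "p_s2",
                   "iti", "required", "t_release", "outcome")

# Small deterministic content hash (FNV-1a over UTF-8 bytes), used to stamp
# the generating configuration into the manifest.
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write a session bundle to disk
#'
#' On-disk layout: `events.csv`, `spikes.csv` (long: unit_id, trial_id,
#' time), `units.csv`, optional `sites.csv` and one `lfp_site<k>.csv` per
#' site (trial_id plus one column per sample), and `manifest.json` carrying
#' the schema version, seed, configuration (and its hash), and LFP
#' metadata. All times are trial-relative seconds.
#'
#' @param session an `ephys_session`.
#' @param path directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(session$events, file.path(path, "events.csv"))
  data.table::fwrite(session$spikes, file.path(path, "spikes.csv"))
  data.table::fwrite(session$units, file.path(path, "units.csv"))
  lfp_meta <- NULL
  if (!is.null(session$lfp)) {
    data.table::fwrite(session$sites, file.path(path, "sites.csv"))
    lfp_meta <- lapply(session$lfp, function(site) {
      df <- data.frame(trial_id = site$trial_ids, site$data)
      names(df) <- c("trial_id", sprintf("s%05d", seq_len(ncol(site$data))))
      data.table::fwrite(df,
                         file.path(path, sprintf("lfp_site%d.csv",
                                                 site$site_id)))
      list(site_id = site$site_id, sampling_rate = site$sampling_rate,
           t0 = site$t0, n_samples = ncol(site$data))
    })
  }
  config_json <- jsonlite::toJSON(unclass_deep(session$config),
                                  auto_unbox = TRUE, digits = NA)
  manifest <- list(
    schema_version = BUNDLE_SCHEMA_VERSION,
    seed = session$config$seed,
    config = jsonlite::fromJSON(config_json, simplifyVector = TRUE),
    config_hash = fnv1a(as.character(config_json)),
    n_trials = nrow(session$events),
    n_units = nrow(session$units),
    lfp = lfp_meta,
    schedules = session$schedules)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else if (is.atomic(x) && !is.null(names(x))) {
    # keep names through JSON (named atomic vectors serialize as arrays)
    as.list(x)
  } else x
}

#' Validate a session bundle on disk
#'
#' Checks manifest presence and schema compatibility, required events
#' columns, non-empty events, referential integrity (every spike and LFP
#' trial id present in the events table), and LFP metadata (sampling rate).
#' Stops with a message listing every violation found.
#'
#' @param path bundle directory.
#' @return the parsed manifest, invisibly.
#' @export
validate_bundle <- function(path) {
  problems <- character(0)
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) {
    stop_invalid("bundle validation failed: manifest.json missing in %s",
                 path)
  }
  manifest <- jsonlite::fromJSON(mf_path, simplifyVector = TRUE)
  if (!identical(manifest$schema_version, BUNDLE_SCHEMA_VERSION)) {
    problems <- c(problems,
                  sprintf("schema version %s incompatible (expected %s)",
                          manifest$schema_version, BUNDLE_SCHEMA_VERSION))
  }
  ev_path <- file.path(path, "events.csv")
  if (!file.exists(ev_path)) {
    problems <- c(problems, "events.csv missing")
  } else {
    events <- as.data.frame(data.table::fread(ev_path))
    if (nrow(events) == 0) problems <- c(problems, "events table is empty")
    missing_cols <- setdiff(EVENT_COLUMNS, names(events))
    if (length(missing_cols)) {
      problems <- c(problems, sprintf("events.csv lacks columns: %s",
                                      paste(missing_cols, collapse = ", ")))
    }
    if (nrow(events) > 0 && "trial_id" %in% names(events)) {
      ids <- events$trial_id
      sp_path <- file.path(path, "spikes.csv")
      if (file.exists(sp_path)) {
        sp <- data.table::fread(sp_path)
        orphan <- setdiff(unique(sp$trial_id), ids)
        if (length(orphan)) {
          problems <- c(problems,
                        sprintf("spikes reference unknown trial ids: %s",
                                paste(utils::head(orphan, 10),
                                      collapse = ", ")))
        }
      }
      if (!is.null(manifest$lfp)) {
        lf <- manifest$lfp
        if (is.data.frame(lf)) lf <- split(lf, seq_len(nrow(lf)))
        for (meta in lf) {
          if (is.null(meta$sampling_rate) || !is.finite(meta$sampling_rate)) {
            problems <- c(problems,
                          sprintf("site %s lacks a sampling-rate attribute",
                                  meta$site_id))
            next
          }
          f <- file.path(path, sprintf("lfp_site%d.csv", meta$site_id))
          if (!file.exists(f)) {
            problems <- c(problems, sprintf("%s missing", basename(f)))
            next
          }
          tid <- data.table::fread(f, select = "trial_id")$trial_id
          orphan <- setdiff(unique(tid), ids)
          if (length(orphan)) {
            problems <- c(problems,
                          sprintf("LFP site %s references unknown trial ids: %s",
                                  meta$site_id,
                                  paste(utils::head(orphan, 10),
                                        collapse = ", ")))
          }
        }
      }
    }
  }
  if (length(problems)) {
    stop_invalid("bundle validation failed:\n- %s",
                 paste(problems, collapse = "\n- "))
  }
  invisible(manifest)
}

#' Read a session bundle from disk
#'
#' Validates the bundle, then reconstructs the in-memory session object
#' (events, spikes, units, LFP matrices, configuration).
#'
#' @param path bundle directory.
#' @return an `ephys_session`.
#' @export
read_bundle <- function(path) {
  manifest <- validate_bundle(path)
  events <- as.data.frame(data.table::fread(file.path(path, "events.csv")))
  for (col in c("matched_task", "seq_id", "required", "outcome")) {
    events[[col]] <- as.character(events[[col]])
    events[[col]][events[[col]] == ""] <- NA_character_
  }
  spikes <- as.data.frame(data.table::fread(file.path(path, "spikes.csv")))
  units <- as.data.frame(data.table::fread(file.path(path, "units.csv")))
  lfp <- NULL
  sites <- NULL
  if (!is.null(manifest$lfp)) {
    sites <- as.data.frame(data.table::fread(file.path(path, "sites.csv")))
    lf <- manifest$lfp
    if (is.data.frame(lf)) lf <- split(lf, seq_len(nrow(lf)))
    lfp <- lapply(lf, function(meta) {
      df <- data.table::fread(file.path(path,
                                        sprintf("lfp_site%d.csv",
                                                meta$site_id)))
      list(site_id = meta$site_id,
           data = as.matrix(df[, -1]),
           trial_ids = df$trial_id,
           sampling_rate = meta$sampling_rate,
           t0 = meta$t0)
    })
  }
  config <- config_from_manifest(manifest$config)
  structure(
    list(events = events, spikes = spikes, lfp = lfp, units = units,
         sites = sites,
         schedules = as.data.frame(manifest$schedules),
         config = config),
    class = "ephys_session")
}

config_from_manifest <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  cfg <- as.list(cfg)
  unit_args <- as.list(cfg$unit)
  unit_args$cue_offset <- unlist(unit_args$cue_offset)
  lfp_args <- as.list(cfg$lfp)
  for (k in c("amplitude", "latency", "width", "band")) {
    lfp_args[[k]] <- unlist(lfp_args[[k]])
  }
  cfg$unit <- do.call(unit_params, unit_args)
  cfg$lfp <- do.call(lfp_params, lfp_args)
  cfg$response_window <- unlist(cfg$response_window)
  cfg$bf_range <- unlist(cfg$bf_range)
  do.call(session_config, cfg)
}

#' Read a run configuration from YAML
#'
#' A thin adapter between a YAML file and [session_config]; keys mirror the
#' function's arguments, with optional `unit:` and `lfp:` blocks.
#'
#' @param path YAML file.
#' @return a `session_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$unit)) {
    if (!is.null(cfg$unit$cue_offset)) {
      cfg$unit$cue_offset <- unlist(cfg$unit$cue_offset)
    }
    cfg$unit <- do.call(unit_params, cfg$unit)
  }
  if (!is.null(cfg$lfp)) cfg$lfp <- do.call(lfp_params, cfg$lfp)
  do.call(session_config, cfg)
}
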