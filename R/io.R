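trial_scalar_cols <- function() {
  c("participant", "trial", "block", "leg", "phase", "condition",
    "f_inference", "delta_f", "delta_f_prev", "f_pursuit", "choice",
    "choice_bin", "p_boost", "decision_time", "inference_duration",
    "inference_capped", "capture_time", "captured_by", "reward",
    "prev_reward")
}

#' Read and write trial logs
#'
#' Trial logs are UTF-8 CSV with a stable column order: the scalar trial
#' fields first (participant, trial, schedule fields, choice, timing,
#' reward), then the 15 feature columns. Reading checks for the required
#' columns and tolerates unknown extra columns with a warning.
#'
#' @param trials a trials tibble (e.g. `generate_dataset()$trials`).
#' @param path CSV file path.
#' @return `read_trials()` returns the tibble; `write_trials()` returns
#'   `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  ord <- c(intersect(trial_scalar_cols(), names(trials)),
           intersect(feature_names(), names(trials)))
  extra <- setdiff(names(trials), ord)
  readr::write_csv(trials[, c(ord, extra)], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  known <- c(participant = "i", trial = "i", block = "i", leg = "i",
             phase = "c", condition = "c", choice = "c", choice_bin = "i",
             inference_capped = "l", captured_by = "c")
  types <- paste(vapply(hdr, function(h) {
    if (h %in% names(known)) known[[h]]
    else if (h %in% c(trial_scalar_cols(), feature_names())) "d"
    else "?"
  }, character(1)), collapse = "")
  out <- readr::read_csv(path, col_types = types, progress = FALSE)
  required <- c("participant", "trial", "condition", "f_inference",
                "delta_f", "f_pursuit", "choice_bin")
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    stop("trial log is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  known <- c(trial_scalar_cols(), feature_names())
  unknown <- setdiff(names(out), known)
  if (length(unknown)) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
  }
  out
}

traj_cols <- function() {
  c("frame", "t", "prey_x", "prey_y", "oppo_x", "oppo_y", "play_x",
    "play_y")
}

#' Read and write per-trial trajectory files
#'
#' One CSV per trial under `dir`, named
#' `p<participant>_t<trial>_<phase>.csv`, columns in the documented order
#' `frame, t, prey_x, prey_y, oppo_x, oppo_y, play_x, play_y[, gaze_x,
#' gaze_y]`.
#'
#' @param trajectories long tibble with `participant`, `trial`,
#'   `phase_name` plus the per-frame columns.
#' @param dir output directory (created if needed).
#' @return `write_trajectories()` returns the written paths invisibly;
#'   `read_trajectories()` returns the long tibble.
#' @export
write_trajectories <- function(trajectories, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keys <- dplyr::distinct(trajectories, .data$participant, .data$trial,
                          .data$phase_name)
  paths <- character(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    d <- dplyr::semi_join(trajectories, k,
                          by = c("participant", "trial", "phase_name"))
    cols <- c(traj_cols(), intersect(c("gaze_x", "gaze_y"), names(d)))
    paths[i] <- file.path(dir, sprintf("p%03d_t%04d_%s.csv",
                                       k$participant, k$trial,
                                       k$phase_name))
    readr::write_csv(d[, cols], paths[i])
  }
  invisible(paths)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(dir) {
  files <- list.files(dir, pattern = "^p\\d+_t\\d+_.*\\.csv$",
                      full.names = TRUE)
  if (!length(files)) stop("no trajectory files in ", dir)
  out <- purrr::map_dfr(files, function(f) {
    m <- regmatches(basename(f),
                    regexec("^p(\\d+)_t(\\d+)_(.*)\\.csv$", basename(f)))[[1]]
    d <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    if (is.unsorted(d$t, strictly = FALSE)) {
      stop("non-monotone time column in ", basename(f))
    }
    d$participant <- as.integer(m[2])
    d$trial <- as.integer(m[3])
    d$phase_name <- m[4]
    d
  })
  out
}

#' Dataset manifest
#'
#' Writes (or validates) a JSON manifest holding the dataset id, the
#' configuration snapshot, the seed, and MD5 checksums of every data file
#' in the directory — enough to regenerate and verify the outputs.
#'
#' @param dir dataset directory.
#' @param config the [game_config()] used.
#' @param seed the seed used.
#' @param id dataset identifier.
#' @return `write_manifest()` returns the manifest path invisibly;
#'   `validate_manifest()` returns `TRUE` or errors on a checksum or file
#'   mismatch.
#' @export
write_manifest <- function(dir, config, seed, id = basename(dir)) {
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  sums <- as.list(tools::md5sum(file.path(dir, files)))
  names(sums) <- files
  manifest <- list(
    id = id,
    package_version = as.character(utils::packageVersion("pursuitlab")),
    seed = seed,
    config = unclass(config),
    checksums = sums
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
validate_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(path)
  for (f in names(manifest$checksums)) {
    fp <- file.path(dir, f)
    if (!file.exists(fp)) stop("manifest file missing: ", f)
    actual <- unname(tools::md5sum(fp))
    if (!identical(actual, manifest$checksums[[f]])) {
      stop("checksum mismatch for ", f)
    }
  }
  TRUE
}

#' Run the full synthetic experiment pipeline
#'
#' Generates a synthetic cohort, runs the choice-level analyses
#' (psychometric fits per condition, inferential bias, entropy curves,
#' SDT), fits the autoregressive inference model per participant,
#' reconstructs per-condition energy landscapes, and summarizes gaze and
#' control stability. Optionally writes everything (trials, trajectories,
#' result JSON, manifest) to `out_dir`.
#'
#' @param n_participants,n_trials cohort size.
#' @param experiment 1 or 2.
#' @param seed integer seed.
#' @param population a [population_params()].
#' @param cfg a [game_config()].
#' @param out_dir optional output directory.
#' @param pursuit simulate pursuit phases (gaze/reward analyses need
#'   them).
#' @return A list with `dataset`, `behavior`, `models`, `landscapes`,
#'   `gaze` summaries.
#' @export
run_experiment <- function(n_participants = 4, n_trials = 60,
                           experiment = 1, seed = 1,
                           population = population_params(),
                           cfg = game_config(), out_dir = NULL,
                           pursuit = TRUE) {
  ds <- generate_dataset(n_participants, n_trials, experiment,
                         population = population, cfg = cfg, seed = seed,
                         pursuit = pursuit,
                         keep_trajectories = if (pursuit) "all"
                                             else "inference")
  tr <- ds$trials
  prev_cond <- dplyr::lag(tr$condition)
  tr$prev_condition <- ifelse(tr$trial == 1, NA, prev_cond)

  behavior <- list(
    bias_overall = inferential_bias(tr),
    bias_by_prev = tr |>
      dplyr::filter(!is.na(.data$prev_condition)) |>
      dplyr::group_by(.data$prev_condition) |>
      dplyr::summarise(bias = inferential_bias(dplyr::pick(
        dplyr::everything())), .groups = "drop"),
    psychometric = fit_psychometric(tr),
    entropy = entropy_by_F(tr),
    sdt = sdt_metrics(tr)
  )

  models <- tr |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_map(~ fit_autoregressive_logit(.x))

  fhat <- fhat_frames(ds, models)
  fhat <- fhat |> label_terciles()
  fhat$prev_condition <- tr$prev_condition[
    match(paste(fhat$participant, fhat$trial),
          paste(tr$participant, tr$trial))]
  landscapes <- condition_landscapes(
    dplyr::filter(fhat, !is.na(.data$prev_condition)),
    groups = c("f_tercile", "prev_condition"))

  gaze_summary <- NULL
  if (pursuit && nrow(ds$gaze)) {
    gaze_summary <- gaze_condition_summary(ds)
  }

  out <- list(dataset = ds, behavior = behavior, models = models,
              landscapes = landscapes, gaze = gaze_summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trials(ds$trials, file.path(out_dir, "trials.csv"))
    if (nrow(ds$trajectories)) {
      write_trajectories(ds$trajectories,
                         file.path(out_dir, "trajectories"))
    }
    res <- list(
      bias_overall = behavior$bias_overall,
      bias_by_prev = behavior$bias_by_prev,
      psychometric = glance(behavior$psychometric),
      sdt = behavior$sdt,
      landscapes = dplyr::select(landscapes, -"landscape")
    )
    jsonlite::write_json(res, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(out_dir, cfg, seed)
  }
  out
}

# Per-frame inferred-F series for every trial of a dataset, using each
# participant's own fitted model.
fhat_frames <- function(ds, models) {
  stopifnot(nrow(ds$trajectories) > 0)
  tr <- ds$trials
  cfg <- ds$config
  parts <- sort(unique(tr$participant))
  inf <- ds$trajectories[ds$trajectories$phase_name == "inference", ]
  mat <- as.matrix(inf[, c("prey_x", "prey_y", "oppo_x", "oppo_y",
                           "play_x", "play_y")])
  key <- paste(inf$participant, inf$trial)
  pieces <- split(seq_len(nrow(inf)), factor(key, levels = unique(key)))
  out_p <- integer(0); out_i <- integer(0)
  fh <- vector("list", length(pieces))
  meta <- matrix(0L, length(pieces), 3)  # participant, trial, n
  for (k in seq_along(pieces)) {
    rows <- pieces[[k]]
    p <- inf$participant[rows[1]]
    i <- inf$trial[rows[1]]
    model <- models[[match(p, parts)]]
    dd <- cpp_pair_distances(mat[rows, , drop = FALSE], cfg$px_per_deg)
    X <- rolling_feature_matrix(dd, cfg$frame_rate)
    dfp <- tr$delta_f_prev[tr$participant == p & tr$trial == i]
    fh[[k]] <- plogis(model$beta0 + drop(X %*% model$beta_t) +
                        model$beta_hys * dfp)
    meta[k, ] <- c(p, i, length(rows))
  }
  n_each <- meta[, 3]
  out <- tibble::tibble(
    participant = rep(meta[, 1], n_each),
    trial = rep(meta[, 2], n_each),
    frame = unlist(lapply(n_each, seq_len)) - 1L,
    f_hat = unlist(fh)
  )
  out$t <- out$frame / cfg$frame_rate
  idx <- match(paste(out$participant, out$trial),
               paste(tr$participant, tr$trial))
  out$f_inference <- tr$f_inference[idx]
  out
}

# Windowed gaze comparison and jerk per trial, by condition. Requires a
# dataset built with keep_trajectories = "all".
gaze_condition_summary <- function(ds, window = c(1.5, 3)) {
  if (!nrow(ds$gaze)) stop("dataset holds no gaze series")
  pur <- dplyr::filter(ds$trajectories, .data$phase_name == "pursuit")
  if (!nrow(pur)) {
    stop("gaze analyses need pursuit trajectories ",
         "(keep_trajectories = \"all\")")
  }
  tr <- ds$trials
  per_trial <- purrr::map_dfr(
    split(ds$gaze, list(ds$gaze$participant, ds$gaze$trial), drop = TRUE),
    function(g) {
      p <- g$participant[1]; i <- g$trial[1]
      d <- pur[pur$participant == p & pur$trial == i, ]
      if (nrow(d) != nrow(g)) return(tibble::tibble())
      row <- tr[tr$participant == p & tr$trial == i, ]
      gc <- gaze_comparison(g, d, window, ds$config)
      jk <- if (nrow(d) >= 4)
        jerk_strength(cbind(d$play_x, d$play_y), ds$config$frame_rate,
                      ds$config$px_per_deg) else NA_real_
      tibble::tibble(participant = p, trial = i, condition = row$condition,
                     window_mean = gc$window_mean, jerk = jk)
    })
  list(
    per_trial = per_trial,
    by_condition = per_trial |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(window_mean = mean(.data$window_mean, na.rm = TRUE),
                       jerk = mean(.data$jerk, na.rm = TRUE),
                       .groups = "drop")
  )
}
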