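#' Configuration for an end-to-end synthetic study
#'
#' @param subjects Character vector of subject ids.
#' @param angles Knee angles (deg) recorded per subject.
#' @param protocol Base [emg_protocol()]; its `knee_angle` is overridden
#'   per session.
#' @param profile An [activation_profile()]; a single profile or a named
#'   list with one profile per subject.
#' @param model A [knee_model()].
#' @param seed Root seed; all per-session and per-stage seeds derive from
#'   it deterministically.
#' @param normalization Activation normalization method, `"max"` or `"rf"`.
#' @param settle_method Settle path for torque measurement.
#' @param band_low Lower frequency limit (Hz) of the activation feature.
#' @param contrast_min Minimum in-trial/rest activity contrast for a trial
#'   to count as active; trials below it get zero activations and torque.
#' @param session_files Optional data frame with columns `file`, `subject`,
#'   `angle` naming previously written sessions to read instead of
#'   generating synthetic ones.
#' @param trial_scale Optional per-trial amplitude scalings passed to the
#'   generator (single vector applied to every session).
#' @return An object of class `study_config`.
#' @export
study_config <- function(subjects = c("aac", "aad"),
                         angles = c(0, 20, 60, 90),
                         protocol = emg_protocol(),
                         profile = activation_profile(),
                         model = knee_model(),
                         seed = 1L,
                         normalization = c("max", "rf"),
                         settle_method = c("static", "dynamic"),
                         band_low = 20,
                         contrast_min = 1.5,
                         session_files = NULL,
                         trial_scale = NULL) {
  structure(
    list(subjects = subjects, angles = angles, protocol = protocol,
         profile = profile, model = model, seed = seed,
         normalization = match.arg(normalization),
         settle_method = match.arg(settle_method),
         band_low = band_low, contrast_min = contrast_min,
         session_files = session_files, trial_scale = trial_scale),
    class = "study_config")
}

## Localize trials of one session; returns segments plus the activity
## trace (for the contrast gate).
localize_session <- function(session, n_trials, seed) {
  sgs <- lapply(seq_len(nrow(session$samples)), function(ch)
    compute_spectrogram(session$samples[ch, ], session$sampling_rate))
  trace <- summed_activity(sgs)
  events <- detect_activity_events(trace)
  segments <- localize_trials(events, n_trials, seed = seed)
  list(segments = segments, trace = trace, n_events = length(events))
}

## In-trial vs rest contrast of the activity trace for one segment.
segment_contrast <- function(trace, segments, k) {
  tt <- trace$frame_times
  inside <- tt >= segments$onset[k] & tt <= segments$offset[k]
  in_any <- rep(FALSE, length(tt))
  for (j in seq_len(nrow(segments)))
    in_any <- in_any | (tt >= segments$onset[j] - 1 &
                          tt <= segments$offset[j] + 1)
  rest <- mean(trace$values[!in_any])
  if (!is.finite(rest) || rest <= 0) return(Inf)
  mean(trace$values[inside]) / rest
}

#' Run the end-to-end study reproduction
#'
#' For every subject and knee angle: generate (or read) the EMG session,
#' localize the contraction trials from the summed spectrogram, compute the
#' frequency cut-off pooled across the subject's sessions, extract raw and
#' normalized per-muscle activations per trial, and measure the balancing
#' knee torque per trial on the musculoskeletal model.  Trials whose
#' in-trial activity does not exceed the rest level by `contrast_min` are
#' recorded with zero activations and zero torque (status `"no_activity"`);
#' trials failing any stage are retained with status `"failed"` rather than
#' dropped.
#'
#' @param config A [study_config()].
#' @return A `study_table` data frame with one row per (subject, angle,
#'   trial): origin time, per-muscle raw features `F_*`, normalized
#'   activations `a_*`, `balancing_torque`, `settled_angle`, `converged`
#'   and `status`; per-subject cut-off results are attached as attribute
#'   `cutoffs`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  rows <- list()
  cutoffs <- list()
  for (si in seq_along(config$subjects)) {
    subj <- config$subjects[si]
    sessions <- list()
    for (ai in seq_along(config$angles)) {
      ang <- config$angles[ai]
      if (!is.null(config$session_files)) {
        sf <- config$session_files
        hit <- which(sf$subject == subj & sf$angle == ang)
        if (length(hit) != 1L)
          stopf("session_files must name exactly one file for %s at %g deg",
                subj, ang)
        sessions[[ai]] <- read_session(sf$file[hit])
      } else {
        proto <- config$protocol
        proto$knee_angle <- ang
        prof <- if (inherits(config$profile, "emg_profile")) config$profile
                else config$profile[[subj]]
        sessions[[ai]] <- generate_session(
          proto, prof, seed = derive_seed(config$seed, si, ai),
          trial_scale = config$trial_scale, subject_id = subj)
      }
    }
    cutoffs[[subj]] <- compute_cutoff(sessions)

    for (ai in seq_along(config$angles)) {
      ang <- config$angles[ai]
      session <- sessions[[ai]]
      n_trials <- config$protocol$n_trials
      loc <- tryCatch(
        localize_session(session, n_trials,
                         seed = derive_seed(config$seed, si, ai, 7L)),
        error = function(e) e)
      if (inherits(loc, "error")) {
        if (grepl("insufficient activity events", conditionMessage(loc))) {
          ## nothing exceeds the SNR threshold: a silent session
          for (k in seq_len(n_trials))
            rows[[length(rows) + 1L]] <- silent_row(subj, ang, k)
        } else {
          rows[[length(rows) + 1L]] <-
            failed_row(subj, ang, NA_integer_, conditionMessage(loc))
        }
        next
      }
      spectra <- tryCatch(trial_spectra(session, loc$segments),
                          error = function(e) e)
      if (inherits(spectra, "error")) {
        rows[[length(rows) + 1L]] <-
          failed_row(subj, ang, NA_integer_, conditionMessage(spectra))
        next
      }
      for (k in seq_len(nrow(loc$segments))) {
        rows[[length(rows) + 1L]] <- tryCatch(
          trial_row(subj, ang, k, loc, spectra, cutoffs[[subj]], config),
          error = function(e)
            failed_row(subj, ang, k, conditionMessage(e)))
      }
    }
    sessions <- NULL
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "cutoffs") <- cutoffs
  class(tab) <- c("study_table", "data.frame")
  tab
}

trial_row <- function(subj, ang, k, loc, spectra, cutoff, config) {
  muscles <- knee_muscles
  feats <- vapply(muscles, function(m)
    activation_feature(list(frequency = spectra$frequencies,
                            amplitude = spectra$v[, m, k]),
                       cutoff, band_low = config$band_low), numeric(1))
  contrast <- segment_contrast(loc$trace, loc$segments, k)
  if (contrast < config$contrast_min) {
    a <- stats::setNames(rep(0, 7L), muscles)
    torque <- 0; settled <- ang; conv <- TRUE; status <- "no_activity"
  } else {
    av <- normalize_activations(feats, method = config$normalization)
    a <- stats::setNames(as.numeric(av), muscles)
    tm <- balancing_torque(av, ang, config$model,
                           method = config$settle_method)
    torque <- tm$balancing_torque; settled <- tm$settled_angle
    conv <- tm$converged; status <- "ok"
  }
  out <- data.frame(subject = subj, angle = ang, trial = k,
                    origin = loc$segments$origin[k],
                    contrast = contrast, stringsAsFactors = FALSE)
  for (m in muscles) out[[paste0("F_", m)]] <- feats[[m]]
  for (m in muscles) out[[paste0("a_", m)]] <- a[[m]]
  out$balancing_torque <- torque
  out$settled_angle <- settled
  out$converged <- conv
  out$status <- status
  out
}

silent_row <- function(subj, ang, k) {
  out <- data.frame(subject = subj, angle = ang, trial = k,
                    origin = NA_real_, contrast = NA_real_,
                    stringsAsFactors = FALSE)
  for (m in knee_muscles) out[[paste0("F_", m)]] <- 0
  for (m in knee_muscles) out[[paste0("a_", m)]] <- 0
  out$balancing_torque <- 0
  out$settled_angle <- ang
  out$converged <- TRUE
  out$status <- "no_activity"
  out
}

failed_row <- function(subj, ang, k, msg) {
  out <- data.frame(subject = subj, angle = ang, trial = k,
                    origin = NA_real_, contrast = NA_real_,
                    stringsAsFactors = FALSE)
  for (m in knee_muscles) out[[paste0("F_", m)]] <- NA_real_
  for (m in knee_muscles) out[[paste0("a_", m)]] <- NA_real_
  out$balancing_torque <- NA_real_
  out$settled_angle <- NA_real_
  out$converged <- FALSE
  out$status <- paste0("failed: ", msg)
  out
}

#' Per-muscle Pearson correlation between activation and knee angle
#'
#' Computes, per subject and muscle, the Pearson correlation between knee
#' angle and normalized activation across trials.  Requires at least three
#' distinct angles per subject; a zero-variance activation series yields an
#' undefined (`NA`) correlation with a note, never 0.
#'
#' @param table A `study_table` from [run_study()].
#' @param use `"normalized"` (the activations applied to the muscles) or
#'   `"raw"` (the raw features `F_m`).
#' @return A `correlation_report` data frame with columns `subject`,
#'   `muscle`, `r`, `n`, `note`.
#' @export
pearson_by_muscle <- function(table, use = c("normalized", "raw")) {
  use <- match.arg(use)
  stopifnot(inherits(table, "data.frame"))
  ok <- table$status == "ok"
  tab <- table[ok, , drop = FALSE]
  out <- list()
  for (subj in unique(tab$subject)) {
    sub <- tab[tab$subject == subj, , drop = FALSE]
    if (length(unique(sub$angle)) < 3L)
      stopf("subject %s has fewer than 3 distinct angles", subj)
    for (m in knee_muscles) {
      col <- paste0(if (use == "normalized") "a_" else "F_", m)
      y <- sub[[col]]
      note <- ""
      r <- if (stats::sd(y) == 0 || stats::sd(sub$angle) == 0) {
        note <- "zero variance: correlation undefined"
        NA_real_
      } else {
        stats::cor(sub$angle, y)
      }
      out[[length(out) + 1L]] <- data.frame(
        subject = subj, muscle = m, r = r, n = nrow(sub), note = note,
        stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  class(rep) <- c("correlation_report", "data.frame")
  rep
}

#' Compare a natural and an evolved synergy
#'
#' Computes per-muscle absolute differences, the cosine similarity of the
#' two activation vectors, and the relative difference of their balancing
#' torques at the target angle.
#'
#' @param natural,evolved Activation vectors (7 values in `[0, 1]`).
#' @param model A [knee_model()].
#' @param target_angle Knee angle (deg) at which torques are measured.
#' @param settle_method Settle path for the torque measurements.
#' @return An object of class `synergy_comparison`: `per_muscle_diff`,
#'   `cosine_similarity`, `torque_natural`, `torque_evolved`,
#'   `torque_relative_error`.
#' @export
compare_synergies <- function(natural, evolved, model, target_angle,
                              settle_method = c("static", "dynamic")) {
  settle_method <- match.arg(settle_method)
  nat <- as.numeric(natural); evo <- as.numeric(evolved)
  stopifnot(length(nat) == 7L, length(evo) == 7L)
  t_nat <- balancing_torque(nat, target_angle, model,
                            method = settle_method)$balancing_torque
  t_evo <- balancing_torque(evo, target_angle, model,
                            method = settle_method)$balancing_torque
  rel <- if (t_nat > 0) abs(t_nat - t_evo) / t_nat else NA_real_
  structure(
    list(per_muscle_diff = stats::setNames(abs(nat - evo), knee_muscles),
         cosine_similarity = cosine_similarity(nat, evo),
         torque_natural = t_nat,
         torque_evolved = t_evo,
         torque_relative_error = rel,
         target_angle = target_angle),
    class = "synergy_comparison")
}

#' @export
print.synergy_comparison <- function(x, ...) {
  cat(sprintf("<synergy_comparison> at %g deg: cosine %.3f, torque %.2f vs %.2f N m (rel err %.3g)\n",
              x$target_angle, x$cosine_similarity, x$torque_natural,
              x$torque_evolved, x$torque_relative_error))
  invisible(x)
}
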