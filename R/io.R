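# Event-log dialect and config I/O. Logs are plain UTF-8 CSV:
# '#'-prefixed header lines (mouse id, group, age, stage, sd, iti, date,
# protocol hash), then `time_s,event,arg` rows with times in seconds from
# session start at millisecond precision. The dialect is device-agnostic and
# diff-friendly; real annotated data can flow through the same path as
# simulated logs (EAT_END is a first-class event).

EVENT_TYPES <- c("STIM_ON", "STIM_OFF", "POKE_APERTURE", "POKE_MAGAZINE",
                 "PELLET_DELIVERED", "PELLET_RETRIEVED", "EAT_END",
                 "HOUSELIGHT_ON", "HOUSELIGHT_OFF", "TIMEOUT_START",
                 "TIMEOUT_END", "SESSION_END")

HEADER_KEYS <- c("mouse_id", "group", "age_days", "stage", "sd_s", "iti_s",
                 "date", "protocol_hash")

#' Hash a protocol configuration
#'
#' A short hex digest over the canonical key-sorted serialization of the
#' config; it changes whenever any field changes, so logs carry a fingerprint
#' of the protocol that produced them.
#'
#' @param config protocol configuration list.
#' @return 8-character hex string.
#' @export
protocol_hash <- function(config) {
  keys <- sort(names(config))
  canon <- paste(vapply(keys, function(k) {
    v <- config[[k]]
    if (is.list(v)) {
      v <- paste(names(v), vapply(v, format, ""), sep = "=", collapse = "|")
    } else {
      v <- paste(format(v, digits = 15), collapse = "|")
    }
    paste0(k, ":", v)
  }, ""), collapse = ";")
  h <- 0
  for (b in utf8ToInt(canon)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

fmt_header_value <- function(v) {
  if (is.null(v) || length(v) == 0 || is.na(v)) "NA" else format(v)
}

#' Write a session event log
#'
#' Serialises an `fc_session`'s event stream to the CSV dialect above.
#' Writing then reading back reproduces the event table exactly (times are
#' already held at millisecond precision in memory).
#'
#' @param session `fc_session` with a non-`NULL` `events` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(session, path) {
  if (is.null(session$events)) {
    stop("session has no event log; simulate with emit_events = TRUE")
  }
  m <- session$meta
  hdr <- vapply(HEADER_KEYS, function(k) {
    paste0("# ", k, ": ", fmt_header_value(m[[k]]))
  }, "")
  ev <- session$events
  arg <- ifelse(is.na(ev$arg), "", as.character(ev$arg))
  rows <- sprintf("%.3f,%s,%s", ev$time_s, ev$event, arg)
  con <- file(path, open = "wb")  # fixed LF endings for byte determinism
  on.exit(close(con))
  writeLines(c(hdr, "time_s,event,arg", rows), con, sep = "\n")
  invisible(path)
}

#' Read and validate a session event log
#'
#' Parses the CSV dialect, validates it (known event types, non-decreasing
#' times, aperture arguments where required, exactly one `SESSION_END`) with
#' line numbers in error messages, and reconstructs the trial list by
#' classifying the event stream (see [classify_events()]).
#'
#' @param path event-log file. CRLF and LF files parse identically.
#' @param config protocol configuration used for trial classification.
#' @return an `fc_session` with `meta`, `events`, `trials` and `summary`.
#' @export
read_event_log <- function(path, config = default_protocol()) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  is_hdr <- grepl("^#", lines)
  hdr <- lines[is_hdr]
  meta <- list()
  for (h in hdr) {
    mm <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(mm) == 3) meta[[trimws(mm[2])]] <- trimws(mm[3])
  }
  missing <- setdiff(HEADER_KEYS, names(meta))
  if (length(missing) > 0) {
    stop("event log header is missing keys: ",
         paste(missing, collapse = ", "))
  }
  for (k in c("age_days", "sd_s", "iti_s")) {
    meta[[k]] <- suppressWarnings(as.numeric(meta[[k]]))
  }
  body <- which(!is_hdr)
  if (length(body) == 0 || lines[body[1]] != "time_s,event,arg") {
    stop("missing 'time_s,event,arg' column header")
  }
  data_idx <- body[-1]
  data_idx <- data_idx[nzchar(lines[data_idx])]
  n <- length(data_idx)
  if (n == 0) stop("event log has no events")
  parts <- strsplit(lines[data_idx], ",", fixed = TRUE)
  bad_cols <- which(vapply(parts, length, 0L) < 2)
  if (length(bad_cols) > 0) {
    stop("malformed row at line ", data_idx[bad_cols[1]])
  }
  time_s <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  event <- vapply(parts, `[`, "", 2)
  argc <- vapply(parts, function(p) if (length(p) >= 3) p[3] else "", "")
  if (any(is.na(time_s))) {
    stop("non-numeric time at line ", data_idx[which(is.na(time_s))[1]])
  }
  unk <- !event %in% EVENT_TYPES
  if (any(unk)) {
    stop("unknown event '", event[which(unk)[1]], "' at line ",
         data_idx[which(unk)[1]])
  }
  nonmono <- which(diff(time_s) < 0)
  if (length(nonmono) > 0) {
    stop("non-monotone time at line ", data_idx[nonmono[1] + 1])
  }
  arg <- suppressWarnings(as.integer(argc))
  need_arg <- event %in% c("STIM_ON", "POKE_APERTURE")
  bad_arg <- need_arg & (is.na(arg) | arg < 1 | arg > 5)
  if (any(bad_arg)) {
    stop("missing or invalid aperture id at line ",
         data_idx[which(bad_arg)[1]])
  }
  if (sum(event == "SESSION_END") != 1) {
    stop("event log must contain exactly one SESSION_END")
  }
  events <- data.frame(time_s = time_s, event = event, arg = arg,
                       stringsAsFactors = FALSE)
  meta$duration_s <- time_s[event == "SESSION_END"]
  trials <- classify_events(events, meta, config)
  s <- list(meta = meta, trials = trials, events = events)
  class(s) <- "fc_session"
  s$summary <- session_summary(s)
  s
}

#' Reconstruct trials from a session event stream
#'
#' Segments a whole-session event log into trials and classifies each one.
#' Cued stages (discrimination, training, test days) are segmented on
#' `STIM_ON`: a poke while no stimulus window is open is premature; the first
#' poke after onset is the response (correct when it matches the cued
#' aperture); a window closed by its timeout with no poke is an omission.
#' Magazine and acquisition logs are segmented on pellet deliveries and
#' aperture pokes respectively. Reward retrievals and `EAT_END` annotations
#' are matched to correct trials first-in-first-out, so eating bouts that
#' outlast subsequent trials are attributed correctly.
#'
#' @param events data.frame `time_s`, `event`, `arg` (time-ordered).
#' @param meta named list; `stage` selects the segmentation rule.
#' @param config protocol configuration (limited hold for cued stages).
#' @return trials data.frame in the same layout as simulated sessions.
#' @export
classify_events <- function(events, meta, config = default_protocol()) {
  stage <- meta$stage
  if (is.null(stage) || is.na(stage)) stop("meta$stage is required")
  if (stage %in% c("magazine", "acquisition")) {
    return(classify_free_events(events, stage))
  }
  lh <- config$train_limited_hold_s
  no_deadline <- stage == "discrimination"

  res <- new_trials_acc()
  onset <- NA_real_
  cued <- NA_integer_
  off_t <- NA_real_
  responded <- FALSE
  # FIFO queues for reward bookkeeping
  open_correct <- integer(0)   # trial rows awaiting retrieval
  eating_open <- integer(0)    # trial rows awaiting EAT_END
  retr_time <- numeric(0)
  eat_idx <- 0L

  close_window <- function(outcome, ap, lat, retr) {
    trials_add(res, list(outcome = outcome, cued_aperture = cued,
                         responded_aperture = ap, response_latency_s = lat,
                         stimulus_onset_s = onset,
                         reward_retrieval_s = retr,
                         eating_duration_s = NA_real_),
               if (!is.na(off_t)) off_t - onset else NA_real_,
               if (!is.null(meta$iti_s)) meta$iti_s else NA_real_)
  }

  for (i in seq_len(nrow(events))) {
    ev <- events$event[i]
    tt <- events$time_s[i]
    ar <- events$arg[i]
    if (ev == "STIM_ON") {
      if (!is.na(onset) && !responded) {
        close_window("omission", NA_integer_, NA_real_, NA_real_)
      }
      onset <- tt
      cued <- as.integer(ar)
      off_t <- NA_real_
      responded <- FALSE
    } else if (ev == "STIM_OFF") {
      if (!is.na(onset) && is.na(off_t)) off_t <- tt
    } else if (ev == "POKE_APERTURE") {
      if (is.na(onset)) {
        # no stimulus pending: premature response
        trials_add(res, list(outcome = "premature",
                             cued_aperture = NA_integer_,
                             responded_aperture = as.integer(ar),
                             response_latency_s = NA_real_,
                             stimulus_onset_s = NA_real_,
                             reward_retrieval_s = NA_real_,
                             eating_duration_s = NA_real_),
                   NA_real_,
                   if (!is.null(meta$iti_s)) meta$iti_s else NA_real_)
      } else if (!responded) {
        lat <- tt - onset
        window_ok <- no_deadline ||
          (!is.na(off_t) && tt <= off_t + lh + 2e-3) ||
          (is.na(off_t))  # light still on
        outc <- if (as.integer(ar) == cued && window_ok) "correct"
                else if (window_ok) "incorrect" else "omission"
        if (outc == "omission") {
          close_window("omission", NA_integer_, NA_real_, NA_real_)
        } else {
          close_window(outc, as.integer(ar), lat, NA_real_)
          if (outc == "correct") {
            open_correct <- c(open_correct, res$n)
          }
        }
        responded <- TRUE
        onset <- NA_real_
        cued <- NA_integer_
        off_t <- NA_real_
      }
    } else if (ev == "TIMEOUT_START") {
      if (!is.na(onset) && !responded) {
        close_window("omission", NA_integer_, NA_real_, NA_real_)
        onset <- NA_real_
        cued <- NA_integer_
        off_t <- NA_real_
        responded <- FALSE
      }
    } else if (ev == "PELLET_RETRIEVED") {
      if (length(open_correct) > 0) {
        row <- open_correct[1]
        open_correct <- open_correct[-1]
        res$reward_retrieval_s[row] <- tt
        eating_open <- c(eating_open, row)
        retr_time <- c(retr_time, tt)
      }
    } else if (ev == "EAT_END") {
      if (length(eating_open) > 0) {
        row <- eating_open[1]
        eating_open <- eating_open[-1]
        res$eating_duration_s[row] <- tt - retr_time[1]
        retr_time <- retr_time[-1]
      }
    } else if (ev == "SESSION_END") {
      if (!is.na(onset) && !responded) {
        close_window("omission", NA_integer_, NA_real_, NA_real_)
        onset <- NA_real_
      }
    }
  }
  trials_collect(res)
}

classify_free_events <- function(events, stage) {
  res <- new_trials_acc()
  eating_open <- integer(0)
  retr_time <- numeric(0)
  trial_start <- 0
  for (i in seq_len(nrow(events))) {
    ev <- events$event[i]
    tt <- events$time_s[i]
    ar <- events$arg[i]
    if (stage == "acquisition" && ev == "POKE_APERTURE") {
      trials_add(res, list(outcome = "correct", cued_aperture = NA_integer_,
                           responded_aperture = as.integer(ar),
                           response_latency_s = tt - trial_start,
                           stimulus_onset_s = trial_start,
                           reward_retrieval_s = NA_real_,
                           eating_duration_s = NA_real_),
                 NA_real_, NA_real_)
    } else if (stage == "magazine" && ev == "PELLET_DELIVERED") {
      trials_add(res, list(outcome = "correct", cued_aperture = NA_integer_,
                           responded_aperture = NA_integer_,
                           response_latency_s = NA_real_,
                           stimulus_onset_s = NA_real_,
                           reward_retrieval_s = NA_real_,
                           eating_duration_s = NA_real_),
                 NA_real_, NA_real_)
    } else if (ev == "PELLET_RETRIEVED") {
      if (res$n > 0 && is.na(res$reward_retrieval_s[res$n])) {
        res$reward_retrieval_s[res$n] <- tt
        eating_open <- c(eating_open, res$n)
        retr_time <- c(retr_time, tt)
        trial_start <- tt  # next acquisition trial begins at retrieval
      }
    } else if (ev == "EAT_END") {
      if (length(eating_open) > 0) {
        row <- eating_open[1]
        eating_open <- eating_open[-1]
        res$eating_duration_s[row] <- tt - retr_time[1]
        retr_time <- retr_time[-1]
      }
    }
  }
  trials_collect(res)
}

#' Write/read protocol and cohort configs as YAML
#'
#' @param config protocol configuration ([default_protocol()] layout).
#' @param path file path.
#' @return `read_protocol()` returns a validated `fc_protocol`.
#' @export
write_protocol <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "fc_protocol"
  validate_protocol(cfg)
  cfg
}

#' Write a cohort's event logs to a directory
#'
#' One CSV per session, named `<mouse>_<stage>_<k>.csv`.
#'
#' @param cohort `fc_cohort` simulated with `emit_events = TRUE`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_cohort_logs <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (m in cohort$mice) {
    for (i in seq_along(m$sessions)) {
      s <- m$sessions[[i]]
      if (is.null(s$events)) next
      s$meta$date <- NA
      fn <- file.path(dir, sprintf("%s_%02d_%s.csv", m$meta$mouse_id, i,
                                   s$meta$stage))
      write_event_log(s, fn)
      paths <- c(paths, fn)
    }
  }
  invisible(paths)
}
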