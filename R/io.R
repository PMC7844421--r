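# Plain-text interchange: force traces with metadata sidecars, ground
# truth logs, event tables, motility tracks with a manifest.

#' Write / read a force trace as columnar text with a metadata sidecar
#'
#' The trace is written as two-column whitespace-separated text
#' (`time_s`, `force_pN`); construct, trap parameters and the simulation
#' seed go to a YAML sidecar `<path>.meta.yaml`.
#'
#' @param trace a `trap_trace`.
#' @param path output file.
#' @return `path` (write) or a `trap_trace` (read; ground truth is not
#'   round-tripped).
#' @export
write_trap_trace <- function(trace, path) {
  trap <- .trace_meta(trace)
  p <- attr(trace, "params")
  utils::write.table(data.frame(time_s = trace$time, force_pN = trace$force),
                     path, row.names = FALSE, quote = FALSE)
  meta <- list(construct = p$construct_label %||% "unknown",
               seed = attr(trace, "seed"),
               trap = unclass(trap),
               motor = unclass(p))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_trap_trace
#' @export
read_trap_trace <- function(path) {
  d <- utils::read.table(path, header = TRUE)
  out <- tibble(time = d$time_s, force = d$force_pN)
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    attr(out, "trap") <- do.call(trap_config, meta$trap)
    if (!is.null(meta$motor)) {
      attr(out, "params") <- do.call(motor_params, meta$motor)
    }
    attr(out, "seed") <- meta$seed
  }
  class(out) <- c("trap_trace", class(out))
  out
}

#' Write a ground-truth log as structured text
#'
#' One record per transition, three sections (attachments, steps,
#' encounters) in a single tab-separated file with a `record` column.
#'
#' @param truth a `truth_log` (see [ground_truth()]).
#' @param path output file.
#' @export
write_truth_log <- function(truth, path) {
  att <- mutate(truth$attachments, record = "attachment")
  stp <- mutate(truth$steps, record = "step")
  enc <- mutate(truth$encounters, record = "encounter")
  all <- bind_rows(att, stp, enc)
  utils::write.table(all, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-trace event table as text
#'
#' @param events output of [detect_events()] (with optional stall counts).
#' @param path output file.
#' @export
write_event_table <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read motility tracks as per-event text files with a manifest
#'
#' Each track becomes `track_<id>.txt` (`time_s`, `position_um`) inside
#' `dir`; the manifest (`manifest.yaml`) stores per-track metadata
#' (microtubule, MT length, concentration, movie duration, frame
#' interval).
#'
#' @param tracks a `motility_tracks` tibble.
#' @param dir output directory (created if needed).
#' @return `dir` (write) or a `motility_tracks` tibble (read).
#' @export
write_motility_tracks <- function(tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list()
  for (r in seq_len(nrow(tracks))) {
    f <- file.path(dir, sprintf("track_%04d.txt", tracks$track[r]))
    d <- tracks$data[[r]]
    utils::write.table(data.frame(time_s = d$time, position_um = d$position),
                       f, row.names = FALSE, quote = FALSE)
    meta[[length(meta) + 1L]] <- list(
      track = tracks$track[r], file = basename(f), mt = tracks$mt[r],
      mt_length = tracks$mt_length[r], conc = tracks$conc[r],
      movie_duration = tracks$movie_duration[r],
      frame_dt = tracks$frame_dt[r])
  }
  yaml::write_yaml(list(mt_lengths = as.numeric(attr(tracks, "mt_lengths")),
                        tracks = meta),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_motility_tracks
#' @export
read_motility_tracks <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  rows <- purrr::map(man$tracks, function(m) {
    d <- utils::read.table(file.path(dir, m$file), header = TRUE)
    tibble(track = m$track, mt = m$mt, mt_length = m$mt_length,
           conc = m$conc, movie_duration = m$movie_duration,
           frame_dt = m$frame_dt,
           data = list(tibble(time = d$time_s, position = d$position_um)))
  })
  out <- bind_rows(rows)
  class(out) <- c("motility_tracks", class(out))
  attr(out, "mt_lengths") <- man$mt_lengths
  out
}
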