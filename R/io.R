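#' @name trial_format
#' @title Plain-text trial interchange format
#' @description
#' One file per participant, tab-separated, self-describing, version
#' line first.  Row types:
#' \itemize{
#'   \item `GAZEFMT <version>` — format version line (always first).
#'   \item `P <participant_id>` — participant header.
#'   \item `G <distance_mm> <px_w> <px_h> <mm_w> <mm_h>` — optional
#'     viewing geometry.
#'   \item `T <trial_id> <rate_hz> <unit> <condition|->` — starts a
#'     trial block.
#'   \item `C <eye> [<eye> ...]` — eye channels present in `S` rows.
#'   \item `S <idx> <t> <x> <y> <valid>...` — one sample; one
#'     `x y valid` triple per declared eye; `idx` is the 0-based sample
#'     index, `t = idx / rate_hz` seconds (9 decimals).  Positions are
#'     written at full precision; invalid samples carry `NA`.
#'   \item `F <eye> <onset> <offset>` — fixation interval, 0-based
#'     half-open sample indices.
#'   \item `M <eye> <onset> <offset> [<onl> <offl> <onr> <offr>]` —
#'     microsaccade interval; binocular events also carry the per-eye
#'     intervals.
#'   \item `E <t> <label>` — event marker.
#' }
#' Coordinates use screen convention (origin top-left, y downward); no
#' unit conversion happens in I/O — the unit tag is preserved.
NULL

FORMAT_NAME <- "GAZEFMT"
FORMAT_VERSION <- 1L
COND_FORMAT_NAME <- "GAZECOND"

num_full <- function(v) {
  ifelse(is.na(v), "NA", sprintf("%.17g", v))
}

#' Bundle trials into a participant object
#'
#' @param participant_id Identifier.
#' @param trials List of [gaze_trial()] objects.
#' @param geometry Optional [viewing_geometry()].
#' @return An object of class `gaze_participant`.
#' @export
gaze_participant <- function(participant_id, trials, geometry = NULL) {
  structure(list(participant_id = as.character(participant_id),
                 trials = trials, geometry = geometry),
            class = "gaze_participant")
}

#' @export
print.gaze_participant <- function(x, ...) {
  cat(sprintf("<gaze_participant> %s: %d trial(s)\n",
              x$participant_id, length(x$trials)))
  invisible(x)
}

# serialize one trial block to lines
format_trial_block <- function(trial) {
  eyes <- names(trial$traces)
  tr1 <- trial$traces[[1]]
  n <- length(tr1$x)
  cond <- if (is.na(trial$condition)) "-" else trial$condition
  lines <- c(
    paste("T", trial$trial_id, format(tr1$rate_hz), tr1$unit, cond,
          sep = "\t"),
    paste(c("C", eyes), collapse = "\t")
  )
  cols <- list(sprintf("%d", seq_len(n) - 1L),
               sprintf("%.9f", trace_times(tr1)))
  for (e in eyes) {
    tr <- trial$traces[[e]]
    xs <- ifelse(tr$valid, num_full(tr$x), "NA")
    ys <- ifelse(tr$valid, num_full(tr$y), "NA")
    cols <- c(cols, list(xs, ys, ifelse(tr$valid, "1", "0")))
  }
  srows <- do.call(paste, c(list("S"), cols, sep = "\t"))
  lines <- c(lines, srows)
  fmt_iv <- function(tag, df) {
    if (is.null(df) || nrow(df) == 0) return(character(0))
    extra <- character(nrow(df))
    if (tag == "M" && all(c("onset_left", "offset_left",
                            "onset_right", "offset_right") %in% names(df))) {
      has <- !is.na(df$onset_left)
      extra <- ifelse(has,
        paste(df$onset_left - 1L, df$offset_left - 1L,
              df$onset_right - 1L, df$offset_right - 1L, sep = "\t"),
        "")
    }
    paste0(tag, "\t", df$eye, "\t", df$onset - 1L, "\t", df$offset - 1L,
           ifelse(nzchar(extra), paste0("\t", extra), ""))
  }
  lines <- c(lines, fmt_iv("F", trial$fixations))
  lines <- c(lines, fmt_iv("M", trial$microsaccades))
  em <- trial$event_markers
  if (!is.null(em) && nrow(em)) {
    lines <- c(lines, paste("E", sprintf("%.9f", em$t), em$label, sep = "\t"))
  }
  lines
}

check_disjoint_sorted <- function(df, what) {
  if (is.null(df) || nrow(df) < 2) return(invisible())
  for (e in unique(df$eye)) {
    d <- df[df$eye == e, , drop = FALSE]
    d <- d[order(d$onset), , drop = FALSE]
    if (any(d$onset[-1] < d$offset[-nrow(d)])) {
      stop("overlapping ", what, " intervals for eye '", e,
           "'; refusing to write", call. = FALSE)
    }
  }
  invisible()
}

#' Write a participant's trials to a trial file
#'
#' @param participant A [gaze_participant()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_file <- function(participant, path) {
  lines <- c(paste(FORMAT_NAME, FORMAT_VERSION, sep = "\t"),
             paste("P", participant$participant_id, sep = "\t"))
  g <- participant$geometry
  if (!is.null(g)) {
    lines <- c(lines, paste("G", num_full(g$distance_mm),
                            num_full(g$screen_px[1]), num_full(g$screen_px[2]),
                            num_full(g$screen_mm[1]), num_full(g$screen_mm[2]),
                            sep = "\t"))
  }
  for (trial in participant$trials) {
    check_disjoint_sorted(trial$fixations, "fixation")
    check_disjoint_sorted(trial$microsaccades, "microsaccade")
    lines <- c(lines, format_trial_block(trial))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write detection results for one trial to a trial file
#'
#' Exports the trial's raw samples together with the supplied
#' (detected) fixations and microsaccades so the file round-trips
#' through [read_trial_file()] with all intervals intact.  Overlapping
#' events of the same class are refused.
#'
#' @param trial A [gaze_trial()].
#' @param fixations Fixation data frame (from [detect_fixations()] or
#'   [derive_fixations()]); may be `NULL`.
#' @param microsaccades Microsaccade event data frame; may be `NULL`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_file <- function(trial, fixations, microsaccades, path) {
  tr <- trial
  if (!is.null(fixations) && nrow(fixations)) {
    fx <- fixations
    if (is.null(fx$eye)) fx$eye <- "averaged"
    tr$fixations <- fx[, c("eye", "onset", "offset")]
  } else {
    tr$fixations <- NULL
  }
  if (!is.null(microsaccades) && nrow(microsaccades)) {
    keep <- intersect(c("eye", "onset", "offset", "onset_left", "offset_left",
                        "onset_right", "offset_right"),
                      names(microsaccades))
    tr$microsaccades <- microsaccades[, keep]
  } else {
    tr$microsaccades <- NULL
  }
  write_trial_file(
    gaze_participant(trial$participant_id, list(tr)), path)
}

parse_error <- function(lineno, msg) {
  stop(sprintf("parse error at line %d: %s", lineno, msg), call. = FALSE)
}

#' Read a trial file
#'
#' Parses the format described in [trial_format].  Timestamps are
#' reconstructed exactly from sample index and rate; missing-data
#' ranges are inferred from invalid samples.
#'
#' @param path Input path.
#' @param geometry Optional [viewing_geometry()] overriding/supplying a
#'   geometry absent from the file header.
#' @return A [gaze_participant()].
#' @export
read_trial_file <- function(path, geometry = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  if (length(lines) == 0) parse_error(1, "empty file")
  head_tok <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (head_tok[1] != FORMAT_NAME) {
    parse_error(1, paste0("expected '", FORMAT_NAME, "' version line"))
  }
  participant_id <- NA_character_
  file_geom <- NULL
  trials <- list()

  cur <- NULL  # accumulator for the open trial block
  flush_trial <- function(cur) {
    if (is.null(cur)) return(NULL)
    n <- length(cur$idx)
    if (n == 0) parse_error(cur$lineno, "trial block has no samples")
    if (any(diff(cur$idx) <= 0)) {
      stop("validation error: non-monotonic timestamps in trial '",
           cur$trial_id, "'", call. = FALSE)
    }
    if (cur$rate < 200) {
      warning("trial '", cur$trial_id, "' sampled below 200 Hz; ",
              "microsaccade detection is unreliable", call. = FALSE)
    }
    traces <- list()
    for (k in seq_along(cur$eyes)) {
      e <- cur$eyes[k]
      suppressWarnings(
        traces[[e]] <- gaze_trace(cur$x[[k]], cur$y[[k]], cur$rate,
                                  unit = cur$unit, eye = e,
                                  valid = cur$valid[[k]],
                                  t0 = cur$idx[1] / cur$rate)
      )
    }
    mk_iv <- function(rows, with_eyes = FALSE) {
      if (length(rows) == 0) return(NULL)
      df <- do.call(rbind, rows)
      rownames(df) <- NULL
      df
    }
    gaze_trial(cur$trial_id, traces,
               participant_id = participant_id,
               condition = cur$condition,
               fixations = mk_iv(cur$fix),
               microsaccades = mk_iv(cur$ms),
               event_markers = if (length(cur$ev))
                 do.call(rbind, cur$ev) else NULL)
  }

  i <- 1L
  while (i < length(lines)) {
    i <- i + 1L
    ln <- lines[[i]]
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    tag <- tok[1]
    if (tag == "P") {
      participant_id <- tok[2]
    } else if (tag == "G") {
      if (length(tok) != 6) parse_error(i, "G row needs 5 values")
      v <- suppressWarnings(as.numeric(tok[2:6]))
      if (any(is.na(v))) parse_error(i, "non-numeric geometry")
      file_geom <- viewing_geometry(v[1], v[2:3], v[4:5])
    } else if (tag == "T") {
      if (!is.null(cur)) trials[[length(trials) + 1L]] <- flush_trial(cur)
      if (length(tok) < 4) parse_error(i, "T row needs trial id, rate, unit")
      rate <- suppressWarnings(as.numeric(tok[3]))
      if (is.na(rate) || rate <= 0) parse_error(i, "bad sampling rate")
      if (!tok[4] %in% c("px", "deg")) parse_error(i, "unit must be px or deg")
      cond <- if (length(tok) >= 5 && tok[5] != "-") tok[5] else NA_character_
      cur <- list(trial_id = tok[2], rate = rate, unit = tok[4],
                  condition = cond, lineno = i, eyes = character(0),
                  idx = integer(0), x = list(), y = list(), valid = list(),
                  fix = list(), ms = list(), ev = list())
    } else if (is.null(cur)) {
      parse_error(i, paste0("row '", tag, "' outside a trial block"))
    } else if (tag == "C") {
      eyes <- tok[-1]
      if (length(eyes) == 0 ||
          !all(eyes %in% c("left", "right", "averaged"))) {
        parse_error(i, "C row must list eyes among left/right/averaged")
      }
      cur$eyes <- eyes
      cur$x <- rep(list(numeric(0)), length(eyes))
      cur$y <- rep(list(numeric(0)), length(eyes))
      cur$valid <- rep(list(logical(0)), length(eyes))
    } else if (tag == "S") {
      ne <- length(cur$eyes)
      if (ne == 0) parse_error(i, "S row before C row")
      if (length(tok) != 3 + 3 * ne) {
        parse_error(i, sprintf("S row needs %d fields, got %d",
                               3 + 3 * ne, length(tok)))
      }
      idx <- suppressWarnings(as.integer(tok[2]))
      if (is.na(idx)) parse_error(i, "bad sample index")
      cur$idx <- c(cur$idx, idx)
      for (k in seq_len(ne)) {
        off <- 4L + (k - 1L) * 3L
        vs <- tok[off + 2]
        good <- vs == "1"
        xv <- suppressWarnings(as.numeric(tok[off]))
        yv <- suppressWarnings(as.numeric(tok[off + 1]))
        if (good && (is.na(xv) || is.na(yv))) {
          parse_error(i, "valid sample with non-numeric position")
        }
        cur$x[[k]] <- c(cur$x[[k]], xv)
        cur$y[[k]] <- c(cur$y[[k]], yv)
        cur$valid[[k]] <- c(cur$valid[[k]], good)
      }
    } else if (tag %in% c("F", "M")) {
      if (length(tok) < 4) parse_error(i, "interval row needs eye, onset, offset")
      on <- suppressWarnings(as.integer(tok[3]))
      off <- suppressWarnings(as.integer(tok[4]))
      if (is.na(on) || is.na(off) || off <= on) {
        parse_error(i, "bad interval bounds")
      }
      row <- data.frame(eye = tok[2], onset = on + 1L, offset = off + 1L)
      if (tag == "M") {
        if (length(tok) >= 8) {
          pe <- suppressWarnings(as.integer(tok[5:8]))
          if (any(is.na(pe))) parse_error(i, "bad per-eye interval bounds")
          row$onset_left <- pe[1] + 1L
          row$offset_left <- pe[2] + 1L
          row$onset_right <- pe[3] + 1L
          row$offset_right <- pe[4] + 1L
        } else {
          row$onset_left <- NA_integer_
          row$offset_left <- NA_integer_
          row$onset_right <- NA_integer_
          row$offset_right <- NA_integer_
        }
        cur$ms[[length(cur$ms) + 1L]] <- row
      } else {
        cur$fix[[length(cur$fix) + 1L]] <- row
      }
    } else if (tag == "E") {
      if (length(tok) < 3) parse_error(i, "E row needs time and label")
      t <- suppressWarnings(as.numeric(tok[2]))
      if (is.na(t)) parse_error(i, "bad event time")
      cur$ev[[length(cur$ev) + 1L]] <- data.frame(t = t, label = tok[3])
    } else {
      parse_error(i, paste0("unknown row type '", tag, "'"))
    }
  }
  if (!is.null(cur)) trials[[length(trials) + 1L]] <- flush_trial(cur)
  gaze_participant(participant_id, trials,
                   geometry = if (!is.null(geometry)) geometry else file_geom)
}

#' Read a test-condition table
#'
#' Two-column tab-separated file (after the version line) mapping trial
#' id to condition label.  Duplicate trial ids are rejected.
#'
#' @param path Input path.
#' @return Data frame with `trial_id`, `condition`.
#' @export
read_condition_file <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  if (length(lines) == 0 ||
      strsplit(lines[[1]], "\t")[[1]][1] != COND_FORMAT_NAME) {
    parse_error(1, paste0("expected '", COND_FORMAT_NAME, "' version line"))
  }
  out <- data.frame(trial_id = character(0), condition = character(0))
  for (i in seq_along(lines)[-1]) {
    if (!nzchar(lines[[i]])) next
    tok <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(tok) != 2 || !nzchar(tok[2])) {
      parse_error(i, "condition rows need trial id and non-empty label")
    }
    if (tok[1] %in% out$trial_id) {
      stop("duplicate trial id in condition file: '", tok[1], "'",
           call. = FALSE)
    }
    out <- rbind(out, data.frame(trial_id = tok[1], condition = tok[2]))
  }
  out
}

#' Write a test-condition table
#'
#' @param table Data frame with `trial_id`, `condition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_condition_file <- function(table, path) {
  lines <- c(paste(COND_FORMAT_NAME, FORMAT_VERSION, sep = "\t"),
             paste(table$trial_id, table$condition, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Attach condition labels to trials
#'
#' @param participants List of [gaze_participant()] objects (or one).
#' @param table Condition table from [read_condition_file()].
#' @return The participants with trial conditions filled in.  Unknown
#'   trial ids in the table are rejected.
#' @export
assign_conditions <- function(participants, table) {
  single <- inherits(participants, "gaze_participant")
  if (single) participants <- list(participants)
  all_ids <- unlist(lapply(participants, function(p)
    vapply(p$trials, function(tr) tr$trial_id, character(1))))
  unknown <- setdiff(table$trial_id, all_ids)
  if (length(unknown)) {
    stop("condition table names unknown trial id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(participants)) {
    for (j in seq_along(participants[[i]]$trials)) {
      id <- participants[[i]]$trials[[j]]$trial_id
      hit <- match(id, table$trial_id)
      if (!is.na(hit)) {
        participants[[i]]$trials[[j]]$condition <- table$condition[hit]
      }
    }
  }
  if (single) participants[[1]] else participants
}

#' Export aggregated statistics as CSV
#'
#' One row per participant and condition (see [summary_statistics()]),
#' comma-separated with a `#`-prefixed format-version line, `.` decimal
#' separator regardless of locale, empty fields for undefined means.
#'
#' @param stats Data frame from [summary_statistics()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_aggregate_csv <- function(stats, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# GAZEAGG ", FORMAT_VERSION), con)
  utils::write.table(stats, con, sep = ",", dec = ".", row.names = FALSE,
                     col.names = TRUE, qmethod = "double", na = "")
  invisible(path)
}

#' Read an aggregated-statistics CSV
#'
#' @param path Path written by [export_aggregate_csv()].
#' @return Data frame.
#' @export
read_aggregate_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
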