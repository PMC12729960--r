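#' Ordinal fatigue classes
#'
#' The three fatigue states used throughout the package, in increasing order
#' of fatigue: \code{"normal"} (not fatigued), \code{"slight"} (slight
#' fatigue) and \code{"fatigued"}.
#'
#' @return Character vector of the three class names, ordered.
#' @export
fatigue_levels <- function() c("normal", "slight", "fatigued")

#' Coerce labels to the ordered fatigue factor
#'
#' @param x character, integer (0/1/2) or factor of class labels.
#' @return An ordered factor with levels \code{fatigue_levels()}.
#' @export
fatigue_factor <- function(x) {
  lev <- fatigue_levels()
  if (is.numeric(x)) x <- lev[x + 1L]
  f <- factor(as.character(x), levels = lev, ordered = TRUE)
  if (anyNA(f)) stop_fcg("unknown fatigue class label(s): %s",
                         paste(unique(setdiff(as.character(x), lev)), collapse = ", "))
  f
}

#' Session slots within a study day
#' @return Character vector \code{c("morning", "noon", "evening")}.
#' @export
session_levels <- function() c("morning", "noon", "evening")

#' Map a Borg 6-20 rating of perceived exertion to a fatigue class
#'
#' Scores up to \code{cutoffs[1]} map to \code{normal}, scores in
#' \code{(cutoffs[1], cutoffs[2]]} to \code{slight}, and higher scores to
#' \code{fatigued}. The default cutoffs (11, 14) put the boundaries at the
#' conventional "light" and "hard" RPE anchors; the mapping is monotone
#' non-decreasing in the score for every legal cutoff pair.
#'
#' @param score integer Borg rating(s), each in \code{[6, 20]}.
#' @param cutoffs integer pair \code{c(c1, c2)} with \code{6 < c1 <= c2 < 20}.
#' @return Ordered factor of fatigue classes, same length as \code{score}.
#' @examples
#' map_borg_to_class(c(6, 13, 20))
#' @export
map_borg_to_class <- function(score, cutoffs = c(11L, 14L)) {
  if (length(cutoffs) != 2L || !all(is.finite(cutoffs))) {
    stop_fcg("`cutoffs` must be two finite numbers")
  }
  if (!(6 < cutoffs[1] && cutoffs[1] <= cutoffs[2] && cutoffs[2] < 20)) {
    stop_fcg("cutoffs must satisfy 6 < c1 <= c2 < 20, got (%g, %g)",
             cutoffs[1], cutoffs[2])
  }
  if (!is.numeric(score) || anyNA(score) || any(score < 6 | score > 20)) {
    stop_fcg("Borg score(s) must lie in the Borg 6-20 range; got: %s",
             paste(score[is.na(score) | score < 6 | score > 20], collapse = ", "))
  }
  cls <- ifelse(score <= cutoffs[1], "normal",
                ifelse(score <= cutoffs[2], "slight", "fatigued"))
  fatigue_factor(cls)
}

#' Construct a single-lead ECG recording
#'
#' @param samples numeric vector of voltages (mV); must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param subject_id subject identifier.
#' @param day study day (integer >= 1).
#' @param session one of \code{session_levels()}.
#' @param borg_score optional Borg 6-20 rating for the session.
#' @return An object of class \code{ecg_record} with derived field
#'   \code{duration_s = length(samples) / fs}.
#' @export
ecg_record <- function(samples, fs, subject_id = "s1", day = 1L,
                       session = "morning", borg_score = NULL) {
  check_number(fs, "fs", lower = .Machine$double.eps)
  if (!is.numeric(samples)) stop_fcg("`samples` must be numeric")
  bad <- which(!is.finite(samples))
  if (length(bad)) {
    stop_fcg("non-finite sample at index %d (of %d)", bad[1], length(samples))
  }
  check_number(day, "day", lower = 1)
  session <- match.arg(session, session_levels())
  if (!is.null(borg_score)) {
    check_number(borg_score, "borg_score", lower = 6, upper = 20)
  }
  structure(list(samples = as.numeric(samples), fs = fs,
                 subject_id = as.character(subject_id), day = as.integer(day),
                 session = session, borg_score = borg_score,
                 duration_s = length(samples) / fs),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> subject %s day %d %s: %.1f s @ %g Hz%s\n",
              x$subject_id, x$day, x$session, x$duration_s, x$fs,
              if (is.null(x$borg_score)) "" else sprintf(", Borg %g", x$borg_score)))
  invisible(x)
}

#' Construct a labelled fixed-duration ECG segment
#'
#' @param samples numeric voltages (mV).
#' @param fs sampling rate (Hz).
#' @param label fatigue class (see \code{\link{fatigue_factor}}).
#' @param subject_id,day,session,segment_index provenance of the window.
#' @return Object of class \code{ecg_segment}.
#' @export
ecg_segment <- function(samples, fs, label, subject_id = "s1", day = 1L,
                        session = "morning", segment_index = 0L) {
  check_number(fs, "fs", lower = .Machine$double.eps)
  if (segment_index < 0) stop_fcg("segment_index must be >= 0")
  structure(list(samples = as.numeric(samples), fs = fs,
                 duration_s = length(samples) / fs,
                 label = fatigue_factor(label),
                 subject_id = as.character(subject_id), day = as.integer(day),
                 session = session, segment_index = as.integer(segment_index)),
            class = "ecg_segment")
}

#' @export
print.ecg_segment <- function(x, ...) {
  cat(sprintf("<ecg_segment> %s/d%d/%s #%d: %.1f s @ %g Hz, label %s\n",
              x$subject_id, x$day, x$session, x$segment_index, x$duration_s,
              x$fs, as.character(x$label)))
  invisible(x)
}

#' Write an ECG record as a plain-text CSV sample file
#'
#' The dialect is a one-line header \code{fs=<Hz>} followed by one voltage
#' (mV) per line; trivially diffable and read back bit-exactly by
#' \code{\link{read_ecg}}.
#'
#' @param record an \code{ecg_record}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_ecg <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fs=%s", format(record$fs, digits = 17)), con)
  writeLines(format(record$samples, digits = 17, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

#' Read a single-lead ECG sample file
#'
#' @param path file to read. For \code{format = "csv"}, a header line
#'   \code{fs=<Hz>} followed by one mV value per line. For
#'   \code{format = "wfdb"}, \code{path} is the header (\code{.hea}) file of a
#'   single-signal WFDB-compatible record stored as 16-bit little-endian
#'   integers (format 16) with gain and baseline applied on read.
#' @param format file format.
#' @param ... metadata (\code{subject_id}, \code{day}, \code{session},
#'   \code{borg_score}) forwarded to \code{\link{ecg_record}}.
#' @return An \code{ecg_record}.
#' @export
read_ecg <- function(path, format = c("csv", "wfdb"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fcg("file not found: %s", path)
  if (format == "csv") {
    lines <- readLines(path)
    if (!length(lines) || !grepl("^fs=", lines[1])) {
      stop_fcg("missing `fs=<Hz>` header in %s", path)
    }
    fs <- suppressWarnings(as.numeric(sub("^fs=", "", lines[1])))
    if (!isTRUE(is.finite(fs)) || fs <= 0) stop_fcg("invalid sampling rate in %s", path)
    body <- lines[-1]
    body <- body[nzchar(body)]
    samples <- suppressWarnings(as.numeric(body))
    bad <- which(!is.finite(samples))
    if (length(bad)) {
      stop_fcg("non-finite sample at row %d of %s", bad[1] + 1L, path)
    }
    ecg_record(samples, fs, ...)
  } else {
    read_wfdb_record(path, ...)
  }
}

# Minimal WFDB interoperability: single signal, format 16 (int16 LE),
# header "<name> 1 <fs> <n>" then "<file> 16 <gain>(<baseline>)/mV ...".
read_wfdb_record <- function(hea_path, ...) {
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 4) stop_fcg("malformed WFDB header %s", hea_path)
  fs <- as.numeric(hdr[3]); n <- as.integer(hdr[4])
  if (!isTRUE(is.finite(fs)) || fs <= 0) stop_fcg("missing sampling rate in %s", hea_path)
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  dat_file <- file.path(dirname(hea_path), sig[1])
  if (sig[2] != "16") stop_fcg("only WFDB format 16 supported, got %s", sig[2])
  gain_spec <- sig[3]
  baseline <- 0
  if (grepl("\\(", gain_spec)) {
    baseline <- as.numeric(sub(".*\\(([-0-9.]+)\\).*", "\\1", gain_spec))
  }
  gain <- as.numeric(sub("[(/].*$", "", gain_spec))
  if (!isTRUE(is.finite(gain)) || gain == 0) gain <- 200  # WFDB default adu/mV
  raw <- readBin(dat_file, what = "integer", size = 2L, n = n, endian = "little")
  ecg_record((raw - baseline) / gain, fs, ...)
}

#' Write a single-signal WFDB-compatible record (format 16)
#'
#' @param record an \code{ecg_record}.
#' @param record_name base name (without extension); files
#'   \code{<name>.hea} and \code{<name>.dat} are written in \code{dir}.
#' @param dir output directory.
#' @param gain analogue-to-digital units per mV (default 200).
#' @return Path of the header file, invisibly.
#' @export
write_wfdb <- function(record, record_name, dir = ".", gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  hea <- file.path(dir, paste0(record_name, ".hea"))
  dat <- paste0(record_name, ".dat")
  adu <- as.integer(round(record$samples * gain))
  if (any(abs(adu) > 32767)) stop_fcg("signal exceeds int16 range at gain %g", gain)
  writeLines(c(sprintf("%s 1 %g %d", record_name, record$fs, length(adu)),
               sprintf("%s 16 %g(0)/mV 16 0 %d 0 0 ECG", dat, gain,
                       if (length(adu)) adu[1] else 0L)),
             hea)
  writeBin(adu, file.path(dir, dat), size = 2L, endian = "little")
  invisible(hea)
}

#' Load a study manifest
#'
#' A manifest is a CSV with columns \code{subject_id}, \code{day},
#' \code{session}, \code{borg} and \code{path} (path of the session's ECG
#' sample file, relative to the manifest location unless absolute). One row
#' per recording session; \code{(subject_id, day, session)} must be unique.
#'
#' @param path manifest CSV path.
#' @param cutoffs Borg-to-class cutoffs used to validate scores and derive
#'   the \code{label} column (see \code{\link{map_borg_to_class}}).
#' @return A \code{data.frame} of class \code{study_manifest} with an added
#'   ordered-factor column \code{label}.
#' @export
load_manifest <- function(path, cutoffs = c(11L, 14L)) {
  if (!file.exists(path)) stop_fcg("manifest not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("empty manifest: ", path)
    return(as_manifest(data.frame(subject_id = character(), day = integer(),
                                  session = character(), borg = integer(),
                                  path = character())))
  }
  req <- c("subject_id", "day", "session", "borg", "path")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_fcg("manifest missing column(s): %s", paste(miss, collapse = ", "))
  as_manifest(df, cutoffs = cutoffs, base_dir = dirname(path))
}

as_manifest <- function(df, cutoffs = c(11L, 14L), base_dir = NULL) {
  if (nrow(df)) {
    key <- paste(df$subject_id, df$day, df$session, sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) {
      stop_fcg("duplicate (subject, day, session) key: (%s, %s, %s)",
               df$subject_id[dup][1], df$day[dup][1], df$session[dup][1])
    }
    bad <- !df$session %in% session_levels()
    if (any(bad)) stop_fcg("unknown session label: %s", df$session[bad][1])
    df$label <- map_borg_to_class(df$borg, cutoffs)
    if (!is.null(base_dir) && !is.null(df$path)) {
      rel <- !grepl("^(/|[A-Za-z]:)", df$path)
      df$path[rel] <- file.path(base_dir, df$path[rel])
    }
  } else if (!"label" %in% names(df)) {
    df$label <- fatigue_factor(character())
  }
  class(df) <- c("study_manifest", "data.frame")
  df
}

#' Write a study manifest CSV
#' @param manifest a \code{study_manifest} (or data frame with its columns).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  keep <- intersect(c("subject_id", "day", "session", "borg", "path"),
                    names(manifest))
  utils::write.csv(as.data.frame(manifest)[, keep, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a manifest's integrity
#'
#' Checks key uniqueness, Borg-score range and that every referenced sample
#' file resolves.
#'
#' @param manifest a \code{study_manifest}.
#' @return \code{TRUE} invisibly on success; otherwise an error.
#' @export
validate_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "study_manifest"))
  if (nrow(manifest) && !is.null(manifest$path)) {
    missing <- manifest$path[!file.exists(manifest$path) & nzchar(manifest$path)]
    if (length(missing)) stop_fcg("unresolvable file(s): %s",
                                  paste(utils::head(missing, 3), collapse = ", "))
  }
  invisible(TRUE)
}
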