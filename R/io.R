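SESSIONS_SCHEMA <- "tabvis-sessions-v1"
SESSION_KEY <- c("participant_id", "test", "run_index", "trial_index")
SESSION_COLS <- c(SESSION_KEY,
                  "level_d", "correct", "threshold_estimate_d",
                  "loc", "col", "row", "ecc_deg", "rt_s", "seed")

#' Assemble one long session table from a cohort
#'
#' Binds the face (trial-level) and search (location-level) session records
#' into a single long table keyed by (participant_id, test, run_index,
#' trial_index); payload columns that do not apply to a test are NA.
#'
#' @param cohort a \code{tabvis_cohort}.
#' @return a data.frame with the canonical session column set.
#' @export
session_table <- function(cohort) {
  if (!inherits(cohort, "tabvis_cohort"))
    stop("'cohort' must be a tabvis_cohort", call. = FALSE)
  pad <- function(df) {
    for (cc in setdiff(SESSION_COLS, names(df))) df[[cc]] <- NA
    df[, SESSION_COLS]
  }
  out <- rbind(pad(cohort$face_sessions), pad(cohort$search_sessions))
  rownames(out) <- NULL
  out
}

#' Write / read session tables
#'
#' CSV with a schema-version header line (\code{# tabvis-sessions-v1}) so
#' files written by other tools or versions fail loudly instead of parsing
#' into silently wrong columns. Reading validates the header, the column
#' set, and the uniqueness of the (participant, test, run, trial) key, and
#' refuses empty tables.
#'
#' @param table session data.frame (from \code{\link{session_table}} or the
#'   same schema).
#' @param path file path.
#' @return \code{read_sessions} returns the validated data.frame;
#'   \code{write_sessions} invisibly returns \code{path}.
#' @export
write_sessions <- function(table, path) {
  missing <- setdiff(SESSION_COLS, names(table))
  if (length(missing))
    stop("session table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", SESSIONS_SCHEMA), con)
  utils::write.csv(table[, SESSION_COLS], con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  if (!identical(trimws(sub("^#", "", first)), SESSIONS_SCHEMA))
    stop("not a tabvis session file (missing '# ", SESSIONS_SCHEMA,
         "' header): ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    stop("session file contains no rows: ", path, call. = FALSE)
  missing <- setdiff(SESSION_COLS, names(df))
  if (length(missing))
    stop("session file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  key <- do.call(paste, c(df[SESSION_KEY], sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate session keys at rows: ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  bad_run <- !df$run_index %in% c(1, 2)
  if (any(bad_run))
    stop("run_index outside {1, 2} at rows: ",
         paste(utils::head(which(bad_run), 10), collapse = ", "),
         call. = FALSE)
  bad_test <- !df$test %in% c("faces", "search")
  if (any(bad_test))
    stop("unknown test label at rows: ",
         paste(utils::head(which(bad_test), 10), collapse = ", "),
         call. = FALSE)
  df
}

PARTICIPANT_ROLES <- c("participant_id",
                       "faces_run1", "faces_run2",
                       "search_run1", "search_run2",
                       "acuity_logmar", "contrast_logcs", "digit_span",
                       "usability_faces", "usability_search")

#' Read a participant summary table with a column-role mapping
#'
#' Participant tables in the wild (including supplementary data files
#' distributed with studies) use arbitrary headers, so the reader takes an
#' explicit mapping from the roles the pipeline needs to the file's actual
#' column names. Values are validated: usability ratings must lie in
#' [0, 10], thresholds and RTs must be positive where present. Face scores
#' may be missing for participants who only performed the search test.
#'
#' @param path CSV file path.
#' @param column_map named character vector or list mapping each role in
#'   \code{PARTICIPANT_ROLES} to a column name in the file, or the path to
#'   a YAML file holding that mapping.
#' @return a data.frame with the canonical role names as columns.
#' @export
read_participants <- function(path, column_map) {
  if (is.character(column_map) && length(column_map) == 1L &&
      file.exists(column_map))
    column_map <- yaml::read_yaml(column_map)
  column_map <- unlist(column_map)
  missing_roles <- setdiff(PARTICIPANT_ROLES, names(column_map))
  if (length(missing_roles))
    stop("column_map lacks required roles: ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing_cols <- setdiff(unname(column_map[PARTICIPANT_ROLES]), names(df))
  if (length(missing_cols))
    stop("file lacks mapped columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- stats::setNames(df[, unname(column_map[PARTICIPANT_ROLES])],
                         PARTICIPANT_ROLES)
  for (role in c("usability_faces", "usability_search")) {
    v <- out[[role]]
    if (any(is.finite(v) & (v < 0 | v > 10)))
      stop("role '", role, "' has ratings outside [0, 10]", call. = FALSE)
  }
  for (role in c("faces_run1", "faces_run2", "search_run1", "search_run2")) {
    v <- out[[role]]
    if (any(is.finite(v) & v <= 0))
      stop("role '", role, "' has non-positive scores", call. = FALSE)
  }
  if (anyDuplicated(out$participant_id))
    stop("duplicate participant_id values", call. = FALSE)
  out
}

#' Generate the bundled worked-example fixtures
#'
#' Writes a deterministic small synthetic cohort (50 search participants,
#' 30 of whom also have face data, mirroring the asymmetric study design),
#' two toy landmark faces, the column-role map, and an expected-output JSON
#' containing key pipeline statistics recomputed from the fixtures, for use
#' in regression tests. Running twice with the same seed reproduces the
#' directory byte-for-byte.
#'
#' @param dir output directory (created if needed).
#' @param seed master integer seed.
#' @param n_search,n_faces cohort sizes.
#' @return invisibly, the list of files written.
#' @export
make_fixtures <- function(dir = tempfile("tabvis-fixtures-"), seed = 1,
                          n_search = 50, n_faces = 30) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  coh <- generate_cohort(n_search = n_search, n_faces = n_faces, seed = seed)

  files <- c(sessions = file.path(dir, "sessions.csv"),
             participants = file.path(dir, "participants.csv"),
             column_map = file.path(dir, "column_map.yaml"),
             face_a = file.path(dir, "synthetic_face_a.txt"),
             face_b = file.path(dir, "synthetic_face_b.txt"),
             expected = file.path(dir, "expected.json"))

  write_sessions(session_table(coh), files["sessions"])
  con <- file(files["participants"], "w")
  writeLines("# synthetic participant table (tabvis fixture)", con)
  utils::write.csv(format(coh$participants, digits = 15, trim = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  close(con)
  writeLines(yaml::as.yaml(as.list(stats::setNames(PARTICIPANT_ROLES,
                                                   PARTICIPANT_ROLES))),
             files["column_map"])

  faces <- with_seed(derive_seed(seed, 99), {
    a <- landmark_face(matrix(stats::rnorm(254, sd = 10), ncol = 2),
                       id = "synthetic_face_a")
    b <- morph_face(a, landmark_face(matrix(0, 127, 2), id = "origin"), 5)
    list(a = a, b = b)
  })
  write_landmarks(faces$a, files["face_a"])
  write_landmarks(faces$b, files["face_b"])

  p <- coh$participants
  ok <- is.finite(p$faces_run1)
  expected <- list(
    faces_cor95 = bland_altman(p$faces_run1[ok], p$faces_run2[ok],
                               ci = FALSE)$cor95,
    search_cor95 = bland_altman(p$search_run1, p$search_run2,
                                ci = FALSE)$cor95,
    faces_cutoff99 = fit_normative(
      suppressWarnings(combine_runs(p$faces_run1[ok], p$faces_run2[ok])),
      "gaussian")$cutoff99,
    search_cutoff99 = fit_normative(
      suppressWarnings(combine_runs(p$search_run1, p$search_run2)),
      "gamma")$cutoff99,
    usability_faces_mean = mean(p$usability_faces),
    n_search = nrow(p), n_faces = sum(ok))
  jsonlite::write_json(expected, files["expected"], auto_unbox = TRUE,
                       digits = NA)
  invisible(files)
}
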