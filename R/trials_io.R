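#' Trial-log sessions
#'
#' A session set is a tibble of trial records — one row per encounter with a
#' reward site — shared by the drift-diffusion simulator, the hazard-model
#' session generator, and any externally recorded data mapped into the same
#' schema. Columns, in canonical order:
#'
#' * `subject_id`, `session_id`, `site_id` — character identifiers.
#' * `offer_s` — offered delay in integer seconds (within the offer support,
#'   by default 1--30).
#' * `accepted` — logical; did the subject enter the wait zone?
#' * `time_spent_s` — integer seconds spent in the wait zone (0 for skips,
#'   the quit time for quits, the full offer for earns).
#' * `outcome` — `"skip"`, `"quit"` or `"earn"`.
#' * `w0` — initial willingness to wait (simulation-origin data only; `NA`
#'   otherwise).
#'
#' Record invariants: a skip has `accepted = FALSE` and `time_spent_s = 0`;
#' an earn has `time_spent_s = offer_s`; a quit has
#' `1 <= time_spent_s <= offer_s - 1` (the countdown never completes).
#'
#' @param trials A data frame with the columns above (`w0` optional).
#' @param meta Named list of provenance metadata (generator name, seed,
#'   configuration echo). Stored as the `"meta"` attribute and written to a
#'   JSON sidecar by [write_trials_csv()]. Should contain `offer_support`
#'   (integer vector) when the support differs from 1--30.
#' @param validate Stop on invariant violations? Default `TRUE`.
#' @return A `session_set`: a tibble with class `"session_set"` and a
#'   `"meta"` attribute.
#' @seealso [read_trials_csv()], [write_trials_csv()], [validate_trials()]
#' @export
session_set <- function(trials, meta = list(), validate = TRUE) {
  trials <- tibble::as_tibble(trials)
  required <- c("subject_id", "session_id", "site_id", "offer_s",
                "accepted", "time_spent_s", "outcome")
  missing <- setdiff(required, names(trials))
  if (length(missing)) {
    stop("session_set: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"w0" %in% names(trials)) trials$w0 <- NA_real_
  trials <- trials[, c(required, "w0")]
  for (col in c("subject_id", "session_id", "site_id", "outcome")) {
    trials[[col]] <- as.character(trials[[col]])
  }
  trials$accepted <- as.logical(trials$accepted)
  trials$offer_s <- floor_seconds(trials$offer_s, "offer_s")
  trials$time_spent_s <- floor_seconds(trials$time_spent_s, "time_spent_s")
  trials$w0 <- as.numeric(trials$w0)
  if (is.null(meta$offer_support)) meta$offer_support <- 1:30
  x <- structure(trials, meta = meta,
                 class = c("session_set", class(trials)))
  if (validate) {
    v <- validate_trials(x)
    if (nrow(v)) {
      stop("session_set: ", nrow(v), " invariant violation(s); first: row ",
           v$row[1], ": ", v$message[1], call. = FALSE)
    }
  }
  x
}

# Times are handled on a 1 s grid; real-valued inputs are floored (warned once).
floor_seconds <- function(x, what) {
  x <- as.numeric(x)
  if (any(x %% 1 != 0, na.rm = TRUE)) {
    warning("non-integer ", what, " floored to whole seconds", call. = FALSE)
    x <- floor(x)
  }
  as.integer(x)
}

#' Session metadata
#'
#' @param x A `session_set`.
#' @return The provenance metadata list.
#' @export
session_meta <- function(x) attr(x, "meta", exact = TRUE)

#' Validate trial records
#'
#' Checks every record of a session set against the trial invariants (see
#' [session_set()]) and the configured offer support. Violations are returned
#' as data, not raised.
#'
#' @param data A `session_set` or compatible data frame.
#' @return A tibble with columns `row`, `field`, `message`; zero rows when
#'   every invariant holds.
#' @export
validate_trials <- function(data) {
  meta <- attr(data, "meta", exact = TRUE)
  support <- if (!is.null(meta$offer_support)) meta$offer_support else 1:30
  res <- list()
  bad <- function(rows, field, message) {
    if (length(rows)) {
      res[[length(res) + 1]] <<- tibble::tibble(row = rows, field = field,
                                                message = message)
    }
  }
  off <- data$offer_s
  acc <- data$accepted
  spent <- data$time_spent_s
  out <- data$outcome
  bad(which(!out %in% c("skip", "quit", "earn")), "outcome",
      "outcome must be one of skip, quit, earn")
  bad(which(!off %in% support), "offer_s", "offer outside the offer support")
  bad(which(is.na(acc)), "accepted", "accepted must be TRUE or FALSE")
  bad(which((out == "skip") != (!acc %in% TRUE)), "accepted",
      "outcome is skip if and only if the offer was not accepted")
  bad(which(out == "skip" & spent != 0L), "time_spent_s",
      "a skipped offer has no time spent")
  bad(which(out == "earn" & spent != off), "time_spent_s",
      "an earned offer has time spent equal to the offer")
  bad(which(out == "quit" & (spent < 1L | spent > off - 1L)), "time_spent_s",
      "a quit happens strictly inside the countdown (1..offer-1)")
  if (length(res) == 0) {
    return(tibble::tibble(row = integer(), field = character(),
                          message = character()))
  }
  v <- do.call(rbind, res)
  v[order(v$row), ]
}

trial_columns <- c("subject_id", "session_id", "site_id", "offer_s",
                   "accepted", "time_spent_s", "outcome", "w0")

#' Read a trial-log CSV
#'
#' Reads the RFC-4180 trial-log schema written by [write_trials_csv()]
#' (header required; columns `subject_id, session_id, site_id, offer_s,
#' accepted, time_spent_s, outcome, w0`, with `accepted` coded 0/1 and `w0`
#' blank when absent). If a JSON sidecar `<path>.meta.json` exists its
#' contents become the session metadata.
#'
#' @param path CSV file path.
#' @param validate Stop on invariant violations (with the offending row
#'   number)? Default `TRUE`.
#' @return A [session_set()].
#' @export
read_trials_csv <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "", colClasses = "character")
  missing <- setdiff(setdiff(trial_columns, "w0"), names(df))
  if (length(missing)) {
    stop("trial-log schema error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta <- list()
  sidecar <- meta_sidecar_path(path)
  if (file.exists(sidecar)) {
    all_meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    key <- basename(path)
    meta <- if (!is.null(all_meta[[key]])) all_meta[[key]] else all_meta
    if (!is.null(meta$offer_support)) {
      meta$offer_support <- as.integer(meta$offer_support)
    }
  }
  if (nrow(df) == 0) {
    empty <- tibble::tibble(subject_id = character(), session_id = character(),
                            site_id = character(), offer_s = integer(),
                            accepted = logical(), time_spent_s = integer(),
                            outcome = character(), w0 = numeric())
    return(session_set(empty, meta = meta, validate = FALSE))
  }
  df$offer_s <- as.numeric(df$offer_s)
  df$accepted <- as.numeric(df$accepted) != 0
  df$time_spent_s <- as.numeric(df$time_spent_s)
  df$w0 <- if ("w0" %in% names(df)) as.numeric(df$w0) else NA_real_
  x <- session_set(df, meta = meta, validate = FALSE)
  if (validate) {
    v <- validate_trials(x)
    if (nrow(v)) {
      stop("trial-log validation error at row ", v$row[1], " (", v$field[1],
           "): ", v$message[1],
           if (nrow(v) > 1) paste0(" [and ", nrow(v) - 1, " more]") else "",
           call. = FALSE)
    }
  }
  x
}

meta_sidecar_path <- function(path) paste0(path, ".meta.json")

#' Write a trial-log CSV
#'
#' Writes the canonical schema (see [read_trials_csv()]); `accepted` is coded
#' 0/1 and absent `w0` values are written as empty cells. Session metadata is
#' written to a JSON sidecar `<path>.meta.json`, keyed by the file name, so
#' that `read_trials_csv(write_trials_csv(x))` reproduces `x` field for field.
#'
#' @param data A [session_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(data, path) {
  df <- as.data.frame(data)[, trial_columns]
  df$accepted <- as.integer(df$accepted)
  # full double precision so read(write(x)) reproduces w0 bit for bit
  df$w0 <- ifelse(is.na(df$w0), NA_character_, sprintf("%.17g", df$w0))
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  meta <- session_meta(data)
  if (!is.null(meta) && length(meta)) {
    payload <- stats::setNames(list(meta), basename(path))
    jsonlite::write_json(payload, meta_sidecar_path(path),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
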