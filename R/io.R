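#' Validate a data frame of physiological records
#'
#' Checks the physiological invariants row by row: the eight parameters
#' present and finite, `spo2 <= 100`, `gsr >= 0`, `sbp > dbp`, positive
#' glucose where present. Violations are reported with the field name and
#' the (1-based) record number.
#'
#' @param records Data frame of records.
#' @return The records, invisibly, if valid; otherwise an error naming
#'   every offending field and record.
#' @export
validate_records <- function(records) {
  if (!is.data.frame(records)) stop("records must be a data frame")
  if (nrow(records) == 0) {
    warning("empty record set")
    return(invisible(records))
  }
  miss <- setdiff(physio_params(), names(records))
  if (length(miss))
    stop("schema violation: missing column(s): ", paste(miss, collapse = ", "))
  problems <- character(0)
  flag <- function(bad, msg) {
    if (any(bad, na.rm = TRUE))
      problems <<- c(problems, paste0(msg, " at record(s) ",
                                      paste(utils::head(which(bad), 5), collapse = ", ")))
  }
  for (p in physio_params())
    flag(!is.finite(records[[p]]), paste0("non-finite '", p, "'"))
  flag(records$spo2 > 100, "'spo2' above 100")
  flag(records$gsr < 0, "negative 'gsr'")
  flag(records$sbp <= records$dbp, "'sbp' not greater than 'dbp'")
  if (!is.null(records$glucose))
    flag(records$glucose <= 0, "non-positive 'glucose'")
  if (length(problems))
    stop("invalid record(s): ", paste(problems, collapse = "; "))
  invisible(records)
}

infer_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("jsonl", "csv")))
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl"
  else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
  else stop("cannot infer format from '", path, "'; pass format explicitly")
}

#' Write physiological records to CSV or JSON-lines
#'
#' JSON-lines (one object per line) is the canonical interchange format;
#' CSV is a flattened convenience view. Writing then reading returns the
#' same values.
#'
#' @param records Data frame of records (validated before writing).
#' @param path Output file; the extension picks the format unless `format`
#'   is given.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = NULL) {
  format <- infer_format(path, format)
  validate_records(records)
  df <- records
  for (j in seq_along(df)) if (is.factor(df[[j]])) df[[j]] <- as.character(df[[j]])
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(df)))
      writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA, na = "null"),
                 con)
  }
  invisible(path)
}

#' Read physiological records from CSV or JSON-lines
#'
#' @param path Input file.
#' @param format `"jsonl"` or `"csv"`; inferred from the extension when
#'   omitted.
#' @param validate Check the physiological invariants after reading
#'   (default `TRUE`); parse or validation failures report line numbers.
#' @return Data frame of records (empty, with a warning, for an empty file).
#' @export
read_records <- function(path, format = NULL, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- infer_format(path, format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      warning("empty record file: ", path)
      return(data.frame())
    }
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e)
        stop("parse error at line ", i, " of ", path, ": ",
             conditionMessage(e), call. = FALSE))
      rec[vapply(rec, is.null, logical(1))] <- NA
      rows[[i]] <- as.data.frame(rec, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
  }
  if (nrow(df) == 0) {
    warning("empty record file: ", path)
    return(df)
  }
  if (validate) {
    tryCatch(validate_records(df), error = function(e)
      stop(conditionMessage(e), " [file ", path, "]", call. = FALSE))
  }
  df
}

#' Default configuration tree
#'
#' The full configuration of the toolchain as a nested list with sections
#' `ranges` (the reference-range table), `engine` (see [engine_config()]),
#' `cohort` (see [cohort_spec()]) and `ppg` (SpO2 calibration line). This is
#' what `fuzzphys config --show` prints and what [read_config()] merges
#' user YAML files over.
#'
#' @return Nested list.
#' @export
default_config <- function() {
  eng <- engine_config()
  coh <- cohort_spec()
  list(
    ranges = reference_ranges(),
    engine = list(tnorm = eng$tnorm,
                  transition_fraction = eng$transition_fraction,
                  degenerate_policy = eng$degenerate_policy,
                  t_low = eng$t_low, t_high = eng$t_high),
    cohort = unclass(coh),
    ppg = list(calibration = c(110, -25), fs = 300,
               window = 8, hop = 0.5)
  )
}

#' Read a YAML configuration file
#'
#' Values present in the file override the defaults section-wise; anything
#' omitted keeps its default.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Nested configuration list (see [default_config()]).
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (sect in intersect(names(user), names(cfg))) {
    if (sect == "ranges") {
      cfg$ranges <- as.data.frame(user$ranges, stringsAsFactors = FALSE)
      validate_ranges(cfg$ranges)
    } else {
      cfg[[sect]] <- utils::modifyList(cfg[[sect]], user[[sect]])
    }
  }
  cfg
}

config_to_objects <- function(cfg) {
  eng <- do.call(engine_config, cfg$engine)
  ranges <- cfg$ranges
  list(engine = eng,
       fis = stress_fis(ranges, eng),
       cohort = do.call(cohort_spec,
                        cfg$cohort[setdiff(names(cfg$cohort), character(0))]),
       ppg = cfg$ppg)
}
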