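record_schema <- function() {
  list(
    integer = c("user_id", "day", "slot", "available", "considered", "push",
                "outcome_24h", "week_in_study", "which_day",
                "pushed_indicator", "has_charted_10"),
    numeric = c("prob", "sel_prob", "days_since_chart", "push_success_ratio"))
}

record_columns <- function() {
  c("user_id", "day", "slot", "available", "considered", "prob", "sel_prob",
    "push", "outcome_24h", "week_in_study", "which_day", "days_since_chart",
    "pushed_indicator", "push_success_ratio", "has_charted_10")
}

#' Validate a decision-record table
#'
#' Checks the declared schema (exact column set) and the row-level
#' invariants: binary flags are 0/1, `considered == 1` implies
#' `available == 1`, `push == 1` implies `considered == 1`, the
#' randomization probability lies strictly in (0, 1) exactly on
#' considered rows, `push_success_ratio` lies in [0, 1] and is 0
#' whenever `pushed_indicator` is 0, and each user-day has at most one
#' considered slot.  Every violation is reported, with the offending
#' row and column named.
#'
#' @param records A decision-record `data.frame`.
#' @return `records`, invisibly, if valid; otherwise an error listing
#'   all violations.
#' @export
validate_records <- function(records) {
  sch <- record_schema()
  cols <- record_columns()
  miss <- setdiff(cols, names(records))
  extra <- setdiff(names(records), cols)
  if (length(miss) || length(extra))
    stop("schema error: ",
         if (length(miss)) paste("missing columns:",
                                 paste(miss, collapse = ", ")),
         if (length(miss) && length(extra)) "; ",
         if (length(extra)) paste("unexpected columns:",
                                  paste(extra, collapse = ", ")),
         call. = FALSE)

  bad <- character(0)
  note <- function(rows, col, what) {
    if (any(rows)) sprintf("rows %s, column `%s`: %s",
                           paste(utils::head(which(rows), 5), collapse = ","),
                           col, what)
  }
  for (v in c("available", "considered", "push", "outcome_24h",
              "pushed_indicator", "has_charted_10", "which_day"))
    bad <- c(bad, note(!records[[v]] %in% c(0L, 1L), v, "not 0/1"))
  bad <- c(bad, note(records$considered == 1L & records$available != 1L,
                     "considered", "considered but not available"))
  bad <- c(bad, note(records$push == 1L & records$considered != 1L,
                     "push", "pushed but not considered"))
  p <- records$prob
  bad <- c(bad, note(records$considered == 1L &
                       (is.na(p) | p <= 0 | p >= 1),
                     "prob", "considered row without prob in (0,1)"))
  bad <- c(bad, note(records$considered == 0L & !is.na(p),
                     "prob", "prob set on a non-considered row"))
  psr <- records$push_success_ratio
  bad <- c(bad, note(psr < 0 | psr > 1, "push_success_ratio", "outside [0,1]"))
  bad <- c(bad, note(records$pushed_indicator == 0L & psr != 0,
                     "push_success_ratio", "nonzero without any past push"))
  per_day <- tapply(records$considered, paste(records$user_id, records$day), sum)
  if (any(per_day > 1L))
    bad <- c(bad, sprintf("user-days with more than one considered slot: %s",
                          paste(utils::head(names(per_day)[per_day > 1L], 5),
                                collapse = "; ")))
  bad <- bad[!vapply(bad, is.null, logical(1))]
  if (length(bad))
    stop(paste(c("invalid decision records:",
                 paste0("  - ", unlist(bad))), collapse = "\n"), call. = FALSE)
  invisible(records)
}

#' Trial-wide design-rule checks on a record table
#'
#' Asserts the design rules that span rows: at most one considered slot
#' per user-day, considered decisions of the same user at least the
#' minimum bucket wait (2 days by default) apart, no considered slot
#' before noon on weekends when the weekend-morning exclusion is on,
#' and row-level validity via [validate_records()].
#'
#' @param records A decision-record `data.frame`.
#' @param config The [trial_config()] that generated it.
#' @return `TRUE`, invisibly; errors on the first violated rule.
#' @export
check_design_invariants <- function(records, config = trial_config()) {
  validate_records(records)
  cons <- records[records$considered == 1L, ]
  gaps <- unlist(tapply(cons$day, cons$user_id,
                        function(d) diff(sort(d))), use.names = FALSE)
  min_wait <- min(config$rules$wait_days)
  if (length(gaps) && any(gaps < min_wait))
    stop("considered decisions closer than the minimum wait of ",
         min_wait, " days", call. = FALSE)
  if (config$weekend_morning_blocked) {
    wknd <- is_weekend_day(config, cons$day)
    closed <- config$slot_minutes[cons$slot] < 12 * 60
    if (any(wknd & closed))
      stop("considered decision in a blocked weekend-morning slot",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Read / write decision-record CSV files
#'
#' The interchange format is a single long-format CSV (comma separator,
#' UTF-8, `.` decimal, header required) with one row per user x day x
#' slot.  `prob` and `sel_prob` are empty on rows where they are not
#' defined.  Numeric columns are written with 17 significant digits so
#' a write/read round trip reproduces the table exactly.
#'
#' @param path File path.
#' @param records A validated decision-record `data.frame`.
#' @return `read_records()` returns the validated `data.frame`;
#'   `write_records()` returns `path` invisibly.
#' @export
read_records <- function(path) {
  sch <- record_schema()
  first <- utils::read.csv(path, nrows = 1, check.names = FALSE)
  classes <- stats::setNames(rep("character", ncol(first)), names(first))
  classes[names(first) %in% sch$integer] <- "integer"
  classes[names(first) %in% sch$numeric] <- "numeric"
  df <- utils::read.csv(path, colClasses = unname(classes),
                        check.names = FALSE, na.strings = "")
  validate_records(df)
  df
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  validate_records(records)
  out <- records
  for (v in record_schema()$numeric) {
    x <- formatC(out[[v]], digits = 17, format = "g")
    x[is.na(out[[v]])] <- ""
    out[[v]] <- trimws(x)
  }
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Load a study configuration file
#'
#' Reads a YAML configuration with up to four top-level sections --
#' `trial`, `cohort`, `outcome`, `model` -- each mirroring the fields of
#' the corresponding constructor ([trial_config()], [cohort_config()],
#' [outcome_params()], [model_spec()]).  Every default is overridable;
#' an empty (or absent-section) file yields the full default
#' configuration.  Unknown keys are an error, and all validation
#' failures are reported together.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `trial`, `cohort`, `outcome`, `model`.
#' @export
load_config <- function(path) {
  if (!is.character(path) || !nzchar(path) || !file.exists(path))
    stop("configuration file not found: '", path, "'", call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("trial", "cohort", "outcome", "model")
  unknown <- setdiff(names(raw), known)
  problems <- character(0)
  if (length(unknown))
    problems <- c(problems, paste("unknown top-level keys:",
                                  paste(unknown, collapse = ", ")))

  build <- function(section, fn, rename = list()) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    allowed <- names(formals(fn))
    bad <- setdiff(names(args), c(allowed, names(rename)))
    if (length(bad)) {
      problems <<- c(problems, paste0("unknown keys in `", section, "`: ",
                                      paste(bad, collapse = ", ")))
      return(NULL)
    }
    for (k in names(rename)) if (!is.null(args[[k]])) {
      args[[rename[[k]]]] <- args[[k]]; args[[k]] <- NULL
    }
    tryCatch(do.call(fn, lapply(args, unlist)),
             error = function(e) {
               problems <<- c(problems, paste0("`", section, "`: ",
                                               conditionMessage(e)))
               NULL
             })
  }

  trial_args <- raw$trial
  rules <- NULL
  if (!is.null(trial_args$rules)) {
    rules <- tryCatch(
      availability_rules(breaks = unlist(trial_args$rules$breaks),
                         wait_days = unlist(trial_args$rules$wait_days)),
      error = function(e) {
        problems <<- c(problems, paste0("`trial$rules`: ",
                                        conditionMessage(e)))
        NULL
      })
    raw$trial$rules <- NULL
  }
  trial <- build("trial", trial_config)
  if (!is.null(trial) && !is.null(rules))
    trial <- trial_config(n_days = trial$n_days,
                          slot_times = trial$slot_times,
                          randomization_prob = trial$randomization_prob,
                          rules = rules,
                          weekend_morning_blocked = trial$weekend_morning_blocked,
                          start_weekday = trial$start_weekday)
  cohort <- build("cohort", cohort_config)
  outcome <- build("outcome", outcome_params)
  model <- build("model", model_spec)

  if (length(problems))
    stop(paste(c("invalid configuration file:", paste0("  - ", problems)),
               collapse = "\n"), call. = FALSE)
  list(trial = trial, cohort = cohort, outcome = outcome, model = model)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a deterministic pipeline
#' stage: the seed, a configuration snapshot, the package version, and
#' MD5 digests of the input and output files.
#'
#' @param path Output JSON path.
#' @param seed Integer seed(s) used by the stage.
#' @param config Optional configuration list to snapshot.
#' @param inputs,outputs Character vectors of file paths to digest.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, seed, config = NULL,
                               inputs = character(0), outputs = character(0)) {
  digest <- function(files) {
    if (!length(files)) return(NULL)
    as.list(tools::md5sum(files))
  }
  manifest <- list(
    package = "mrtpush",
    version = as.character(utils::packageVersion("mrtpush")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_digests = digest(inputs),
    output_digests = digest(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Deterministic toy record fixture
#'
#' A tiny, fully reproducible dataset (5 users, 14 days, 6 slots = 420
#' rows) used for regression tests and worked examples.  The committed
#' copy in `inst/extdata/toy_records.csv` was written by this function
#' with its default seed.
#'
#' @param seed Fixed seed (default 20170301).
#' @return A decision-record `data.frame` with 420 rows.
#' @export
toy_mrt_records <- function(seed = 20170301) {
  simulate_mrt(trial_config(n_days = 14),
               cohort_config(n_users = 5),
               outcome_params(), seed = seed)
}
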