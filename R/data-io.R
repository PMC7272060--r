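#' Assemble a mark-resight dataset
#'
#' Bundles per-survey resight counts with the per-period marking record into
#' a single validated object, the common currency of all downstream
#' estimation functions. A *survey period* is a multi-day field trip anchored
#' on one night of mass carapace painting; each resight survey is identified
#' by the period, the day since marking, the diel slot (morning/afternoon)
#' and the survey method.
#'
#' @param surveys Data frame with columns `period_id`, `day`, `diel`
#'   (`"AM"`/`"PM"`), `method` (`"SO"`, `"UWV"` or `"UAV"`), `marked_seen`
#'   and `unmarked_seen`. A `total_seen` column, if present, is discarded and
#'   recomputed as `marked_seen + unmarked_seen`.
#' @param markings Data frame with columns `period_id` and `n_marked` (the
#'   number of turtles painted that period, one row per period).
#' @param allow_any_day Accept survey days outside 1--3? The standard design
#'   resights on the three days following marking; longer designs are useful
#'   in simulation studies.
#' @return An object of class `resight_data`: a list with tibbles `surveys`
#'   and `markings`. Errors if any hard invariant is violated (see
#'   [validate_resight()]); soft findings are attached as attribute
#'   `"findings"` and surfaced by [validate_resight()].
#' @seealso [read_surveys()], [write_surveys()], [validate_resight()]
#' @export
#' @examples
#' d <- resight_data(
#'   surveys  = data.frame(period_id = "Dec 2016", day = 1, diel = "AM",
#'                         method = "UAV", marked_seen = 95,
#'                         unmarked_seen = 1365),
#'   markings = data.frame(period_id = "Dec 2016", n_marked = 2000)
#' )
#' d$surveys$total_seen
resight_data <- function(surveys, markings, allow_any_day = FALSE) {
  surveys <- as_tibble(surveys)
  markings <- as_tibble(markings)
  need_s <- c("period_id", "day", "diel", "method", "marked_seen", "unmarked_seen")
  need_m <- c("period_id", "n_marked")
  miss <- setdiff(need_s, names(surveys))
  if (length(miss) > 0L)
    abort(paste0("surveys is missing column(s): ", paste(miss, collapse = ", ")),
          class = "markresight_schema_error")
  miss <- setdiff(need_m, names(markings))
  if (length(miss) > 0L)
    abort(paste0("markings is missing column(s): ", paste(miss, collapse = ", ")),
          class = "markresight_schema_error")

  surveys <- surveys %>%
    mutate(
      period_id     = as.character(.data$period_id),
      day           = as.integer(.data$day),
      diel          = as.character(.data$diel),
      method        = as.character(.data$method),
      marked_seen   = as.integer(.data$marked_seen),
      unmarked_seen = as.integer(.data$unmarked_seen),
      # never trusted from input
      total_seen    = as.integer(.data$marked_seen + .data$unmarked_seen)
    ) %>%
    select(dplyr::all_of(c(need_s, "total_seen")))
  markings <- markings %>%
    mutate(period_id = as.character(.data$period_id),
           n_marked  = as.integer(.data$n_marked)) %>%
    select(dplyr::all_of(need_m))

  x <- structure(list(surveys = surveys, markings = markings),
                 class = "resight_data",
                 allow_any_day = isTRUE(allow_any_day))
  f <- validate_resight(x)
  hard <- f[f$severity == "error", , drop = FALSE]
  if (nrow(hard) > 0L)
    abort(paste0("invalid resight data:\n  ",
                 paste(hard$message, collapse = "\n  ")),
          class = "markresight_validation_error")
  attr(x, "findings") <- f
  x
}

#' @export
print.resight_data <- function(x, ...) {
  cat("<resight_data> ", nrow(x$surveys), " surveys, ",
      nrow(x$markings), " marking period(s)\n", sep = "")
  if (nrow(x$surveys) > 0L) {
    tab <- x$surveys %>% count(.data$period_id, .data$method)
    print(tidyr::pivot_wider(tab, names_from = "method", values_from = "n",
                             values_fill = 0L))
  }
  invisible(x)
}

new_finding <- function(record, rule, message, severity = "error") {
  tibble(record = record, rule = rule, message = message, severity = severity)
}

#' Validate a mark-resight dataset
#'
#' Checks every structural invariant and returns findings rather than
#' throwing: an empty tibble means the dataset is clean. Severity `"error"`
#' marks violations that make estimation meaningless (e.g. more marked
#' turtles resighted than were ever painted); `"warning"` marks conditions
#' worth a look but not fatal (e.g. a sparse period), which are flagged but
#' never dropped.
#'
#' @param data A `resight_data` object, or any list with `surveys` and
#'   `markings` data frames.
#' @return A tibble with columns `record` (row reference), `rule`,
#'   `message`, `severity`; zero rows iff all invariants hold.
#' @export
validate_resight <- function(data) {
  s <- as_tibble(data$surveys)
  m <- as_tibble(data$markings)
  allow_any_day <- isTRUE(attr(data, "allow_any_day"))
  out <- list()

  dup <- m$period_id[duplicated(m$period_id)]
  for (p in unique(dup))
    out[[length(out) + 1L]] <- new_finding(
      paste0("marking:", p), "unique_marking",
      paste0("duplicate marking record for period '", p, "'"))
  for (i in seq_len(nrow(m))) {
    if (is.na(m$n_marked[i]) || m$n_marked[i] <= 0L)
      out[[length(out) + 1L]] <- new_finding(
        paste0("marking:", m$period_id[i]), "n_marked_positive",
        paste0("n_marked must be a positive integer for period '",
               m$period_id[i], "'"))
  }

  if (nrow(s) > 0L) {
    mm <- m[!duplicated(m$period_id), ]
    nm <- setNames(mm$n_marked, mm$period_id)
    for (i in seq_len(nrow(s))) {
      rec <- paste0("survey:", i)
      if (!s$method[i] %in% method_levels())
        out[[length(out) + 1L]] <- new_finding(
          rec, "method_label",
          paste0("row ", i, ": unknown method '", s$method[i],
                 "' (allowed: ", paste(method_levels(), collapse = ", "), ")"))
      if (!s$diel[i] %in% diel_levels())
        out[[length(out) + 1L]] <- new_finding(
          rec, "diel_label",
          paste0("row ", i, ": unknown diel '", s$diel[i],
                 "' (allowed: ", paste(diel_levels(), collapse = ", "), ")"))
      if (is.na(s$marked_seen[i]) || s$marked_seen[i] < 0L ||
          is.na(s$unmarked_seen[i]) || s$unmarked_seen[i] < 0L)
        out[[length(out) + 1L]] <- new_finding(
          rec, "counts_nonnegative",
          paste0("row ", i, ": counts must be non-negative integers"))
      if (!allow_any_day && (is.na(s$day[i]) || !s$day[i] %in% 1:3))
        out[[length(out) + 1L]] <- new_finding(
          rec, "day_range",
          paste0("row ", i, ": day ", s$day[i],
                 " outside 1-3 (set allow_any_day = TRUE for longer designs)"))
      if (!s$period_id[i] %in% mm$period_id) {
        out[[length(out) + 1L]] <- new_finding(
          rec, "marking_present",
          paste0("row ", i, ": no marking record for period '",
                 s$period_id[i], "'"))
      } else if (!is.na(s$marked_seen[i]) &&
                 s$marked_seen[i] > nm[[s$period_id[i]]]) {
        out[[length(out) + 1L]] <- new_finding(
          rec, "marked_within_population",
          paste0("row ", i, ": marked exceeds marked population (",
                 s$marked_seen[i], " > ", nm[[s$period_id[i]]], ")"))
      }
    }
    sparse <- s %>% count(.data$period_id) %>% filter(n < 2L)
    for (p in sparse$period_id)
      out[[length(out) + 1L]] <- new_finding(
        paste0("period:", p), "sparse_period",
        paste0("period '", p, "' has a single survey; ",
               "period-level standard errors fall back to the analytic form"),
        severity = "warning")
  }
  if (length(out) == 0L)
    return(new_finding(character(), character(), character(), character())[0, ])
  bind_rows(out)
}

survey_sort <- function(s, period_order) {
  ord <- order(match(s$period_id, period_order), s$day,
               match(s$diel, diel_levels()),
               match(s$method, method_levels()))
  s[ord, , drop = FALSE]
}

#' Read mark-resight survey and marking files
#'
#' Reads the two-file comma-separated schema: a survey file with header
#' `period_id,day,diel,method,marked_seen,unmarked_seen` and a marking file
#' with header `period_id,n_marked`. Lines starting with `#` (provenance
#' headers written by [write_surveys()]) are skipped. Totals are always
#' recomputed from the two count columns.
#'
#' @param surveys_path,markings_path Paths to the CSV files.
#' @inheritParams resight_data
#' @return A validated [resight_data()] object; row order of the survey file
#'   is preserved.
#' @export
read_surveys <- function(surveys_path, markings_path, allow_any_day = FALSE) {
  s <- readr::read_csv(surveys_path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  m <- readr::read_csv(markings_path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  resight_data(s, m, allow_any_day = allow_any_day)
}

#' Write a mark-resight dataset to CSV
#'
#' Writes the two-file schema read by [read_surveys()]; the round trip
#' reproduces the dataset field-for-field. Surveys are written sorted by
#' (period, day, diel AM<PM, method SO<UWV<UAV), the sampling chronology.
#'
#' @param data A `resight_data` object.
#' @param surveys_path,markings_path Output paths.
#' @param provenance Optional named character vector (e.g. seed, config
#'   hash) written as `# key=value` comment lines so reruns are
#'   self-documenting; identical inputs yield byte-identical files.
#' @return Invisibly, `data`.
#' @export
write_surveys <- function(data, surveys_path, markings_path,
                          provenance = NULL) {
  stopifnot(inherits(data, "resight_data"))
  hdr <- provenance_header(provenance)
  s <- survey_sort(data$surveys, data$markings$period_id) %>%
    select(-"total_seen")
  write_with_header(s, surveys_path, hdr)
  write_with_header(data$markings, markings_path, hdr)
  invisible(data)
}

provenance_header <- function(provenance) {
  if (is.null(provenance)) return(character())
  paste0("# ", names(provenance), "=", unname(provenance))
}

write_with_header <- function(df, path, header_lines) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header_lines) > 0L)
    writeLines(header_lines, con)
  readr::write_csv(df, con)
  invisible(path)
}
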