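# Readers/writers for sig corpora and parse results, as JSON Lines or
# flat CSV. Dose/duration decimals are serialized as plain decimal strings
# with at most 3 decimal places so that write -> read round trips are
# exact (no binary-float drift); a second write of re-read data is
# byte-identical.

period_fields <- c("optional_period", "start_condition",
                   "daily_dose_low", "daily_dose_high", "daily_dose_units",
                   "alt_daily_dose_low", "alt_daily_dose_high",
                   "alt_daily_dose_units",
                   "duration_low", "duration_high", "duration_units",
                   "hold_condition")

period_to_list <- function(p) {
  l <- list()
  if (p$optional_period) l$optional_period <- TRUE
  if (nzchar(p$start_condition)) l$start_condition <- p$start_condition
  l$daily_dose_low <- fmt_dec(p$daily_dose_low)
  l$daily_dose_high <- fmt_dec(p$daily_dose_high)
  l$daily_dose_units <- p$daily_dose_units
  if (!is.na(p$alt_daily_dose_low)) {
    l$alt_daily_dose_low <- fmt_dec(p$alt_daily_dose_low)
    l$alt_daily_dose_high <- fmt_dec(p$alt_daily_dose_high)
    l$alt_daily_dose_units <- p$alt_daily_dose_units
  }
  if (!is.na(p$duration_low) || !is.na(p$duration_high)) {
    l$duration_low <- fmt_dec(p$duration_low)
    l$duration_high <- fmt_dec(p$duration_high)
    l$duration_units <- p$duration_units
  }
  if (nzchar(p$hold_condition)) l$hold_condition <- p$hold_condition
  l
}

chr_or_na <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x) || !nzchar(x)) NA_character_
  else as.character(x)
}

period_from_list <- function(l) {
  period_object(
    daily_dose_low = parse_dec(l$daily_dose_low),
    daily_dose_high = parse_dec(l$daily_dose_high),
    daily_dose_units = chr_or_na(l$daily_dose_units),
    alt_daily_dose_low = parse_dec(l$alt_daily_dose_low),
    alt_daily_dose_high = parse_dec(l$alt_daily_dose_high),
    alt_daily_dose_units = chr_or_na(l$alt_daily_dose_units),
    duration_low = parse_dec(l$duration_low),
    duration_high = parse_dec(l$duration_high),
    duration_units = chr_or_na(l$duration_units),
    optional_period = isTRUE(l$optional_period),
    start_condition = l$start_condition %||% "",
    hold_condition = l$hold_condition %||% ""
  )
}

to_jsonl <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA)
}

#' Read sig records from a file
#'
#' JSONL schema: one object per line with `sig_id`, `text`, optional
#' `groups` (label -> value map) and optional `gold` (array of period
#' objects). A missing `gold` key means unannotated; `"gold": []` means
#' annotated-as-no-daily-dose — the distinction survives the round trip.
#'
#' CSV schema: header row; one row per (sig, gold period) with columns
#' `sig_id`, `text`, `annotated` ("true"/"false"), `period_index`, the
#' twelve `gold_*` period columns and any number of `group_*` columns.
#' Rows of one sig are contiguous.
#'
#' @param path input file
#' @param format "jsonl" or "csv"
#' @return list of [sig_record()]s in file order
#' @export
read_sigs <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "jsonl") read_sigs_jsonl(path) else read_sigs_csv(path)
}

read_sigs_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  records <- vector("list", length(lines_keep))
  for (j in seq_along(lines_keep)) {
    i <- lines_keep[j]
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e)
                      stop("malformed JSON on line ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    if (is.null(obj$sig_id) || is.null(obj$text))
      stop("line ", i, ": sig_id and text are required", call. = FALSE)
    gold <- NULL
    if ("gold" %in% names(obj))
      gold <- lapply(obj$gold, function(l)
        tryCatch(period_from_list(l), error = function(e)
          stop("line ", i, ": invalid gold period: ",
               conditionMessage(e), call. = FALSE)))
    records[[j]] <- sig_record(obj$sig_id, obj$text,
                               groups = obj$groups, gold = gold)
  }
  check_unique_ids(records)
  records
}

read_sigs_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        encoding = "UTF-8")
  need <- c("sig_id", "text", "annotated", "period_index")
  if (!all(need %in% names(df)))
    stop("sig CSV must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  group_cols <- grep("^group_", names(df), value = TRUE)
  ids <- rle(df$sig_id)$values
  if (anyDuplicated(ids))
    stop("duplicate sig_id: ", ids[duplicated(ids)][1], call. = FALSE)
  records <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    rows <- df[df$sig_id == ids[k], , drop = FALSE]
    r1 <- rows[1, ]
    groups <- NULL
    if (length(group_cols) > 0) {
      vals <- as.list(r1[group_cols])
      names(vals) <- sub("^group_", "", group_cols)
      vals <- vals[vapply(vals, nzchar, logical(1))]
      if (length(vals) > 0) groups <- vals
    }
    gold <- NULL
    if (identical(r1$annotated, "true")) {
      with_periods <- rows[nzchar(rows$period_index), , drop = FALSE]
      gold <- lapply(seq_len(nrow(with_periods)), function(j) {
        row <- with_periods[j, ]
        l <- as.list(row[paste0("gold_", period_fields)])
        names(l) <- period_fields
        l$optional_period <- identical(l$optional_period, "true")
        period_from_list(l)
      })
    }
    records[[k]] <- sig_record(ids[k], r1$text, groups = groups, gold = gold)
  }
  records
}

check_unique_ids <- function(records) {
  ids <- vapply(records, `[[`, "", "sig_id")
  if (anyDuplicated(ids))
    stop("duplicate sig_id: ", ids[duplicated(ids)][1], call. = FALSE)
  invisible(records)
}

#' Write sig records to a file
#'
#' Inverse of [read_sigs()]; see there for the schemas. Writing then
#' re-reading yields identical records.
#'
#' @param records list of [sig_record()]s
#' @param path output file
#' @param format "jsonl" or "csv"
#' @return `path`, invisibly
#' @export
write_sigs <- function(records, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  check_unique_ids(records)
  if (format == "jsonl") {
    lines <- vapply(records, function(r) {
      obj <- list(sig_id = r$sig_id, text = r$text)
      if (!is.null(r$groups)) obj$groups <- r$groups
      if (!is.null(r$gold)) obj$gold <- lapply(r$gold, period_to_list)
      to_jsonl(obj)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    group_labels <- sort(unique(unlist(lapply(records, function(r)
      names(r$groups)))))
    group_cols <- paste0("group_", group_labels)
    cols <- c("sig_id", "text", group_cols, "annotated", "period_index",
              paste0("gold_", period_fields))
    rows <- list()
    for (r in records) {
      base <- stats::setNames(as.list(rep("", length(cols))), cols)
      base$sig_id <- r$sig_id
      base$text <- r$text
      for (g in group_labels)
        base[[paste0("group_", g)]] <- as.character(r$groups[[g]] %||% "")
      base$annotated <- if (is.null(r$gold)) "false" else "true"
      if (is.null(r$gold) || length(r$gold) == 0) {
        rows[[length(rows) + 1L]] <- base
      } else {
        for (j in seq_along(r$gold)) {
          row <- base
          row$period_index <- as.character(j - 1L)
          p <- r$gold[[j]]
          row$gold_optional_period <- if (p$optional_period) "true" else "false"
          row$gold_start_condition <- p$start_condition
          row$gold_daily_dose_low <- fmt_dec(p$daily_dose_low)
          row$gold_daily_dose_high <- fmt_dec(p$daily_dose_high)
          row$gold_daily_dose_units <- p$daily_dose_units
          row$gold_alt_daily_dose_low <- fmt_dec(p$alt_daily_dose_low)
          row$gold_alt_daily_dose_high <- fmt_dec(p$alt_daily_dose_high)
          row$gold_alt_daily_dose_units <-
            if (is.na(p$alt_daily_dose_units)) "" else p$alt_daily_dose_units
          row$gold_duration_low <- fmt_dec(p$duration_low)
          row$gold_duration_high <- fmt_dec(p$duration_high)
          row$gold_duration_units <-
            if (is.na(p$duration_units)) "" else p$duration_units
          row$gold_hold_condition <- p$hold_condition
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
    df <- as.data.frame(do.call(rbind, lapply(rows, function(x)
      unlist(x, use.names = TRUE))), stringsAsFactors = FALSE)
    if (length(rows) == 0)
      df <- as.data.frame(stats::setNames(
        replicate(length(cols), character(0), simplify = FALSE), cols))
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Write parse results to a file
#'
#' JSONL: one object per line mirroring [parse_result()] (`sig_id`,
#' `status`, `normalized_text`, `residual_tokens` array, `periods` array).
#' CSV: one row per (sig, period) with a `period_index` column; results
#' without periods occupy one row with an empty index; `residual_tokens`
#' are joined with "|". An empty result list still produces a valid CSV
#' with a header row.
#'
#' @param results list of [parse_result()]s
#' @param path output file
#' @param format "jsonl" or "csv"
#' @return `path`, invisibly
#' @export
write_parse_results <- function(results, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  lapply(results, function(r) stopifnot(inherits(r, "parse_result")))
  if (format == "jsonl") {
    lines <- vapply(results, function(r) {
      obj <- list(sig_id = r$sig_id, status = r$status,
                  normalized_text = r$normalized_text,
                  residual_tokens = as.list(r$residual_tokens),
                  periods = lapply(r$periods, period_to_list))
      to_jsonl(obj)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    cols <- c("sig_id", "status", "normalized_text", "residual_tokens",
              "period_index", period_fields)
    rows <- list()
    for (r in results) {
      base <- stats::setNames(as.list(rep("", length(cols))), cols)
      base$sig_id <- r$sig_id
      base$status <- r$status
      base$normalized_text <- r$normalized_text
      base$residual_tokens <- paste(r$residual_tokens, collapse = "|")
      if (length(r$periods) == 0) {
        rows[[length(rows) + 1L]] <- base
      } else {
        for (j in seq_along(r$periods)) {
          row <- base
          row$period_index <- as.character(j - 1L)
          p <- r$periods[[j]]
          row$optional_period <- if (p$optional_period) "true" else "false"
          row$start_condition <- p$start_condition
          row$daily_dose_low <- fmt_dec(p$daily_dose_low)
          row$daily_dose_high <- fmt_dec(p$daily_dose_high)
          row$daily_dose_units <- p$daily_dose_units
          row$alt_daily_dose_low <- fmt_dec(p$alt_daily_dose_low)
          row$alt_daily_dose_high <- fmt_dec(p$alt_daily_dose_high)
          row$alt_daily_dose_units <-
            if (is.na(p$alt_daily_dose_units)) "" else p$alt_daily_dose_units
          row$duration_low <- fmt_dec(p$duration_low)
          row$duration_high <- fmt_dec(p$duration_high)
          row$duration_units <-
            if (is.na(p$duration_units)) "" else p$duration_units
          row$hold_condition <- p$hold_condition
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
    df <- if (length(rows) == 0)
      as.data.frame(stats::setNames(
        replicate(length(cols), character(0), simplify = FALSE), cols))
    else
      as.data.frame(do.call(rbind, lapply(rows, function(x)
        unlist(x, use.names = TRUE))), stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read parse results from a file
#'
#' Inverse of [write_parse_results()].
#'
#' @param path input file
#' @param format "jsonl" or "csv"
#' @return list of [parse_result()]s in file order
#' @export
read_parse_results <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    return(lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                      error = function(e)
                        stop("malformed JSON on line ", i, ": ",
                             conditionMessage(e), call. = FALSE))
      parse_result(obj$sig_id, obj$status,
                   periods = lapply(obj$periods, period_from_list),
                   residual_tokens = unlist(obj$residual_tokens) %||% character(0),
                   normalized_text = obj$normalized_text %||% "")
    }))
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        encoding = "UTF-8")
  need <- c("sig_id", "status", "period_index")
  if (!all(need %in% names(df)))
    stop("parse-result CSV must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  ids <- rle(df$sig_id)$values
  if (anyDuplicated(ids))
    stop("duplicate sig_id: ", ids[duplicated(ids)][1], call. = FALSE)
  lapply(ids, function(id) {
    rows <- df[df$sig_id == id, , drop = FALSE]
    r1 <- rows[1, ]
    with_periods <- rows[nzchar(rows$period_index), , drop = FALSE]
    periods <- lapply(seq_len(nrow(with_periods)), function(j) {
      row <- with_periods[j, ]
      l <- as.list(row[period_fields])
      l$optional_period <- identical(l$optional_period, "true")
      period_from_list(l)
    })
    resid <- if (nzchar(r1$residual_tokens))
      strsplit(r1$residual_tokens, "|", fixed = TRUE)[[1]] else character(0)
    parse_result(id, r1$status, periods = periods, residual_tokens = resid,
                 normalized_text = r1$normalized_text)
  })
}
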