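#' Weekly colony census tables
#'
#' A census table is a tibble in long format with one row per colony and
#' census week. Canonical columns are `colony_id`, `treatment_workers`,
#' `week` (integer weeks since colony setup, 0-based: week 0 is the setup
#' week), the offspring counts `eggs`, `pupae_worker`, `pupae_queen`,
#' `pupae_male_winged`, `pupae_male_wingless`, and the logical
#' `queen_alive`. Rows after the queen's death (the post-death window in
#' which remaining brood is allowed to develop and is still counted) carry
#' `queen_alive = FALSE`.
#'
#' Free-form metadata (source, units, the censoring-window length, ...) is
#' kept in the `"metadata"` attribute as a named list and survives the
#' CSV round trip as `#key: value` comment headers.
#'
#' @name census
NULL

new_census <- function(df, metadata = list()) {
  df <- as_tibble(df)
  attr(df, "metadata") <- metadata
  class(df) <- unique(c("cp_census", class(df)))
  df
}

#' Retrieve census metadata
#'
#' @param table a census table.
#' @return Named list of metadata fields (possibly empty).
#' @export
census_metadata <- function(table) {
  attr(table, "metadata") %||% list()
}

default_dialect <- function() {
  stats::setNames(as.list(CENSUS_COLS), CENSUS_COLS)
}

resolve_dialect <- function(dialect) {
  d <- default_dialect()
  if (is.null(dialect)) return(d)
  if (is.character(dialect) && length(dialect) == 1) {
    dialect <- yaml::read_yaml(dialect)
  }
  unknown <- setdiff(names(dialect), CENSUS_COLS)
  if (length(unknown) > 0) {
    abort(paste0(
      "Unknown canonical column(s) in dialect: ",
      paste(unknown, collapse = ", ")
    ), class = "cp_format_error")
  }
  modifyList(d, lapply(dialect, as.character))
}

#' Read a weekly colony census table
#'
#' Reads a delimited long-format census file (UTF-8, header row) and
#' returns a validated, normalized census tibble sorted by
#' `(colony_id, week)`. Lines starting with `#` are treated as comments;
#' lines of the form `#key: value` before the header are collected into
#' the table's metadata. Column names in the file can be mapped to the
#' canonical names through `dialect` (a named list
#' `canonical_name = file_name`, or the path of a YAML file holding one).
#'
#' @param path path of a CSV (or TSV, see `delim`) file.
#' @param dialect optional column-name map, see Details.
#' @param delim field delimiter, `","` by default.
#' @param strict if `TRUE`, gaps in a colony's week sequence are an error
#'   rather than a warning.
#' @return A census tibble (see [census]); columns not part of the
#'   canonical set are preserved.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_census(example_census(), path)
#' read_census(path)
read_census <- function(path, dialect = NULL, delim = ",", strict = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("Census file does not exist: ", path), class = "cp_io_error")
  }
  meta <- read_comment_metadata(path)
  df <- readr::read_delim(
    path, delim = delim, comment = "#", show_col_types = FALSE,
    progress = FALSE, trim_ws = TRUE
  )
  d <- resolve_dialect(dialect)
  for (canonical in names(d)) {
    file_col <- d[[canonical]]
    if (file_col %in% names(df) && !identical(file_col, canonical)) {
      names(df)[names(df) == file_col] <- canonical
    }
  }
  required <- setdiff(CENSUS_COLS, "treatment_workers")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "Census file is missing required column(s): ",
      paste(missing, collapse = ", ")
    ), class = "cp_format_error")
  }
  if (!"treatment_workers" %in% names(df)) df$treatment_workers <- NA_integer_
  if (is.character(df$queen_alive)) {
    df$queen_alive <- toupper(trimws(df$queen_alive)) %in% c("TRUE", "T", "1", "YES")
  }
  df$queen_alive <- as.logical(df$queen_alive)
  tbl <- new_census(df, metadata = meta)
  validate_census(tbl, strict = strict)
}

read_comment_metadata <- function(path) {
  meta <- list()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) break
    if (!startsWith(line, "#")) break
    body <- sub("^#\\s*", "", line)
    if (grepl(":", body, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", body))
      value <- trimws(sub("^[^:]*:", "", body))
      if (nzchar(key)) meta[[key]] <- value
    }
  }
  meta
}

#' Validate a census table
#'
#' Checks the census invariants: all counts non-negative, weeks
#' non-negative integers, no duplicated `(colony_id, week)` keys, and the
#' queen never recorded alive after a week in which she was recorded dead.
#' Gaps in a colony's week sequence are flagged with a warning (error when
#' `strict = TRUE`), never silently filled.
#'
#' @param table a census tibble.
#' @param strict treat week gaps as errors.
#' @return The table, normalized (sorted by colony and week), invisibly
#'   classed as a census table. Errors of class `cp_validation_error`
#'   or `cp_format_error` describe the offending rows.
#' @export
validate_census <- function(table, strict = FALSE) {
  df <- as_tibble(table)
  required <- setdiff(CENSUS_COLS, "treatment_workers")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "Missing required column(s): ", paste(missing, collapse = ", ")
    ), class = "cp_format_error")
  }
  if (nrow(df) == 0) {
    df$week <- as.integer(df$week)
    df$queen_alive <- as.logical(df$queen_alive)
    return(invisible(new_census(df, metadata = census_metadata(table))))
  }
  for (col in COUNT_COLS) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad) > 0) {
      abort(paste0(
        "Negative count in column '", col, "' at row(s) ",
        paste(head(bad, 5), collapse = ", ")
      ), class = "cp_validation_error")
    }
    bad <- which(is.na(df[[col]]))
    if (length(bad) > 0) {
      abort(paste0(
        "Missing count in column '", col, "' at row(s) ",
        paste(head(bad, 5), collapse = ", ")
      ), class = "cp_validation_error")
    }
  }
  if (any(is.na(df$week)) || any(df$week < 0) || any(df$week != round(df$week))) {
    bad <- which(is.na(df$week) | df$week < 0 | df$week != round(df$week))
    abort(paste0(
      "Week must be a non-negative integer; offending row(s) ",
      paste(head(bad, 5), collapse = ", ")
    ), class = "cp_validation_error")
  }
  df$week <- as.integer(df$week)
  key <- paste(df$colony_id, df$week, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    dups <- unique(paste0("(", df$colony_id[dup], ", week ", df$week[dup], ")"))
    abort(paste0(
      "Duplicated (colony, week) key(s): ", paste(head(dups, 5), collapse = ", ")
    ), class = "cp_validation_error")
  }
  if (any(is.na(df$queen_alive))) {
    abort("queen_alive must be TRUE or FALSE for every row",
          class = "cp_validation_error")
  }
  df <- dplyr::arrange(df, .data$colony_id, .data$week)
  # queen must not come back to life
  resurrected <- df %>%
    group_by(.data$colony_id) %>%
    summarise(bad = any(diff(as.integer(.data$queen_alive)) > 0),
              .groups = "drop") %>%
    filter(.data$bad)
  if (nrow(resurrected) > 0) {
    abort(paste0(
      "queen_alive switches back to TRUE in colony(ies): ",
      paste(head(resurrected$colony_id, 5), collapse = ", ")
    ), class = "cp_validation_error")
  }
  gaps <- df %>%
    group_by(.data$colony_id) %>%
    summarise(gap = any(diff(.data$week) != 1L), .groups = "drop") %>%
    filter(.data$gap)
  if (nrow(gaps) > 0) {
    msg <- paste0(
      "Week sequence has gaps in colony(ies): ",
      paste(head(gaps$colony_id, 5), collapse = ", ")
    )
    if (strict) abort(msg, class = "cp_validation_error") else warn(msg)
  }
  invisible(new_census(df, metadata = census_metadata(table)))
}

#' Write a census table
#'
#' Writes the canonical CSV representation; metadata entries are emitted
#' as `#key: value` comment lines before the header, so that
#' `read_census(write_census(t))` reproduces `t` field for field.
#'
#' @param table a census tibble.
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_census <- function(table, path, delim = ",") {
  df <- as_tibble(table)
  meta <- census_metadata(table)
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(paste0("Cannot open path for writing: ", path), class = "cp_io_error")
  })
  ok <- FALSE
  tryCatch({
    for (key in names(meta)) {
      writeLines(paste0("#", key, ": ", meta[[key]]), con)
    }
    close(con)
    ok <- TRUE
  }, error = function(e) {
    close(con)
    abort(paste0("I/O error writing ", path, ": ", conditionMessage(e)),
          class = "cp_io_error")
  })
  readr::write_delim(df, path, delim = delim, append = ok && length(meta) > 0,
                     col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Derive per-colony lifespan records
#'
#' One record per colony. `death_week` is the first census week at which
#' the queen was recorded dead (deaths between weekly censuses are
#' interval-censored to the census boundary). A queen still alive at her
#' colony's last census is right-censored with
#' `death_week = last_week + 1` and `observed = FALSE`.
#'
#' @param table a census tibble.
#' @return Tibble with columns `colony_id`, `treatment_workers`,
#'   `death_week`, `observed`.
#' @export
#' @examples
#' lifespans(example_census())
lifespans <- function(table) {
  df <- as_tibble(table)
  if (nrow(df) == 0) abort("Empty cohort", class = "cp_validation_error")
  out <- df %>%
    group_by(.data$colony_id) %>%
    summarise(
      treatment_workers = first(.data$treatment_workers),
      ever_alive = any(.data$queen_alive),
      first_dead = if (any(!.data$queen_alive))
        min(.data$week[!.data$queen_alive]) else NA_integer_,
      last_week = max(.data$week),
      .groups = "drop"
    )
  never <- out %>% filter(!.data$ever_alive)
  if (nrow(never) > 0) {
    abort(paste0(
      "Colony(ies) never observed with a live queen: ",
      paste(head(never$colony_id, 5), collapse = ", ")
    ), class = "cp_validation_error")
  }
  out %>%
    mutate(
      observed = !is.na(.data$first_dead),
      death_week = as.integer(ifelse(.data$observed, .data$first_dead,
                                     .data$last_week + 1L))
    ) %>%
    select("colony_id", "treatment_workers", "death_week", "observed")
}

#' A small example census table
#'
#' Two colonies, three weeks each; used in examples and tests.
#'
#' @return A census tibble with 6 rows.
#' @export
example_census <- function() {
  new_census(tibble(
    colony_id = rep(c("c1", "c2"), each = 3),
    treatment_workers = rep(c(10L, 20L), each = 3),
    week = rep(0:2, 2),
    eggs = c(0L, 4L, 6L, 1L, 5L, 7L),
    pupae_worker = c(0L, 0L, 2L, 0L, 1L, 3L),
    pupae_queen = c(0L, 0L, 0L, 0L, 0L, 1L),
    pupae_male_winged = 0L,
    pupae_male_wingless = c(0L, 0L, 1L, 0L, 0L, 0L),
    queen_alive = TRUE
  ), metadata = list(source = "example"))
}
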