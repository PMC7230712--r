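# CSV ingest/egress. Schemas:
#   meals.csv    subject_id, timestamp, meal_type, kcal, carb_kcal,
#                sugar_kcal, fat_kcal, satfat_kcal, protein_kcal,
#                alcohol_kcal
#   work.csv     subject_id, start, end
#   sleep.csv    subject_id, onset, wake, is_main
#   subjects.csv subject_id, sex, age_years, height_cm, weight_kg

#' Read a meal log
#' @param path CSV path.
#' @return validated data.frame with POSIXct timestamps.
#' @export
read_meal_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_meal_records(df)
}

#' Read a work log
#' @param path CSV path.
#' @return data.frame `subject_id`, `start`, `end` (POSIXct).
#' @export
read_work_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "start", "end")
  if (!all(need %in% names(df)))
    stop("work log needs columns: ", paste(need, collapse = ", "))
  df$start <- parse_timestamp(df$start)
  df$end <- parse_timestamp(df$end)
  if (any(df$end <= df$start)) stop("work end must be after start")
  df
}

#' Read a sleep log
#' @param path CSV path.
#' @return data.frame `subject_id`, `onset`, `wake`, optional `is_main`.
#' @export
read_sleep_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "onset", "wake")
  if (!all(need %in% names(df)))
    stop("sleep log needs columns: ", paste(need, collapse = ", "))
  df$onset <- parse_timestamp(df$onset)
  df$wake <- parse_timestamp(df$wake)
  if (!is.null(df$is_main)) df$is_main <- as.logical(df$is_main)
  if (any(df$wake <= df$onset)) stop("sleep wake must follow onset")
  df
}

#' Read a subject table
#' @param path CSV path.
#' @return data.frame with demographics and anthropometrics.
#' @export
read_subjects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age_years", "height_cm", "weight_kg")
  if (!all(need %in% names(df)))
    stop("subject table needs columns: ", paste(need, collapse = ", "))
  df
}

write_table <- function(df, path) {
  for (col in names(df))
    if (inherits(df[[col]], "POSIXct")) df[[col]] <- format_timestamp(df[[col]])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
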