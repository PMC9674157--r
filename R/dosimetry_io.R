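.DOSE_COLS <- c("patient_id", "plan_label", "ovary_side", "modality",
                "dose_min_gy", "dose_mean_gy", "dose_max_gy")

.validate_dose_records <- function(df, where = "input") {
  missing_cols <- setdiff(.DOSE_COLS, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing column(s): %s", where,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df <- df[, .DOSE_COLS, drop = FALSE]
  if (nrow(df) == 0L) {
    warning(sprintf("%s: no dose records (header only)", where),
            call. = FALSE)
    return(df)
  }
  for (col in c("dose_min_gy", "dose_mean_gy", "dose_max_gy")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("%s: non-numeric %s in row %d", where, col, bad[1]),
           call. = FALSE)
    df[[col]] <- v
  }
  df$ovary_side <- tolower(trimws(df$ovary_side))
  df$modality <- tolower(trimws(df$modality))
  bad <- which(!df$ovary_side %in% c("left", "right"))
  if (length(bad))
    stop(sprintf("%s: row %d: ovary_side must be 'left' or 'right'",
                 where, bad[1]), call. = FALSE)
  bad <- which(!df$modality %in% c("photon", "proton"))
  if (length(bad))
    stop(sprintf("%s: row %d: modality must be 'photon' or 'proton'",
                 where, bad[1]), call. = FALSE)
  bad <- which(df$dose_min_gy < 0 | df$dose_min_gy > df$dose_mean_gy |
                 df$dose_mean_gy > df$dose_max_gy)
  if (length(bad))
    stop(sprintf(paste0("%s: row %d: dose ordering violated ",
                        "(need 0 <= min <= mean <= max)"), where, bad[1]),
         call. = FALSE)
  key <- paste(df$patient_id, df$plan_label, df$ovary_side, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("%s: row %d: duplicate (patient, plan, ovary_side) record",
                 where, which(duplicated(key))[1]), call. = FALSE)
  df
}

#' Read a per-ovary dose summary table
#'
#' Reads per-ovary dose records from a CSV file (comma-separated, UTF-8,
#' header required) or a JSON array of objects, with fields `patient_id`,
#' `plan_label`, `ovary_side` (left/right), `modality` (photon/proton) and
#' `dose_min_gy`, `dose_mean_gy`, `dose_max_gy` as decimal Gy (CGE for proton
#' plans). An absent (e.g. oophorectomised) ovary is represented by omitting
#' its record, not by zero doses.
#'
#' @param path CSV or JSON file path; `.json` extension selects JSON.
#' @return A validated data frame of dose records, one per
#'   (patient, plan, ovary side).
#' @export
read_dose_summary <- function(path) {
  if (!file.exists(path))
    stop("dose summary file not found: ", path, call. = FALSE)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path)
    if (length(x) == 0L)
      x <- as.data.frame(setNames(rep(list(character()), length(.DOSE_COLS)),
                                  .DOSE_COLS))
    as.data.frame(x, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  }
  .validate_dose_records(df, where = basename(path))
}

#' Write per-ovary dose records to CSV or JSON
#'
#' @param records A data frame of dose records (see [read_dose_summary()]).
#' @param path Output path; `.json` extension selects JSON.
#' @return `path`, invisibly.
#' @export
write_dose_summary <- function(records, path) {
  records <- .validate_dose_records(as.data.frame(records), "records")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    utils::write.csv(records, path, row.names = FALSE)
  }
  invisible(path)
}

#' Select the least-affected ovary for one patient and plan
#'
#' The fertility prediction is driven by the ovary furthest from the target,
#' i.e. the one receiving the lower mean dose. Ties are broken by lower
#' maximum dose, then by the left side.
#'
#' @param records Dose records for a single patient and plan (1 or 2 rows).
#' @return The selected single-row record.
#' @export
least_affected_ovary <- function(records) {
  records <- .validate_dose_records(as.data.frame(records), "records")
  if (nrow(records) == 0L)
    stop("no dose records supplied", call. = FALSE)
  if (length(unique(records$patient_id)) > 1L ||
      length(unique(records$plan_label)) > 1L)
    stop("records must belong to a single patient and plan", call. = FALSE)
  if (nrow(records) > 2L)
    stop("more than two ovary records for one patient and plan",
         call. = FALSE)
  ord <- order(records$dose_mean_gy, records$dose_max_gy,
               match(records$ovary_side, c("left", "right")))
  records[ord[1], , drop = FALSE]
}

#' Compare treatment plans by predicted fertility outcome
#'
#' For each plan of one patient, selects the least-affected ovary, predicts
#' the POI window for the supplied treatment age, and ranks plans from most
#' to least fertility-sparing (descending z = 0 mean-dose POI age). Plans
#' whose z = 0 mean-dose POI age falls before 30 years are flagged for the
#' fertility-preservation discussion.
#'
#' @param records Dose records for one patient covering two or more plans.
#' @param age Age at treatment in years.
#' @param model A `"reserve_model"`.
#' @param ld50_gy Median lethal dose in Gy.
#' @return A data frame of class `"plan_comparison"`, one row per plan, with
#'   the selected ovary, its dose triplet, the z = 0 POI ages at min / mean /
#'   max dose, the z = +/-1 mean-dose window, and the `before_30` flag.
#'   The full `"poi_prediction"` objects are attached as attribute
#'   `"windows"`, named by plan.
#' @export
compare_plans <- function(records, age, model = reserve_params(),
                          ld50_gy = 2.0) {
  records <- .validate_dose_records(as.data.frame(records), "records")
  if (length(unique(records$patient_id)) != 1L)
    stop("'records' must contain exactly one patient_id", call. = FALSE)
  plans <- unique(records$plan_label)
  if (length(plans) < 2L)
    stop("plan comparison needs at least two plan labels", call. = FALSE)
  rows <- list(); windows <- list()
  for (p in plans) {
    rec <- least_affected_ovary(records[records$plan_label == p, ])
    sc <- exposure_scenario(age, rec$dose_min_gy, rec$dose_mean_gy,
                            rec$dose_max_gy, rec$modality)
    w <- predict_window(sc, model, ld50_gy)
    g <- w$grid
    z0 <- function(lab) g$poi_age[g$z == 0 & g$dose_label == lab]
    rows[[p]] <- data.frame(
      plan_label = p, modality = rec$modality, ovary_side = rec$ovary_side,
      dose_min_gy = rec$dose_min_gy, dose_mean_gy = rec$dose_mean_gy,
      dose_max_gy = rec$dose_max_gy,
      poi_age_min_dose = z0("min"), poi_age_mean_dose = z0("mean"),
      poi_age_max_dose = z0("max"),
      poi_age_z_minus1 = g$poi_age[g$z == -1 & g$dose_label == "mean"],
      poi_age_z_plus1 = g$poi_age[g$z == 1 & g$dose_label == "mean"],
      before_30 = z0("mean") < POI_COUNSEL_AGE,
      stringsAsFactors = FALSE)
    windows[[p]] <- w
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$poi_age_mean_dose), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "windows") <- windows
  attr(out, "age_at_treatment") <- age
  class(out) <- c("plan_comparison", "data.frame")
  out
}

#' @export
print.plan_comparison <- function(x, digits = 1, ...) {
  cat(sprintf("Treatment plan comparison at age %.4g y (best plan first)\n",
              attr(x, "age_at_treatment")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print.data.frame(df, row.names = FALSE)
  if (any(x$before_30))
    cat("Plans flagged before_30 predict POI before age 30;",
        "fertility preservation should be discussed.\n")
  invisible(x)
}
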