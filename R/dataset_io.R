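dataset_required_cols <- c("ID", "TIME", "AMT", "RATE", "EVID", "DV", "MDV", "BLQ")
dataset_covariate_cols <- c("AGE", "WT", "SEX", "ALT", "SCR", "TP", "ALB",
                            "ECMO", "CRRT", "CRCL", "EGFR")

#' Write a dosing/observation dataset to CSV
#'
#' Comma-separated, decimal point, one header row; `DV` is blank on dose
#' rows (`MDV = 1`). Times are hours relative to each subject's first dose.
#'
#' @param ds Dataset data frame (see [read_dataset()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  utils::write.csv(ds[, c(dataset_required_cols,
                          intersect(dataset_covariate_cols, names(ds)))],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and validate a dosing/observation dataset
#'
#' Reads the rectangular CSV dialect used throughout: columns `ID`, `TIME`
#' (h), `AMT` (mg), `RATE` (mg/h), `EVID` (1 dose, 0 observation), `DV`
#' (ng/mL, blank when `MDV = 1`), `MDV`, `BLQ`, plus covariate columns.
#' Dose rows are infusions with explicit `RATE`; duration is `AMT/RATE`.
#' Hard errors: missing required columns, observation rows with blank `DV`,
#' dose rows with `RATE = 0` and `AMT > 0` (ambiguous bolus), unsorted
#' times within a subject, subjects lacking a dose or an observation row.
#'
#' @param path CSV file path.
#' @return A validated dataset data frame sorted by `(ID, TIME, EVID desc)`.
#' @export
read_dataset <- function(path) {
  ds <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(dataset_required_cols, names(ds))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  obs_blank <- ds$EVID == 0 & (is.na(ds$DV))
  if (any(obs_blank)) {
    i <- which(obs_blank)[1]
    stop(sprintf("observation row with blank DV at ID=%s TIME=%s",
                 ds$ID[i], ds$TIME[i]))
  }
  bad_bolus <- ds$EVID == 1 & ds$RATE == 0 & ds$AMT > 0
  if (any(bad_bolus)) {
    i <- which(bad_bolus)[1]
    stop(sprintf("ambiguous bolus (RATE=0, AMT>0) at ID=%s TIME=%s",
                 ds$ID[i], ds$TIME[i]))
  }
  if (any(ds$EVID == 1 & ds$MDV != 1)) stop("dose rows must have MDV=1")
  for (id in unique(ds$ID)) {
    sub <- ds[ds$ID == id, ]
    if (is.unsorted(sub$TIME)) stop("unsorted TIME within ID=", id)
    if (!any(sub$EVID == 1)) stop("ID=", id, " has no dose row")
    if (!any(sub$EVID == 0)) stop("ID=", id, " has no observation row")
  }
  if (any(ds$DV[ds$MDV == 0] < 0)) stop("negative DV")
  ds <- ds[order(ds$ID, ds$TIME, -ds$EVID), ]
  rownames(ds) <- NULL
  ds
}

#' Validate a parsed dataset, reporting findings
#'
#' Non-fatal review of a parsed dataset. Errors reported: negative `DV`.
#' Warnings reported: observations before the first dose; `DV` above the
#' 1000 ng/mL upper end of the assay linear range (kept, flagged).
#'
#' @param ds Dataset data frame.
#' @return A data frame of findings with columns `severity`, `ID`, `TIME`,
#'   `message`; zero rows when clean.
#' @export
validate_dataset <- function(ds) {
  out <- data.frame(severity = character(), ID = numeric(), TIME = numeric(),
                    message = character())
  add <- function(sev, id, time, msg) {
    rbind(out, data.frame(severity = sev, ID = id, TIME = time, message = msg))
  }
  obs <- ds[ds$EVID == 0, ]
  neg <- obs[!is.na(obs$DV) & obs$DV < 0, ]
  for (i in seq_len(nrow(neg))) {
    out <- add("error", neg$ID[i], neg$TIME[i], "negative DV")
  }
  high <- obs[!is.na(obs$DV) & obs$DV > 1000, ]
  for (i in seq_len(nrow(high))) {
    out <- add("warning", high$ID[i], high$TIME[i],
               "DV above assay linear range (1000 ng/mL)")
  }
  for (id in unique(ds$ID)) {
    sub <- ds[ds$ID == id, ]
    first_dose <- min(sub$TIME[sub$EVID == 1])
    early <- sub[sub$EVID == 0 & sub$TIME < first_dose, ]
    for (i in seq_len(nrow(early))) {
      out <- add("warning", early$ID[i], early$TIME[i],
                 "observation before first dose")
    }
  }
  out
}

# Internal: explode a dataset into the per-subject structure the FOCE engine
# consumes. BLQ-flagged observations are excluded from fitting (discard rule).
dataset_to_subjects <- function(ds, drop_blq = TRUE) {
  ids <- unique(ds$ID)
  lapply(ids, function(id) {
    sub <- ds[ds$ID == id, ]
    dose <- sub[sub$EVID == 1, ]
    obs <- sub[sub$EVID == 0, ]
    if (drop_blq && "BLQ" %in% names(obs)) obs <- obs[obs$BLQ == 0, ]
    cov <- sub[1, intersect(dataset_covariate_cols, names(sub)), drop = FALSE]
    list(
      id = id,
      y = obs$DV,
      times = obs$TIME,
      starts = dose$TIME,
      rates = dose$RATE,
      durations = dose$AMT / dose$RATE,
      covariates = cov
    )
  })
}
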