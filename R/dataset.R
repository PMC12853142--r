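# NONMEM-style dataset handling. Columns (case-insensitive): ID, TIME (h),
# AMT (mg), EVID (0 observation / 1 dose), MDV, DV (ng/mL), AGE (years),
# WT (kg); optional SS (steady-state dose flag) and II (interval, h).
# "." denotes missing.

.REQUIRED_COLS <- c("ID", "TIME", "AMT", "EVID", "MDV", "DV", "AGE", "WT")

#' Validate a PK dataset
#'
#' Checks the dataset invariants: required columns present, every subject
#' with observations has at least one dose record, observed DV
#' non-negative, and TIME non-decreasing within subject.
#'
#' @param data A data.frame in the layout of [read_dataset()].
#' @return Invisibly `TRUE`; errors describe the first violation found.
#' @export
validate_dataset <- function(data) {
  missing <- setdiff(.REQUIRED_COLS, names(data))
  if (length(missing)) {
    stopf("dataset lacks column(s): %s", paste(missing, collapse = ", "))
  }
  obs <- data$EVID == 0 & data$MDV == 0
  if (any(obs & (!is.finite(data$DV) | data$DV < 0))) {
    stopf("observation records must have finite DV >= 0")
  }
  for (id in unique(data$ID)) {
    rows <- data[data$ID == id, ]
    if (any(rows$EVID == 0 & rows$MDV == 0) && !any(rows$EVID == 1)) {
      stopf("subject %s has observations but no dose record", id)
    }
    if (is.unsorted(rows$TIME)) {
      stopf("TIME must be non-decreasing within subject %s", id)
    }
  }
  invisible(TRUE)
}

#' Read a NONMEM-style CSV dataset
#'
#' Column names are matched case-insensitively and "." is read as missing.
#'
#' @param path CSV file path.
#' @return A validated data.frame with upper-case canonical column names.
#' @export
read_dataset <- function(path) {
  raw <- read.csv(path, na.strings = c(".", "NA", ""),
                  check.names = FALSE, stringsAsFactors = FALSE)
  names(raw) <- toupper(names(raw))
  missing <- setdiff(.REQUIRED_COLS, names(raw))
  if (length(missing)) {
    stopf("dataset '%s' lacks column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  for (cl in setdiff(names(raw), "ID")) {
    if (!is.numeric(raw[[cl]])) raw[[cl]] <- suppressWarnings(
      as.numeric(raw[[cl]]))
  }
  if (any(!is.finite(raw$DV[raw$EVID == 0 & raw$MDV == 0]))) {
    stopf("non-numeric DV on observation records in '%s'", path)
  }
  raw$DV[is.na(raw$DV)] <- 0
  raw$AMT[is.na(raw$AMT)] <- 0
  if (is.null(raw$SS)) raw$SS <- 0
  if (is.null(raw$II)) raw$II <- 0
  validate_dataset(raw)
  raw
}

#' Write a dataset as NONMEM-style CSV ("." for missing DV on dose rows)
#'
#' @param data Dataset data.frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(data, path) {
  out <- data
  out$DV <- ifelse(out$EVID == 1, ".", format(out$DV, digits = 10,
                                              trim = TRUE, scientific = FALSE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Precompute the observation/dose-contribution structure used by the
# likelihood and simulation code. For each observation the contributing
# dose records are: the most recent steady-state dose at or before the
# observation (implying its full preceding history) plus any later
# single doses, or simply all preceding single doses when no steady-state
# record applies.
.prepare_obs <- function(data) {
  obs_rows <- which(data$EVID == 0 & data$MDV == 0)
  ids <- unique(data$ID[obs_rows])
  subj <- data.frame(ID = ids,
                     AGE = data$AGE[match(ids, data$ID)],
                     WT = data$WT[match(ids, data$ID)])
  obs <- data.frame(row = obs_rows,
                    subject = match(data$ID[obs_rows], ids),
                    time = data$TIME[obs_rows],
                    dv = data$DV[obs_rows])
  dose_rows <- which(data$EVID == 1)
  dose_by_id <- split(dose_rows, data$ID[dose_rows])
  obs_by_id <- split(seq_along(obs_rows), data$ID[obs_rows])
  contrib <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    id <- as.character(ids[s])
    dr <- dose_by_id[[id]]
    if (is.null(dr)) next
    dt <- data$TIME[dr]
    damt <- data$AMT[dr]
    dss <- data$SS[dr] > 0
    dii <- ifelse(data$II[dr] > 0, data$II[dr], 24)
    pieces <- lapply(obs_by_id[[id]], function(k) {
      t_obs <- obs$time[k]
      cand <- which(dt <= t_obs)
      if (!length(cand)) return(NULL)
      ss_idx <- cand[dss[cand]]
      keep <- if (length(ss_idx)) {
        last_ss <- max(ss_idx)
        c(last_ss, cand[cand > last_ss & !dss[cand]])
      } else cand
      data.frame(obs = k, amt = damt[keep], tad = t_obs - dt[keep],
                 ss = as.integer(dss[keep]), ii = dii[keep])
    })
    contrib[[s]] <- do.call(rbind, pieces)
  }
  contrib <- do.call(rbind, contrib)
  contrib <- contrib[order(contrib$obs), , drop = FALSE]
  list(subjects = subj, obs = obs, contrib = contrib)
}
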