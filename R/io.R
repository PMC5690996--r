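MATCH_HEADER <- c("patient_id", "fraction", "timepoint",
                  "tx_mm", "ty_mm", "tz_mm", "pitch_deg", "roll_deg",
                  "yaw_deg")
TIMEPOINTS <- c("post_setup", "post_correction", "post_treatment")

#' Write treatment courses as a per-fraction match table
#'
#' Serializes a population (or a single course) to the package's CSV
#' interchange format, one row per patient x fraction x timepoint with
#' header `patient_id,fraction,timepoint,tx_mm,ty_mm,tz_mm,pitch_deg,
#' roll_deg,yaw_deg`. Units are mm and degrees; numbers are written with a
#' fixed number of decimals and no locale-dependent separators.
#'
#' @param population List of [treatment_course()] objects (or one course).
#' @param path Output file path.
#' @param timepoint Timepoint label for the rows (default `"post_setup"`).
#' @param digits Decimal places written (default 10, which round-trips far
#'   below any clinically meaningful precision).
#' @return `path`, invisibly.
#' @export
write_match_table <- function(population, path, timepoint = "post_setup",
                              digits = 10) {
  if (inherits(population, "treatment_course")) population <- list(population)
  timepoint <- match.arg(timepoint, TIMEPOINTS)
  rows <- lapply(population, function(crs) {
    m <- course_matrix(crs)
    data.frame(patient_id = crs$patient_id,
               fraction = seq_len(nrow(m)),
               timepoint = timepoint,
               tx_mm = m[, "tx"], ty_mm = m[, "ty"], tz_mm = m[, "tz"],
               pitch_deg = m[, "pitch"], roll_deg = m[, "roll"],
               yaw_deg = m[, "yaw"])
  })
  df <- do.call(rbind, rows)
  num <- MATCH_HEADER[-(1:3)]
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits,
                                                 format = "f"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-fraction 6DoF match table
#'
#' Parses the CSV interchange format into one [treatment_course()] per
#' patient from the `post_setup` rows. Optional `post_correction` and
#' `post_treatment` rows are returned as data frames when present.
#' Duplicate `(patient_id, fraction, timepoint)` keys, unknown timepoint
#' labels, unparseable numbers and gaps in a patient's post-setup fraction
#' sequence are rejected with the offending line identified — missing
#' fractions are reported, never silently filled.
#'
#' @param path Path to a CSV file with header `patient_id,fraction,
#'   timepoint,tx_mm,ty_mm,tz_mm,pitch_deg,roll_deg,yaw_deg`.
#' @param column_map Optional named character vector mapping the canonical
#'   column names to the names actually used in the file, e.g.
#'   `c(patient_id = "pid")`.
#' @return List with `courses` (list of [treatment_course()], one per
#'   patient, in order of first appearance), and `post_correction` /
#'   `post_treatment` data frames or `NULL`.
#' @export
read_match_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      j <- match(column_map[[canon]], names(df))
      if (is.na(j)) stop("column '", column_map[[canon]],
                         "' (mapped to ", canon, ") not found in ", path,
                         call. = FALSE)
      names(df)[j] <- canon
    }
  }
  missing_cols <- setdiff(MATCH_HEADER, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[MATCH_HEADER]
  line <- seq_len(nrow(df)) + 1L  # physical line numbers (header = line 1)

  bad_tp <- !df$timepoint %in% TIMEPOINTS
  if (any(bad_tp))
    stop("unknown timepoint '", df$timepoint[bad_tp][1L], "' at line ",
         line[bad_tp][1L], " of ", path, call. = FALSE)

  frac <- suppressWarnings(as.integer(df$fraction))
  if (any(is.na(frac)) || any(frac < 1L)) {
    i <- which(is.na(frac) | frac < 1L)[1L]
    stop("invalid fraction '", df$fraction[i], "' at line ", line[i], " of ",
         path, call. = FALSE)
  }
  num <- MATCH_HEADER[-(1:3)]
  vals <- matrix(NA_real_, nrow(df), 6L, dimnames = list(NULL, AXES))
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(df[[num[j]]]))
    if (any(!is.finite(v))) {
      i <- which(!is.finite(v))[1L]
      stop("unparseable value '", df[[num[j]]][i], "' in column ", num[j],
           " at line ", line[i], " of ", path, call. = FALSE)
    }
    vals[, j] <- v
  }

  key <- paste(df$patient_id, frac, df$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop("duplicate (patient_id, fraction, timepoint) = (", df$patient_id[i],
         ", ", frac[i], ", ", df$timepoint[i], ") at line ", line[i], " of ",
         path, call. = FALSE)
  }

  setup <- df$timepoint == "post_setup"
  if (!any(setup))
    stop("no post_setup rows in ", path, call. = FALSE)
  pids <- unique(df$patient_id[setup])
  courses <- lapply(pids, function(pid) {
    sel <- setup & df$patient_id == pid
    f <- frac[sel]
    o <- order(f)
    expect <- seq_len(max(f))
    if (!identical(sort(f), expect)) {
      stop("patient ", pid, " is missing post_setup fraction(s) ",
           paste(setdiff(expect, f), collapse = ", "), " in ", path,
           call. = FALSE)
    }
    treatment_course(pid, vals[sel, , drop = FALSE][o, , drop = FALSE])
  })
  names(courses) <- pids

  extra <- function(tp) {
    sel <- df$timepoint == tp
    if (!any(sel)) return(NULL)
    out <- data.frame(patient_id = df$patient_id[sel], fraction = frac[sel],
                      vals[sel, , drop = FALSE])
    out[order(out$patient_id, out$fraction), , drop = FALSE]
  }
  pc <- extra("post_correction")
  pt <- extra("post_treatment")
  if (is.null(pc) && is.null(pt))
    message("note: no post_correction/post_treatment rows in ", path,
            " (optional)")
  list(courses = courses, post_correction = pc, post_treatment = pt)
}
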