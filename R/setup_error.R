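# Axis order used everywhere in the package: three translations (mm), then
# rotations pitch/roll/yaw = rotations about the x-, y-, z-axis (IEC 61217).
AXES <- c("tx", "ty", "tz", "pitch", "roll", "yaw")
TRANS_AXES <- AXES[1:3]
ROT_AXES <- AXES[4:6]

#' Construct a 6DoF setup error
#'
#' A setup error is the deviation of the patient's actual position from the
#' planned position at one treatment fraction: three translations in mm and
#' three rotations in degrees. Rotations are named after the IEC 61217 machine
#' axes: pitch about x, roll about y, yaw about z.
#'
#' Setup errors form an additive group: `+`, unary `-` and binary `-` are
#' defined component-wise. This additive treatment of rotations is the
#' small-angle approximation used throughout protocol arithmetic; it is
#' accurate to well under 0.02 mm at 100 mm off-axis for rotations up to
#' 3.2 degrees (see the geometry helpers and the package vignette).
#'
#' @param tx,ty,tz Translations along x, y, z in mm.
#' @param pitch,roll,yaw Rotations about x, y, z in degrees.
#' @return An object of class `setup_error`: a named numeric vector with
#'   components `tx, ty, tz, pitch, roll, yaw`.
#' @examples
#' e <- setup_error(tx = 0.5, pitch = 1.0)
#' e + setup_error(tx = 0.25, pitch = -0.4)
#' @export
setup_error <- function(tx = 0, ty = 0, tz = 0, pitch = 0, roll = 0, yaw = 0) {
  x <- c(tx = tx, ty = ty, tz = tz, pitch = pitch, roll = roll, yaw = yaw)
  if (length(x) != 6L)
    stop("each setup-error component must be a single number", call. = FALSE)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("setup-error components must all be finite numbers; got: ",
         paste(format(x), collapse = ", "), call. = FALSE)
  structure(x, class = "setup_error")
}

as_setup_error <- function(x) {
  if (inherits(x, "setup_error")) return(x)
  x <- as.numeric(x)
  if (length(x) != 6L || any(!is.finite(x)))
    stop("expected 6 finite components (tx, ty, tz, pitch, roll, yaw)",
         call. = FALSE)
  names(x) <- AXES
  structure(x, class = "setup_error")
}

#' @export
Ops.setup_error <- function(e1, e2) {
  if (!.Generic %in% c("+", "-"))
    stop("operation '", .Generic, "' is not defined for setup errors",
         call. = FALSE)
  if (missing(e2)) {
    if (.Generic == "-") return(as_setup_error(-unclass(e1)))
    return(e1)
  }
  a <- as_setup_error(e1)
  b <- as_setup_error(e2)
  as_setup_error(get(.Generic)(unclass(a), unclass(b)))
}

#' @export
print.setup_error <- function(x, digits = 4, ...) {
  cat("6DoF setup error (mm / deg):\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Ordered per-fraction setup errors for one patient
#'
#' Bundles a patient's raw per-fraction 6DoF setup errors into a treatment
#' course. Fractions are 1-based and contiguous; row `f` of `errors` is the
#' post-setup error at fraction `f`.
#'
#' @param patient_id Patient identifier (coerced to character).
#' @param errors An `n_fractions x 6` numeric matrix or data frame with
#'   columns `tx, ty, tz, pitch, roll, yaw` (mm, mm, mm, deg, deg, deg), or a
#'   list of [setup_error()] objects.
#' @return An object of class `treatment_course` with fields `patient_id`,
#'   `n_fractions`, and the error matrix `errors`.
#' @examples
#' err <- matrix(0, nrow = 5, ncol = 6, dimnames = list(NULL,
#'   c("tx", "ty", "tz", "pitch", "roll", "yaw")))
#' err[, "pitch"] <- 1.2
#' treatment_course("P001", err)
#' @export
treatment_course <- function(patient_id, errors) {
  if (is.list(errors) && !is.data.frame(errors))
    errors <- do.call(rbind, lapply(errors, function(e) unclass(as_setup_error(e))))
  errors <- as.matrix(errors)
  if (is.null(colnames(errors)) && ncol(errors) == 6L) colnames(errors) <- AXES
  if (!all(AXES %in% colnames(errors)))
    stop("'errors' must have columns ", paste(AXES, collapse = ", "),
         call. = FALSE)
  errors <- errors[, AXES, drop = FALSE]
  storage.mode(errors) <- "double"
  if (nrow(errors) < 1L)
    stop("a treatment course needs at least one fraction", call. = FALSE)
  if (any(!is.finite(errors)))
    stop("non-finite setup error in course for patient ", patient_id,
         call. = FALSE)
  rownames(errors) <- NULL
  structure(
    list(patient_id = as.character(patient_id)[1L],
         n_fractions = nrow(errors),
         errors = errors),
    class = "treatment_course")
}

#' @export
print.treatment_course <- function(x, ...) {
  cat("Treatment course: patient", x$patient_id, "-", x$n_fractions,
      "fractions\n")
  cat("  per-axis mean:",
      paste(sprintf("%s=%.2f", AXES, colMeans(x$errors)), collapse = " "),
      "\n")
  invisible(x)
}

# Internal: extract the n x 6 error/residual matrix from either course type.
course_matrix <- function(x) {
  if (inherits(x, "treatment_course")) return(x$errors)
  if (inherits(x, "residual_course")) return(x$residuals)
  stop("expected a treatment_course or residual_course", call. = FALSE)
}
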