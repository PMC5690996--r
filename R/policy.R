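POLICY_NAMES <- c("none", "online", "nal", "enal", "enal_pp")

#' Define a setup-correction policy
#'
#' A policy pairs an imaging schedule with a rule mapping measured setup
#' errors to the correction applied at each fraction:
#'
#' * `none` — no imaging, no correction (laser setup only).
#' * `online` — daily imaging; every fraction corrected before treatment.
#' * `nal` — no action level: image the first `nal_length` fractions, correct
#'   all later fractions by the negated mean of those measurements.
#' * `enal` — extended NAL: like NAL, plus weekly follow-up images (fractions
#'   `followup_start`, `followup_start + followup_interval`, ...). After each
#'   follow-up the correction is refreshed from a running linear
#'   least-squares fit of all measurements: `C_k = -(S_k + a_k * f_k)` with
#'   `S_k` the intercept, `a_k` the slope, `f_k` the latest measured
#'   fraction. The refreshed correction takes effect at fraction `f_k + 1`.
#' * `enal_pp` — eNAL++: the eNAL schedule and fit, but every imaged fraction
#'   (including the first `nal_length`) is corrected online on the day, so
#'   off-line corrections apply only to non-imaged fractions.
#'
#' Rotational corrections are clipped per-axis to `couch_limit_deg`, the
#' rotational travel of clinical 6DoF couches (3 degrees); translations are
#' not clipped.
#'
#' @param name One of `"none"`, `"online"`, `"nal"`, `"enal"`, `"enal_pp"`.
#' @param nal_length Number of initial measured fractions (default 3).
#' @param followup_start Fraction index of the first follow-up image
#'   (default 8); must exceed `nal_length`.
#' @param followup_interval Fractions between follow-ups (default 5).
#' @param couch_limit_deg Maximum |rotation| correction per axis in degrees
#'   (default 3).
#' @param clip_enabled Clip rotational corrections to the couch limit
#'   (default `TRUE`).
#' @return An object of class `correction_policy`.
#' @examples
#' correction_policy("enal")
#' imaging_schedule(correction_policy("enal"), 30)
#' @export
correction_policy <- function(name,
                              nal_length = 3L,
                              followup_start = 8L,
                              followup_interval = 5L,
                              couch_limit_deg = 3,
                              clip_enabled = TRUE) {
  name <- match.arg(name, POLICY_NAMES)
  nal_length <- as.integer(nal_length)
  followup_start <- as.integer(followup_start)
  followup_interval <- as.integer(followup_interval)
  if (is.na(nal_length) || nal_length < 1L)
    stop("nal_length must be >= 1", call. = FALSE)
  if (is.na(followup_start) || followup_start <= nal_length)
    stop("followup_start must exceed nal_length", call. = FALSE)
  if (is.na(followup_interval) || followup_interval < 1L)
    stop("followup_interval must be >= 1", call. = FALSE)
  if (!is.finite(couch_limit_deg) || couch_limit_deg <= 0)
    stop("couch_limit_deg must be > 0", call. = FALSE)
  structure(
    list(name = name, nal_length = nal_length,
         followup_start = followup_start,
         followup_interval = followup_interval,
         couch_limit_deg = couch_limit_deg,
         clip_enabled = isTRUE(clip_enabled)),
    class = "correction_policy")
}

as_policy <- function(x) {
  if (inherits(x, "correction_policy")) return(x)
  if (is.character(x) && length(x) == 1L) return(correction_policy(x))
  stop("expected a correction_policy or a policy name", call. = FALSE)
}

#' @export
print.correction_policy <- function(x, ...) {
  cat("Correction policy:", x$name, "\n")
  if (x$name %in% c("nal", "enal", "enal_pp"))
    cat("  initial fractions:", x$nal_length,
        if (x$name != "nal")
          sprintf("| follow-ups: %d, %d, ... (every %d)", x$followup_start,
                  x$followup_start + x$followup_interval, x$followup_interval)
        else "",
        "\n")
  cat("  rotation clip:",
      if (x$clip_enabled) sprintf("+/- %g deg", x$couch_limit_deg) else "off",
      "\n")
  invisible(x)
}

#' Imaging schedule of a policy
#'
#' Fractions at which a CBCT is acquired under a policy. For eNAL/eNAL++ with
#' defaults and a 30-fraction course this is `{1, 2, 3, 8, 13, 18, 23, 28}` —
#' eight CBCTs per course.
#'
#' @param policy A [correction_policy()] or policy name.
#' @param n_fractions Course length (>= 1).
#' @return Sorted integer vector of imaged fraction indices (possibly empty).
#' @export
imaging_schedule <- function(policy, n_fractions) {
  policy <- as_policy(policy)
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L)
    stop("n_fractions must be >= 1", call. = FALSE)
  switch(policy$name,
    none = integer(0),
    online = seq_len(n_fractions),
    nal = seq_len(min(policy$nal_length, n_fractions)),
    enal = ,
    enal_pp = {
      initial <- seq_len(min(policy$nal_length, n_fractions))
      followups <- if (policy$followup_start <= n_fractions)
        seq.int(policy$followup_start, n_fractions, by = policy$followup_interval)
      else integer(0)
      sort(unique(c(initial, followups)))
    })
}

#' Imaging workload of a policy
#'
#' Number of CBCTs required per course and the percentage reduction relative
#' to daily online imaging. Off-line protocols need 70-90% fewer scans: NAL
#' images 3 of 30 fractions (90% reduction), eNAL/eNAL++ image 8 of 30
#' (73.3% reduction).
#'
#' @inheritParams imaging_schedule
#' @return List with `n_cbct` and `reduction_vs_online` (percent).
#' @examples
#' workload("enal_pp", 30)
#' @export
workload <- function(policy, n_fractions) {
  n_cbct <- length(imaging_schedule(policy, n_fractions))
  list(n_cbct = n_cbct,
       reduction_vs_online = 100 * (n_fractions - n_cbct) / n_fractions)
}

#' NAL correction from the initial measured fractions
#'
#' The no-action-level correction is the negated per-axis mean of the
#' measured errors at the first `nal_length` fractions; it is applied
#' unchanged to every subsequent fraction.
#'
#' @param measured Numeric vector (one axis) or matrix (fractions x axes) of
#'   measured setup errors at the initial fractions.
#' @param nal_length Required number of measurements (default `nrow`/length
#'   of `measured`).
#' @return Correction with the same axis structure as the input (the value
#'   ADDED to the raw error, so a perfect correction is the negated error).
#' @examples
#' nal_correction(c(1, 2, 3)) # -2
#' @export
nal_correction <- function(measured, nal_length = NULL) {
  m <- if (is.matrix(measured)) measured else matrix(measured, ncol = 1L)
  if (!is.null(nal_length) && nrow(m) != nal_length)
    stop("course too short: need exactly ", nal_length,
         " initial measurements, got ", nrow(m), call. = FALSE)
  if (nrow(m) < 1L) stop("no measurements supplied", call. = FALSE)
  corr <- -colMeans(m)
  if (is.matrix(measured)) corr else unname(corr)
}

#' Running least-squares fit of measured setup errors
#'
#' Fits `e_i = S_k + a_k * f_i` by ordinary least squares over the measured
#' fractions, per axis. With fewer than two points (or coincident fraction
#' indices) the fit is degenerate: the slope is forced to 0 and the
#' intercept is the mean.
#'
#' @param fractions Strictly increasing integer fraction indices.
#' @param values Numeric vector (one axis) or matrix (length(fractions) x
#'   axes) of measured errors.
#' @return List of class `enal_fit`: `S_k` (intercept), `a_k` (slope per
#'   fraction), `f_k` (latest measured fraction), `n_points`.
#' @examples
#' enal_fit(c(1, 2, 3, 8), 0.5 + 0.1 * c(1, 2, 3, 8))
#' @export
enal_fit <- function(fractions, values) {
  f <- as.numeric(fractions)
  if (length(f) < 1L) stop("no measurements to fit", call. = FALSE)
  if (any(diff(f) <= 0))
    stop("fraction indices must be strictly increasing", call. = FALSE)
  y <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  if (nrow(y) != length(f))
    stop("lengths of fractions and values differ", call. = FALSE)
  n <- length(f)
  fbar <- mean(f)
  ss_f <- sum((f - fbar)^2)
  if (n < 2L || ss_f == 0) {
    a <- rep(0, ncol(y))
    s <- colMeans(y)
  } else {
    a <- colSums((f - fbar) * sweep(y, 2L, colMeans(y))) / ss_f
    s <- colMeans(y) - a * fbar
  }
  if (!is.matrix(values)) { a <- unname(a); s <- unname(s) }
  structure(list(S_k = s, a_k = a, f_k = max(f), n_points = n),
            class = "enal_fit")
}

#' Correction from a running fit
#'
#' The eNAL update rule: the fit evaluated at the latest measured fraction,
#' negated — `C_k = -(S_k + a_k * f_k)` — held constant for subsequent
#' fractions until the next measurement refreshes the fit. With zero slope
#' this reduces to the NAL-style running-mean correction.
#'
#' @param fit An [enal_fit()] result.
#' @return Per-axis correction (value added to the raw error).
#' @examples
#' enal_correction(enal_fit(c(1, 2, 3, 8), 0.5 + 0.1 * c(1, 2, 3, 8))) # -1.3
#' @export
enal_correction <- function(fit) {
  if (!inherits(fit, "enal_fit")) stop("expected an enal_fit", call. = FALSE)
  -(fit$S_k + fit$a_k * fit$f_k)
}

# Clip the rotational components of a 6-axis correction to the couch limit.
clip_correction <- function(corr, policy) {
  if (!policy$clip_enabled) return(corr)
  lim <- policy$couch_limit_deg
  corr[ROT_AXES] <- pmin(pmax(corr[ROT_AXES], -lim), lim)
  corr
}

#' Apply a correction policy to a treatment course
#'
#' Replays a policy over a course of raw (pre-correction) setup errors and
#' returns the per-fraction residuals: residual = raw error + correction in
#' force at that fraction. Protocol measurements are the raw post-setup
#' errors at imaged fractions.
#'
#' * `none`: residual = raw error everywhere; no imaging.
#' * `online`: every fraction imaged and corrected; the residual is a draw
#'   from the online-residual noise model (exactly zero when `online_sd` is
#'   `NULL`), representing couch accuracy and intrafraction motion.
#' * `nal`: fractions `1..nal_length` uncorrected; later fractions receive
#'   the fixed NAL correction.
#' * `enal`: fractions `1..nal_length` uncorrected; the NAL correction
#'   applies from the next fraction through the first follow-up; after each
#'   follow-up `f_k` the running fit of all measurements so far yields
#'   `C_k = -(S_k + a_k * f_k)`, effective from fraction `f_k + 1` (a
#'   measurement cannot correct its own fraction off-line).
#' * `enal_pp`: same off-line correction stream as eNAL, computed from the
#'   raw measurements, but every imaged fraction is online-corrected instead
#'   (its residual is an online-noise draw).
#'
#' Rotational corrections are clipped to the couch limit when enabled.
#'
#' @param course A [treatment_course()].
#' @param policy A [correction_policy()] or policy name.
#' @param online_sd Online-residual noise SD: `NULL` for exact-zero online
#'   residuals, a single number applied to all six axes, or a named
#'   length-6 vector (mm for translations, degrees for rotations). Default
#'   0.2 (couch positioning accuracy is 0.2 mm / 0.2 deg) when drawing.
#' @param seed Optional integer; when given, noise draws use a local RNG
#'   seeded with it (the global RNG state is untouched).
#' @return Object of class `residual_course`: `patient_id`, `residuals`
#'   (n x 6), logical flags `imaged` and `online_corrected`, the applied
#'   off-line `corrections` (n x 6, for audit), and `n_cbct`.
#' @examples
#' crs <- treatment_course("P1", matrix(rep(c(0, 0, 0, 1, 0.5, -0.25),
#'   each = 30), nrow = 30, dimnames = list(NULL, c("tx", "ty", "tz",
#'   "pitch", "roll", "yaw"))))
#' res <- apply_policy(crs, "nal")
#' res$residuals[4, ] # exactly zero: constant error is fully corrected
#' @export
apply_policy <- function(course, policy, online_sd = NULL, seed = NULL) {
  if (!inherits(course, "treatment_course"))
    stop("expected a treatment_course", call. = FALSE)
  policy <- as_policy(policy)
  n <- course$n_fractions
  e <- course$errors
  if (policy$name %in% c("nal", "enal", "enal_pp") && n < policy$nal_length)
    stop("course for patient ", course$patient_id, " has ", n,
         " fractions; policy '", policy$name, "' needs at least ",
         policy$nal_length, call. = FALSE)
  sd6 <- expand_online_sd(online_sd)

  sched <- imaging_schedule(policy, n)
  imaged <- seq_len(n) %in% sched
  online <- switch(policy$name,
                   none = , nal = , enal = rep(FALSE, n),
                   online = rep(TRUE, n),
                   enal_pp = imaged)

  corrections <- matrix(0, n, 6L, dimnames = list(NULL, AXES))
  if (policy$name %in% c("nal", "enal", "enal_pp")) {
    current <- rep(0, 6L); names(current) <- AXES
    for (f in seq_len(n)) {
      corrections[f, ] <- current
      if (imaged[f] && f >= policy$nal_length) {
        meas <- sched[sched <= f]
        if (f == policy$nal_length) {
          # initial correction: negated mean of the first measured fractions
          current <- nal_correction(e[meas, , drop = FALSE])
        } else if (policy$name != "nal") {
          fit <- enal_fit(meas, e[meas, , drop = FALSE])
          current <- enal_correction(fit)
        }
        current <- clip_correction(current, policy)
      }
    }
  }

  residuals <- e + corrections
  if (any(online)) {
    draw <- function() {
      noise <- matrix(0, sum(online), 6L, dimnames = list(NULL, AXES))
      if (!is.null(sd6))
        for (j in seq_len(6L))
          if (sd6[j] > 0) noise[, j] <- stats::rnorm(sum(online), 0, sd6[j])
      noise
    }
    noise <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    residuals[online, ] <- noise
  }

  structure(
    list(patient_id = course$patient_id,
         policy = policy$name,
         residuals = residuals,
         imaged = imaged,
         online_corrected = online,
         corrections = corrections,
         n_cbct = sum(imaged)),
    class = "residual_course")
}

# Normalize the online-residual SD spec to a named length-6 vector (or NULL
# for exact zeros).
expand_online_sd <- function(online_sd) {
  if (is.null(online_sd)) return(NULL)
  if (any(!is.finite(online_sd)) || any(online_sd < 0))
    stop("online_sd must be finite and non-negative", call. = FALSE)
  if (length(online_sd) == 1L) {
    sd6 <- rep(as.numeric(online_sd), 6L)
  } else if (length(online_sd) == 6L) {
    sd6 <- as.numeric(if (!is.null(names(online_sd))) online_sd[AXES] else online_sd)
    if (any(is.na(sd6)))
      stop("named online_sd must cover all of: ", paste(AXES, collapse = ", "),
           call. = FALSE)
  } else {
    stop("online_sd must have length 1 or 6", call. = FALSE)
  }
  names(sd6) <- AXES
  sd6
}

#' @export
print.residual_course <- function(x, ...) {
  cat("Residual course: patient", x$patient_id, "| policy", x$policy,
      "|", length(x$imaged), "fractions,", x$n_cbct, "CBCTs,",
      sum(x$online_corrected), "online-corrected\n")
  invisible(x)
}
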