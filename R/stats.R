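#' Per-patient systematic setup error
#'
#' A patient's systematic setup error is the per-axis mean of their setup
#' errors over all fractions of the course (raw or residual).
#'
#' @param x A [treatment_course()] or residual course from [apply_policy()].
#' @return Named numeric vector of per-axis means (mm / deg).
#' @export
patient_systematic <- function(x) {
  m <- course_matrix(x)
  if (nrow(m) < 1L) stop("empty course", call. = FALSE)
  colMeans(m)
}

#' Per-patient random setup error
#'
#' The day-to-day scatter of a patient's setup error about their own mean:
#' the per-axis sample standard deviation (denominator n-1) over fractions.
#'
#' @inheritParams patient_systematic
#' @return Named numeric vector of per-axis sample SDs.
#' @export
patient_random_sd <- function(x) {
  m <- course_matrix(x)
  if (nrow(m) < 2L)
    stop("need at least 2 fractions for a per-patient SD", call. = FALSE)
  apply(m, 2L, stats::sd)
}

#' Decompose a population of courses into systematic and random components
#'
#' The standard population decomposition of setup errors, applied per axis:
#'
#' * `mu` — population mean: mean over patients of the per-patient
#'   systematic errors `S_p`;
#' * `Sigma` — SD of the systematic error: sample SD (n-1) of `S_p` over
#'   patients;
#' * `sigma` — random error: RMS over patients of the per-patient sample SDs.
#'
#' All fractions of each course enter the decomposition, including the
#' uncorrected initial fractions of NAL/eNAL courses.
#'
#' @param courses List of [treatment_course()] or residual courses.
#' @return Object of class `population_stats`: named per-axis vectors `mu`,
#'   `Sigma`, `sigma`, plus `range_S` (per-axis min-max of the per-patient
#'   systematic errors), `n_patients` and `mean_n_cbct` (NA for raw courses).
#' @examples
#' courses <- lapply(1:3, function(i) treatment_course(i,
#'   matrix(i, 5, 6, dimnames = list(NULL,
#'     c("tx", "ty", "tz", "pitch", "roll", "yaw")))))
#' decompose_population(courses)
#' @export
decompose_population <- function(courses) {
  if (!is.list(courses) || length(courses) < 2L)
    stop("need at least 2 patients to estimate Sigma; got ",
         length(courses), call. = FALSE)
  nf <- vapply(courses, function(x) nrow(course_matrix(x)), integer(1))
  if (any(nf < 2L))
    stop("need at least 2 fractions per patient to estimate sigma; patient ",
         which(nf < 2L)[1L], " has ", min(nf), call. = FALSE)
  s <- t(vapply(courses, patient_systematic, numeric(6)))
  sds <- t(vapply(courses, patient_random_sd, numeric(6)))
  n_cbct <- vapply(courses, function(x)
    if (inherits(x, "residual_course")) as.numeric(x$n_cbct) else NA_real_,
    numeric(1))
  structure(
    list(mu = colMeans(s),
         Sigma = apply(s, 2L, stats::sd),
         sigma = sqrt(colMeans(sds^2)),
         range_S = apply(s, 2L, range),
         n_patients = length(courses),
         mean_n_cbct = mean(n_cbct)),
    class = "population_stats")
}

#' @export
print.population_stats <- function(x, digits = 3, ...) {
  cat("Population setup-error decomposition (", x$n_patients, " patients",
      if (!is.na(x$mean_n_cbct))
        sprintf(", mean %.1f CBCTs/patient", x$mean_n_cbct), "):\n", sep = "")
  print(round(rbind(mu = x$mu, Sigma = x$Sigma, sigma = x$sigma), digits))
  invisible(x)
}

#' @export
as.data.frame.population_stats <- function(x, ...) {
  data.frame(axis = AXES,
             unit = c(rep("mm", 3), rep("deg", 3)),
             mu = unname(x$mu),
             Sigma = unname(x$Sigma),
             sigma = unname(x$sigma),
             S_min = x$range_S[1L, ],
             S_max = x$range_S[2L, ],
             row.names = NULL)
}

#' Compare correction policies on one population
#'
#' Applies each policy to every course of a population and decomposes the
#' residuals, yielding the accuracy-versus-workload table: per policy and
#' axis, the residual `mu`, `Sigma` (systematic) and `sigma` (random), the
#' mean CBCT count and the imaging reduction relative to daily online.
#'
#' @param population List of [treatment_course()] objects.
#' @param policies Character vector of policy names and/or a list of
#'   [correction_policy()] objects.
#' @param online_sd Online-residual noise SD passed to [apply_policy()]
#'   (default 0.2 on all axes; `NULL` for exact-zero online residuals).
#' @param seed Optional integer seed; all noise draws flow from it and the
#'   result is reproducible.
#' @return Long-format data frame: one row per policy x axis with columns
#'   `policy, axis, unit, mu, Sigma, sigma, mean_n_cbct, reduction_pct`.
#' @examples
#' pop <- simulate_population(simulation_config(n_patients = 5, seed = 7))
#' compare_protocols(pop, c("none", "nal"), online_sd = NULL)
#' @export
compare_protocols <- function(population,
                              policies = c("none", "nal", "enal",
                                           "enal_pp", "online"),
                              online_sd = 0.2,
                              seed = NULL) {
  if (!is.list(population) || !length(population))
    stop("empty population", call. = FALSE)
  if (!is.list(policies)) policies <- as.list(policies)
  run <- function() {
    rows <- lapply(policies, function(pol) {
      pol <- as_policy(pol)
      res <- lapply(population, apply_policy, policy = pol,
                    online_sd = online_sd)
      st <- decompose_population(res)
      nf <- mean(vapply(population, function(x) x$n_fractions, numeric(1)))
      cbind(data.frame(policy = pol$name), as.data.frame(st)[, 1:5],
            mean_n_cbct = st$mean_n_cbct,
            reduction_pct = 100 * (nf - st$mean_n_cbct) / nf)
    })
    do.call(rbind, rows)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  rownames(out) <- NULL
  out
}
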