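#' Calibrate raw latent utility scores onto EQ-5D-3L anchors
#'
#' Affine rescaling of raw latent health scores onto the utility scale
#' spanned by the worst (-0.53) and best (1.00) values of the French
#' EQ-5D-3L social value set:
#' \deqn{\hat U_{EQ5D} = \frac{\hat U_{RAW} - \min \hat U_{RAW}}
#'   {\max \hat U_{RAW} - \min \hat U_{RAW}} \times (1 + 0.53) - 0.53.}
#' The minimum maps to -0.53 exactly and the maximum to 1.00 exactly; the
#' map is strictly increasing, so the ranking of scores is preserved.
#'
#' The anchoring min/max are taken over the raw scores supplied in `anchors`
#' (by default `raw` itself): freeze them once over all assessment records
#' and reuse the same anchors when calibrating model predictions later.
#'
#' @param raw numeric vector of raw latent scores (e.g. EAP estimates).
#' @param anchors numeric vector whose range defines the calibration
#'   (default `raw`).
#' @param worst,best target anchors (default -0.53 and 1.00, the French
#'   EQ-5D-3L extremes).
#' @return numeric vector of calibrated utilities in `[worst, best]` when
#'   `raw` lies within the anchor range.
#' @examples
#' calibrate_utility(c(-2, 0, 2))   # -0.53, 0.235, 1.00
#' @export
calibrate_utility <- function(raw, anchors = raw, worst = -0.53, best = 1.00) {
  rng <- range(anchors, na.rm = TRUE)
  if (!is.finite(rng[1]) || !is.finite(rng[2]) || rng[2] <= rng[1])
    stop("degenerate raw score scale: max must exceed min")
  (raw - rng[1]) / (rng[2] - rng[1]) * (best - worst) + worst
}

#' Daily linear interpolation of utility between assessments
#'
#' Builds a per-patient daily utility trajectory by linear interpolation
#' between all assessment records, from the first to the last record day of
#' the patient (across separate post-acute stays); no extrapolation beyond
#' that span. Duplicate same-day records are averaged before interpolation,
#' so multiple stays touching the same day collapse to one node.
#'
#' @param days integer vector of assessment days.
#' @param utility numeric vector of calibrated utilities, same length.
#' @return data frame with `day` (consecutive integers from first to last
#'   record day) and `utility`. A single record yields a single-day
#'   trajectory.
#' @export
interpolate_daily <- function(days, utility) {
  stopifnot(length(days) == length(utility), length(days) >= 1L)
  ok <- !is.na(days) & !is.na(utility)
  days <- days[ok]; utility <- utility[ok]
  if (length(days) == 0L) stop("no usable assessment records")
  u <- tapply(utility, days, mean)
  d <- as.integer(names(u))
  o <- order(d)
  d <- d[o]; u <- as.numeric(u[o])
  if (length(d) == 1L) return(data.frame(day = d, utility = u))
  grid <- seq.int(d[1], d[length(d)])
  data.frame(day = grid,
             utility = stats::approx(d, u, xout = grid, method = "linear")$y)
}

#' Daily utility trajectories for all patients
#'
#' Applies [interpolate_daily()] per patient to a long table of calibrated
#' assessment-level utilities.
#'
#' @param scored data frame with columns `patient_id`, `day`, `utility`.
#' @return data frame with columns `patient_id`, `day`, `utility`, one row
#'   per patient-day covered by that patient's records.
#' @export
build_trajectories <- function(scored) {
  stopifnot(all(c("patient_id", "day", "utility") %in% names(scored)))
  parts <- lapply(split(scored, scored$patient_id), function(df) {
    tr <- interpolate_daily(df$day, df$utility)
    cbind(patient_id = df$patient_id[1], tr)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
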