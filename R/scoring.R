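#' Widespread Pain Index
#'
#' Counts the body regions (out of 19) marked painful in the preceding week.
#'
#' @param regions logical vector of length 19.
#' @return integer WPI score, 0-19.
#' @export
score_wpi <- function(regions) {
  if (length(regions) != 19L) {
    stop("WPI requires exactly 19 region flags", call. = FALSE)
  }
  regions <- as.logical(regions)
  if (anyNA(regions)) stop("WPI region flags must be TRUE/FALSE", call. = FALSE)
  sum(regions)
}

#' Symptom Severity Index
#'
#' Sum of three severity items (fatigue, waking unrefreshed, cognitive
#' symptoms; each 0-3) plus one point for each of three dichotomous symptoms
#' (headaches, lower-abdominal pain or cramps, depression).
#'
#' @param severity integer vector of length 3, each item 0-3.
#' @param binary logical vector of length 3.
#' @return integer SSI score, 0-12.
#' @export
score_ssi <- function(severity, binary) {
  if (length(severity) != 3L || length(binary) != 3L) {
    stop("SSI requires 3 severity items and 3 binary items", call. = FALSE)
  }
  if (any(severity != round(severity)) || any(severity < 0) ||
      any(severity > 3)) {
    stop("SSI severity items must be integers in 0-3", call. = FALSE)
  }
  binary <- as.logical(binary)
  if (anyNA(binary)) stop("SSI binary items must be TRUE/FALSE", call. = FALSE)
  sum(severity) + sum(binary)
}

#' ACR 2016 fibromyalgia criteria
#'
#' A participant meets the criteria when pain is generalised (at least 4 of 5
#' body regions), symptoms have persisted at a similar level for at least
#' three months, and the severity scores satisfy either WPI >= 7 with
#' SSI >= 5, or WPI 4-6 with SSI >= 9.
#'
#' @param wpi Widespread Pain Index, 0-19.
#' @param ssi Symptom Severity Index, 0-12.
#' @param generalised_pain logical; pain in at least 4 of 5 regions.
#' @param symptoms_3_months logical; symptoms present for at least 3 months.
#' @return logical. Vectorised over all four arguments.
#' @export
meets_acr_2016 <- function(wpi, ssi, generalised_pain, symptoms_3_months) {
  if (any(wpi < 0 | wpi > 19)) stop("WPI out of range 0-19", call. = FALSE)
  if (any(ssi < 0 | ssi > 12)) stop("SSI out of range 0-12", call. = FALSE)
  score_ok <- (wpi >= 7 & ssi >= 5) | (wpi >= 4 & wpi <= 6 & ssi >= 9)
  as.logical(generalised_pain) & as.logical(symptoms_3_months) & score_ok
}

#' Small-fibre-neuropathy screening score
#'
#' Total of 8 symptom-frequency items (0-4) and 13 seriousness items (0-5).
#' Totals below 11 indicate no small-fibre neuropathy and totals above 48
#' indicate small-fibre neuropathy; both cut-offs are strict, so totals of
#' exactly 11 or 48 are indeterminate.
#'
#' @param frequency integer vector of length 8, items 0-4.
#' @param seriousness integer vector of length 13, items 0-5.
#' @return list with `total` and `category`
#'   (`"none"`, `"indeterminate"`, or `"sfn"`).
#' @export
score_sfn <- function(frequency, seriousness) {
  if (length(frequency) != 8L || length(seriousness) != 13L) {
    stop("SFN requires 8 frequency and 13 seriousness items", call. = FALSE)
  }
  if (any(frequency != round(frequency)) || any(frequency < 0) ||
      any(frequency > 4)) {
    stop("SFN frequency items must be integers in 0-4", call. = FALSE)
  }
  if (any(seriousness != round(seriousness)) || any(seriousness < 0) ||
      any(seriousness > 5)) {
    stop("SFN seriousness items must be integers in 0-5", call. = FALSE)
  }
  total <- sum(frequency) + sum(seriousness)
  category <- if (total < 11) "none" else if (total > 48) "sfn" else
    "indeterminate"
  list(total = total, category = category)
}

#' Pain Catastrophizing Scale total
#'
#' @param items integer vector of length 13, each item 0-4.
#' @return integer total, 0-52.
#' @export
score_pcs <- function(items) {
  if (length(items) != 13L) stop("PCS requires 13 items", call. = FALSE)
  if (any(items != round(items)) || any(items < 0) || any(items > 4)) {
    stop("PCS items must be integers in 0-4", call. = FALSE)
  }
  sum(items)
}

#' Pressure pain threshold from repeated readings
#'
#' A site's pressure pain threshold is the arithmetic mean of three successive
#' algometer readings.
#'
#' @param readings numeric vector of exactly 3 positive readings in kPa.
#' @return mean threshold in kPa.
#' @export
ppt_from_readings <- function(readings) {
  if (length(readings) != 3L) {
    stop("PPT requires exactly 3 readings", call. = FALSE)
  }
  if (any(readings <= 0)) stop("PPT readings must be positive", call. = FALSE)
  mean(readings)
}
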