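#' @include AllClasses.R
NULL

#' Fit a headspace-DMS calibration curve
#'
#' Ordinary least-squares line \code{response = slope * amount +
#' intercept} through the calibration standards (an eight-point series in
#' routine use; at least three distinct amounts are required).
#'
#' @param standards data.frame with columns \code{amount} (nmol DMS) and
#'   \code{response} (instrument units).
#' @param detectionLimit Headspace DMS detection limit in nmol (default
#'   0.015).
#' @return A \linkS4class{CalibrationCurve}.
#' @export
#' @examples
#' fitCalibration(data.frame(amount = 1:4, response = 2 * (1:4)))
fitCalibration <- function(standards, detectionLimit = 0.015) {
  stopifnot(all(c("amount", "response") %in% colnames(standards)))
  if (nrow(standards) < 3L || length(unique(standards$amount)) < 3L)
    stop("calibration requires >= 3 standards with distinct amounts")
  fit <- lm(response ~ amount, data = standards)
  ssRes <- sum(residuals(fit)^2)
  ssTot <- sum((standards$response - mean(standards$response))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else NA_real_
  new("CalibrationCurve", standards = standards,
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      rSquared = min(max(r2, 0), 1), detectionLimit = detectionLimit)
}

#' Quantify DMSP from headspace-DMS responses
#'
#' Inverts the calibration line to a DMS amount per replicate, censors
#' amounts below the detection limit, and converts to concentration per
#' sample mass (nmol per g, or per L for seawater volumes).  Because no
#' correction for endogenous DMS is applied, results represent total DMSP
#' plus endogenous DMS.
#'
#' @param responses Numeric vector of replicate instrument responses.
#' @param curve A \linkS4class{CalibrationCurve}.
#' @param mass Sample mass in g (or volume in L).
#' @return data.frame with \code{response, amount, censored,
#'   concentration} (concentration NA where censored).
#' @export
quantifyDmsp <- function(responses, curve, mass) {
  stopifnot(is(curve, "CalibrationCurve"), mass > 0)
  if (curve@slope == 0) stop("degenerate calibration: slope is zero")
  amount <- (responses - curve@intercept) / curve@slope
  censored <- amount < curve@detectionLimit
  data.frame(response = responses, amount = amount, censored = censored,
             concentration = ifelse(censored, NA_real_, amount / mass))
}

#' Summarize replicate DMSP measurements
#'
#' @param quant data.frame from \code{\link{quantifyDmsp}}.
#' @return List with \code{mean}, \code{sd} (over uncensored replicates)
#'   and \code{nCensored}.
#' @export
summarizeDmsp <- function(quant) {
  conc <- quant$concentration[!quant$censored]
  list(mean = if (length(conc)) mean(conc) else NA_real_,
       sd = if (length(conc) > 1L) sd(conc) else NA_real_,
       nCensored = sum(quant$censored))
}

#' Fold ratio of DMSP between environment groups
#'
#' Arithmetic mean of per-site DMSP means in group A divided by the same
#' in group B.  Sediment (nmol per g) and seawater (nmol per L) values are
#' never mixed in one ratio unless \code{unitBridge = TRUE}.
#'
#' @param measurements data.frame with columns \code{site, environment,
#'   dmspMean, unit}; one row per site measurement series.
#' @param groupA,groupB Character vectors of environment labels.
#' @param unitBridge Allow mixing units (default FALSE).
#' @return The fold ratio (group A mean / group B mean).
#' @export
#' @examples
#' m <- data.frame(site = c("a", "b"), environment = c("x", "y"),
#'                 dmspMean = c(10, 5), unit = "nmol/g")
#' environmentRatio(m, "x", "y")
environmentRatio <- function(measurements, groupA, groupB,
                             unitBridge = FALSE) {
  a <- measurements[measurements$environment %in% groupA, , drop = FALSE]
  b <- measurements[measurements$environment %in% groupB, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("grouping error: both groups must be non-empty")
  if (!unitBridge && length(unique(c(a$unit, b$unit))) > 1L)
    stop("groups mix units (", paste(unique(c(a$unit, b$unit)),
         collapse = " vs "), "); set unitBridge = TRUE to override")
  denom <- mean(b$dmspMean)
  if (denom <= 0) stop("grouping error: group B mean must be positive")
  mean(a$dmspMean) / denom
}

#' Packaged field measurements of sediment DMSP standing stock
#'
#' Per-site mean (+/- sd) DMSP concentrations for Yellow Sea and Bohai Sea
#' sediment sites, Okinawa Trough hydrothermal sediment and polymetallic
#' sulfide, and literature seawater values, as shipped in
#' \code{inst/extdata/table1_dmsp.tsv}.
#'
#' @return data.frame with columns \code{site, environment, fraction}
#'   (total for the alkaline-lysis sediment assays; DMSPd/DMSPp for the
#'   literature seawater values), \code{dmspMean, dmspSd, unit}.
#' @export
#' @examples
#' head(loadFieldDmsp())
loadFieldDmsp <- function() {
  read.delim(system.file("extdata", "table1_dmsp.tsv",
                         package = "sulfurCensus"),
             stringsAsFactors = FALSE)
}

#' Read calibration standards / measurement TSVs
#'
#' @param path TSV path: standards need \code{amount, response};
#'   measurements need \code{site, environment, mass, response} (one row
#'   per replicate).
#' @return data.frame.
#' @export
readStandards <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' @rdname readStandards
#' @export
readMeasurements <- function(path) read.delim(path, stringsAsFactors = FALSE)
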