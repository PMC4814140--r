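# Stopped-flow and yeast-assay kinetics: single-exponential rate fitting,
# rate-vs-gradient regression, NH3/NH4+ speciation, background correction,
# and specificity ratios with propagated errors.
#
# Rate conventions follow the yeast transport table: ammonia rates are
# reported in units of 1e-2 s^-1 and water rates in s^-1; the specificity
# ratio is corrected_ammonia / corrected_water in those units (i.e. the
# printed "x 1e-2" ratio).

#' Construct a stopped-flow trace
#'
#' @param times Time points in seconds, strictly increasing, >= 10 points.
#' @param signal Detector signal (arbitrary units: scattering or
#'   fluorescence).
#' @param channel "scattering" or "fluorescence".
#' @param meta Optional named list (construct id, LPR, gradient, ...).
#' @return Object of class \code{sf_trace}.
#' @export
sf_trace <- function(times, signal, channel = c("scattering", "fluorescence"),
                     meta = list()) {
  channel <- match.arg(channel)
  if (length(times) < 10) stop("a trace needs at least 10 points")
  if (any(diff(times) <= 0)) stop("trace times must be strictly increasing")
  if (length(signal) != length(times)) stop("times/signal length mismatch")
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 channel = channel, meta = meta), class = "sf_trace")
}

#' Fit a single-exponential rate to a stopped-flow trace
#'
#' Fits s(t) = A (1 - exp(-k t)) + c for rising traces or
#' s(t) = A exp(-k t) + c for falling traces (direction auto-detected from
#' the trend), by Levenberg-Marquardt least squares.  Points before
#' \code{dead_time} are excluded.
#'
#' @param trace An \code{sf_trace} (or list with \code{times},
#'   \code{signal}).
#' @param dead_time Instrument dead time in seconds; earlier points are
#'   dropped.
#' @return Object of class \code{rate_fit}: list with \code{k} (s^-1),
#'   \code{k_stderr}, \code{amplitude}, \code{offset}, \code{r_squared},
#'   \code{direction} and \code{flags} (e.g. "degenerate" for flat traces,
#'   fitted as k = 0 with infinite standard error).
#' @export
fit_single_exponential <- function(trace, dead_time = 0) {
  keep <- trace$times >= dead_time
  t <- trace$times[keep] - dead_time
  s <- trace$signal[keep]
  if (length(t) < 5) stop("too few points after dead-time exclusion")
  n <- length(t)
  head_m <- mean(s[seq_len(max(3, n %/% 10))])
  tail_m <- mean(s[(n - max(3, n %/% 10) + 1):n])
  if (sd(s) < 1e-12 * max(abs(s), 1) || abs(tail_m - head_m) < 1e-12) {
    warning("trace is flat; returning k = 0 with infinite standard error")
    return(structure(list(k = 0, k_stderr = Inf, amplitude = 0,
                          offset = mean(s), r_squared = 0,
                          direction = "flat", flags = "degenerate"),
                     class = "rate_fit"))
  }
  rising <- tail_m > head_m
  # log-linear start value for k from the residual decay toward the plateau
  resid0 <- abs(s - tail_m)
  pos <- resid0 > max(resid0) * 1e-6 & t > 0
  k0 <- if (sum(pos) >= 2)
    max(1e-6, -coef(lm(log(resid0[pos]) ~ t[pos]))[2]) else 1 / max(t)
  df <- data.frame(t = t, s = s)
  fit <- tryCatch({
    if (rising) {
      minpack.lm::nlsLM(s ~ A * (1 - exp(-k * t)) + c0, data = df,
                        start = list(A = tail_m - head_m, k = k0, c0 = head_m),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(s ~ A * exp(-k * t) + c0, data = df,
                        start = list(A = head_m - tail_m, k = k0, c0 = tail_m),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e)
    stop("single-exponential fit failed to converge: ", conditionMessage(e),
         call. = FALSE))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(cf)))
  res <- stats::residuals(fit)
  r2 <- 1 - sum(res^2) / sum((s - mean(s))^2)
  structure(list(k = unname(abs(cf["k"])), k_stderr = unname(se["k"]),
                 amplitude = unname(cf["A"]), offset = unname(cf["c0"]),
                 r_squared = r2, direction = if (rising) "rising" else "falling",
                 flags = character(0)),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> k = %.6g +/- %.2g s^-1 (%s, R^2 = %.4f)\n",
              x$k, x$k_stderr, x$direction, x$r_squared))
  invisible(x)
}

#' Linear fit of rate constants against solute gradient
#'
#' Ordinary least squares on the mean rates; per-point standard deviations
#' are echoed for plotting but do not weight the fit.
#'
#' @param gradient Numeric vector of initial concentration gradients.
#' @param k Mean single-exponential rate per gradient (s^-1).
#' @param sd Optional per-point standard deviations.
#' @return List with \code{slope}, \code{intercept}, \code{r} (Pearson
#'   correlation), \code{slope_se} and the input table.
#' @export
rate_vs_gradient <- function(gradient, k, sd = NULL) {
  if (length(gradient) < 3) stop("need at least 3 gradient points")
  if (length(unique(gradient)) < 2)
    stop("all gradients identical; design is singular")
  fit <- lm(k ~ gradient)
  cf <- coef(fit)
  # exact lines trigger a benign "essentially perfect fit" note in summary()
  se <- suppressWarnings(summary(fit))$coefficients[, "Std. Error"]
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       r = unname(cor(gradient, k)), slope_se = unname(se[2]),
       points = data.frame(gradient = gradient, k = k,
                           sd = if (is.null(sd)) NA_real_ else sd))
}

#' Free-ammonia concentration from total ammonium
#'
#' Henderson-Hasselbalch speciation of the NH4+/NH3 pair:
#' NH3 = total / (1 + 10^(pKa - pH)).  A 20 mM total gradient at pH 5.6
#' (pKa 9.25) gives 4.5 uM free NH3.
#'
#' @param total_ammonium Total NH4+ + NH3 concentration (mol/L, > 0).
#' @param pH Solution pH (0 < pH < 14).
#' @param pKa Acid dissociation constant of ammonium (default 9.25).
#' @return Free NH3 concentration in mol/L.
#' @export
nh3_gradient <- function(total_ammonium, pH, pKa = 9.25) {
  if (any(total_ammonium <= 0)) stop("total ammonium must be positive")
  if (any(pH <= 0 | pH >= 14)) stop("pH out of range (0, 14)")
  total_ammonium / (1 + 10^(pKa - pH))
}

#' Background-correct a transport rate
#'
#' Subtracts the empty-vector (no channel) rate; negative corrected rates
#' are set to zero.
#'
#' @param rate,background Non-negative finite rates in the same unit.
#' @return max(rate - background, 0), vectorised.
#' @export
background_correct <- function(rate, background) {
  if (any(!is.finite(rate)) || any(!is.finite(background)))
    stop("rates must be finite")
  if (any(rate < 0) || any(background < 0))
    stop("rates must be non-negative")
  pmax(rate - background, 0)
}

#' Specificity ratio with propagated error
#'
#' Ratio of background-corrected ammonia rate (unit 1e-2 s^-1) to
#' background-corrected water rate (s^-1), as printed ("x 1e-2").  The
#' standard error is first-order propagation,
#' ratio * sqrt((se_a/a)^2 + (se_w/w)^2), where each corrected-rate error is
#' the quadrature of the construct's and the background's fit errors.  The
#' ratio is NA (not applicable) when transport is insignificant: the
#' corrected water rate below the significance floor while the corrected
#' ammonia rate is zero (or both zero).  A zero water rate with non-zero
#' ammonia is flagged \code{infinite}.
#'
#' @param corr_ammonia,corr_water Background-corrected rates (>= 0).
#' @param se_ammonia,se_water Propagated standard errors of the corrected
#'   rates.
#' @param floor Significance floor in the printed unit (default 0.1).
#' @param sig_mult A corrected rate is insignificant when below
#'   \code{max(sig_mult * se, floor)} (default 3).
#' @return List with \code{ratio}, \code{se} and \code{flag} ("ok",
#'   "insignificant" or "infinite").
#' @export
specificity_ratio <- function(corr_ammonia, corr_water, se_ammonia = 0,
                              se_water = 0, floor = 0.1, sig_mult = 3) {
  stopifnot(corr_ammonia >= 0, corr_water >= 0)
  w_sig <- corr_water >= max(sig_mult * se_water, floor)
  if ((!w_sig && corr_ammonia == 0) || (corr_water == 0 && corr_ammonia == 0))
    return(list(ratio = NA_real_, se = NA_real_, flag = "insignificant"))
  if (corr_water == 0)
    return(list(ratio = NA_real_, se = NA_real_, flag = "infinite"))
  ratio <- corr_ammonia / corr_water
  se <- if (corr_ammonia > 0)
    ratio * sqrt((se_ammonia / corr_ammonia)^2 + (se_water / corr_water)^2)
  else se_ammonia / corr_water
  list(ratio = ratio, se = se, flag = "ok")
}

#' Classify a construct by its specificity ratio
#'
#' Relative to the reference channel's ratio: within \code{like_band}
#' (default +/- 25\%) is "AtTIP2;1-like", above is "Ammonia", below
#' (including zero) is "Water"; an undefined ratio is "NA" unless flagged
#' infinite (ammonia transport with no measurable water transport), which is
#' "Ammonia".
#'
#' @param ratio Specificity ratio (may be NA).
#' @param reference_ratio Ratio of the reference construct (> 0).
#' @param like_band Relative half-width of the "similar" band.
#' @param flag Flag from \code{\link{specificity_ratio}}.
#' @return One of "Water", "Ammonia", "AtTIP2;1-like", "NA".
#' @export
classify_construct <- function(ratio, reference_ratio, like_band = 0.25,
                               flag = "ok") {
  if (identical(flag, "infinite")) return("Ammonia")
  if (is.na(ratio)) return("NA")
  if (!is.finite(reference_ratio) || reference_ratio <= 0) return("NA")
  rel <- ratio / reference_ratio
  if (rel > 1 + like_band) "Ammonia"
  else if (rel < 1 - like_band) "Water"
  else "AtTIP2;1-like"
}

#' Build the background-corrected specificity table
#'
#' Applies background correction, ratio computation with error propagation,
#' and classification to every non-background construct of a raw-rate table.
#'
#' @param rates Data frame with columns \code{construct},
#'   \code{filter_code}, \code{ammonia_rate}, \code{ammonia_se} (unit 1e-2
#'   s^-1), \code{water_rate}, \code{water_se} (s^-1).
#' @param background Construct id of the empty-vector background row.
#' @param reference Construct id of the reference channel (its in-table
#'   ratio defines the "similar" band).
#' @param like_band,floor,sig_mult See \code{\link{classify_construct}} and
#'   \code{\link{specificity_ratio}}.
#' @return Data frame of class \code{specificity_table} with one row per
#'   non-background construct: corrected rates, ratio +/- propagated se and
#'   the classification call.
#' @export
build_specificity_table <- function(rates, background = "Empty vector",
                                    reference = "AtTIP2;1", like_band = 0.25,
                                    floor = 0.1, sig_mult = 3) {
  need <- c("construct", "ammonia_rate", "ammonia_se", "water_rate",
            "water_se")
  miss <- setdiff(need, names(rates))
  if (length(miss)) stop("rates table lacks column(s): ",
                         paste(miss, collapse = ", "))
  bg <- rates[rates$construct == background, ]
  if (nrow(bg) != 1) stop("background construct '", background,
                          "' not found (or not unique) in rates table")
  con <- rates[rates$construct != background, , drop = FALSE]
  if (!nrow(con)) stop("no constructs besides the background")
  corr <- lapply(seq_len(nrow(con)), function(i) {
    a <- background_correct(con$ammonia_rate[i], bg$ammonia_rate)
    w <- background_correct(con$water_rate[i], bg$water_rate)
    se_a <- sqrt(con$ammonia_se[i]^2 + bg$ammonia_se^2)
    se_w <- sqrt(con$water_se[i]^2 + bg$water_se^2)
    r <- specificity_ratio(a, w, se_a, se_w, floor = floor,
                           sig_mult = sig_mult)
    data.frame(construct = con$construct[i],
               filter_code = if ("filter_code" %in% names(con))
                 con$filter_code[i] else NA_character_,
               corrected_ammonia = a, corrected_water = w,
               ratio = r$ratio, ratio_se = r$se, flag = r$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, corr)
  iref <- which(out$construct == reference)
  if (length(iref) != 1) stop("reference construct '", reference,
                              "' not found in rates table")
  ref_ratio <- out$ratio[iref]
  out$call <- vapply(seq_len(nrow(out)), function(i)
    classify_construct(out$ratio[i], ref_ratio, like_band = like_band,
                       flag = out$flag[i]), character(1))
  rownames(out) <- NULL
  structure(out, class = c("specificity_table", "data.frame"),
            background = background, reference = reference,
            reference_ratio = ref_ratio, like_band = like_band)
}

#' @export
print.specificity_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$corrected_ammonia <- signif(df$corrected_ammonia, digits)
  df$corrected_water <- signif(df$corrected_water, digits)
  df$ratio <- signif(df$ratio, 2)
  df$ratio_se <- signif(df$ratio_se, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
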