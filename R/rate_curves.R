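#' @title Piecewise-linear pH-rate curves
#'
#' @description
#' Each mechanistic pathway contributes a piecewise-linear log10(k) vs pH
#' curve fully determined by its plateau level L (the maximum log-rate),
#' the molecule's acidity constants, and the configured rise/fall slopes:
#'
#' * k1: falls from L at pH 0 with slope -1 (acid-mediated).
#' * k2, k2Ar: rise at +0.75 up to pKa, then plateau at L (boronate route).
#' * k2cat: symmetric tent peaking at L at pH = pKa, slopes +2/-2
#'   (autoprotodeboronation needs neutral and anionic species together).
#' * k3: rises at +2 toward its maximum L at pH 14 (hydroxide-mediated).
#' * k4: plateau at L on the zwitterion window `[pKaH, pKa]`, falling at
#'   0.75 per pH unit on either side.
#' * k5: falls from L at pH 0 with slope -0.75.
#'
#' The observed rate is the sum over pathways in linear rate space; the
#' combined prediction is capped to the configured range (default
#' `[-9, +2]`).
#'
#' @name rate-curves
NULL

#' Build one mechanism's piecewise-linear rate curve
#'
#' @param mechanism Mechanism identifier.
#' @param L Plateau level: the curve's maximum, in log10(k).
#' @param pKa Acidity constant of the boronic acid site (pH units);
#'   required by k2/k2Ar/k2cat/k4.
#' @param pKaH Protonation constant of the basic site; required by k4
#'   (with `pKaH < pKa`).
#' @param config An `algo_config` supplying the slopes.
#' @return A list with class `"rate_curve"`: `mechanism`, `plateau_level`,
#'   `breakpoints` (ascending interior pH breakpoints), `segment_slopes`
#'   (one per segment, `length(breakpoints) + 1`), and the reference point
#'   `ref_pH` at which the curve attains `plateau_level`.
#' @export
#' @examples
#' cfg <- default_algo_config()
#' crv <- mechanism_curve("k4", L = -3, pKa = 9, pKaH = 4, config = cfg)
#' predict(crv, c(2, 6, 12))
mechanism_curve <- function(mechanism, L, pKa = NA_real_, pKaH = NA_real_,
                            config = default_algo_config()) {
  check_mechanism(mechanism)
  stopifnot(is.finite(L))
  sl <- config$slopes[[mechanism]]
  rise <- abs(sl[1])
  fall <- -abs(sl[length(sl)])
  need_pKa <- mechanism %in% c("k2", "k2Ar", "k2cat", "k4")
  if (need_pKa && is.na(pKa)) {
    stop(mechanism, " curve requires pKa", call. = FALSE)
  }
  if (mechanism == "k4") {
    if (is.na(pKaH)) stop("k4 curve requires pKaH", call. = FALSE)
    if (pKaH >= pKa) stop("k4 curve requires pKaH < pKa", call. = FALSE)
  }
  geom <- switch(mechanism,
    k1    = list(bp = numeric(0), sl = fall, ref = 0),
    k2    = ,
    k2Ar  = list(bp = pKa, sl = c(rise, 0), ref = pKa),
    k2cat = list(bp = pKa, sl = c(rise, fall), ref = pKa),
    k3    = list(bp = numeric(0), sl = rise, ref = 14),
    k4    = list(bp = c(pKaH, pKa), sl = c(rise, 0, fall), ref = pKaH),
    k5    = list(bp = numeric(0), sl = fall, ref = 0)
  )
  structure(list(mechanism = mechanism, plateau_level = L,
                 breakpoints = geom$bp, segment_slopes = geom$sl,
                 ref_pH = geom$ref),
            class = "rate_curve")
}

#' Evaluate a rate curve at given pH values
#'
#' @param object A `rate_curve`.
#' @param pH Numeric vector of pH values.
#' @param ... Unused.
#' @return log10(k) at each pH (uncapped).
#' @export
predict.rate_curve <- function(object, pH, ...) {
  bp <- object$breakpoints
  sl <- object$segment_slopes
  ref <- object$ref_pH
  vapply(pH, function(p) {
    lo <- min(ref, p)
    hi <- max(ref, p)
    sgn <- if (p >= ref) 1 else -1
    edges <- c(lo, bp[bp > lo & bp < hi], hi)
    run <- 0
    for (i in seq_len(length(edges) - 1L)) {
      mid <- (edges[i] + edges[i + 1L]) / 2
      seg <- findInterval(mid, bp) + 1L
      run <- run + sl[seg] * (edges[i + 1L] - edges[i])
    }
    object$plateau_level + sgn * run
  }, numeric(1))
}

#' @export
print.rate_curve <- function(x, ...) {
  cat(sprintf("rate_curve %s: L = %.4g, breakpoints (%s), slopes (%s)\n",
              x$mechanism, x$plateau_level,
              paste(format(x$breakpoints), collapse = ", "),
              paste(format(x$segment_slopes), collapse = ", ")))
  invisible(x)
}

# log10 of a sum of powers of ten, computed stably (log-sum-exp)
log10_sum <- function(log10_terms) {
  m <- max(log10_terms)
  if (!is.finite(m)) return(m)
  m + log10(sum(10^(log10_terms - m)))
}

#' Combine mechanism curves into an observed-rate profile
#'
#' The observable rate is the sum of the active pathways' rates in linear
#' rate space: `combined = log10(sum_n 10^curve_n)`, evaluated stably via
#' log-sum-exp. The combined curve — and only the combined curve — is then
#' capped to `[cap_low, cap_high]`; per-mechanism values are stored
#' uncapped for explainability.
#'
#' @param curves List of `rate_curve` objects (at least one).
#' @param pH_grid Ascending pH values within `[0, 14]`.
#' @param config An `algo_config` (supplies the caps).
#' @return A list with class `"predicted_profile"`: `molecule_id` (NA
#'   here; filled by [predict_profile()]), `pH_grid`, `per_mechanism`
#'   (matrix, one column per mechanism, uncapped), `combined` (capped) and
#'   `combined_uncapped`.
#' @export
combine_curves <- function(curves, pH_grid, config = default_algo_config()) {
  if (length(curves) == 0L) stop("no curves to combine", call. = FALSE)
  stopifnot(all(pH_grid >= 0 & pH_grid <= 14), !is.unsorted(pH_grid))
  vals <- vapply(curves, predict, numeric(length(pH_grid)), pH = pH_grid)
  vals <- matrix(vals, nrow = length(pH_grid),
                 dimnames = list(NULL, vapply(curves, `[[`, character(1),
                                              "mechanism")))
  m <- apply(vals, 1L, max)
  uncapped <- m + log10(rowSums(10^(vals - m)))
  structure(list(molecule_id = NA_character_,
                 pH_grid = pH_grid,
                 per_mechanism = vals,
                 combined = cap_rates(uncapped, config),
                 combined_uncapped = uncapped),
            class = "predicted_profile")
}

#' Cap combined log-rates to the configured range
#'
#' Clipping to `[cap_low, cap_high]` (default `[-9, +2]`, the span of the
#' measured data). Idempotent and order-preserving.
#'
#' @param log_k Numeric vector of log10(k) values.
#' @param config An `algo_config`.
#' @return Clipped vector.
#' @export
cap_rates <- function(log_k, config = default_algo_config()) {
  pmin(pmax(log_k, config$cap_low), config$cap_high)
}

#' Predict the full pH-rate profile of one molecule
#'
#' Runs the prediction pipeline for a single boronic acid: determine the
#' active pathways from its category, predict each pathway's plateau level
#' from its energy difference through the fitted linear calibration, build
#' the piecewise-linear curves (imputing absent pKa/pKaH from the training
#' table if provided), and sum them into the capped observed-rate profile.
#' Active mechanisms lacking an energy difference or a calibration are
#' dropped with a warning naming them.
#'
#' @param mol One-row molecule data frame.
#' @param calibrations Named list of `linear_calibration` objects.
#' @param config An `algo_config`.
#' @param rules Mechanism rule table.
#' @param training Optional molecule data frame used to impute absent
#'   pKa/pKaH (see [impute_acidity()]).
#' @param pH_grid pH values at which to evaluate; defaults to the config
#'   grid (`ph_min` to `ph_max` by `ph_step`).
#' @return A `predicted_profile` with extra fields `mechanisms`
#'   (contributing pathways), `dropped`, and `extrapolated` (pathways whose
#'   energy difference fell outside the calibration's training range).
#' @export
predict_profile <- function(mol, calibrations,
                            config = default_algo_config(),
                            rules = default_mechanism_rules(),
                            training = NULL,
                            pH_grid = seq(config$ph_min, config$ph_max,
                                          by = config$ph_step)) {
  stopifnot(nrow(mol) == 1L)
  active <- active_mechanisms(mol$category, rules)
  dE <- molecule_deltaE(mol)
  usable <- active[!is.na(dE[active]) & active %in% names(calibrations)]
  dropped <- setdiff(active, usable)
  if (length(dropped)) {
    warning("molecule '", mol$id, "': dropping mechanism(s) without an ",
            "energy difference or calibration: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (!length(usable)) {
    stop("molecule '", mol$id, "': no active mechanism has both an energy ",
         "difference and a calibration", call. = FALSE)
  }
  needs_pKa <- any(usable %in% c("k2", "k2Ar", "k2cat", "k4"))
  needs_pKaH <- "k4" %in% usable
  if (!is.null(training) &&
        ((needs_pKa && is.na(mol$pKa)) || (needs_pKaH && is.na(mol$pKaH)))) {
    mol <- impute_acidity(mol, training, config)
  }
  extrapolated <- character(0)
  curves <- lapply(usable, function(mech) {
    pred <- predict_log_kmax(calibrations[[mech]], dE[[mech]])
    if (pred$extrapolated) extrapolated <<- c(extrapolated, mech)
    mechanism_curve(mech, pred$log_kmax, pKa = mol$pKa, pKaH = mol$pKaH,
                    config = config)
  })
  prof <- combine_curves(curves, pH_grid, config)
  prof$molecule_id <- mol$id
  prof$mechanisms <- usable
  prof$dropped <- dropped
  prof$extrapolated <- extrapolated
  prof
}

#' @export
print.predicted_profile <- function(x, ...) {
  cat(sprintf("predicted_profile %s: %d pH points, mechanisms: %s\n",
              x$molecule_id, length(x$pH_grid),
              paste(colnames(x$per_mechanism), collapse = ", ")))
  if (length(x$extrapolated)) {
    cat("  extrapolated beyond calibration range:",
        paste(x$extrapolated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write predicted profiles to CSV
#'
#' One row per (molecule, pH): columns `molecule_id`, `pH`, one
#' `log_k_<mechanism>` column per pathway (empty for inactive pathways)
#' and the capped `log_kobs`.
#'
#' @param profiles List of `predicted_profile` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    out <- data.frame(molecule_id = p$molecule_id, pH = p$pH_grid)
    for (mech in MECHANISMS) {
      out[[paste0("log_k_", mech)]] <- if (mech %in% colnames(p$per_mechanism)) {
        p$per_mechanism[, mech]
      } else {
        NA_real_
      }
    }
    out$log_kobs <- p$combined
    out
  })
  out <- do.call(rbind, rows)
  for (col in setdiff(names(out), c("molecule_id"))) {
    out[[col]] <- .fmt_num(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Half-life of a first-order process from its log rate constant
#'
#' `t_1/2 = ln(2) / k` with `k = 10^log_k` in 1/s: log k = +2 gives about
#' 7 ms, log k = -9 about 22 years.
#'
#' @param log_k log10 of a first-order rate constant in 1/s (vectorised).
#' @return Half-life in seconds.
#' @export
#' @examples
#' half_life(c(2, 0, -9))
half_life <- function(log_k) {
  stopifnot(all(is.finite(log_k)))
  log(2) / 10^log_k
}
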