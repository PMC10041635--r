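#' @title Calibrating pathway rates against DFT energy differences
#'
#' @description
#' A pathway's rate cannot be measured directly, but at its anchor pH it
#' dominates the observed rate, so `log(k_n) ~ log(k_obs)` there. Reading
#' the observed rate at each active pathway's anchor yields one calibration
#' point per molecule and pathway; across molecules the maximum log-rate of
#' a pathway is linear in its characteristic energy difference (a linear
#' free-energy relationship), fitted here by ordinary least squares.
#'
#' @name calibration
NULL

#' The pH at which a mechanism's rate is maximal
#'
#' Anchor rules (configurable): k1 at pH 0; k2 and k2Ar on the plateau
#' above pKa, read at pH 14; k3 at pH 14; k4 on the zwitterion plateau,
#' read at pH = pKaH; k2cat at its peak pH = pKa; k5 at pH 0.
#'
#' @param mechanism Mechanism identifier.
#' @param pKa,pKaH Acidity constants (pH units); needed only where the
#'   anchor rule uses them.
#' @param config An `algo_config`.
#' @return A single pH value.
#' @export
#' @examples
#' anchor_pH("k4", pKa = 9, pKaH = 4)
#' anchor_pH("k2", pKa = 9)
anchor_pH <- function(mechanism, pKa = NA_real_, pKaH = NA_real_,
                      config = default_algo_config()) {
  check_mechanism(mechanism)
  rule <- config$anchors[[mechanism]]
  switch(rule,
    "max-at-pH-0" = 0,
    "max-at-pH-0-fall" = 0,
    "max-at-pH-14" = 14,
    "plateau-above-pKa" = 14,
    "peak-at-pKa" = {
      if (is.na(pKa)) stop("anchor for ", mechanism, " requires pKa",
                           call. = FALSE)
      pKa
    },
    "plateau-between-pKaH-and-pKa" = {
      if (is.na(pKaH)) {
        stop("anchor for ", mechanism,
             " requires pKaH (measure or impute it first)", call. = FALSE)
      }
      pKaH
    }
  )
}

new_linear_calibration <- function(mechanism, slope, intercept, n_points,
                                   r_squared, deltaE_range) {
  stopifnot(n_points >= 2L, deltaE_range[1] <= deltaE_range[2])
  structure(list(mechanism = mechanism, slope = slope, intercept = intercept,
                 n_points = as.integer(n_points), r_squared = r_squared,
                 deltaE_range = deltaE_range),
            class = "linear_calibration")
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat(sprintf(paste0("linear_calibration %s: log10(k_max) = %.6g * dE %+.6g",
                     "  (n = %d, R^2 = %.4f, dE range [%.4g, %.4g] hartree)\n"),
              x$mechanism, x$slope, x$intercept, x$n_points, x$r_squared,
              x$deltaE_range[1], x$deltaE_range[2]))
  invisible(x)
}

#' Fit one mechanism's energy-difference calibration
#'
#' Ordinary least squares of the maximum log-rate on the energy difference
#' for all calibration points of one mechanism. With exactly two points
#' the line passes through both and R^2 = 1 (some rare pathways have only
#' two training molecules).
#'
#' @param points Data frame with columns `mechanism`, `deltaE`,
#'   `log_kmax` (all rows must share one mechanism).
#' @return A `linear_calibration`.
#' @export
fit_mechanism_regression <- function(points) {
  mech <- unique(points$mechanism)
  if (length(mech) != 1L) {
    stop("calibration points must belong to a single mechanism", call. = FALSE)
  }
  check_mechanism(mech)
  if (nrow(points) < 2L) {
    stop("mechanism ", mech, ": need at least 2 calibration points, got ",
         nrow(points), call. = FALSE)
  }
  if (length(unique(points$deltaE)) < 2L) {
    stop("mechanism ", mech, ": all energy differences identical; ",
         "regression is underdetermined", call. = FALSE)
  }
  fit <- stats::lm(log_kmax ~ deltaE, data = points)
  ss_tot <- sum((points$log_kmax - mean(points$log_kmax))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  new_linear_calibration(
    mechanism = mech,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n_points = nrow(points),
    r_squared = r2,
    deltaE_range = range(points$deltaE)
  )
}

#' Predict a pathway's maximum log-rate from its energy difference
#'
#' Applies the fitted line; the prediction is flagged as an extrapolation
#' when the energy difference falls outside the closed interval of values
#' seen in training (the calibration's domain of applicability). An
#' extrapolated prediction is still returned — trust is the user's call.
#'
#' @param cal A `linear_calibration`.
#' @param deltaE Energy difference in hartree.
#' @return List with `log_kmax` and logical `extrapolated`.
#' @export
predict_log_kmax <- function(cal, deltaE) {
  stopifnot(inherits(cal, "linear_calibration"), is.finite(deltaE))
  list(log_kmax = cal$slope * deltaE + cal$intercept,
       extrapolated = deltaE < cal$deltaE_range[1] ||
         deltaE > cal$deltaE_range[2])
}

# observed log k at a target pH: the nearest measurement if within
# `tol` pH units, otherwise linear interpolation between the bracketing
# measurements; NA if the target is unbracketed
.observed_at <- function(measurements, target, tol) {
  d <- abs(measurements$pH - target)
  i <- which.min(d)
  if (d[i] <= tol) return(measurements$log_kobs[i])
  below <- measurements$pH < target
  if (!any(below) || all(below)) return(NA_real_)
  lo <- which(below)[which.max(measurements$pH[below])]
  above <- which(!below)
  hi <- above[which.min(measurements$pH[above])]
  w <- (target - measurements$pH[lo]) / (measurements$pH[hi] - measurements$pH[lo])
  (1 - w) * measurements$log_kobs[lo] + w * measurements$log_kobs[hi]
}

#' Decompose one measured pH-rate curve into per-mechanism plateau levels
#'
#' Fits the plateau levels L_n — the only free parameters of the
#' summed-curve model, all slopes and breakpoints being fixed by the
#' configuration and the molecule's acidity constants — to the measured
#' log k_obs values by least squares on the capped combined curve. A fixed
#' multi-start grid (each L in \{-9, -7, ..., +1\}) is screened and the best
#' starts are refined by Levenberg-Marquardt, making the fit deterministic.
#'
#' @param measurements Data frame with columns `pH`, `log_kobs` for one
#'   molecule.
#' @param active Character vector of active mechanisms to decompose into.
#' @param pKa,pKaH Acidity constants.
#' @param config An `algo_config`.
#' @return Named numeric vector of plateau levels, with attribute `"rss"`
#'   (residual sum of squares of the fit).
#' @export
fit_plateaus <- function(measurements, active, pKa = NA_real_,
                         pKaH = NA_real_, config = default_algo_config()) {
  if (length(active) == 0L) stop("empty active mechanism set", call. = FALSE)
  if (nrow(measurements) == 0L) stop("no measurements to fit", call. = FALSE)
  if (nrow(measurements) < length(active)) {
    stop("more free plateau levels (", length(active),
         ") than measurements (", nrow(measurements), ")", call. = FALSE)
  }
  pH <- measurements$pH
  obs <- measurements$log_kobs
  k <- length(active)
  # precompute each mechanism's curve shape at L = 0; the curve at level L
  # is shape + L, so the combined model is a cheap function of L
  shapes <- vapply(active, function(mech) {
    predict(mechanism_curve(mech, 0, pKa = pKa, pKaH = pKaH, config = config),
            pH)
  }, numeric(length(pH)))
  shapes <- matrix(shapes, ncol = k)
  model_resid <- function(L) {
    vals <- sweep(shapes, 2L, L, `+`)
    m <- apply(vals, 1L, max)
    comb <- cap_rates(m + log10(rowSums(10^(vals - m))), config)
    comb - obs
  }
  grid_levels <- seq(-9, 1, by = 2)
  grid <- as.matrix(expand.grid(rep(list(grid_levels), k)))
  rss <- apply(grid, 1L, function(L) sum(model_resid(L)^2))
  starts <- grid[order(rss)[seq_len(min(10L, nrow(grid)))], , drop = FALSE]
  # the combined rate is linear in the plateau weights 10^L, so uncapped
  # points admit a direct least-squares seed; exact on noiseless data and
  # a strong start otherwise, including for pathways buried well below the
  # dominant one where the log-space gradient is nearly flat
  lo <- config$cap_low - 5
  hi <- config$cap_high + 3
  free <- obs > config$cap_low + 1e-9 & obs < config$cap_high - 1e-9
  if (sum(free) >= k) {
    w <- try(qr.solve(10^shapes[free, , drop = FALSE], 10^obs[free]),
             silent = TRUE)
    if (!inherits(w, "try-error")) {
      seed <- pmin(pmax(log10(pmax(w, 10^lo)), lo), hi)
      starts <- rbind(seed, starts)
    }
  }
  best <- NULL
  best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- minpack.lm::nls.lm(
      par = starts[i, ], fn = model_resid,
      lower = rep(lo, k), upper = rep(hi, k),
      control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15,
                                           ptol = 1e-15, gtol = 0)
    )
    fr <- sum(fit$fvec^2)
    if (fr < best_rss) {
      best_rss <- fr
      best <- fit$par
    }
  }
  structure(stats::setNames(as.numeric(best), active), rss = best_rss)
}

#' Extract calibration points from a kinetic dataset
#'
#' For every molecule and every active mechanism with a recorded energy
#' difference, determines the pathway's maximum log-rate from the measured
#' curve. For a molecule with a single active pathway, the observed rate
#' at the anchor pH is read directly (nearest measurement within
#' `anchor_tol` pH units, else linear interpolation between bracketing
#' points). When several pathways are active, the molecule's curve is
#' first decomposed into plateau levels ([fit_plateaus()]); the direct
#' anchor reading replaces the decomposed level only where every other
#' pathway is negligible at that anchor (at least `dominance_margin`
#' log10 units slower). Mechanisms whose anchor pH is not bracketed by
#' measurements are skipped with a warning.
#'
#' @param dataset A `pdb_dataset`.
#' @param config An `algo_config`.
#' @param rules Mechanism rule table.
#' @return Data frame with columns `molecule_id`, `mechanism`, `deltaE`,
#'   `log_kmax`, `anchor_pH`, `method` (`"anchor"` or `"decomposition"`).
#' @export
extract_calibration_points <- function(dataset,
                                       config = default_algo_config(),
                                       rules = default_mechanism_rules()) {
  stopifnot(inherits(dataset, "pdb_dataset"))
  out <- list()
  for (i in seq_len(nrow(dataset$molecules))) {
    mol <- dataset$molecules[i, , drop = FALSE]
    meas <- dataset$measurements[dataset$measurements$molecule_id == mol$id, ,
                                 drop = FALSE]
    meas <- meas[order(meas$pH), , drop = FALSE]
    active <- active_mechanisms(mol$category, rules)
    dE <- molecule_deltaE(mol)
    usable <- active[!is.na(dE[active])]
    if (!length(usable) || nrow(meas) == 0L) {
      warning("molecule '", mol$id, "': no usable mechanism or no ",
              "measurements; contributes no calibration points",
              call. = FALSE)
      next
    }
    anchors <- vapply(usable, function(mech) {
      tryCatch(anchor_pH(mech, pKa = mol$pKa, pKaH = mol$pKaH, config = config),
               error = function(e) NA_real_)
    }, numeric(1))
    bracketed <- vapply(seq_along(usable), function(j) {
      !is.na(anchors[j]) && !is.na(.observed_at(meas, anchors[j],
                                                config$anchor_tol))
    }, logical(1))
    if (any(!bracketed)) {
      warning("molecule '", mol$id, "': anchor unbracketed for ",
              paste(usable[!bracketed], collapse = ", "), "; skipped",
              call. = FALSE)
    }
    decomp <- NULL
    if (length(usable) > 1L && any(bracketed)) {
      decomp <- try(fit_plateaus(meas, usable, pKa = mol$pKa,
                                 pKaH = mol$pKaH, config = config),
                    silent = TRUE)
      if (inherits(decomp, "try-error")) {
        warning("molecule '", mol$id, "': curve decomposition failed; ",
                "skipping its ambiguous calibration points", call. = FALSE)
        decomp <- NULL
      }
    }
    for (j in which(bracketed)) {
      mech <- usable[j]
      a <- anchors[j]
      direct <- .observed_at(meas, a, config$anchor_tol)
      if (length(usable) == 1L) {
        log_kmax <- direct
        method <- "anchor"
      } else {
        if (is.null(decomp)) next
        # the direct anchor reading is trusted only when (a) an actual
        # measurement sits on the mechanism's maximum region (interpolating
        # across a breakpoint kink is biased) and (b) every other pathway
        # is negligible there per the provisional decomposition
        d_near <- abs(meas$pH - a)
        near <- which.min(d_near)
        on_max <- d_near[near] <= config$anchor_tol &&
          predict(mechanism_curve(mech, 0, pKa = mol$pKa, pKaH = mol$pKaH,
                                  config = config),
                  meas$pH[near]) > -1e-9
        others <- setdiff(usable, mech)
        other_vals <- vapply(others, function(om) {
          predict(mechanism_curve(om, decomp[[om]], pKa = mol$pKa,
                                  pKaH = mol$pKaH, config = config),
                  meas$pH[near])
        }, numeric(1))
        dominance <- decomp[[mech]] - log10_sum(other_vals)
        if (on_max && dominance >= config$dominance_margin) {
          log_kmax <- meas$log_kobs[near]
          method <- "anchor"
        } else {
          log_kmax <- decomp[[mech]]
          method <- "decomposition"
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        molecule_id = mol$id, mechanism = mech, deltaE = dE[[mech]],
        log_kmax = log_kmax, anchor_pH = a, method = method,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(molecule_id = character(0), mechanism = character(0),
                      deltaE = numeric(0), log_kmax = numeric(0),
                      anchor_pH = numeric(0), method = character(0)))
  }
  do.call(rbind, out)
}

#' Fit all mechanism calibrations from extracted points
#'
#' Splits calibration points by mechanism and fits each regression that
#' has at least two points with distinct energy differences; mechanisms
#' that cannot be fitted are dropped with a warning.
#'
#' @param points Data frame from [extract_calibration_points()].
#' @return Named list of `linear_calibration` objects.
#' @export
fit_calibrations <- function(points) {
  cals <- list()
  for (mech in intersect(MECHANISMS, unique(points$mechanism))) {
    sub <- points[points$mechanism == mech, , drop = FALSE]
    cal <- try(fit_mechanism_regression(sub), silent = TRUE)
    if (inherits(cal, "try-error")) {
      warning("mechanism ", mech, ": calibration not fitted (",
              attr(cal, "condition")$message, ")", call. = FALSE)
    } else {
      cals[[mech]] <- cal
    }
  }
  cals
}
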