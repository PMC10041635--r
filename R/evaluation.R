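#' @title Leave-one-out cross-validation and residual metrics
#'
#' @description
#' The model is assessed by leave-one-out cross-validation by molecule:
#' all of a molecule's measurements are held out together, calibrations
#' are refitted on the remaining molecules, the held-out molecule's
#' profile is predicted, and residuals are collected at its measured pH
#' values on the capped combined curve (matching a parity plot of final
#' predictions against observations).
#'
#' @name evaluation
NULL

#' Residual metrics for observed/predicted pairs
#'
#' MAE (mean absolute error), MSE (mean squared error) and R^2. By default
#' R^2 is the coefficient of determination
#' `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`, which can be
#' negative for predictions worse than the observed mean; `"pearson"`
#' reports the squared Pearson correlation instead.
#'
#' @param observed,predicted Numeric vectors of equal length (at least
#'   one pair; at least two for R^2, otherwise R^2 is `NA`).
#' @param method `"cod"` (default) or `"pearson"`.
#' @return List with `mae`, `mse`, `r_squared`.
#' @export
#' @examples
#' prediction_metrics(c(0, 2), c(1, 1))  # mae 1, mse 1, R^2 -1
prediction_metrics <- function(observed, predicted,
                               method = c("cod", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(observed) == length(predicted))
  if (length(observed) == 0L) {
    stop("no observed/predicted pairs", call. = FALSE)
  }
  resid <- observed - predicted
  r2 <- if (length(observed) < 2L) {
    NA_real_
  } else if (method == "pearson") {
    stats::cor(observed, predicted)^2
  } else {
    1 - sum(resid^2) / sum((observed - mean(observed))^2)
  }
  list(mae = mean(abs(resid)), mse = mean(resid^2), r_squared = r2)
}

#' Leave-one-out cross-validation by molecule
#'
#' For each molecule in turn: calibration points are taken from all other
#' molecules only, regressions refitted per mechanism (a mechanism left
#' with fewer than two points in a fold is skipped for that fold), the
#' held-out molecule's profile predicted (imputing absent pKa/pKaH from
#' the fold's training molecules) and evaluated at its measured pH values.
#' Residuals are `predicted - observed` on the capped combined curve.
#'
#' Calibration-point extraction is purely per-molecule (each molecule's
#' points depend only on its own measurements), so points are extracted
#' once and folds merely select them, which keeps folds independent by
#' construction.
#'
#' @param dataset A `pdb_dataset` with at least 3 molecules.
#' @param config An `algo_config`.
#' @param rules Mechanism rule table.
#' @return A list with class `"loocv_report"`: `per_point` (data frame
#'   `molecule_id, pH, observed, predicted, residual`), `mae`, `mse`,
#'   `r_squared`, `n_points`, `n_molecules`, and `skipped` (data frame
#'   `molecule_id, reason`).
#' @export
loocv <- function(dataset, config = default_algo_config(),
                  rules = default_mechanism_rules()) {
  stopifnot(inherits(dataset, "pdb_dataset"))
  mols <- dataset$molecules
  if (nrow(mols) < 3L) {
    stop("leave-one-out cross-validation needs at least 3 molecules, got ",
         nrow(mols), call. = FALSE)
  }
  points <- extract_calibration_points(dataset, config, rules)
  per_point <- list()
  skipped <- list()
  note_skip <- function(id, reason) {
    skipped[[length(skipped) + 1L]] <<- data.frame(molecule_id = id,
                                                   reason = reason,
                                                   stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(mols))) {
    mol <- mols[i, , drop = FALSE]
    meas <- dataset$measurements[dataset$measurements$molecule_id == mol$id, ,
                                 drop = FALSE]
    if (nrow(meas) == 0L) {
      note_skip(mol$id, "no measurements")
      next
    }
    train_points <- points[points$molecule_id != mol$id, , drop = FALSE]
    cals <- suppressWarnings(fit_calibrations(train_points))
    prof <- tryCatch(
      suppressWarnings(predict_profile(
        mol, cals, config = config, rules = rules,
        training = mols[-i, , drop = FALSE], pH_grid = sort(unique(meas$pH))
      )),
      error = function(e) e
    )
    if (inherits(prof, "error")) {
      note_skip(mol$id, conditionMessage(prof))
      next
    }
    if (length(prof$dropped)) {
      note_skip(mol$id, paste("mechanism(s) unavailable in fold:",
                              paste(prof$dropped, collapse = ", ")))
    }
    pred <- prof$combined[match(meas$pH, prof$pH_grid)]
    per_point[[length(per_point) + 1L]] <- data.frame(
      molecule_id = mol$id, pH = meas$pH, observed = meas$log_kobs,
      predicted = pred, residual = pred - meas$log_kobs,
      stringsAsFactors = FALSE
    )
  }
  per_point <- if (length(per_point)) {
    do.call(rbind, per_point)
  } else {
    data.frame(molecule_id = character(0), pH = numeric(0),
               observed = numeric(0), predicted = numeric(0),
               residual = numeric(0))
  }
  skipped <- if (length(skipped)) {
    do.call(rbind, skipped)
  } else {
    data.frame(molecule_id = character(0), reason = character(0))
  }
  mets <- if (nrow(per_point)) {
    prediction_metrics(per_point$observed, per_point$predicted,
                       method = config$r_squared_method)
  } else {
    list(mae = NA_real_, mse = NA_real_, r_squared = NA_real_)
  }
  structure(list(per_point = per_point, mae = mets$mae, mse = mets$mse,
                 r_squared = mets$r_squared, n_points = nrow(per_point),
                 n_molecules = length(unique(per_point$molecule_id)),
                 skipped = skipped),
            class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf(paste0("LOOCV report: %d molecules, %d points\n",
                     "  MAE = %.4f  MSE = %.4f  R^2 = %.4f\n"),
              x$n_molecules, x$n_points, x$mae, x$mse, x$r_squared))
  if (nrow(x$skipped)) {
    cat("  skipped:", nrow(x$skipped), "entries\n")
  }
  invisible(x)
}

#' Write a cross-validation report to JSON
#'
#' Includes the aggregate metrics, per-molecule residual summaries and the
#' full per-point table.
#'
#' @param report A `loocv_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loocv_report <- function(report, path) {
  per_mol <- lapply(split(report$per_point, report$per_point$molecule_id),
                    function(d) {
                      list(n_points = nrow(d),
                           mae = mean(abs(d$residual)),
                           residuals = d$residual)
                    })
  payload <- list(
    mae = report$mae, mse = report$mse, r_squared = report$r_squared,
    n_points = report$n_points, n_molecules = report$n_molecules,
    per_molecule = per_mol,
    per_point = report$per_point,
    skipped = report$skipped
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Write parity-plot data to CSV
#'
#' @param report A `loocv_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parity <- function(report, path) {
  out <- report$per_point[, c("observed", "predicted", "molecule_id")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
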