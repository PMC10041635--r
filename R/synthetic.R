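#' @title Synthetic kinetic datasets with known ground truth
#'
#' @description
#' Generates molecule tables and measured pH-rate curves from known linear
#' calibrations so that calibration, curve construction and
#' cross-validation can be exercised end to end against exact ground
#' truth. The generator emulates the scale and structure of the real
#' benchmark (about fifty boronic acids, a few hundred points, energy
#' differences of order 1e-2 hartree, log-rates spanning `[-9, +2]`) with
#' homoscedastic Gaussian noise in log10 space.
#'
#' @name synthetic
NULL

#' Specification for a synthetic dataset
#'
#' Defaults mirror the reference study conditions: 50 molecules dominated
#' by aryl and heteroaryl classes, roughly ten pH points per molecule
#' spanning 0 to 14, energy differences of order 1e-2 hartree with
#' calibration slopes of order -10^2.5 log10-units per hartree, and
#' measurement noise of 0.3 log10 units.
#'
#' @param n_molecules Number of molecules.
#' @param category_mix Named proportions over category labels (must sum
#'   to 1).
#' @param true_calibrations Named list per mechanism of
#'   `list(slope, intercept)` generating the plateau levels
#'   `L = slope * deltaE + intercept`.
#' @param deltaE_ranges Named list per mechanism of `c(min, max)` hartree.
#' @param pKa_range,pKaH_range pH intervals to draw acidity constants
#'   from (`pKaH_range` must lie below `pKa_range` so that pKaH < pKa).
#' @param noise_sd Gaussian noise standard deviation in log10 units
#'   (>= 0).
#' @param pH_points pH values at which each molecule is "measured".
#' @param seed Integer seed; a fixed seed makes the output fully
#'   reproducible.
#' @return A list with class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_molecules = 50L,
                           category_mix = c(aryl = 0.40,
                                            other_basic_heterocycle = 0.20,
                                            basic_six_membered_heterocycle = 0.20,
                                            nonbasic_five_membered_heterocycle = 0.10,
                                            activated_aryl = 0.06,
                                            alkenyl = 0.04),
                           true_calibrations = NULL,
                           deltaE_ranges = NULL,
                           pKa_range = c(5, 9),
                           pKaH_range = c(1.5, 4.5),
                           noise_sd = 0.3,
                           pH_points = seq(0, 14, length.out = 10L),
                           seed = 1L) {
  if (is.null(true_calibrations)) {
    slopes <- c(k1 = -250, k2 = -300, k2Ar = -320, k2cat = -150,
                k3 = -280, k4 = -260, k5 = -240)
    intercepts <- c(k1 = -4.5, k2 = -4, k2Ar = -4, k2cat = -3.5,
                    k3 = -4, k4 = -3.5, k5 = -4.5)
    true_calibrations <- lapply(stats::setNames(MECHANISMS, MECHANISMS),
                                function(m) list(slope = slopes[[m]],
                                                 intercept = intercepts[[m]]))
  }
  if (is.null(deltaE_ranges)) {
    deltaE_ranges <- lapply(stats::setNames(MECHANISMS, MECHANISMS),
                            function(m) c(-0.012, 0.010))
    deltaE_ranges$k2cat <- c(-0.0137, 0.0065)
  }
  if (abs(sum(category_mix) - 1) > 1e-8) {
    stop("category_mix proportions must sum to 1", call. = FALSE)
  }
  if (any(category_mix < 0)) {
    stop("category_mix proportions must be non-negative", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (max(pKaH_range) >= min(pKa_range)) {
    stop("pKaH_range must lie strictly below pKa_range", call. = FALSE)
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 category_mix = category_mix,
                 true_calibrations = true_calibrations,
                 deltaE_ranges = deltaE_ranges,
                 pKa_range = pKa_range, pKaH_range = pKaH_range,
                 noise_sd = noise_sd, pH_points = pH_points,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# run `expr` under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# deterministic largest-remainder apportionment of n among proportions
.apportion <- function(n, prop) {
  raw <- n * prop
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

#' Generate a synthetic dataset with ground truth
#'
#' Draws molecules with categories apportioned per the mix, energy
#' differences uniform within each mechanism's range, and acidity
#' constants uniform in their intervals (pKaH only for categories whose
#' pathways include k4). Each pathway's plateau level is
#' `slope * deltaE + intercept` from the true calibrations; measurements
#' are the capped combined curve at the spec's pH points plus Gaussian
#' noise.
#'
#' @param spec A `synthetic_spec`.
#' @param config An `algo_config` (curve slopes and caps).
#' @param rules Mechanism rule table.
#' @return List with `dataset` (a `pdb_dataset`) and `truth`: the
#'   generating `calibrations`, per-molecule `plateaus` (data frame
#'   `molecule_id, mechanism, deltaE, L`) and the noiseless `curves`
#'   (data frame `molecule_id, pH, log_kobs_true`).
#' @export
generate_synthetic <- function(spec, config = default_algo_config(),
                               rules = default_mechanism_rules()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, {
    counts <- .apportion(spec$n_molecules, spec$category_mix)
    categories <- rep(names(spec$category_mix), counts)
    n <- length(categories)
    ids <- sprintf("synth_%03d", seq_len(n))
    mols <- data.frame(id = ids,
                       name = paste("synthetic", ids),
                       smiles = NA_character_,
                       category = categories,
                       pKa = stats::runif(n, spec$pKa_range[1],
                                          spec$pKa_range[2]),
                       pKaH = NA_real_,
                       stringsAsFactors = FALSE)
    for (col in .dE_cols) mols[[col]] <- NA_real_
    plateaus <- list()
    for (i in seq_len(n)) {
      active <- active_mechanisms(mols$category[i], rules)
      if ("k4" %in% active) {
        mols$pKaH[i] <- stats::runif(1, spec$pKaH_range[1],
                                     spec$pKaH_range[2])
      }
      for (mech in active) {
        rng <- spec$deltaE_ranges[[mech]]
        dE <- stats::runif(1, rng[1], rng[2])
        mols[[paste0("dE_", mech)]][i] <- dE
        cal <- spec$true_calibrations[[mech]]
        plateaus[[length(plateaus) + 1L]] <- data.frame(
          molecule_id = mols$id[i], mechanism = mech, deltaE = dE,
          L = cal$slope * dE + cal$intercept, stringsAsFactors = FALSE)
      }
    }
    plateaus <- do.call(rbind, plateaus)
    mols$pKa_imputed <- FALSE
    mols$pKaH_imputed <- FALSE
    meas <- list()
    curves <- list()
    for (i in seq_len(n)) {
      pl <- plateaus[plateaus$molecule_id == mols$id[i], , drop = FALSE]
      crvs <- lapply(seq_len(nrow(pl)), function(j) {
        mechanism_curve(pl$mechanism[j], pl$L[j], pKa = mols$pKa[i],
                        pKaH = mols$pKaH[i], config = config)
      })
      prof <- combine_curves(crvs, spec$pH_points, config)
      noise <- if (spec$noise_sd > 0) {
        stats::rnorm(length(spec$pH_points), 0, spec$noise_sd)
      } else {
        0
      }
      meas[[i]] <- data.frame(molecule_id = mols$id[i],
                              pH = spec$pH_points,
                              log_kobs = prof$combined + noise,
                              stringsAsFactors = FALSE)
      curves[[i]] <- data.frame(molecule_id = mols$id[i],
                                pH = spec$pH_points,
                                log_kobs_true = prof$combined,
                                stringsAsFactors = FALSE)
    }
    dataset <- pdb_dataset(mols, do.call(rbind, meas))
    list(dataset = dataset,
         truth = list(calibrations = spec$true_calibrations,
                      plateaus = plateaus,
                      curves = do.call(rbind, curves)))
  })
}

#' Add Gaussian noise to a dataset's measured log-rates
#'
#' Molecule records are untouched; only `log_kobs` is perturbed, with
#' independent draws.
#'
#' @param dataset A `pdb_dataset`.
#' @param noise_sd Standard deviation in log10 units (>= 0).
#' @param seed Integer seed for reproducibility.
#' @return A new `pdb_dataset`.
#' @export
perturb_measurements <- function(dataset, noise_sd, seed = 1L) {
  stopifnot(inherits(dataset, "pdb_dataset"), noise_sd >= 0)
  .with_seed(seed, {
    meas <- dataset$measurements
    meas$log_kobs <- meas$log_kobs +
      stats::rnorm(nrow(meas), 0, noise_sd)
    pdb_dataset(dataset$molecules, meas)
  })
}

#' Write a synthetic dataset and its ground truth to a directory
#'
#' Writes `molecules.csv`, `rates.csv` and `truth.json`.
#'
#' @param synth Output of [generate_synthetic()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_molecules(synth$dataset$molecules, file.path(dir, "molecules.csv"))
  write_measurements(synth$dataset$measurements, file.path(dir, "rates.csv"))
  jsonlite::write_json(synth$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(dir)
}
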