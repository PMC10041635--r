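#' @title Molecule and kinetic-measurement tables
#'
#' @description
#' Molecule tables are plain data frames with one boronic acid per row:
#' columns `id`, `name`, `smiles`, `category`, `pKa`, `pKaH` and one
#' `dE_<mechanism>` column per pathway holding the characteristic energy
#' difference in hartree. Empty CSV cells mean "absent" (`NA`); a present
#' ΔE of 0 is meaningful and distinct from absent. Measurement tables hold
#' one `(molecule_id, pH, log_kobs)` observation per row, with `log_kobs`
#' the base-10 logarithm of a first-order rate constant in 1/s.
#'
#' @name tables
NULL

.dE_cols <- paste0("dE_", MECHANISMS)
.mol_cols <- c("id", "name", "smiles", "category", "pKa", "pKaH", .dE_cols)

# parse one character column to numeric; errors name the offending cell
.parse_num_col <- function(x, col, file) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' in %s, row %d, column '%s'",
                 x[bad[1]], file, bad[1], col), call. = FALSE)
  }
  out
}

#' Read a molecule table from CSV
#'
#' Expects header columns
#' `id,name,smiles,category,pKa,pKaH,dE_k1,dE_k2,dE_k2Ar,dE_k2cat,dE_k3,dE_k4,dE_k5`
#' (UTF-8, comma-separated, dot decimal separator regardless of locale).
#' Empty cells are read as absent (`NA`); absent pKa/pKaH are retained as
#' absent — imputation is a separate, explicit step ([impute_acidity()]).
#'
#' @param path Path to the CSV file.
#' @param rules Mechanism rule table (see [default_mechanism_rules()]); used
#'   to validate category labels against the closed taxonomy.
#' @return A data frame of molecule records with logical columns
#'   `pKa_imputed` / `pKaH_imputed` initialised to `FALSE`.
#' @export
read_molecules <- function(path, rules = default_mechanism_rules()) {
  if (!file.exists(path)) stop("molecule file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing <- setdiff(.mol_cols, names(raw))
  if (length(missing)) {
    stop("molecule table ", path, " lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, .mol_cols, drop = FALSE]
  if (nrow(raw) == 0L) return(.finish_molecules(raw, rules))
  dup <- unique(raw$id[duplicated(raw$id)])
  if (length(dup)) {
    stop("duplicate molecule id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  for (col in c("pKa", "pKaH", .dE_cols)) {
    raw[[col]] <- .parse_num_col(raw[[col]], col, path)
  }
  bad <- !vapply(raw[.dE_cols], function(x) all(is.na(x) | is.finite(x)),
                 logical(1))
  if (any(bad)) {
    stop("non-finite energy difference in column ",
         names(which(bad))[1], call. = FALSE)
  }
  .finish_molecules(raw, rules)
}

.finish_molecules <- function(df, rules) {
  taxonomy <- names(rules$categories)
  unknown <- setdiff(unique(df$category), taxonomy)
  if (length(unknown)) {
    stop("unknown category label(s): ", paste(unknown, collapse = ", "),
         "; valid labels are: ", paste(taxonomy, collapse = ", "),
         call. = FALSE)
  }
  both <- !is.na(df$pKa) & !is.na(df$pKaH)
  if (any(both & df$pKaH >= df$pKa)) {
    bad <- df$id[both & df$pKaH >= df$pKa]
    stop("pKaH must be below pKa; violated for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df$smiles[!is.na(df$smiles) & trimws(df$smiles) == ""] <- NA_character_
  df$pKa_imputed <- rep(FALSE, nrow(df))
  df$pKaH_imputed <- rep(FALSE, nrow(df))
  rownames(df) <- NULL
  df
}

#' Read a kinetic-measurement table from CSV
#'
#' Expects header `molecule_id,pH,log_kobs`. Rows are preserved in file
#' order. pH must lie in `[0, 14]`; `log_kobs` is log10 of a first-order
#' rate constant in 1/s.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `molecule_id`, `pH`, `log_kobs`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("molecule_id", "pH", "log_kobs")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("measurement table ", path, " lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, need, drop = FALSE]
  raw$pH <- .parse_num_col(raw$pH, "pH", path)
  raw$log_kobs <- .parse_num_col(raw$log_kobs, "log_kobs", path)
  if (anyNA(raw$pH) || anyNA(raw$log_kobs)) {
    stop("missing pH or log_kobs value in ", path, ", row ",
         which(is.na(raw$pH) | is.na(raw$log_kobs))[1], call. = FALSE)
  }
  bad <- which(raw$pH < 0 | raw$pH > 14)
  if (length(bad)) {
    stop(sprintf("pH %.4g outside [0, 14] in %s, row %d",
                 raw$pH[bad[1]], path, bad[1]), call. = FALSE)
  }
  rownames(raw) <- NULL
  raw
}

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' Write a molecule table to CSV
#'
#' Inverse of [read_molecules()]: absent values become empty cells and
#' numbers are written with 15 significant digits so that a write/read
#' round trip preserves them to at least 12 significant digits.
#'
#' @param molecules Molecule data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(molecules, path) {
  out <- molecules[, .mol_cols, drop = FALSE]
  for (col in c("pKa", "pKaH", .dE_cols)) out[[col]] <- .fmt_num(out[[col]])
  out$smiles[is.na(out$smiles)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a measurement table to CSV
#' @param measurements Measurement data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  out <- measurements[, c("molecule_id", "pH", "log_kobs"), drop = FALSE]
  out$pH <- .fmt_num(out$pH)
  out$log_kobs <- .fmt_num(out$log_kobs)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Bundle molecules and measurements into a dataset
#'
#' Checks referential integrity: every measurement's `molecule_id` must
#' resolve to exactly one molecule record.
#'
#' @param molecules Molecule data frame ([read_molecules()]).
#' @param measurements Measurement data frame ([read_measurements()]).
#' @return A list with class `"pdb_dataset"` and elements `molecules`,
#'   `measurements`.
#' @export
pdb_dataset <- function(molecules, measurements) {
  orphan <- setdiff(unique(measurements$molecule_id), molecules$id)
  if (length(orphan)) {
    stop("measurements reference unknown molecule id(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  structure(list(molecules = molecules, measurements = measurements),
            class = "pdb_dataset")
}

#' @export
print.pdb_dataset <- function(x, ...) {
  cat(sprintf("Protodeboronation dataset: %d molecules, %d measurements\n",
              nrow(x$molecules), nrow(x$measurements)))
  invisible(x)
}

#' Impute missing acidity constants from training means
#'
#' Replaces an absent pKa (resp. pKaH) of one molecule record by the
#' arithmetic mean of the non-absent training values of that constant, and
#' flags the record as imputed. Present values are never overwritten. If
#' the training table carries no value for the needed constant, the
#' configuration fallbacks `pKa_impute` / `pKaH_impute` are used; if those
#' are also absent, imputation fails.
#'
#' @param mol A one-row molecule data frame.
#' @param training Molecule data frame supplying the means.
#' @param config An `algo_config`.
#' @return The (possibly updated) one-row molecule data frame.
#' @export
impute_acidity <- function(mol, training, config = default_algo_config()) {
  stopifnot(nrow(mol) == 1L)
  for (const in c("pKa", "pKaH")) {
    if (!is.na(mol[[const]])) next
    vals <- training[[const]][!is.na(training[[const]])]
    fallback <- config[[paste0(const, "_impute")]]
    if (length(vals)) {
      mol[[const]] <- mean(vals)
    } else if (!is.na(fallback)) {
      mol[[const]] <- fallback
    } else {
      stop("cannot impute ", const, " for molecule '", mol$id,
           "': no training values and no config fallback", call. = FALSE)
    }
    mol[[paste0(const, "_imputed")]] <- TRUE
  }
  mol
}

#' Per-mechanism energy differences of one molecule record
#'
#' @param mol A one-row molecule data frame.
#' @return Named numeric vector over the seven mechanisms (NA = absent).
#' @export
molecule_deltaE <- function(mol) {
  stopifnot(nrow(mol) == 1L)
  stats::setNames(as.numeric(mol[1, .dE_cols]), MECHANISMS)
}

#' Write fitted calibrations to CSV
#'
#' Columns: `mechanism,slope,intercept,n_points,r_squared,deltaE_min,deltaE_max`.
#'
#' @param calibrations Named list of `linear_calibration` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibrations <- function(calibrations, path) {
  rows <- lapply(calibrations, function(cal) {
    data.frame(mechanism = cal$mechanism, slope = cal$slope,
               intercept = cal$intercept, n_points = cal$n_points,
               r_squared = cal$r_squared,
               deltaE_min = cal$deltaE_range[1],
               deltaE_max = cal$deltaE_range[2])
  })
  out <- do.call(rbind, rows)
  for (col in c("slope", "intercept", "r_squared", "deltaE_min", "deltaE_max")) {
    out[[col]] <- .fmt_num(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read fitted calibrations from CSV
#'
#' @param path Path written by [write_calibrations()].
#' @return Named list of `linear_calibration` objects.
#' @export
read_calibrations <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  need <- c("mechanism", "slope", "intercept", "n_points", "r_squared",
            "deltaE_min", "deltaE_max")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("calibration table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cals <- lapply(seq_len(nrow(raw)), function(i) {
    mech <- check_mechanism(raw$mechanism[i])
    new_linear_calibration(
      mechanism = mech,
      slope = as.numeric(raw$slope[i]),
      intercept = as.numeric(raw$intercept[i]),
      n_points = as.integer(raw$n_points[i]),
      r_squared = as.numeric(raw$r_squared[i]),
      deltaE_range = c(as.numeric(raw$deltaE_min[i]),
                       as.numeric(raw$deltaE_max[i]))
    )
  })
  stats::setNames(cals, vapply(cals, `[[`, character(1), "mechanism"))
}
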