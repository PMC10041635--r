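# Builders for small in-memory fixtures used across the suite.

mol_row <- function(id = "m1", category = "aryl", pKa = 8, pKaH = NA_real_,
                    dE = c(), smiles = NA_character_, name = id) {
  df <- data.frame(id = id, name = name, smiles = smiles,
                   category = category, pKa = pKa, pKaH = pKaH,
                   stringsAsFactors = FALSE)
  for (m in MECHANISMS) {
    df[[paste0("dE_", m)]] <- if (m %in% names(dE)) dE[[m]] else NA_real_
  }
  df$pKa_imputed <- FALSE
  df$pKaH_imputed <- FALSE
  df
}

meas_rows <- function(id, pH, log_kobs) {
  data.frame(molecule_id = id, pH = pH, log_kobs = log_kobs,
             stringsAsFactors = FALSE)
}

# a calibration with chosen slope/intercept, built from two synthetic points
cal_from_line <- function(mechanism, slope, intercept,
                          deltaE = c(-0.01, 0.01)) {
  fit_mechanism_regression(data.frame(
    molecule_id = c("a", "b"), mechanism = mechanism, deltaE = deltaE,
    log_kmax = slope * deltaE + intercept, stringsAsFactors = FALSE))
}

# molecule table CSV content with the canonical header
mol_csv <- function(rows) {
  c("id,name,smiles,category,pKa,pKaH,dE_k1,dE_k2,dE_k2Ar,dE_k2cat,dE_k3,dE_k4,dE_k5",
    rows)
}

write_csv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# mix used for compact multi-pathway datasets in which every mechanism
# keeps at least 3 calibration points after any single hold-out
balanced_mix <- c(aryl = 1 / 3, other_basic_heterocycle = 1 / 3,
                  basic_six_membered_heterocycle = 1 / 3)
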