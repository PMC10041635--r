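#' Mechanistic pathway identifiers
#'
#' The seven protodeboronation pathways recognised by the model. `k2Ar` is
#' the pathway specific to simple aryl boronic acids; `k2cat`
#' (autoprotodeboronation) couples two boronic acid molecules in its
#' transition state; `k4` proceeds through the zwitterion and so requires a
#' basic site.
#'
#' @format Character vector of length 7.
#' @export
MECHANISMS <- c("k1", "k2", "k2Ar", "k2cat", "k3", "k4", "k5")

#' Assert that a label is a valid mechanism identifier
#'
#' @param mechanism Character scalar.
#' @return The label, invisibly, if valid; otherwise an error.
#' @keywords internal
check_mechanism <- function(mechanism) {
  if (!(is.character(mechanism) && length(mechanism) == 1L &&
          mechanism %in% MECHANISMS)) {
    stop("unknown mechanism '", paste(mechanism, collapse = ","),
         "'; valid mechanisms are: ", paste(MECHANISMS, collapse = ", "),
         call. = FALSE)
  }
  invisible(mechanism)
}

# Anchor rules: where on the pH axis each pathway attains its maximum rate.
# The k1/k2/k3/k4 rules are fixed by the mechanistic model (pH 0, the
# plateau above pKa, pH 14 and the zwitterion plateau [pKaH, pKa]); the
# k2Ar/k2cat/k5 rules are model defaults and remain configurable.
.anchor_rules <- c(
  k1    = "max-at-pH-0",
  k2    = "plateau-above-pKa",
  k2Ar  = "plateau-above-pKa",
  k2cat = "peak-at-pKa",
  k3    = "max-at-pH-14",
  k4    = "plateau-between-pKaH-and-pKa",
  k5    = "max-at-pH-0-fall"
)

.valid_anchor_rules <- c("max-at-pH-0", "plateau-above-pKa", "max-at-pH-14",
                         "plateau-between-pKaH-and-pKa", "peak-at-pKa",
                         "max-at-pH-0-fall")

#' Default algorithm configuration
#'
#' Returns the configuration object used throughout the package: the
#' per-mechanism rise/fall slopes of the piecewise-linear log10(k) vs pH
#' curves, the anchor rule for each mechanism (the pH at which its rate is
#' maximal), the caps applied to the combined observed-rate prediction, and
#' numerical settings for calibration-point extraction.
#'
#' Default slopes, in log10(k) per pH unit, follow the mechanistic model:
#' k1: -1; k2: +0.75; k2Ar: +0.75; k2cat: +2/-2; k3: +2; k4: +0.75/-0.75;
#' k5: -0.75. Two-sided mechanisms (k2cat, k4) carry a rise and a fall
#' slope. The combined prediction is capped to `[-9, +2]` log10 units, the
#' span of the measured kinetic data (roughly 22-year to 7-ms half-lives).
#'
#' @param ... Named overrides for any top-level field, e.g.
#'   `cap_high = 3` or `slopes = list(k3 = 1.5)` (slope overrides are merged
#'   into the defaults mechanism by mechanism).
#' @return A list with class `"algo_config"`.
#' @export
#' @examples
#' cfg <- default_algo_config()
#' cfg$slopes$k4
#' default_algo_config(cap_high = 3)$cap_high
default_algo_config <- function(...) {
  cfg <- list(
    slopes = list(
      k1    = -1,
      k2    = 0.75,
      k2Ar  = 0.75,
      k2cat = c(2, -2),
      k3    = 2,
      k4    = c(0.75, -0.75),
      k5    = -0.75
    ),
    anchors  = as.list(.anchor_rules),
    cap_low  = -9,
    cap_high = 2,
    # fallbacks used by impute_acidity() when the training table carries no
    # measured value; NA means "no fallback, fail instead"
    pKa_impute  = NA_real_,
    pKaH_impute = NA_real_,
    # a measurement within this distance of an anchor pH counts as "at" it
    anchor_tol = 0.25,
    # an anchor measurement is attributed directly to a mechanism only when
    # every other active mechanism is at least this many log10 units slower
    # there; otherwise the plateau levels are obtained by joint
    # decomposition of the molecule's whole curve
    dominance_margin = 6,
    # coefficient of determination ("cod") or squared Pearson correlation
    # ("pearson") for reported R^2
    r_squared_method = "cod",
    ph_min  = 0,
    ph_max  = 14,
    ph_step = 0.1
  )
  cfg <- merge_config(cfg, list(...))
  validate_config(cfg)
}

#' Merge configuration overrides into a base configuration
#' @keywords internal
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (nm %in% c("slopes", "anchors") && is.list(override[[nm]])) {
      for (mech in names(override[[nm]])) {
        check_mechanism(mech)
        base[[nm]][[mech]] <- override[[nm]][[mech]]
      }
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Validate an algorithm configuration
#' @param cfg A configuration list.
#' @return `cfg` with class `"algo_config"`, or an error.
#' @keywords internal
validate_config <- function(cfg) {
  stopifnot(is.list(cfg$slopes), is.list(cfg$anchors))
  missing <- setdiff(MECHANISMS, names(cfg$slopes))
  if (length(missing)) {
    stop("config lacks slopes for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (mech in MECHANISMS) {
    s <- cfg$slopes[[mech]]
    if (!is.numeric(s) || !all(is.finite(s)) || length(s) > 2L) {
      stop("invalid slope entry for ", mech, call. = FALSE)
    }
    rule <- cfg$anchors[[mech]]
    if (is.null(rule) || !(rule %in% .valid_anchor_rules)) {
      stop("invalid anchor rule for ", mech, "; valid rules are: ",
           paste(.valid_anchor_rules, collapse = ", "), call. = FALSE)
    }
  }
  if (!(is.numeric(cfg$cap_low) && is.numeric(cfg$cap_high) &&
          cfg$cap_low < cfg$cap_high)) {
    stop("cap_low must be strictly less than cap_high", call. = FALSE)
  }
  if (!(cfg$r_squared_method %in% c("cod", "pearson"))) {
    stop("r_squared_method must be 'cod' or 'pearson'", call. = FALSE)
  }
  structure(cfg, class = "algo_config")
}

#' Read an algorithm configuration from a JSON or YAML file
#'
#' The file may override any subset of fields of [default_algo_config()];
#' unspecified fields keep their defaults. Slope entries may be scalars or
#' two-element rise/fall vectors.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An `algo_config` object.
#' @export
read_algo_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  override <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.list(override)) stop("config file must contain a mapping", call. = FALSE)
  validate_config(merge_config(unclass(default_algo_config()), override))
}

#' @export
print.algo_config <- function(x, ...) {
  cat("Protodeboronation algorithm configuration\n")
  cat("  caps on combined log10(k):", x$cap_low, "to", x$cap_high, "\n")
  cat("  slopes (log10(k)/pH):\n")
  for (mech in MECHANISMS) {
    cat(sprintf("    %-6s %s  [%s]\n", mech,
                paste(format(x$slopes[[mech]]), collapse = " / "),
                x$anchors[[mech]]))
  }
  invisible(x)
}
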