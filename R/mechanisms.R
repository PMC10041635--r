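#' @title Structural categories and active mechanistic pathways
#'
#' @description
#' Not every protodeboronation pathway operates for every boronic acid: the
#' active subset is determined by the structural class of the molecule
#' (e.g. whether it carries a basic ring nitrogen capable of forming the
#' zwitterion required by k4). The taxonomy and the category-to-pathway
#' mapping are shipped as an editable JSON rule table; a declared category
#' column in the molecule table always takes precedence over SMILES-based
#' classification.
#'
#' @name mechanism-rules
NULL

#' Load the packaged mechanism rule table
#'
#' @return A list with elements `categories` (named list mapping category
#'   label to its active mechanisms), `smarts_rules` (ordered substructure
#'   rules for [classify_category()]), `boronic_acid_smarts` and
#'   `heavy_atom_warning`.
#' @export
default_mechanism_rules <- function() {
  read_mechanism_rules(system.file("extdata", "mechanism_rules.json",
                                   package = "protodebor", mustWork = TRUE))
}

#' Read a mechanism rule table from JSON
#'
#' @param path Path to a rule file with the same layout as the packaged
#'   `extdata/mechanism_rules.json`.
#' @return Validated rule list (see [default_mechanism_rules()]).
#' @export
read_mechanism_rules <- function(path) {
  if (!file.exists(path)) stop("rule file not found: ", path, call. = FALSE)
  rules <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(rules$categories) || !length(rules$categories)) {
    stop("rule table defines no categories", call. = FALSE)
  }
  rules$categories <- lapply(rules$categories, function(m) unlist(m))
  for (lab in names(rules$categories)) {
    mechs <- rules$categories[[lab]]
    if (!length(mechs)) {
      stop("category '", lab, "' maps to an empty mechanism set", call. = FALSE)
    }
    bad <- setdiff(mechs, MECHANISMS)
    if (length(bad)) {
      stop("category '", lab, "' lists unknown mechanism(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  rules$smarts_rules <- lapply(rules$smarts_rules, function(r) {
    r$all_of <- unlist(r$all_of)
    r$any_of <- unlist(r$any_of)
    r$none_of <- unlist(r$none_of)
    r
  })
  if (is.null(rules$heavy_atom_warning)) rules$heavy_atom_warning <- 15L
  rules
}

#' Mechanisms active for a structural category
#'
#' Deterministic lookup in the rule table: e.g. `other_basic_heterocycle`
#' activates k1, k2, k3 and k4, while a plain `aryl` boronic acid
#' protodeboronates through k2Ar alone.
#'
#' @param category Category label (must belong to the rule table's closed
#'   taxonomy).
#' @param rules Rule table (see [default_mechanism_rules()]).
#' @return Character vector of active mechanism identifiers (never empty).
#' @export
#' @examples
#' active_mechanisms("other_basic_heterocycle")
#' active_mechanisms("aryl")
active_mechanisms <- function(category, rules = default_mechanism_rules()) {
  stopifnot(is.character(category), length(category) == 1L)
  mechs <- rules$categories[[category]]
  if (is.null(mechs)) {
    stop("unknown category '", category, "'; valid labels are: ",
         paste(names(rules$categories), collapse = ", "), call. = FALSE)
  }
  mechs
}

.require_chemmine <- function() {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
        !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("SMILES classification requires the ChemmineR and ChemmineOB ",
         "packages; assign categories manually instead", call. = FALSE)
  }
}

.smarts_count <- function(sdf, pattern) {
  as.integer(ChemmineR::smartsSearchOB(sdf, pattern, uniqueMatches = FALSE))
}

#' Classify a boronic acid into a structural category from its SMILES
#'
#' Parses the SMILES, checks that the molecule contains exactly one
#' B(OH)2 group bonded to carbon, then evaluates the substructure rules of
#' the rule table in their fixed priority order (most specific first); the
#' first rule whose conditions all hold assigns the category. A molecule
#' with more than `heavy_atom_warning` heavy atoms triggers a warning (the
#' model was built on small boronic acids) but is still classified.
#'
#' This is a convenience layer: a category recorded in the molecule table
#' always wins over SMILES classification.
#'
#' @param smiles SMILES string.
#' @param rules Rule table (see [default_mechanism_rules()]).
#' @return A category label.
#' @export
classify_category <- function(smiles, rules = default_mechanism_rules()) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  .require_chemmine()
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "query"))),
    error = function(e) stop("could not parse SMILES '", smiles, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  n_ba <- .smarts_count(sdf, rules$boronic_acid_smarts)
  if (n_ba == 0L) {
    stop("molecule '", smiles, "' is not of type R-B(OH)2", call. = FALSE)
  }
  if (n_ba > 1L) {
    stop("molecule '", smiles, "' carries ", n_ba, " B(OH)2 groups; ",
         "assign a category manually", call. = FALSE)
  }
  heavy <- sum(ChemmineR::atomcountMA(sdf, addH = FALSE))
  if (heavy > rules$heavy_atom_warning) {
    warning("molecule has ", heavy, " heavy atoms (> ",
            rules$heavy_atom_warning, "); prediction is less reliable for ",
            "large boronic acids", call. = FALSE)
  }
  for (rule in rules$smarts_rules) {
    ok <- all(vapply(rule$all_of, function(p) .smarts_count(sdf, p) > 0L,
                     logical(1)))
    if (ok && length(rule$any_of)) {
      ok <- any(vapply(rule$any_of, function(p) .smarts_count(sdf, p) > 0L,
                       logical(1)))
    }
    if (ok && length(rule$none_of)) {
      ok <- all(vapply(rule$none_of, function(p) .smarts_count(sdf, p) == 0L,
                       logical(1)))
    }
    if (ok && length(rule$min_counts)) {
      ok <- all(vapply(names(rule$min_counts), function(p) {
        .smarts_count(sdf, p) >= as.integer(rule$min_counts[[p]])
      }, logical(1)))
    }
    if (ok) return(rule$category)
  }
  stop("no classification rule matches '", smiles,
       "'; assign a category manually (valid labels: ",
       paste(names(rules$categories), collapse = ", "), ")", call. = FALSE)
}
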