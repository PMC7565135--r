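# Diagnosis class labels, exactly as registry reports print them.
DIAG_BENIGN    <- "Benign/negative for malignancy"
DIAG_MALIGNANT <- "Neoplasm, malignant"
DIAG_ATYPIA    <- "Atypia/dysplasia"
DIAG_UNCERTAIN <- "Neoplasm, uncertain whether benign or malignant"
DIAG_UNCLASSIFIABLE <- "Unclassifiable"

#' Default SNOMED morphology/topography classification rule set
#'
#' Encodes the assignment logic mapping a morphology code combination to a
#' diagnosis class, sub-diagnosis, inflammation sub-result and ICD-O-3 codes,
#' and a topography combination to an organ.
#'
#' Class precedence is Malignant > Uncertain > Atypia/dysplasia > Benign:
#' any malignant code makes the whole combination malignant (a biopsy mixing
#' normal tissue with adenocarcinoma is a cancer case), and so on down the
#' severity ladder. Combinations containing only neutral codes (normal
#' tissue, morphologic description only) are benign with sub-diagnosis
#' "No pathologic diagnosis"; combinations containing only unrecognised
#' codes are Unclassifiable.
#'
#' Benign sub-diagnoses are composed from the components found, joined in
#' the fixed clinical reporting order inflammation, hypertrophy, hyperplasia,
#' edema, atrophy, adenosis (see [benign_label()]). The inflammation,
#' hypertrophy and hyperplasia components are named by explicit codes; the
#' remaining components — and any user-dictionary code — activate by
#' case-insensitive keyword match on the code's dictionary description, so
#' extending the dictionary extends the classifier without code changes.
#' Inflammation-type qualifiers (acute, chronic, granulomatous, ...) found in
#' the descriptions of inflammation codes populate the sub-result.
#'
#' ICD-O-3 behaviour codes follow the registry scheme: benign 8000/0,
#' malignant 8000/3 (adenocarcinoma 8140/3, carcinoma 8010/3, undifferentiated
#' malignant neoplasm 8000/3), uncertain 8000/1, high grade intraepithelial
#' lesion 8148/2. The atypia/dysplasia diagnosis class carries 8000/0, the
#' convention of the registry tables this package reproduces.
#'
#' @return A list of class `snomed_rules`.
#' @seealso [read_rules()] to load a modified rule set from YAML.
#' @export
default_rules <- function() {
  structure(list(
    malignant_codes = c(
      "M-81403" = "Adenocarcinoma",
      "M-80103" = "Carcinoma",
      "M-80003" = "Malignant neoplasm"
    ),
    malignant_icdo3 = c(
      "Adenocarcinoma"     = "8140/3",
      "Carcinoma"          = "8010/3",
      "Malignant neoplasm" = "8000/3"
    ),
    # sub-diagnosis precedence when several malignant codes co-occur
    malignant_order = c("Adenocarcinoma", "Carcinoma", "Malignant neoplasm"),
    uncertain_codes = "M-80001",
    atypia_codes    = "M-69700",
    dysplasia_codes = "M-74000",
    hgpin_codes     = "M-74008",
    hgpin_label     = "High grade intraepithelial lesion",
    hgpin_icdo3     = "8148/2",
    benign_component_codes = c(
      "M-40000" = "inflammation",
      "M-71000" = "hypertrophy",
      "M-72000" = "hyperplasia",
      "M-72440" = "hyperplasia",
      "M-72450" = "hyperplasia"
    ),
    benign_component_keywords = c(
      inflammation = "inflammation|prostatitis",
      hypertrophy  = "hypertroph",
      hyperplasia  = "hyperplas",
      edema        = "\\bo?edema",
      atrophy      = "atroph",
      adenosis     = "adenosis"
    ),
    benign_order = c("inflammation", "hypertrophy", "hyperplasia",
                     "edema", "atrophy", "adenosis"),
    neutral_codes = c("M-00100", "M-09350"),
    inflammation_qualifiers = c("acute", "chronic", "granulomatous"),
    prostate_codes = c("T-92000", "T-28000"),
    diagnosis_icdo3 = c(
      "8000/0", "8000/3", "8000/0", "8000/1", NA_character_
    ) |> stats::setNames(c(DIAG_BENIGN, DIAG_MALIGNANT, DIAG_ATYPIA,
                           DIAG_UNCERTAIN, DIAG_UNCLASSIFIABLE))
  ), class = "snomed_rules")
}

#' Load / save a rule set as a YAML config file
#'
#' Registry teams extend the classifier by editing a plain-text config
#' rather than code. The YAML mirrors the fields of [default_rules()];
#' absent fields fall back to the defaults.
#'
#' @param path YAML file path.
#' @param rules A `snomed_rules` object.
#' @return `read_rules()` returns a `snomed_rules` object.
#' @export
read_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- default_rules()
  for (nm in intersect(names(raw), names(base))) {
    v <- raw[[nm]]
    base[[nm]] <- if (is.list(v)) unlist(v) else v
  }
  validate_rules(base)
  base
}

#' @rdname read_rules
#' @export
write_rules <- function(rules, path) {
  yaml::write_yaml(lapply(unclass(rules), as.list), path)
  invisible(path)
}

validate_rules <- function(rules) {
  if (!identical(rules$benign_order,
                 c("inflammation", "hypertrophy", "hyperplasia",
                   "edema", "atrophy", "adenosis"))) {
    warn("Non-standard benign reporting order in rule set")
  }
  cats <- list(names(rules$malignant_codes), rules$uncertain_codes,
               rules$atypia_codes, rules$dysplasia_codes, rules$hgpin_codes,
               names(rules$benign_component_codes), rules$neutral_codes)
  all_codes <- unlist(cats)
  dup <- unique(all_codes[duplicated(all_codes)])
  if (length(dup) > 0) {
    abort(sprintf("Code(s) assigned to more than one rule category: %s",
                  paste(dup, collapse = ", ")),
          class = "biopsycoder_rules_error")
  }
  invisible(rules)
}

# Which benign component (if any) a single code contributes. Explicit code
# mappings win; otherwise the dictionary description is keyword-matched so
# user-supplied codes participate.
benign_component_of <- function(codes, rules, dict) {
  comp <- unname(rules$benign_component_codes[codes])
  desc <- tolower(dict_lookup(codes, dict))
  for (k in names(rules$benign_component_keywords)) {
    hit <- is.na(comp) & !is.na(desc) &
      grepl(rules$benign_component_keywords[[k]], desc)
    comp[hit] <- k
  }
  comp
}

#' Compose a benign sub-diagnosis label
#'
#' Components are reported in the fixed clinical order (inflammation,
#' hypertrophy, hyperplasia, edema, atrophy, adenosis), joined with
#' `" and "` for two components and `"a, b and c"` style for three or more;
#' only the first component is capitalised, matching registry table strings
#' such as `"Inflammation, hypertrophy and hyperplasia"`.
#'
#' @param components Character vector drawn from the six benign components
#'   (any case, any order).
#' @param rules A `snomed_rules` object supplying the order.
#' @return A single label string.
#' @examples
#' benign_label(c("hypertrophy", "inflammation"))
#' @export
benign_label <- function(components, rules = default_rules()) {
  comp <- tolower(unique(components))
  bad <- setdiff(comp, rules$benign_order)
  if (length(bad) > 0) {
    abort(sprintf("Unknown benign component(s): %s",
                  paste(bad, collapse = ", ")),
          class = "biopsycoder_rules_error")
  }
  if (length(comp) == 0) {
    abort("benign_label() requires at least one component",
          class = "biopsycoder_rules_error")
  }
  comp <- rules$benign_order[rules$benign_order %in% comp]
  lab <- if (length(comp) == 1) {
    comp
  } else if (length(comp) == 2) {
    paste(comp, collapse = " and ")
  } else {
    paste0(paste(comp[-length(comp)], collapse = ", "),
           " and ", comp[length(comp)])
  }
  paste0(toupper(substr(lab, 1, 1)), substr(lab, 2, nchar(lab)))
}

#' Classify a morphology code combination
#'
#' The central assignment: maps one (order-insensitive) combination of
#' SNOMED M codes to the five coded variables of the M lookup table.
#'
#' @param set A `chained_codes` object or character vector of normalised M
#'   codes; must be non-empty.
#' @param rules A `snomed_rules` object.
#' @param dict A code dictionary.
#' @return A one-row tibble with columns `diagnosis`, `diagnosis_icdo3`,
#'   `sub_diagnosis`, `sub_diagnosis_icdo3`, `sub_result` (`NA` where
#'   absent).
#' @examples
#' d <- snomed_dictionary()
#' classify_morphology(c("M-00100", "M-81403"), dict = d)
#' @export
classify_morphology <- function(set, rules = default_rules(),
                                dict = snomed_dictionary()) {
  codes <- if (inherits(set, "chained_codes")) set$codes else set
  if (length(codes) == 0L) {
    abort("Cannot classify an empty (not captured) code set",
          class = "biopsycoder_key_error")
  }
  codes <- unique(codes)
  out <- function(diagnosis, sub_diagnosis = NA_character_,
                  sub_diagnosis_icdo3 = NA_character_,
                  sub_result = NA_character_) {
    tibble(
      diagnosis = diagnosis,
      diagnosis_icdo3 = unname(rules$diagnosis_icdo3[diagnosis]),
      sub_diagnosis = sub_diagnosis,
      sub_diagnosis_icdo3 = sub_diagnosis_icdo3,
      sub_result = sub_result
    )
  }

  malig <- rules$malignant_codes[intersect(codes, names(rules$malignant_codes))]
  if (length(malig) > 0) {
    sub <- rules$malignant_order[rules$malignant_order %in% malig][1]
    return(out(DIAG_MALIGNANT, sub, unname(rules$malignant_icdo3[sub])))
  }

  if (any(codes %in% rules$uncertain_codes)) {
    return(out(DIAG_UNCERTAIN, DIAG_UNCERTAIN, "8000/1"))
  }

  has_hgpin <- any(codes %in% rules$hgpin_codes)
  has_aty   <- any(codes %in% rules$atypia_codes)
  has_dys   <- any(codes %in% rules$dysplasia_codes)
  if (has_hgpin || has_aty || has_dys) {
    if (has_hgpin) {
      return(out(DIAG_ATYPIA, rules$hgpin_label, rules$hgpin_icdo3))
    }
    sub <- if (has_aty && has_dys) "Atypia/dysplasia"
           else if (has_aty) "Atypia" else "Dysplasia"
    return(out(DIAG_ATYPIA, sub))
  }

  comp <- benign_component_of(codes, rules, dict)
  if (any(!is.na(comp))) {
    label <- benign_label(comp[!is.na(comp)], rules)
    sub_result <- NA_character_
    if ("inflammation" %in% comp) {
      infl_desc <- tolower(dict_lookup(codes[which(comp == "inflammation")],
                                       dict))
      quals <- rules$inflammation_qualifiers[
        vapply(rules$inflammation_qualifiers,
               function(q) any(grepl(q, infl_desc, fixed = TRUE)), logical(1))]
      if (length(quals) > 0) sub_result <- paste(quals, collapse = ", ")
    }
    return(out(DIAG_BENIGN, label, sub_result = sub_result))
  }

  if (any(codes %in% rules$neutral_codes)) {
    return(out(DIAG_BENIGN, "No pathologic diagnosis"))
  }

  out(DIAG_UNCLASSIFIABLE)
}

#' Classify a topography code combination
#'
#' A combination is of prostatic origin iff it contains a prostatic-structure
#' code (T-92000 or T-28000 in the default rules); prostate carries ICD-O-3
#' topography C61.9.
#'
#' @inheritParams classify_morphology
#' @return A one-row tibble with columns `organ` (`"Prostate"`/`"Other"`)
#'   and `organ_icdo3` (`"C61.9"` or `NA`).
#' @export
classify_topography <- function(set, rules = default_rules()) {
  codes <- if (inherits(set, "chained_codes")) set$codes else set
  if (length(codes) == 0L) {
    abort("Cannot classify an empty (not captured) code set",
          class = "biopsycoder_key_error")
  }
  prostate <- any(codes %in% rules$prostate_codes)
  tibble(
    organ = if (prostate) "Prostate" else "Other",
    organ_icdo3 = if (prostate) "C61.9" else NA_character_
  )
}
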