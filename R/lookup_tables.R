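#' Extract the unique chained-code combinations from a SNOMED extract column
#'
#' The lookup tables are built over unique code combinations, not records:
#' two extract rows listing the same codes in different orders (or with
#' different spacing) belong to one combination. Raw order-sensitive
#' variants are retained for frequency reporting.
#'
#' @param raws Character vector of chained code strings (blanks/`NA`
#'   allowed; skipped).
#' @param axis `"M"` or `"T"`.
#' @return A tibble with one row per distinct canonical key, sorted by key:
#'   `key`, `codes` (list of normalised code vectors, first-seen capture
#'   order), `raw_variants` (list of distinct raw strings observed), `n_records`.
#' @export
extract_unique_combinations <- function(raws, axis = c("M", "T")) {
  axis <- match.arg(axis)
  code_lists <- chain_parse_column(raws, axis)
  captured <- lengths(code_lists) > 0L
  if (!any(captured)) {
    return(tibble(key = character(0), codes = list(),
                  raw_variants = list(), n_records = integer(0)))
  }
  keys <- vapply(code_lists[captured], canonical_key, character(1))
  tibble(
    key = keys,
    codes = code_lists[captured],
    raw = trimws(as.character(raws)[captured])
  ) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      codes = list(.data$codes[[1]]),
      raw_variants = list(unique(.data$raw)),
      n_records = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$key)
}

#' Build the morphology (M) lookup table
#'
#' One row per unique M-code combination carrying the five coded variables
#' assigned by [classify_morphology()], plus the combined dictionary
#' description. The table is the reusable product of the pipeline: exported
#' once, reviewed/overridden by domain experts, and joined onto any extract.
#'
#' @param combos Output of [extract_unique_combinations()] (or a character
#'   vector of chained strings, converted internally).
#' @param dict Code dictionary.
#' @param rules Classification rule set.
#' @return A tibble of class `m_lookup` with columns `key`,
#'   `combined_description`, `diagnosis`, `diagnosis_icdo3`,
#'   `sub_diagnosis`, `sub_diagnosis_icdo3`, `sub_result`; attributes
#'   `build_stats` (unique-combination counts, order-sensitive variant
#'   count, unknown codes) and `raw_variants`.
#' @export
build_m_lookup <- function(combos, dict = snomed_dictionary(),
                           rules = default_rules()) {
  combos <- as_combos(combos, "M")
  entries <- purrr::map2_dfr(combos$key, combos$codes, function(key, codes) {
    cls <- tryCatch(
      classify_morphology(codes, rules, dict),
      error = function(e) {
        abort(sprintf("While classifying combination %s: %s",
                      key, conditionMessage(e)),
              class = "biopsycoder_rules_error")
      })
    desc <- describe_codes(codes, dict)
    dplyr::bind_cols(
      tibble(key = key, combined_description = as.character(desc)), cls
    )
  })
  if (nrow(entries) == 0) entries <- empty_m_lookup()
  finish_lookup(entries, combos, dict, axis = "M", class = "m_lookup")
}

#' Build the topography (T) lookup table
#'
#' One row per unique T-code combination carrying the organ and its ICD-O-3
#' topography code, assigned by [classify_topography()].
#'
#' @inheritParams build_m_lookup
#' @return A tibble of class `t_lookup` with columns `key`,
#'   `combined_description`, `organ`, `organ_icdo3`.
#' @export
build_t_lookup <- function(combos, dict = snomed_dictionary(),
                           rules = default_rules()) {
  combos <- as_combos(combos, "T")
  entries <- purrr::map2_dfr(combos$key, combos$codes, function(key, codes) {
    dplyr::bind_cols(
      tibble(key = key,
             combined_description = as.character(describe_codes(codes, dict))),
      classify_topography(codes, rules)
    )
  })
  if (nrow(entries) == 0) entries <- empty_t_lookup()
  finish_lookup(entries, combos, dict, axis = "T", class = "t_lookup")
}

as_combos <- function(combos, axis) {
  if (is.character(combos)) combos <- extract_unique_combinations(combos, axis)
  stopifnot(all(c("key", "codes") %in% names(combos)))
  if (anyDuplicated(combos$key)) {
    abort("Combination keys must be unique", class = "biopsycoder_key_error")
  }
  combos
}

finish_lookup <- function(entries, combos, dict, axis, class) {
  entries <- dplyr::arrange(entries, .data$key)
  all_codes <- unique(unlist(combos$codes))
  unknown <- sort(setdiff(all_codes, dict$code))
  raw_variants <- if ("raw_variants" %in% names(combos)) {
    stats::setNames(combos$raw_variants, combos$key)
  } else NULL
  structure(entries,
            class = c(class, "snomed_lookup", class(entries)),
            axis = axis,
            raw_variants = raw_variants,
            build_stats = list(
              n_unique_combinations = nrow(entries),
              n_order_sensitive_variants =
                if (is.null(raw_variants)) NA_integer_
                else length(unique(unlist(raw_variants))),
              unknown_codes = unknown
            ))
}

empty_m_lookup <- function() {
  tibble(key = character(0), combined_description = character(0),
         diagnosis = character(0), diagnosis_icdo3 = character(0),
         sub_diagnosis = character(0), sub_diagnosis_icdo3 = character(0),
         sub_result = character(0))
}

empty_t_lookup <- function() {
  tibble(key = character(0), combined_description = character(0),
         organ = character(0), organ_icdo3 = character(0))
}

#' Lookup-table build statistics
#'
#' @param table A lookup table built by [build_m_lookup()] /
#'   [build_t_lookup()].
#' @return A list: number of unique (order-insensitive) combinations, number
#'   of distinct order-sensitive raw variants, unknown codes encountered.
#' @export
build_stats <- function(table) {
  attr(table, "build_stats")
}

lookup_columns <- list(
  M = c("key", "combined_description", "diagnosis", "diagnosis_icdo3",
        "sub_diagnosis", "sub_diagnosis_icdo3", "sub_result"),
  T = c("key", "combined_description", "organ", "organ_icdo3")
)

#' Persist / load a lookup table as delimited text
#'
#' The round trip is exact (`import_lookup(export_lookup(t))` equals `t`
#' column-for-column), so curated hand edits — the expert-review step of
#' lookup-table maintenance — survive re-import.
#'
#' @param table An `m_lookup` or `t_lookup` tibble.
#' @param path Output file; tab-separated, header row.
#' @param axis `"M"` or `"T"`; inferred from columns when `NULL`.
#' @return `import_lookup()` returns the lookup tibble; a file whose header
#'   lacks required columns raises a load error naming them.
#' @export
export_lookup <- function(table, path) {
  axis <- attr(table, "axis") %||% if ("organ" %in% names(table)) "T" else "M"
  readr::write_tsv(as_tibble(table)[lookup_columns[[axis]]], path, na = "")
  invisible(path)
}

#' @rdname export_lookup
#' @export
import_lookup <- function(path, axis = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  axis <- axis %||% if ("organ" %in% names(tbl)) "T" else "M"
  need <- lookup_columns[[axis]]
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("Lookup file %s lacks column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "biopsycoder_schema_error")
  }
  tbl <- as_tibble(tbl)[need]
  tbl[tbl == ""] <- NA
  cls <- if (axis == "M") "m_lookup" else "t_lookup"
  structure(dplyr::arrange(tbl, .data$key),
            class = c(cls, "snomed_lookup", class(tbl)), axis = axis)
}

#' Apply expert curation overrides to a lookup table
#'
#' Models the manual-review step: a small table of hand-assigned entries,
#' keyed like the lookup table, whose non-`NA` fields replace the rule-based
#' assignment. Precedence: override > rule. Override keys absent from the
#' table are appended as new entries.
#'
#' @param table An `m_lookup`/`t_lookup` tibble.
#' @param overrides A tibble with a `key` column plus any subset of the
#'   table's coded columns.
#' @return The curated lookup table.
#' @export
apply_overrides <- function(table, overrides) {
  stopifnot("key" %in% names(overrides))
  unknown_cols <- setdiff(names(overrides), names(table))
  if (length(unknown_cols) > 0) {
    abort(sprintf("Override column(s) not in lookup table: %s",
                  paste(unknown_cols, collapse = ", ")),
          class = "biopsycoder_schema_error")
  }
  out <- as_tibble(table)
  for (i in seq_len(nrow(overrides))) {
    row <- overrides[i, ]
    j <- match(row$key, out$key)
    if (is.na(j)) {
      out <- dplyr::bind_rows(out, row)
    } else {
      for (col in setdiff(names(overrides), "key")) {
        if (!is.na(row[[col]])) out[j, col] <- row[[col]]
      }
    }
  }
  out <- dplyr::arrange(out, .data$key)
  attr(out, "axis") <- attr(table, "axis")
  attr(out, "build_stats") <- attr(table, "build_stats")
  attr(out, "raw_variants") <- attr(table, "raw_variants")
  class(out) <- class(table)
  out
}
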