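#' Normalise SNOMED CT axis code tokens
#'
#' Laboratory systems and printed reports write the same SNOMED CT axis code
#' in several presentation forms (`"M-81 403"`, `"m-81403"`). The canonical
#' form used throughout this package is upper case with all internal
#' whitespace removed, matching `[MT]-[0-9]+` (e.g. `"M-81403"`).
#'
#' @param raw Character vector of code tokens as captured.
#' @return Character vector of normalised codes, same length as `raw`.
#'   Malformed tokens (no `M-`/`T-` prefix, non-digit body) raise an error
#'   naming the offending token.
#' @examples
#' normalize_code("M-81 403")  # "M-81403"
#' normalize_code("t-92 000")  # "T-92000"
#' @export
normalize_code <- function(raw) {
  if (length(raw) == 0) return(character(0))
  code <- toupper(gsub("[[:space:]]+", "", raw))
  bad <- is.na(code) | !grepl("^[MT]-[0-9]+$", code)
  if (any(bad)) {
    abort(sprintf(
      "Malformed SNOMED axis code token(s): %s (expected e.g. \"M-81 403\")",
      paste(sprintf("\"%s\"", raw[bad]), collapse = ", ")
    ), class = "biopsycoder_parse_error")
  }
  code
}

#' @rdname normalize_code
#' @param code Normalised code(s).
#' @return `code_axis()`: the axis letter, `"M"` or `"T"`.
#' @export
code_axis <- function(code) {
  substr(code, 1L, 1L)
}

#' Render a normalised code in its printed display form
#'
#' Reinserts the conventional thin space in the numeric part (`"M-81403"` ->
#' `"M-81 403"`), the form pathology reports print.
#'
#' @param code Character vector of normalised codes.
#' @return Character vector of display forms.
#' @export
display_code <- function(code) {
  num <- sub("^[MT]-", "", code)
  axis <- substr(code, 1L, 2L)
  spaced <- ifelse(
    nchar(num) > 3,
    paste0(substr(num, 1L, nchar(num) - 3L), " ",
           substr(num, nchar(num) - 2L, nchar(num))),
    num
  )
  paste0(axis, spaced)
}

#' Parse a chained (comma-separated) SNOMED code string
#'
#' One biopsy episode may carry several axis codes captured as a single
#' comma-separated string (e.g. `"M-00 100, M-43 000, M-72 450"`). Parsing
#' splits on commas, trims and normalises each token, and drops exact
#' duplicates keeping the first occurrence. A missing or blank string (or one
#' containing only commas/whitespace) yields an empty, not-captured set.
#'
#' @param raw A single chained string, or `NA`.
#' @param axis `"M"` or `"T"`; every parsed code must carry this axis.
#' @param episode Optional episode identifier included in parse-error
#'   messages.
#' @return An object of class `chained_codes`: a list with elements `axis`,
#'   `codes` (normalised, order as captured, de-duplicated), `raw` and
#'   `captured` (`FALSE` iff `codes` is empty).
#' @examples
#' parse_chained("M-72 450,M-00 100", "M")
#' parse_chained("", "M")$captured  # FALSE
#' @export
parse_chained <- function(raw, axis = c("M", "T"), episode = NULL) {
  axis <- match.arg(axis)
  codes <- chain_parse_column(raw, axis, episode)[[1]]
  structure(
    list(axis = axis, codes = codes,
         raw = if (is.na(raw %||% NA)) "" else as.character(raw),
         captured = length(codes) > 0L),
    class = "chained_codes"
  )
}

# Vectorised workhorse: a character vector of chained strings -> list of
# normalised code vectors. Used by the linkage layer on whole extract columns.
chain_parse_column <- function(raws, axis, episodes = NULL) {
  raws <- as.character(raws)
  raws[is.na(raws)] <- ""
  parts <- strsplit(raws, ",", fixed = TRUE)
  purrr::imap(parts, function(tokens, i) {
    tokens <- trimws(tokens)
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) == 0L) return(character(0))
    codes <- withCallingHandlers(
      normalize_code(tokens),
      error = function(e) {
        if (!is.null(episodes)) {
          abort(sprintf("Episode %s: %s", episodes[[i]], conditionMessage(e)),
                class = "biopsycoder_parse_error")
        }
      }
    )
    wrong <- code_axis(codes) != axis
    if (any(wrong)) {
      abort(sprintf(
        "%sCode(s) %s do not belong to axis %s",
        if (is.null(episodes)) "" else sprintf("Episode %s: ", episodes[[i]]),
        paste(codes[wrong], collapse = ", "), axis
      ), class = "biopsycoder_parse_error")
    }
    codes[!duplicated(codes)]
  })
}

#' @export
print.chained_codes <- function(x, ...) {
  cat(sprintf("<chained_codes %s> %s\n", x$axis,
              if (x$captured) serialize_chain(x) else "(not captured)"))
  invisible(x)
}

#' Serialise a chained code set back to a chained string
#'
#' Joins the display forms with `", "`; re-parsing the result recovers the
#' same normalised code list.
#'
#' @param set A `chained_codes` object.
#' @return A single chained string.
#' @export
serialize_chain <- function(set) {
  paste(display_code(set$codes), collapse = ", ")
}

#' Order- and duplication-insensitive combination key
#'
#' Two chained strings naming the same codes in different orders (both
#' orderings of an adenocarcinoma + malignant-neoplasm pair occur in real
#' extracts) must classify identically, so lookup tables are keyed by the
#' lexicographically sorted, de-duplicated, `"|"`-joined normalised codes.
#'
#' @param set A `chained_codes` object, or a character vector of normalised
#'   codes.
#' @return A single key string, e.g. `"M-80003|M-81403"`.
#' @export
canonical_key <- function(set) {
  codes <- if (inherits(set, "chained_codes")) set$codes else set
  if (length(codes) == 0L) {
    abort("Cannot form a combination key from an empty code set",
          class = "biopsycoder_key_error")
  }
  paste(sort(unique(codes)), collapse = "|")
}

codes_from_key <- function(key) {
  strsplit(key, "|", fixed = TRUE)
}

#' Code dictionary: SNOMED code to description
#'
#' A two-column table mapping normalised axis codes to their LIS description
#' text, used to build the combined-description column of the lookup tables
#' and to drive keyword-based classification of codes the rule set does not
#' name explicitly.
#'
#' `snomed_dictionary()` loads the dictionary shipped with the package: a
#' synthetic stand-in for a real LIS code table covering the morphology and
#' topography codes this pipeline classifies (the real national code table is
#' not redistributable). `read_code_dictionary()` loads a user-supplied file
#' in the same format (delimited text, header row, columns `code` and
#' `description`); user entries override shipped ones for the same code.
#'
#' @param path Path to a delimited dictionary file.
#' @param extra Optional path to a user dictionary merged over the shipped
#'   one.
#' @return A tibble with columns `code`, `description` and a `source`
#'   attribute.
#' @export
snomed_dictionary <- function(extra = NULL) {
  shipped <- read_code_dictionary(
    system.file("extdata", "snomed_dictionary_synthetic.tsv",
                package = "biopsycoder"),
    source = "biopsycoder shipped dictionary (synthetic)"
  )
  if (is.null(extra)) return(shipped)
  user <- read_code_dictionary(extra)
  merged <- dplyr::bind_rows(user, shipped)
  merged <- merged[!duplicated(merged$code), ]
  attr(merged, "source") <- paste0(attr(user, "source"), " + shipped")
  merged
}

#' @rdname snomed_dictionary
#' @param source Provenance label stored on the returned table.
#' @export
read_code_dictionary <- function(path, source = path) {
  tbl <- readr::read_delim(path, delim = guess_delim(path),
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  need <- c("code", "description")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("Dictionary file %s lacks column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "biopsycoder_schema_error")
  }
  out <- tibble(code = normalize_code(tbl$code), description = tbl$description)
  attr(out, "source") <- source
  out
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

dict_lookup <- function(codes, dict) {
  dict$description[match(codes, dict$code)]
}

#' Combined description of a chained code set
#'
#' Joins the per-code dictionary descriptions with a single space in captured
#' order, the form the M/T lookup tables carry. Codes absent from the
#' dictionary render as `"<code>:UNKNOWN"` and are reported via the
#' `unknown` attribute rather than aborting the run.
#'
#' @param set A `chained_codes` object or character vector of normalised
#'   codes.
#' @param dict A code dictionary (see [snomed_dictionary()]).
#' @return A single description string with attribute `unknown` listing
#'   unresolved codes.
#' @export
describe_codes <- function(set, dict) {
  codes <- if (inherits(set, "chained_codes")) set$codes else set
  if (length(codes) == 0L) {
    abort("Cannot describe an empty (not captured) code set",
          class = "biopsycoder_key_error")
  }
  desc <- dict_lookup(codes, dict)
  unknown <- codes[is.na(desc)]
  desc[is.na(desc)] <- paste0(unknown, ":UNKNOWN")
  structure(paste(desc, collapse = " "), unknown = unknown)
}
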