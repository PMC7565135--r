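#' Read the biopsy and SNOMED extracts
#'
#' Both extracts are delimited text (comma by default, tab accepted) with a
#' header row, UTF-8. The biopsy extract carries one row per episode with
#' the demographic/administrative variables and the narrative report; the
#' SNOMED extract carries the chained M and T code strings per episode.
#'
#' @param path File path.
#' @param m_codes_col,t_codes_col Names of the chained-code columns in the
#'   SNOMED extract.
#' @return A tibble. `read_biopsy_extract()` parses `reviewed_date` as a
#'   `Date` and `age` as integer.
#' @export
read_biopsy_extract <- function(path) {
  tbl <- readr::read_delim(path, delim = guess_delim(path),
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  need <- c("episode", "patient_id", "age", "gender", "facility_code",
            "facility_name", "reviewed_date", "narrative")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("Biopsy extract %s lacks column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "biopsycoder_schema_error")
  }
  if (!"race" %in% names(tbl)) tbl$race <- NA_character_
  dplyr::mutate(tbl,
                age = as.integer(.data$age),
                reviewed_date = as.Date(.data$reviewed_date))
}

#' @rdname read_biopsy_extract
#' @export
read_snomed_extract <- function(path, m_codes_col = "m_codes",
                                t_codes_col = "t_codes") {
  tbl <- readr::read_delim(path, delim = guess_delim(path),
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  missing <- setdiff(c("episode", m_codes_col, t_codes_col), names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("SNOMED extract %s lacks column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "biopsycoder_schema_error")
  }
  dplyr::rename(tbl, m_codes = dplyr::all_of(m_codes_col),
                t_codes = dplyr::all_of(t_codes_col))
}

#' Join extracts and lookup tables into classified episodes
#'
#' Reproduces the relational-database step of the workflow: the biopsy
#' extract is the left table; the SNOMED extract and the two lookup tables
#' contribute matching values only (left outer join, referential
#' integrity). Every input biopsy appears exactly once in the output.
#'
#' Episodes without a SNOMED row, or with a blank chained string (blank
#' after trimming, including strings of only commas), are flagged not
#' captured on the corresponding axis and carry no coded fields for it.
#' Combinations absent from a lookup table are flagged unmapped — counted,
#' never dropped. Should a LIS emit several SNOMED rows for one episode,
#' their codes are unioned per axis before classification (classification is
#' combination-based).
#'
#' @param biopsies Biopsy extract tibble ([read_biopsy_extract()]).
#' @param snomed SNOMED extract tibble ([read_snomed_extract()]).
#' @param m_table,t_table Lookup tables ([build_m_lookup()],
#'   [build_t_lookup()]).
#' @return A tibble of classified episodes, sorted by episode, with the
#'   biopsy variables plus `m_raw`, `t_raw`, `m_key`, `t_key`,
#'   `m_captured`, `t_captured`, `m_unmapped`, `t_unmapped`, the five
#'   morphology coded variables and the two topography ones. Attribute
#'   `link_stats` reconciles the counts.
#' @export
join_extracts <- function(biopsies, snomed, m_table, t_table) {
  dup_b <- unique(biopsies$episode[duplicated(biopsies$episode)])
  if (length(dup_b) > 0) {
    abort(sprintf("Duplicate episode(s) in biopsy extract: %s",
                  paste(dup_b, collapse = ", ")),
          class = "biopsycoder_linkage_error")
  }

  # union codes per axis across any repeated SNOMED rows for an episode
  m_lists <- chain_parse_column(snomed$m_codes, "M", snomed$episode)
  t_lists <- chain_parse_column(snomed$t_codes, "T", snomed$episode)
  per_ep <- tibble(episode = snomed$episode,
                   m_raw = trimws(dplyr::coalesce(as.character(snomed$m_codes), "")),
                   t_raw = trimws(dplyr::coalesce(as.character(snomed$t_codes), "")),
                   m_list = m_lists, t_list = t_lists)
  if (anyDuplicated(per_ep$episode)) {
    per_ep <- per_ep |>
      dplyr::group_by(.data$episode) |>
      dplyr::summarise(
        m_raw = paste(unique(.data$m_raw[nzchar(.data$m_raw)]), collapse = ","),
        t_raw = paste(unique(.data$t_raw[nzchar(.data$t_raw)]), collapse = ","),
        m_list = list(unique(unlist(.data$m_list))),
        t_list = list(unique(unlist(.data$t_list))),
        .groups = "drop")
  }
  per_ep <- dplyr::mutate(
    per_ep,
    m_captured = lengths(.data$m_list) > 0L,
    t_captured = lengths(.data$t_list) > 0L,
    m_key = ifelse(.data$m_captured,
                   vapply(.data$m_list, function(x)
                     if (length(x)) canonical_key(x) else NA_character_,
                     character(1)), NA_character_),
    t_key = ifelse(.data$t_captured,
                   vapply(.data$t_list, function(x)
                     if (length(x)) canonical_key(x) else NA_character_,
                     character(1)), NA_character_)
  )

  out <- biopsies |>
    dplyr::left_join(dplyr::select(per_ep, -"m_list", -"t_list"),
                     by = "episode") |>
    dplyr::mutate(
      m_raw = dplyr::coalesce(.data$m_raw, ""),
      t_raw = dplyr::coalesce(.data$t_raw, ""),
      m_captured = dplyr::coalesce(.data$m_captured, FALSE),
      t_captured = dplyr::coalesce(.data$t_captured, FALSE)
    ) |>
    dplyr::left_join(
      as_tibble(m_table)[lookup_columns$M] |>
        dplyr::rename(m_key = "key",
                      m_combined_description = "combined_description"),
      by = "m_key") |>
    dplyr::left_join(
      as_tibble(t_table)[lookup_columns$T] |>
        dplyr::rename(t_key = "key",
                      t_combined_description = "combined_description"),
      by = "t_key") |>
    dplyr::mutate(
      m_unmapped = .data$m_captured & is.na(.data$diagnosis),
      t_unmapped = .data$t_captured & is.na(.data$organ)
    ) |>
    dplyr::arrange(.data$episode)

  stopifnot(nrow(out) == nrow(biopsies))
  attr(out, "link_stats") <- list(
    n_input = nrow(biopsies),
    n_both_captured = sum(out$m_captured & out$t_captured),
    n_m_captured = sum(out$m_captured),
    n_t_captured = sum(out$t_captured),
    n_m_unmapped = sum(out$m_unmapped),
    n_t_unmapped = sum(out$t_unmapped),
    n_no_snomed_row = sum(!biopsies$episode %in% per_ep$episode)
  )
  out
}

#' Cohort filter: age, review-date window, narrative keyword
#'
#' Keeps episodes of men at or above a minimum age, reviewed within an
#' inclusive calendar window, whose narrative report contains a keyword
#' (case-insensitive). Records lacking an age or review date cannot satisfy
#' the filter and are excluded (and counted in the `filter_stats`
#' attribute).
#'
#' @param records Classified episodes (or any tibble with `age`,
#'   `reviewed_date`, `narrative`).
#' @param min_age Minimum age in years, inclusive. Default 30.
#' @param date_range Length-2 `Date` (or coercible) vector, inclusive
#'   endpoints. Default 2006-01-01 to 2016-12-31.
#' @param keyword Narrative keyword. Default `"prostate"`.
#' @return The filtered tibble with attribute `filter_stats`.
#' @export
filter_cohort <- function(records, min_age = 30,
                          date_range = as.Date(c("2006-01-01", "2016-12-31")),
                          keyword = "prostate") {
  date_range <- as.Date(date_range)
  keep_age <- !is.na(records$age) & records$age >= min_age
  keep_date <- !is.na(records$reviewed_date) &
    records$reviewed_date >= date_range[1] &
    records$reviewed_date <= date_range[2]
  keep_kw <- !is.na(records$narrative) &
    stringr::str_detect(stringr::str_to_lower(records$narrative),
                        stringr::fixed(tolower(keyword)))
  out <- records[keep_age & keep_date & keep_kw, ]
  attr(out, "filter_stats") <- list(
    n_input = nrow(records),
    n_kept = nrow(out),
    n_missing_age = sum(is.na(records$age)),
    n_missing_date = sum(is.na(records$reviewed_date)),
    n_excluded_age = sum(!keep_age),
    n_excluded_date = sum(!keep_date),
    n_excluded_keyword = sum(!keep_kw)
  )
  out
}

#' Episodes of prostatic origin with both axes coded
#'
#' The denominator of the diagnosis frequency tables: episodes with both an
#' M and a T code captured whose topography classifies as Prostate.
#'
#' @param records Classified episodes with `m_captured`, `t_captured`,
#'   `organ`.
#' @return The subset, same columns.
#' @export
prostatic_subset <- function(records) {
  records[records$m_captured & records$t_captured &
            !is.na(records$organ) & records$organ == "Prostate", ]
}
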