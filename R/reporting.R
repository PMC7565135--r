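#' Capture contingency table (M x T code completeness)
#'
#' Cross-tabulates whether the M and T chained codes were captured, with
#' margins and percentages of the grand total — the data-completeness
#' surface of the pipeline (e.g. "88% of biopsies carry both codes").
#'
#' @param records Classified episodes with logical `m_captured`,
#'   `t_captured`.
#' @param digits Decimal places for the percentages (0 matches the
#'   registry-table convention).
#' @return An object of class `capture_contingency`: list with integer
#'   `counts` and numeric `percents` matrices (rows M captured / M not /
#'   Total, columns T captured / T not / Total) and `grand_total`.
#' @export
capture_contingency <- function(records, digits = 0) {
  if (nrow(records) == 0) {
    warn("Empty input: capture contingency is all zero")
  }
  m <- factor(ifelse(records$m_captured, "captured", "not_captured"),
              levels = c("captured", "not_captured"))
  t_ <- factor(ifelse(records$t_captured, "captured", "not_captured"),
               levels = c("captured", "not_captured"))
  cells <- table(m, t_)
  counts <- rbind(cbind(cells, Total = rowSums(cells)),
                  Total = c(colSums(cells), sum(cells)))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(
    M = c("M captured", "M not captured", "Total"),
    T = c("T captured", "T not captured", "Total"))
  grand <- sum(cells)
  percents <- pct_matrix(counts, grand, digits)
  structure(list(counts = counts, percents = percents, grand_total = grand,
                 digits = digits),
            class = "capture_contingency")
}

pct_matrix <- function(counts, grand, digits) {
  p <- if (grand == 0) counts * 0 else round_half_up(100 * counts / grand,
                                                     digits)
  dimnames(p) <- dimnames(counts)
  p
}

#' @export
print.capture_contingency <- function(x, ...) {
  cat("Capture contingency (percent of grand total)\n")
  m <- matrix(sprintf("%d (%s%%)", x$counts, fmt_pct(x$percents, x$digits)),
              nrow = 3, dimnames = dimnames(x$counts))
  print(m, quote = FALSE)
  invisible(x)
}

#' @export
as_tibble.capture_contingency <- function(x, ...) {
  tibble(
    m_status = rep(rownames(x$counts), times = 3),
    t_status = rep(colnames(x$counts), each = 3),
    n = as.integer(x$counts),
    percent = as.numeric(x$percents)
  )
}

#' Top-N most frequent M-code combinations
#'
#' Counts the order-sensitive chained M code strings among M-captured
#' episodes — the two orderings of the same code pair are reported as
#' separate rows, as captured in the LIS. Percentages are over all
#' M-captured episodes; ordering is descending by count with lexicographic
#' tie-break on the rendered combination, so output is deterministic.
#'
#' @param records Classified episodes with `m_captured`, `m_raw`.
#' @param n Number of rows to keep (default 10).
#' @param dict Code dictionary for the chained descriptions.
#' @param digits Decimal places for percentages (default 1).
#' @return A tibble `m_codes` (display form), `description`, `n`,
#'   `percent`, with attribute `denominator`.
#' @export
top_combinations <- function(records, n = 10, dict = snomed_dictionary(),
                             digits = 1) {
  stopifnot(n >= 1)
  cap <- records[records$m_captured, ]
  denom <- nrow(cap)
  if (denom == 0) {
    out <- tibble(m_codes = character(0), description = character(0),
                  n = integer(0), percent = numeric(0))
    attr(out, "denominator") <- 0L
    return(out)
  }
  code_lists <- chain_parse_column(cap$m_raw, "M")
  shown <- vapply(code_lists, function(cc) paste(display_code(cc),
                                                 collapse = ", "),
                  character(1))
  out <- tibble(m_codes = shown) |>
    dplyr::count(.data$m_codes, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$m_codes) |>
    dplyr::slice_head(n = n) |>
    dplyr::mutate(
      description = vapply(
        chain_parse_column(.data$m_codes, "M"),
        function(cc) as.character(describe_codes(cc, dict)), character(1)),
      percent = pct(.data$n, denom, digits)
    ) |>
    dplyr::select("m_codes", "description", "n", "percent")
  attr(out, "denominator") <- denom
  out
}

#' Nested diagnosis / sub-diagnosis frequency tables
#'
#' The main result surface: diagnosis-class frequencies over the episodes
#' of prostatic origin, and within each diagnosis the sub-diagnosis
#' frequencies over that diagnosis's count. Where a diagnosis accumulates
#' more than `top_n` sub-diagnoses, the most frequent `top_n` are reported
#' and the remainder rolled up as `"Other"`.
#'
#' @param records Episodes restricted to the prostatic subset (see
#'   [prostatic_subset()]); its size is the diagnosis-level denominator.
#' @param digits Decimal places for percentages (default 2).
#' @param top_n Sub-diagnosis rows before the `"Other"` roll-up.
#' @return An object of class `diagnosis_frequencies`: list with
#'   `diagnosis` (tibble `label`, `icdo3`, `n`, `percent`),
#'   `sub_diagnosis` (named list of tibbles, percents over the diagnosis
#'   count) and `denominator`.
#' @export
diagnosis_frequencies <- function(records, digits = 2, top_n = 10) {
  denom <- nrow(records)
  if (denom == 0) warn("Empty input: diagnosis frequencies are empty")
  diag_tbl <- records |>
    dplyr::filter(!is.na(.data$diagnosis)) |>
    dplyr::count(.data$diagnosis, .data$diagnosis_icdo3, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$diagnosis) |>
    dplyr::mutate(percent = pct(.data$n, denom, digits)) |>
    dplyr::rename(label = "diagnosis", icdo3 = "diagnosis_icdo3")

  subs <- lapply(stats::setNames(diag_tbl$label, diag_tbl$label),
                 function(d) {
    grp <- records[!is.na(records$diagnosis) & records$diagnosis == d, ]
    sub_tbl <- grp |>
      dplyr::mutate(sub_diagnosis =
                      dplyr::coalesce(.data$sub_diagnosis, "(unassigned)")) |>
      dplyr::count(.data$sub_diagnosis, .data$sub_diagnosis_icdo3,
                   name = "n") |>
      dplyr::arrange(dplyr::desc(.data$n), .data$sub_diagnosis) |>
      dplyr::rename(label = "sub_diagnosis", icdo3 = "sub_diagnosis_icdo3")
    if (nrow(sub_tbl) > top_n) {
      head_tbl <- sub_tbl[seq_len(top_n), ]
      other_n <- sum(sub_tbl$n[-seq_len(top_n)])
      sub_tbl <- dplyr::bind_rows(
        head_tbl,
        tibble(label = "Other", icdo3 = NA_character_, n = other_n))
    }
    dplyr::mutate(sub_tbl, percent = pct(.data$n, nrow(grp), digits))
  })

  structure(list(diagnosis = diag_tbl, sub_diagnosis = subs,
                 denominator = denom, digits = digits),
            class = "diagnosis_frequencies")
}

#' @export
print.diagnosis_frequencies <- function(x, ...) {
  cat(sprintf("Diagnosis frequencies (denominator %d)\n", x$denominator))
  print(x$diagnosis, n = Inf)
  for (d in names(x$sub_diagnosis)) {
    cat(sprintf("\nSub-diagnoses: %s\n", d))
    print(x$sub_diagnosis[[d]], n = Inf)
  }
  invisible(x)
}

#' @export
as_tibble.diagnosis_frequencies <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$diagnosis, level = "diagnosis",
                  diagnosis = .data$label, .before = 1),
    purrr::imap_dfr(x$sub_diagnosis, function(tbl, d) {
      dplyr::mutate(tbl, level = "sub_diagnosis", diagnosis = d, .before = 1)
    })
  ) |>
    dplyr::select("level", "diagnosis", "label", "icdo3", "n", "percent")
}

#' Write the report tables to disk
#'
#' Writes each report both as delimited text (for downstream use) and as an
#' aligned plain-text rendering (for reading); output is byte-identical
#' across reruns on identical input. Files: `table2_capture`,
#' `table3_top_combos`, `table4_frequencies` with `.csv`/`.txt`
#' extensions.
#'
#' @param tables A list with any of `capture` ([capture_contingency()]),
#'   `top_combos` ([top_combinations()]), `frequencies`
#'   ([diagnosis_frequencies()]).
#' @param dir Output directory (created if needed).
#' @param format `"delimited"`, `"text"`, or both (default).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(tables, dir, format = c("delimited", "text")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(stem, tbl, txt) {
    if ("delimited" %in% format) {
      p <- file.path(dir, paste0(stem, ".csv"))
      readr::write_csv(tbl, p, na = "")
      paths <<- c(paths, p)
    }
    if ("text" %in% format) {
      p <- file.path(dir, paste0(stem, ".txt"))
      writeLines(txt, p)
      paths <<- c(paths, p)
    }
  }
  if (!is.null(tables$capture)) {
    x <- tables$capture
    emit("table2_capture", as_tibble(x),
         utils::capture.output(print(x)))
  }
  if (!is.null(tables$top_combos)) {
    x <- tables$top_combos
    emit("table3_top_combos", x,
         c(sprintf("Top M code combinations (denominator %d)",
                   attr(x, "denominator") %||% sum(x$n)),
           utils::capture.output(as.data.frame(x))))
  }
  if (!is.null(tables$frequencies)) {
    x <- tables$frequencies
    emit("table4_frequencies", as_tibble(x),
         utils::capture.output(print(x)))
  }
  invisible(paths)
}
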