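# Run `code` with a locally seeded RNG, restoring any prior RNG state so a
# generator call never perturbs the caller's random stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Study-condition defaults. Capture-cell rates are the completeness pattern
# of a national LIS extract (both codes ~88%, T-only ~10%, the rest ~1%
# each); the combination distribution is the observed frequency profile of
# prostate-biopsy morphology reporting (inflammation-only the most common
# single combination at ~15.5% of M-coded episodes, adenocarcinoma
# combinations next), with a tail of less common benign, atypia and
# uncertain combinations.
default_capture_rates <- function() {
  c(both = 22009, m_only = 186, t_only = 2537, neither = 278) / 25010
}

default_combo_distribution <- function() {
  counts <- c(
    "M-40 000" = 3440,
    "M-81 403" = 2677,
    "M-81 403, M-80 003" = 2166,
    "M-00 100" = 1668,
    "M-80 003, M-81 403" = 1596,
    "M-00 100, M-81 403" = 1299,
    "M-00 100, M-72 440" = 1081,
    "M-80 003" = 706,
    "M-09 350" = 394,
    "M-72 440" = 370,
    # tail: benign combinations, chronic/acute prostatitis, atrophy,
    # atypia/dysplasia/HGPIN, uncertain
    "M-40 000, M-72 000" = 2000,
    "M-43 000" = 1500,
    "M-00 100, M-72 450" = 884,
    "M-71 000, M-40 000" = 600,
    "M-69 700" = 616,
    "M-58 000" = 500,
    "M-40 000, M-58 000" = 300,
    "M-72 000, M-58 000" = 250,
    "M-74 000" = 87,
    "M-80 001" = 48,
    "M-74 008" = 13
  )
  counts / sum(counts)
}

default_t_distribution <- function() {
  c("T-92 000" = 0.89375,
    "T-28 000" = 0.02,
    "T-92 000, T-74 000" = 0.02,
    "T-74 000" = 0.06625)
}

default_narrative_templates <- function() {
  c(paste("Clinical history: a {age}-year-old male patient.",
          "Microscopy: cores of prostatic tissue with features of {finding}.",
          "Diagnosis: prostate - {finding}."),
    paste("Clinical details: {age}-year-old man, elevated prostate specific",
          "antigen. Microscopy: sections show prostate tissue exhibiting",
          "{finding}. Pathological diagnosis: prostate: {finding}."))
}

#' Configuration for the synthetic LIS-extract generator
#'
#' Bundles and validates the knobs of [generate_extracts()]. Defaults
#' emulate a national prostate-biopsy extract: 25 010 episodes, the
#' observed capture-completeness pattern, the observed M-code combination
#' frequency profile with a realistic tail, predominantly prostatic
#' topography, ages concentrated in the 55-75 band (support down to 18 so
#' the age filter is exercised), review dates uniform over 2006-2016, and
#' narrative templates that always carry the word "prostate" for in-cohort
#' episodes.
#'
#' @param n_records Number of episodes.
#' @param seed Integer seed; all randomness of a run flows from it.
#' @param capture_rates Named probabilities `both`, `m_only`, `t_only`,
#'   `neither`; must sum to 1 (tolerance 1e-9).
#' @param combo_distribution Named probabilities over chained M strings
#'   (display form); must sum to 1.
#' @param t_distribution Named probabilities over chained T strings.
#' @param order_scramble_prob Probability that a multi-code chained string
#'   is emitted with its codes in a permuted order, emulating
#'   capture-order variation in the LIS.
#' @param age_mean,age_sd,age_min,age_max Age distribution (truncated
#'   normal, rounded to years).
#' @param date_range Inclusive review-date window.
#' @param narrative_templates Character templates with `{age}`/`{finding}`
#'   slots.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_records = 25010,
                             seed = 20060101,
                             capture_rates = default_capture_rates(),
                             combo_distribution = default_combo_distribution(),
                             t_distribution = default_t_distribution(),
                             order_scramble_prob = 0.25,
                             age_mean = 65, age_sd = 11,
                             age_min = 18, age_max = 95,
                             date_range = as.Date(c("2006-01-01",
                                                    "2016-12-31")),
                             narrative_templates =
                               default_narrative_templates()) {
  check_dist <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      abort(sprintf("%s must be non-negative and sum to 1 (got %.12f)",
                    what, sum(p)), class = "biopsycoder_config_error")
    }
  }
  check_dist(capture_rates, "capture_rates")
  check_dist(combo_distribution, "combo_distribution")
  check_dist(t_distribution, "t_distribution")
  stopifnot(setequal(names(capture_rates),
                     c("both", "m_only", "t_only", "neither")),
            n_records >= 1, order_scramble_prob >= 0,
            order_scramble_prob <= 1)
  structure(list(
    n_records = as.integer(n_records), seed = as.integer(seed),
    capture_rates = capture_rates[c("both", "m_only", "t_only", "neither")],
    combo_distribution = combo_distribution,
    t_distribution = t_distribution,
    order_scramble_prob = order_scramble_prob,
    age_mean = age_mean, age_sd = age_sd,
    age_min = age_min, age_max = age_max,
    date_range = as.Date(date_range),
    narrative_templates = narrative_templates
  ), class = "generator_config")
}

#' @rdname generator_config
#' @param path YAML file whose keys mirror the `generator_config()`
#'   arguments.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("capture_rates", "combo_distribution", "t_distribution")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(generator_config, raw)
}

scramble_chain <- function(raw, prob) {
  codes <- strsplit(raw, ",", fixed = TRUE)[[1]] |> trimws()
  if (length(codes) > 1 && stats::runif(1) < prob) {
    codes <- sample(codes)
  }
  paste(codes, collapse = ",")
}

finding_keyword <- function(m_raw, rules, dict) {
  if (!nzchar(m_raw)) return("no specific histological abnormality")
  cls <- classify_morphology(parse_chained(m_raw, "M"), rules, dict)
  switch(cls$diagnosis,
         "Neoplasm, malignant" =
           paste0(tolower(cls$sub_diagnosis), ", Gleason 4 + 3 = 7"),
         "Benign/negative for malignancy" = tolower(cls$sub_diagnosis),
         "Atypia/dysplasia" = tolower(cls$sub_diagnosis),
         "no specific histological abnormality")
}

#' Generate synthetic biopsy and SNOMED extracts
#'
#' Emulates the two LIS/warehouse extract files the coding pipeline
#' consumes: a biopsy extract (episode, patient, age, gender, race,
#' facility, review date, narrative report) and a SNOMED extract (episode,
#' chained M string, chained T string). Missing-code patterns follow the
#' configured capture rates; chained strings are drawn from the configured
#' combination distributions, rendered in the spaced display form, and
#' order-scrambled with the configured probability. Output is fully
#' reproducible from the seed.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_extracts` with tibbles `biopsy` and
#'   `snomed`.
#' @export
generate_extracts <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  rules <- default_rules()
  dict <- snomed_dictionary()
  n <- config$n_records
  with_local_seed(config$seed, {
    cell <- sample(names(config$capture_rates), n, replace = TRUE,
                   prob = config$capture_rates)
    m_cap <- cell %in% c("both", "m_only")
    t_cap <- cell %in% c("both", "t_only")
    m_raw <- character(n)
    m_raw[m_cap] <- sample(names(config$combo_distribution), sum(m_cap),
                           replace = TRUE, prob = config$combo_distribution)
    t_raw <- character(n)
    t_raw[t_cap] <- sample(names(config$t_distribution), sum(t_cap),
                           replace = TRUE, prob = config$t_distribution)
    m_raw[m_cap] <- vapply(m_raw[m_cap], scramble_chain, character(1),
                           prob = config$order_scramble_prob)
    t_raw[t_cap] <- vapply(t_raw[t_cap], scramble_chain, character(1),
                           prob = config$order_scramble_prob)

    age <- pmin(pmax(round(stats::rnorm(n, config$age_mean, config$age_sd)),
                     config$age_min), config$age_max)
    dates <- config$date_range[1] +
      sample.int(as.integer(diff(config$date_range)) + 1L, n,
                 replace = TRUE) - 1L
    template <- sample(config$narrative_templates, n, replace = TRUE)
    finding <- vapply(m_raw, finding_keyword, character(1),
                      rules = rules, dict = dict)
    narrative <- stringr::str_replace_all(
      template, stringr::fixed("{age}"), as.character(age))
    narrative <- stringr::str_replace_all(
      narrative, stringr::fixed("{finding}"), finding)

    fac <- sprintf("F%02d", sample.int(25, n, replace = TRUE))
    biopsy <- tibble(
      episode = sprintf("E%06d", seq_len(n)),
      patient_id = sprintf("P%06d",
                           sample.int(ceiling(n * 0.9), n, replace = TRUE)),
      age = as.integer(age),
      gender = "Male",
      race = ifelse(stats::runif(n) < 0.15, NA_character_,
                    sample(c("Black African", "White", "Coloured", "Indian"),
                           n, replace = TRUE)),
      facility_code = fac,
      facility_name = paste("Facility", fac),
      reviewed_date = dates,
      narrative = narrative
    )
    snomed <- tibble(episode = biopsy$episode,
                     m_codes = m_raw, t_codes = t_raw)
    # episodes with neither code may be absent from the SNOMED extract
    # entirely, as in a real warehouse pull
    snomed <- snomed[cell != "neither" | seq_len(n) %% 2L == 0L, ]
    structure(list(biopsy = biopsy, snomed = snomed),
              class = "synthetic_extracts")
  })
}

#' @rdname generate_extracts
#' @param extracts A `synthetic_extracts` list.
#' @param dir Output directory.
#' @return `write_extracts()` invisibly returns the two file paths
#'   (`biopsy_extract.csv`, `snomed_extract.csv`).
#' @export
write_extracts <- function(extracts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bp <- file.path(dir, "biopsy_extract.csv")
  sp <- file.path(dir, "snomed_extract.csv")
  readr::write_csv(extracts$biopsy, bp, na = "")
  readr::write_csv(extracts$snomed, sp, na = "")
  invisible(c(biopsy = bp, snomed = sp))
}

#' Four worked example episodes
#'
#' A fixed four-episode fixture covering the canonical cases: two benign
#' hyperplasia biopsies (one adenofibromyomatous with normal tissue, one
#' plain), one adenocarcinoma with normal tissue (order showing that a
#' malignant code anywhere in the chain makes the episode malignant), and
#' one benign inflammation-and-hypertrophy biopsy. All four are of
#' prostatic origin (T-92 000). Narratives are synthetic condensed reports
#' containing the word "prostate" (and a Gleason mention for the malignant
#' episode, which this pipeline deliberately does not parse).
#'
#' @return A list of class `synthetic_extracts` with tibbles `biopsy` and
#'   `snomed` (episodes `A`-`D`).
#' @export
table1_fixture <- function() {
  biopsy <- tibble(
    episode = c("A", "B", "C", "D"),
    patient_id = paste0("P", 1:4),
    age = c(86L, 57L, 82L, 61L),
    gender = "Male",
    race = NA_character_,
    facility_code = "F01",
    facility_name = "Facility F01",
    reviewed_date = as.Date(c("2009-10-19", "2013-03-12",
                              "2014-02-16", "2016-10-28")),
    narrative = c(
      paste("An 86-year-old male, PSA 14.1. Multiple cores of prostatic",
            "tissue with benign fibromuscular and adenomatous hyperplasia.",
            "Diagnosis: prostate - benign hyperplasia."),
      paste("A 57-year-old man, re-TURP. Fragments of prostate tissue with",
            "benign nodular glandular and stromal hyperplasia and mild",
            "chronic prostatitis. No malignancy."),
      paste("An 82-year-old patient, PSA 273, hard multinodular prostate.",
            "Numerous cores with extensive infiltration by adenocarcinoma,",
            "Gleason 4 + 3 = 7. Focal perineural invasion."),
      paste("A 61-year-old male, PSA 10.4. Prostate: seminal vesicles and",
            "rectal mucosa represented; foci of chronic inflammation;",
            "benign prostatic enlargement. No PIN or adenocarcinoma.")
    )
  )
  snomed <- tibble(
    episode = c("A", "B", "C", "D"),
    m_codes = c("M-72 450,M-00 100", "M-72 000",
                "M-00 100,M-81 403", "M-71 000,M-40 000"),
    t_codes = c("T-92 000", "T-92 000", "T-92 000", "T-92 000")
  )
  structure(list(biopsy = biopsy, snomed = snomed),
            class = "synthetic_extracts")
}

# label -> ICD-O-3 for fixture records
sub_label_icdo3 <- function(label) {
  map <- c("Adenocarcinoma" = "8140/3", "Carcinoma" = "8010/3",
           "Malignant neoplasm" = "8000/3",
           "High grade intraepithelial lesion" = "8148/2")
  map[label] |> unname()
}

# Benign sub-diagnosis labels not among `named`, used to split an "Other"
# roll-up count into record-level labels that stay out of the top-N.
unnamed_benign_labels <- function(named, rules = default_rules()) {
  comps <- rules$benign_order
  subsets <- c(lapply(comps, identity),
               utils::combn(comps, 2, simplify = FALSE),
               utils::combn(comps, 3, simplify = FALSE))
  labels <- vapply(subsets, benign_label, character(1), rules = rules)
  setdiff(labels, named)
}

#' Build a record-level fixture from exact category counts
#'
#' Inverse of the reporting layer: given exact counts for the capture
#' contingency cells, the number of prostatic-origin episodes, the
#' diagnosis/sub-diagnosis distribution and/or the chained M combination
#' distribution, construct a deterministic classified-episode tibble whose
#' reports reproduce those counts exactly. Used to drive the reporting
#' surfaces with published marginal counts when the record-level source
#' data cannot be shipped.
#'
#' A benign `"Other"` sub-diagnosis count is split across unnamed benign
#' component labels, each kept strictly below the smallest named count, so
#' a top-N + Other roll-up reproduces the named rows exactly. Combination
#' counts beyond those named are filled with distinct low-frequency tail
#' combinations the same way.
#'
#' @param capture Named integer vector `both`, `m_only`, `t_only`,
#'   `neither`.
#' @param organ_prostate Number of both-captured episodes of prostatic
#'   origin (at most `capture["both"]`).
#' @param diagnoses Tibble with columns `diagnosis`, `sub_diagnosis`, `n`:
#'   the sub-diagnosis-level counts over the prostatic subset; must sum to
#'   `organ_prostate`.
#' @param combos Tibble with columns `raw` (chained M display string) and
#'   `n`: counts over all M-captured episodes; must sum to at most the
#'   M-captured total (the remainder is filled with tail combinations).
#' @return A classified-episode tibble compatible with
#'   [capture_contingency()], [top_combinations()], [prostatic_subset()]
#'   and [diagnosis_frequencies()]. Inconsistent nested counts raise an
#'   error naming the violated sum.
#' @export
fixture_from_counts <- function(capture, organ_prostate = NULL,
                                diagnoses = NULL, combos = NULL) {
  capture <- capture[c("both", "m_only", "t_only", "neither")]
  if (anyNA(capture) || any(capture < 0)) {
    abort("capture must supply non-negative counts both/m_only/t_only/neither",
          class = "biopsycoder_config_error")
  }
  n <- sum(capture)
  n_both <- capture[["both"]]
  n_mcap <- capture[["both"]] + capture[["m_only"]]
  if (!is.null(organ_prostate) && organ_prostate > n_both) {
    abort(sprintf(
      "organ_prostate (%d) exceeds the both-captured count (%d)",
      organ_prostate, n_both), class = "biopsycoder_config_error")
  }
  if (!is.null(diagnoses)) {
    if (is.null(organ_prostate)) organ_prostate <- sum(diagnoses$n)
    if (sum(diagnoses$n) != organ_prostate) {
      abort(sprintf(
        "diagnosis counts sum to %d but organ_prostate is %d",
        sum(diagnoses$n), organ_prostate),
        class = "biopsycoder_config_error")
    }
  }
  organ_prostate <- organ_prostate %||% n_both

  rec <- tibble(
    episode = sprintf("E%06d", seq_len(n)),
    patient_id = sprintf("P%06d", seq_len(n)),
    age = 65L, gender = "Male", race = NA_character_,
    facility_code = "F01", facility_name = "Facility F01",
    reviewed_date = as.Date("2010-06-15"),
    narrative = "Synthetic prostate biopsy report.",
    m_captured = rep(c(TRUE, TRUE, FALSE, FALSE), capture),
    t_captured = rep(c(TRUE, FALSE, TRUE, FALSE), capture),
    m_raw = "", t_raw = "",
    organ = NA_character_, organ_icdo3 = NA_character_,
    diagnosis = NA_character_, diagnosis_icdo3 = NA_character_,
    sub_diagnosis = NA_character_, sub_diagnosis_icdo3 = NA_character_,
    sub_result = NA_character_
  )

  both_idx <- which(rec$m_captured & rec$t_captured)
  pro_idx <- both_idx[seq_len(organ_prostate)]
  rec$organ[both_idx] <- "Other"
  rec$t_raw[rec$t_captured] <- "T-74 000"
  rec$organ[pro_idx] <- "Prostate"
  rec$organ_icdo3[pro_idx] <- "C61.9"
  rec$t_raw[pro_idx] <- "T-92 000"
  # T-only records still carry a topography
  t_only_idx <- which(!rec$m_captured & rec$t_captured)
  rec$t_raw[t_only_idx] <- "T-92 000"
  rec$organ[t_only_idx] <- "Prostate"
  rec$organ_icdo3[t_only_idx] <- "C61.9"

  if (!is.null(diagnoses)) {
    diagnoses <- expand_other_rows(diagnoses)
    rules <- default_rules()
    lab <- rep(seq_len(nrow(diagnoses)), diagnoses$n)
    rec$diagnosis[pro_idx] <- diagnoses$diagnosis[lab]
    rec$diagnosis_icdo3[pro_idx] <-
      unname(rules$diagnosis_icdo3[diagnoses$diagnosis[lab]])
    rec$sub_diagnosis[pro_idx] <- diagnoses$sub_diagnosis[lab]
    rec$sub_diagnosis_icdo3[pro_idx] <-
      sub_label_icdo3(diagnoses$sub_diagnosis[lab])
  }

  mcap_idx <- which(rec$m_captured)
  if (!is.null(combos)) {
    if (sum(combos$n) > n_mcap) {
      abort(sprintf(
        "combination counts sum to %d but only %d episodes are M-captured",
        sum(combos$n), n_mcap), class = "biopsycoder_config_error")
    }
    combos <- fill_combo_remainder(combos, n_mcap)
    rec$m_raw[mcap_idx] <- rep(combos$raw, combos$n)
  } else {
    rec$m_raw[mcap_idx] <- "M-00 100"
  }
  rec
}

# Split rows whose sub_diagnosis is "Other" into unnamed benign labels each
# strictly below the smallest named benign count.
expand_other_rows <- function(diagnoses) {
  is_other <- diagnoses$sub_diagnosis == "Other"
  if (!any(is_other)) return(diagnoses)
  out <- diagnoses[!is_other, ]
  for (i in which(is_other)) {
    d <- diagnoses$diagnosis[i]
    named_n <- diagnoses$n[!is_other & diagnoses$diagnosis == d]
    cap <- max(1L, min(named_n) - 1L)
    pool <- unnamed_benign_labels(
      diagnoses$sub_diagnosis[diagnoses$diagnosis == d])
    remaining <- diagnoses$n[i]
    k <- 0L
    while (remaining > 0) {
      k <- k + 1L
      if (k > length(pool)) {
        abort(sprintf(
          "Cannot split Other count %d below the named minimum %d: pool of %d labels exhausted",
          diagnoses$n[i], min(named_n), length(pool)),
          class = "biopsycoder_config_error")
      }
      take <- min(cap, remaining)
      out <- dplyr::bind_rows(out, tibble(
        diagnosis = d, sub_diagnosis = pool[k], n = take))
      remaining <- remaining - take
    }
  }
  out
}

# Fill the gap between named combination counts and the M-captured total
# with distinct tail combinations, each strictly below the named minimum.
fill_combo_remainder <- function(combos, n_mcap) {
  remaining <- n_mcap - sum(combos$n)
  if (remaining == 0) return(combos)
  cap <- max(1L, min(combos$n) - 1L)
  pool_codes <- c("M-00 100", "M-09 350", "M-36 300", "M-41 000", "M-43 000",
                  "M-44 000", "M-58 000", "M-71 000", "M-72 000", "M-72 400",
                  "M-72 440", "M-72 450")
  pairs <- expand.grid(a = pool_codes, b = pool_codes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  pool <- c(pool_codes, paste(pairs$a, pairs$b, sep = ", "))
  norm <- function(x) vapply(chain_parse_column(x, "M"),
                             function(cc) paste(cc, collapse = ","),
                             character(1))
  pool <- pool[!norm(pool) %in% norm(combos$raw)]
  k <- 0L
  while (remaining > 0) {
    k <- k + 1L
    if (k > length(pool)) {
      abort("Cannot fill combination remainder: tail pool exhausted",
            class = "biopsycoder_config_error")
    }
    take <- min(cap, remaining)
    combos <- dplyr::bind_rows(combos, tibble(raw = pool[k], n = take))
    remaining <- remaining - take
  }
  combos
}
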