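test_that("generator configs validate their probability mappings", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(capture_rates = c(both = 0.5, m_only = 0.2,
                                                  t_only = 0.2,
                                                  neither = 0.2)),
               "sum to 1", class = "biopsycoder_config_error")
  expect_error(generator_config(combo_distribution = c("M-40 000" = 0.9)),
               class = "biopsycoder_config_error")

  p <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_records = 50, seed = 3,
                        order_scramble_prob = 0), p)
  cfg <- read_generator_config(p)
  expect_identical(cfg$n_records, 50L)
  expect_identical(cfg$order_scramble_prob, 0)
})

test_that("the same seed yields byte-identical extracts", {
  cfg <- generator_config(n_records = 400, seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_extracts(generate_extracts(cfg), d1)
  write_extracts(generate_extracts(cfg), d2)
  for (f in c("biopsy_extract.csv", "snomed_extract.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  other <- generate_extracts(generator_config(n_records = 400, seed = 78))
  expect_false(identical(other, generate_extracts(cfg)))
})

test_that("generated extracts respect the configured structure", {
  cfg <- generator_config(n_records = 2000, seed = 5)
  ex <- generate_extracts(cfg)
  expect_identical(nrow(ex$biopsy), 2000L)
  expect_false(anyDuplicated(ex$biopsy$episode) > 0)
  expect_true(all(grepl("prostat", tolower(ex$biopsy$narrative))))
  expect_true(all(ex$biopsy$age >= 18))
  expect_true(all(ex$biopsy$reviewed_date >= as.Date("2006-01-01") &
                    ex$biopsy$reviewed_date <= as.Date("2016-12-31")))
  # chained strings parse cleanly in display form
  nz <- ex$snomed$m_codes[nzchar(ex$snomed$m_codes)]
  expect_silent(invisible(lapply(nz[1:50], parse_chained, axis = "M")))
})

test_that("generation recovers the configured rates within binomial error", {
  cfg <- generator_config(n_records = 10000, seed = 20060101)
  ex <- generate_extracts(cfg)
  cls <- run_pipeline(ex)
  n <- nrow(cls)

  p_both <- cfg$capture_rates[["both"]]
  se <- sqrt(p_both * (1 - p_both) / n)
  both_frac <- mean(cls$m_captured & cls$t_captured)
  expect_lt(abs(both_frac - p_both), 3 * se)

  # per-category morphology proportions among M-captured episodes
  mcap <- cls[cls$m_captured, ]
  combo_norm <- vapply(
    biopsycoder:::chain_parse_column(names(cfg$combo_distribution), "M"),
    canonical_key, character(1))
  target <- tapply(cfg$combo_distribution, combo_norm, sum)
  for (key in c("M-40000", "M-80003|M-81403", "M-00100")) {
    p <- sum(target[names(target) == key])
    got <- mean(mcap$m_key == key)
    expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / nrow(mcap)))
  }

  # prostatic fraction among both-captured episodes
  both <- cls[cls$m_captured & cls$t_captured, ]
  p_pro <- sum(cfg$t_distribution[c("T-92 000", "T-28 000",
                                    "T-92 000, T-74 000")])
  got_pro <- mean(both$organ == "Prostate")
  expect_lt(abs(got_pro - p_pro), 3 * sqrt(p_pro * (1 - p_pro) / nrow(both)))
})

test_that("order scrambling never changes classification output", {
  base <- generator_config(n_records = 600, seed = 9,
                           order_scramble_prob = 0)
  scrambled <- generator_config(n_records = 600, seed = 9,
                                order_scramble_prob = 1)
  a <- run_pipeline(generate_extracts(base))
  b <- run_pipeline(generate_extracts(scrambled))
  cols <- c("episode", "m_captured", "t_captured", "diagnosis",
            "diagnosis_icdo3", "sub_diagnosis", "sub_diagnosis_icdo3",
            "sub_result", "organ", "organ_icdo3")
  expect_identical(as.data.frame(a[cols]), as.data.frame(b[cols]))
})

test_that("exact-count fixtures reproduce their specification and validate nesting", {
  rec <- fixture_from_counts(capture_counts, organ_prostate = 20551,
                             diagnoses = diagnosis_counts,
                             combos = combo_counts)
  expect_identical(nrow(rec), 25010L)
  ct <- capture_contingency(rec)
  expect_identical(as.integer(ct$counts[1:2, 1:2]),
                   c(22009L, 2537L, 186L, 278L))
  f <- diagnosis_frequencies(prostatic_subset(rec))
  got <- f$diagnosis$n[match(unique(diagnosis_counts$diagnosis),
                             f$diagnosis$label)]
  want <- tapply(diagnosis_counts$n, diagnosis_counts$diagnosis, sum)
  expect_identical(got, as.integer(want[unique(diagnosis_counts$diagnosis)]))

  # round trip: report of fixture equals the spec (fixture o report identity)
  ben <- f$sub_diagnosis[["Benign/negative for malignancy"]]
  spec_ben <- diagnosis_counts[
    diagnosis_counts$diagnosis == "Benign/negative for malignancy", ]
  expect_identical(
    ben$n[match(spec_ben$sub_diagnosis[spec_ben$sub_diagnosis != "Other"],
                ben$label)],
    as.integer(spec_ben$n[spec_ben$sub_diagnosis != "Other"]))
  expect_identical(ben$n[ben$label == "Other"],
                   as.integer(spec_ben$n[spec_ben$sub_diagnosis == "Other"]))

  # zero-count categories are omitted
  f0 <- diagnosis_frequencies(prostatic_subset(
    fixture_from_counts(c(both = 10, m_only = 0, t_only = 0, neither = 0),
                        diagnoses = tibble::tibble(
                          diagnosis = c("Neoplasm, malignant",
                                        "Atypia/dysplasia"),
                          sub_diagnosis = c("Adenocarcinoma", "Atypia"),
                          n = c(10, 0)))))
  expect_identical(f0$diagnosis$label, "Neoplasm, malignant")

  # inconsistent nesting errors name the violated sum
  expect_error(
    fixture_from_counts(capture_counts, organ_prostate = 100,
                        diagnoses = diagnosis_counts),
    "20551", class = "biopsycoder_config_error")
  expect_error(
    fixture_from_counts(c(both = 10, m_only = 0, t_only = 0, neither = 0),
                        organ_prostate = 20),
    "exceeds", class = "biopsycoder_config_error")
  expect_error(
    fixture_from_counts(c(both = 5, m_only = 0, t_only = 0, neither = 0),
                        combos = tibble::tibble(raw = "M-40 000", n = 9)),
    class = "biopsycoder_config_error")
})

test_that("the worked-example fixture carries the printed codes and dates", {
  fx <- table1_fixture()
  expect_identical(fx$snomed$m_codes,
                   c("M-72 450,M-00 100", "M-72 000", "M-00 100,M-81 403",
                     "M-71 000,M-40 000"))
  expect_true(all(fx$snomed$t_codes == "T-92 000"))
  expect_identical(fx$biopsy$reviewed_date,
                   as.Date(c("2009-10-19", "2013-03-12", "2014-02-16",
                             "2016-10-28")))
  expect_true(grepl("Gleason", fx$biopsy$narrative[3]))
  expect_true(all(grepl("prostate", tolower(fx$biopsy$narrative))))
})
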