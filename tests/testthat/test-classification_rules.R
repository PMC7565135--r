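dict <- snomed_dictionary()
rules <- default_rules()

test_that("the four worked episodes classify to their published assignments", {
  cases <- list(
    list(c("M-72450", "M-00100"), "Benign/negative for malignancy", "8000/0",
         "Hyperplasia", NA),
    list("M-72000", "Benign/negative for malignancy", "8000/0",
         "Hyperplasia", NA),
    list(c("M-00100", "M-81403"), "Neoplasm, malignant", "8000/3",
         "Adenocarcinoma", "8140/3"),
    list(c("M-71000", "M-40000"), "Benign/negative for malignancy", "8000/0",
         "Inflammation and hypertrophy", NA)
  )
  for (cs in cases) {
    got <- classify_morphology(cs[[1]], rules, dict)
    expect_identical(got$diagnosis, cs[[2]])
    expect_identical(got$diagnosis_icdo3, cs[[3]])
    expect_identical(got$sub_diagnosis, cs[[4]])
    expect_identical(got$sub_diagnosis_icdo3, as.character(cs[[5]]))
  }
})

test_that("malignant sub-diagnosis precedence and the M-80003-only case", {
  only_malig <- classify_morphology("M-80003", rules, dict)
  expect_identical(only_malig$sub_diagnosis, "Malignant neoplasm")
  expect_identical(only_malig$sub_diagnosis_icdo3, "8000/3")

  both <- classify_morphology(c("M-80003", "M-81403"), rules, dict)
  expect_identical(both$sub_diagnosis, "Adenocarcinoma")
  expect_identical(both$sub_diagnosis_icdo3, "8140/3")
  expect_identical(both, classify_morphology(c("M-81403", "M-80003"),
                                             rules, dict))

  carc <- classify_morphology(c("M-80103", "M-80003"), rules, dict)
  expect_identical(carc$sub_diagnosis, "Carcinoma")
  expect_identical(carc$sub_diagnosis_icdo3, "8010/3")
})

test_that("atypia, dysplasia, HGPIN and uncertain classes assign as specified", {
  expect_identical(classify_morphology("M-69700", rules, dict)$sub_diagnosis,
                   "Atypia")
  expect_identical(classify_morphology("M-74000", rules, dict)$sub_diagnosis,
                   "Dysplasia")
  both <- classify_morphology(c("M-69700", "M-74000"), rules, dict)
  expect_identical(both$sub_diagnosis, "Atypia/dysplasia")
  expect_identical(both$diagnosis_icdo3, "8000/0")

  hg <- classify_morphology(c("M-74008", "M-69700"), rules, dict)
  expect_identical(hg$sub_diagnosis, "High grade intraepithelial lesion")
  expect_identical(hg$sub_diagnosis_icdo3, "8148/2")

  un <- classify_morphology("M-80001", rules, dict)
  expect_identical(un$diagnosis,
                   "Neoplasm, uncertain whether benign or malignant")
  expect_identical(un$diagnosis_icdo3, "8000/1")

  # severity precedence: malignant beats uncertain beats atypia beats benign
  expect_identical(
    classify_morphology(c("M-80001", "M-81403"), rules, dict)$diagnosis,
    "Neoplasm, malignant")
  expect_identical(
    classify_morphology(c("M-69700", "M-80001"), rules, dict)$diagnosis,
    "Neoplasm, uncertain whether benign or malignant")
  expect_identical(
    classify_morphology(c("M-40000", "M-69700"), rules, dict)$diagnosis,
    "Atypia/dysplasia")
})

test_that("benign labels follow the fixed six-component reporting order", {
  expect_identical(benign_label(c("hypertrophy", "inflammation")),
                   "Inflammation and hypertrophy")
  expect_identical(
    benign_label(c("hyperplasia", "hypertrophy", "inflammation")),
    "Inflammation, hypertrophy and hyperplasia")
  expect_identical(benign_label("inflammation"), "Inflammation")
  expect_identical(benign_label(c("adenosis", "edema", "atrophy")),
                   "Edema, atrophy and adenosis")
  expect_error(benign_label("necrosis"), "necrosis",
               class = "biopsycoder_rules_error")
  expect_error(benign_label(character(0)),
               class = "biopsycoder_rules_error")
})

test_that("neutral-only, unknown-only and inflammation qualifiers", {
  no_path <- classify_morphology("M-00100", rules, dict)
  expect_identical(no_path$diagnosis, "Benign/negative for malignancy")
  expect_identical(no_path$sub_diagnosis, "No pathologic diagnosis")

  expect_identical(classify_morphology("M-99999", rules, dict)$diagnosis,
                   "Unclassifiable")
  expect_error(classify_morphology(character(0), rules, dict),
               class = "biopsycoder_key_error")

  # inflammation sub-result from the code description keyword
  chronic <- classify_morphology("M-43000", rules, dict)
  expect_identical(chronic$sub_diagnosis, "Inflammation")
  expect_identical(chronic$sub_result, "chronic")
  expect_identical(classify_morphology("M-41000", rules, dict)$sub_result,
                   "acute")
  expect_identical(classify_morphology("M-44000", rules, dict)$sub_result,
                   "granulomatous")
  expect_true(is.na(classify_morphology("M-40000", rules, dict)$sub_result))

  # keyword-activated benign components (edema/atrophy/adenosis)
  expect_identical(classify_morphology("M-58000", rules, dict)$sub_diagnosis,
                   "Atrophy")
  expect_identical(
    classify_morphology(c("M-40000", "M-36300"), rules, dict)$sub_diagnosis,
    "Inflammation and edema")
})

test_that("topography classifies prostatic origin from either prostate code", {
  expect_identical(classify_topography("T-92000", rules)$organ_icdo3, "C61.9")
  expect_identical(classify_topography("T-28000", rules)$organ, "Prostate")
  other <- classify_topography("T-74000", rules)
  expect_identical(other$organ, "Other")
  expect_true(is.na(other$organ_icdo3))
  expect_identical(classify_topography(c("T-92000", "T-74000"),
                                       rules)$organ, "Prostate")
  expect_error(classify_topography(character(0), rules),
               class = "biopsycoder_key_error")
})

test_that("classification is a pure function of the canonical key", {
  pool <- c("M-00100", "M-09350", "M-40000", "M-43000", "M-58000",
            "M-71000", "M-72000", "M-72440", "M-72450", "M-80003",
            "M-81403", "M-69700", "M-80001")
  set.seed(31)
  for (i in 1:40) {
    codes <- sample(pool, sample(1:4, 1))
    base <- classify_morphology(codes, rules, dict)
    perm <- classify_morphology(sample(codes), rules, dict)
    dup <- classify_morphology(sample(rep(codes, 2)), rules, dict)
    expect_identical(perm, base)
    expect_identical(dup, base)
  }
})

test_that("rule engine agrees with a brute-force oracle over all small subsets", {
  # independent oracle: the precedence ladder written as literal nested
  # conditionals over code membership, no shared code with the rule engine
  oracle <- function(codes) {
    if ("M-81403" %in% codes) return(c("Neoplasm, malignant", "Adenocarcinoma"))
    if ("M-80103" %in% codes) return(c("Neoplasm, malignant", "Carcinoma"))
    if ("M-80003" %in% codes) return(c("Neoplasm, malignant",
                                       "Malignant neoplasm"))
    if ("M-80001" %in% codes) {
      return(rep("Neoplasm, uncertain whether benign or malignant", 2))
    }
    if ("M-74008" %in% codes) return(c("Atypia/dysplasia",
                                       "High grade intraepithelial lesion"))
    has_aty <- "M-69700" %in% codes
    has_dys <- "M-74000" %in% codes
    if (has_aty && has_dys) return(c("Atypia/dysplasia", "Atypia/dysplasia"))
    if (has_aty) return(c("Atypia/dysplasia", "Atypia"))
    if (has_dys) return(c("Atypia/dysplasia", "Dysplasia"))
    comp <- c(
      if (any(codes %in% c("M-40000", "M-41000", "M-43000", "M-44000")))
        "inflammation",
      if ("M-71000" %in% codes) "hypertrophy",
      if (any(codes %in% c("M-72000", "M-72440", "M-72450"))) "hyperplasia",
      if ("M-36300" %in% codes) "edema",
      if ("M-58000" %in% codes) "atrophy",
      if ("M-72400" %in% codes) "adenosis")
    if (length(comp) > 0) {
      lab <- if (length(comp) == 1) comp
             else if (length(comp) == 2) paste(comp, collapse = " and ")
             else paste0(paste(head(comp, -1), collapse = ", "), " and ",
                         tail(comp, 1))
      substr(lab, 1, 1) <- toupper(substr(lab, 1, 1))
      return(c("Benign/negative for malignancy", lab))
    }
    if (any(codes %in% c("M-00100", "M-09350"))) {
      return(c("Benign/negative for malignancy", "No pathologic diagnosis"))
    }
    c("Unclassifiable", NA)
  }

  m_codes <- dict$code[code_axis(dict$code) == "M"]
  subsets <- c(lapply(m_codes, identity),
               utils::combn(m_codes, 2, simplify = FALSE),
               utils::combn(m_codes, 3, simplify = FALSE))
  for (codes in subsets) {
    got <- classify_morphology(codes, rules, dict)
    want <- oracle(codes)
    expect_identical(got$diagnosis, want[1])
    expect_identical(got$sub_diagnosis, as.character(want[2]))
  }
})

test_that("rule sets round-trip through YAML and reject category overlap", {
  p <- withr::local_tempfile(fileext = ".yaml")
  write_rules(rules, p)
  back <- read_rules(p)
  expect_identical(back$benign_order, rules$benign_order)
  expect_identical(
    classify_morphology(c("M-40000", "M-71000"), back, dict),
    classify_morphology(c("M-40000", "M-71000"), rules, dict))

  clash <- rules
  clash$neutral_codes <- c(clash$neutral_codes, "M-81403")
  expect_error(biopsycoder:::validate_rules(clash), "M-81403",
               class = "biopsycoder_rules_error")
})
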