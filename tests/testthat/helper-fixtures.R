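# Shared fixtures built in code: the published marginal counts of the
# capture contingency table and of the diagnosis/sub-diagnosis distribution,
# used as exact-count inputs to the fixture builder.

capture_counts <- c(both = 22009, m_only = 186, t_only = 2537, neither = 278)

diagnosis_counts <- tibble::tribble(
  ~diagnosis, ~sub_diagnosis, ~n,
  "Benign/negative for malignancy", "Inflammation", 4075,
  "Benign/negative for malignancy", "No pathologic diagnosis", 2809,
  "Benign/negative for malignancy", "Hyperplasia", 2174,
  "Benign/negative for malignancy", "Inflammation and hyperplasia", 788,
  "Benign/negative for malignancy", "Inflammation and hypertrophy", 123,
  "Benign/negative for malignancy", "Atrophy", 120,
  "Benign/negative for malignancy", "Hypertrophy", 82,
  "Benign/negative for malignancy", "Inflammation and atrophy", 63,
  "Benign/negative for malignancy", "Hyperplasia and atrophy", 55,
  "Benign/negative for malignancy",
    "Inflammation, hypertrophy and hyperplasia", 31,
  "Benign/negative for malignancy", "Other", 121,
  "Neoplasm, malignant", "Adenocarcinoma", 8201,
  "Neoplasm, malignant", "Carcinoma", 408,
  "Neoplasm, malignant", "Malignant neoplasm", 693,
  "Atypia/dysplasia", "Atypia", 616,
  "Atypia/dysplasia", "Dysplasia", 87,
  "Atypia/dysplasia", "Atypia/dysplasia", 44,
  "Atypia/dysplasia", "High grade intraepithelial lesion", 13,
  "Neoplasm, uncertain whether benign or malignant",
    "Neoplasm, uncertain whether benign or malignant", 48
)

combo_counts <- tibble::tribble(
  ~raw, ~n,
  "M-40 000", 3440,
  "M-81 403", 2677,
  "M-81 403, M-80 003", 2166,
  "M-00 100", 1668,
  "M-80 003, M-81 403", 1596,
  "M-00 100, M-81 403", 1299,
  "M-00 100, M-72 440", 1081,
  "M-80 003", 706,
  "M-09 350", 394,
  "M-72 440", 370
)

# run the complete pipeline (lookup build + join) on an extracts pair
run_pipeline <- function(extracts, dict = snomed_dictionary(),
                         rules = default_rules()) {
  m <- build_m_lookup(extract_unique_combinations(extracts$snomed$m_codes,
                                                  "M"), dict, rules)
  t <- build_t_lookup(extract_unique_combinations(extracts$snomed$t_codes,
                                                  "T"), dict, rules)
  join_extracts(extracts$biopsy, extracts$snomed, m, t)
}
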