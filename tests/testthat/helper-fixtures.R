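# Shared fixtures, loaded once per test run.
table1 <- load_fixture("table1")
table2 <- load_fixture("table2")
hwe33 <- filter_hwe(table1)
wetdry22 <- filter_hwe(table2)

# A tiny hand-made study table for unit tests.
toy_studies <- function(counts) {
  # counts: list of 6-vectors c(case_AA, case_AG, case_GG, ctrl_AA, ctrl_AG, ctrl_GG)
  df <- tibble::tibble(
    author = sprintf("Toy%d", seq_along(counts)),
    year = 2000L + seq_along(counts),
    country = "toyland", ethnicity = "Asian", amd_type = "AMD",
    soc = "HB", method = "Sequencing",
    case_AA = vapply(counts, `[`, 0, 1), case_AG = vapply(counts, `[`, 0, 2),
    case_GG = vapply(counts, `[`, 0, 3), ctrl_AA = vapply(counts, `[`, 0, 4),
    ctrl_AG = vapply(counts, `[`, 0, 5), ctrl_GG = vapply(counts, `[`, 0, 6),
    hwe_p_printed = NA_character_)
  dplyr::bind_cols(tibble::tibble(study_id = paste(df$author, df$year)), df)
}

# Tables tibble straight from 2x2 cells.
toy_tables <- function(a, b, c, d) {
  tibble::tibble(study_id = sprintf("s%d", seq_along(a)),
                 a = a, b = b, c = c, d = d, continuity = FALSE)
}
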