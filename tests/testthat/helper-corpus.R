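# Minimal valid concurrent-reader corpus rows for targeted edits in tests.
make_corpus_row <- function(study_label = "Study A",
                            reading_mode = "concurrent_reader",
                            no_cad = 150, with_cad = 100,
                            diff = with_cad - no_cad,
                            sd_no = 30, sd_with = 25, ...) {
  tibble::tibble(
    study_label = study_label, country = "Nowhere", modality = "CT",
    cad_product = "TestCAD", reading_mode = reading_mode,
    reader_label = NA_character_,
    no_cad_central = no_cad, no_cad_dispersion_kind = "sd",
    no_cad_dispersion = sd_no, no_cad_lo = NA_real_, no_cad_hi = NA_real_,
    with_cad_central = with_cad, with_cad_dispersion_kind = "sd",
    with_cad_dispersion = sd_with, with_cad_lo = NA_real_,
    with_cad_hi = NA_real_,
    diff_seconds = diff, diff_ci_lo = NA_real_, diff_ci_hi = NA_real_,
    p_value = NA_character_, ...
  )
}

default_settings <- function() load_settings("default")
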