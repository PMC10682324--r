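test_that("packaged evidence table loads with the expected composition", {
  corpus <- load_corpus("table1")
  expect_s3_class(corpus, "rt_corpus")
  expect_equal(nrow(corpus), 8)
  expect_equal(sum(corpus$reading_mode == "concurrent_reader"), 6)
  expect_equal(sum(corpus$reading_mode == "second_reader"), 2)
  # the two-reader study contributes two rows under one label
  expect_equal(sum(corpus$study_label == "Hempel (2022)"), 2)
})

test_that("fixture matches the published table cell-for-cell", {
  corpus <- load_corpus("table1")
  hsu2 <- corpus[corpus$study_label == "Hsu (2021)" &
                 corpus$reading_mode == "second_reader", ]
  expect_equal(hsu2$diff_seconds, 41)
  expect_equal(c(hsu2$diff_ci_lo, hsu2$diff_ci_hi), c(39, 44))
  expect_equal(c(hsu2$no_cad_central, hsu2$no_cad_dispersion), c(156, 34))
  expect_equal(c(hsu2$with_cad_central, hsu2$with_cad_dispersion), c(197, 46))

  hempel <- corpus[corpus$study_label == "Hempel (2022)", ]
  expect_equal(hempel$reader_label, c("Reader 1", "Reader 2"))
  expect_equal(hempel$no_cad_central, c(226.4, 320.8))
  expect_equal(hempel$with_cad_central, c(150.8, 184.2))
  expect_equal(hempel$diff_seconds, c(-75.6, -136.6))

  jacobs <- corpus[corpus$study_label == "Jacobs (2021)", ]
  expect_equal(jacobs$no_cad_dispersion_kind, "iqr_bounds")
  expect_equal(c(jacobs$no_cad_lo, jacobs$no_cad_central, jacobs$no_cad_hi),
               c(96, 160, 245))
  expect_equal(c(jacobs$with_cad_lo, jacobs$with_cad_central,
                 jacobs$with_cad_hi), c(51, 86, 141))

  kozuka <- corpus[corpus$study_label == "Kozuka (2020)", ]
  expect_equal(kozuka$no_cad_dispersion_kind, "none")
  expect_true(is.na(kozuka$p_value))
  expect_equal(kozuka$diff_seconds, -18)

  lo <- corpus[corpus$study_label == "Lo (2018)", ]
  expect_equal(c(lo$no_cad_central, lo$with_cad_central), c(127.2, 95.6))
  # CI stored sign-normalized and ordered
  expect_equal(c(lo$diff_ci_lo, lo$diff_ci_hi), c(-47.4, -15.9))
})

test_that("corpus round-trips identically through CSV and JSON", {
  corpus <- load_corpus("table1")
  for (ext in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_corpus(corpus, path)
    reread <- load_corpus(path)
    expect_equal(as.data.frame(reread), as.data.frame(corpus),
                 tolerance = 1e-12)
  }
})

test_that("empty corpus file yields an empty corpus with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(cadbreakeven:::corpus_columns, collapse = ","), path)
  expect_warning(corpus <- load_corpus(path), "empty")
  expect_equal(nrow(corpus), 0)
})

test_that("validation rejects malformed observations with row and field", {
  row <- make_corpus_row()
  bad <- row; bad$no_cad_central <- NA_real_
  expect_error(validate_corpus(bad), "no_cad_central.*mandatory")
  bad <- row; bad$no_cad_central <- -5
  expect_error(validate_corpus(bad), "row 1.*no_cad_central.*> 0")
  bad <- row; bad$with_cad_dispersion <- NA_real_
  expect_error(validate_corpus(bad), "sd must be present")
  bad <- row; bad$no_cad_dispersion_kind <- "iqr_bounds"
  expect_error(validate_corpus(bad), "bounds required")
  bad <- row; bad$diff_ci_lo <- 10; bad$diff_ci_hi <- 5
  expect_error(validate_corpus(bad), "out of order")
  # sign convention is enforced per reading mode
  bad <- row; bad$diff_seconds <- 12
  expect_error(validate_corpus(bad), "concurrent_reader.*negative")
  bad <- make_corpus_row(reading_mode = "second_reader", diff = -4)
  expect_error(validate_corpus(bad), "second_reader.*positive")
})

test_that("default settings reproduce the published configuration", {
  s <- default_settings()
  expect_equal(s$countries$name, c("USA", "UK", "Poland"))
  expect_equal(s$countries$hourly_cost_eur, c(196, 127, 45))
  expect_equal(s$countries$eur_per_local_unit, c(0.9518, 1.1731, 0.2135))
  ppu <- s$pricing[s$pricing$kind == "pay_per_use", ]
  expect_equal(c(ppu$price_eur_lo, ppu$price_eur_hi), c(5.9, 8.8))
  expect_equal(
    s$pricing$price_eur[s$pricing$kind == "one_off_license"], 51616)
  expect_equal(
    s$pricing$price_eur[s$pricing$kind == "yearly_subscription"], 20000)
  expect_equal(s$scenario$prevalence_lo, 0.22)
  expect_equal(s$scenario$prevalence_hi, 0.51)
  expect_equal(s$scenario$ruleout_fraction, 0.80)
  expect_equal(s$printed_pooled$no_cad$mean, 162)
  expect_equal(s$printed_pooled$saved_time_concurrent$ci_lo, 47)
})

test_that("settings validation catches bad rates and prices", {
  cfg <- list(
    countries = list(list(name = "X", hourly_cost_local = 100,
                          currency_code = "XXX", eur_per_local_unit = -1)),
    pricing = list(list(kind = "one_off_license", price_eur = 1000)))
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  expect_error(load_settings(path), "exchange rate must be > 0")
  cfg$countries[[1]]$eur_per_local_unit <- 1
  cfg$pricing[[1]]$price_eur <- -5
  yaml::write_yaml(cfg, path)
  expect_error(load_settings(path), "positive `price_eur`")
})

test_that("currency conversion matches published figures and is linear", {
  expect_equal(convert_to_eur(44000, 1.1731), 51616.4)
  expect_equal(round_half_up(convert_to_eur(44000, 1.1731), 0), 51616)
  expect_equal(round_half_up(convert_to_eur(211, 0.2135), 0), 45)
  expect_equal(round_half_up(convert_to_eur(206, 0.9518), 0), 196)
  expect_equal(convert_to_eur(123.4, 1.0), 123.4)
  expect_error(convert_to_eur(10, 0), "> 0")
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 0, 1e5); b <- runif(1, 0, 1e5); r <- runif(1, 0.1, 2)
    expect_equal(convert_to_eur(a + b, r),
                 convert_to_eur(a, r) + convert_to_eur(b, r))
  }
})
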