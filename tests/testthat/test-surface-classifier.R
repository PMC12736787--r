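planted_sp <- paste0("MK", strrep("L", 10), "AQA", strrep("D", 30))
planted_lipo <- paste0("MK", strrep("L", 10), "LSGC", strrep("E", 30))
planted_lpxtg <- paste0("M", strrep("E", 100), "LPKTG", strrep("I", 18), "KRKRK")

test_that("signal-peptide detector finds planted constructs and rejects controls", {
  sp <- detect_signal_peptide(planted_sp)
  expect_equal(sp$cleavage_pos, 15L)
  expect_lte(sp$h_end, sp$cleavage_pos - 1L)
  expect_equal(sp$sp_mean_kd, window_hydropathy(planted_sp, 1, sp$cleavage_pos))
  expect_null(detect_signal_peptide(strrep("D", 60)))
  # hydrophobic window alone is not enough: cleavage motif must sit in range
  expect_null(detect_signal_peptide(paste0("MK", strrep("L", 10), strrep("D", 40))))
  # A-X-A too early (before sp_cleave_min) does not qualify
  expect_null(detect_signal_peptide(paste0("MAQA", strrep("L", 8), strrep("D", 40))))
})

test_that("lipobox detector enforces pattern, position gate, and hydrophobic region", {
  expect_equal(detect_lipobox(planted_lipo), 13L)
  expect_null(detect_lipobox(paste0("LSGC", strrep("D", 40))))          # Cys at 4 < min
  expect_null(detect_lipobox(paste0("MK", strrep("L", 10), "LTGC", strrep("E", 30))))  # T not A/S
  expect_null(detect_lipobox(paste0("MK", strrep("D", 10), "LSGC", strrep("E", 30))))  # no h-region
})

test_that("LPXTG detector requires motif, TM window after it, and charged tail", {
  expect_equal(detect_lpxtg_anchor(planted_lpxtg), 102L)
  expect_null(detect_lpxtg_anchor(paste0("M", strrep("E", 100), "LPKTG", strrep("I", 18), "QQQQQ")))
  expect_null(detect_lpxtg_anchor(paste0("M", strrep("E", 100), "LPKTG", strrep("D", 18), "KRKRK")))
  # motif too far from the C-terminus
  expect_null(detect_lpxtg_anchor(paste0("M", "LPKTG", strrep("E", 100), strrep("I", 18), "KRKRK")))
  # last qualifying motif wins
  two <- paste0("M", strrep("E", 80), "LPATG", strrep("E", 10), "LPKTG", strrep("I", 18), "KRKRK")
  expect_equal(detect_lpxtg_anchor(two), 97L)
})

test_that("classification applies the lpxtg > lipoprotein > secreted precedence", {
  expect_equal(classify_protein("a", planted_sp)$category, "secreted")
  expect_equal(classify_protein("b", planted_lipo)$category, "lipoprotein")
  expect_equal(classify_protein("c", planted_lpxtg)$category, "lpxtg_anchored")
  expect_equal(classify_protein("d", strrep("D", 80))$category, "none")

  # a sequence with both a cleavage motif and a lipobox is a lipoprotein
  both <- paste0("MK", strrep("L", 10), "AQA", "LSGC", strrep("E", 30))
  call <- classify_protein("e", both)
  expect_equal(call$category, "lipoprotein")
  expect_false(is.na(call$cleavage_pos))  # evidence is retained
})

test_that("proteome classification partitions proteins and counts add up", {
  lab <- generate_proteome(
    proteome_spec(n_proteins = 400, n_secreted = 30, n_lipoprotein = 3,
                  n_lpxtg = 4, seed = 21)
  )
  calls <- classify_proteome(lab$proteome)
  expect_equal(nrow(calls), 400)
  expect_true(all(calls$category %in% c("secreted", "lipoprotein", "lpxtg_anchored", "none")))
  s <- surface_summary(calls)
  expect_equal(s$n_surface, s$n_secreted + s$n_lipoprotein + s$n_lpxtg)
  expect_equal(s$n_total, 400)
  expect_identical(glance(calls), s)

  # identical calls regardless of record order
  shuffled <- lab$proteome[sample(nrow(lab$proteome)), ]
  calls2 <- classify_proteome(shuffled)
  reord <- calls2[match(calls$protein_id, calls2$protein_id), ]
  expect_equal(as.data.frame(reord), as.data.frame(calls))
})

test_that("raising the hydrophobicity threshold never increases secreted calls", {
  lab <- generate_proteome(
    proteome_spec(n_proteins = 300, n_secreted = 25, n_lipoprotein = 2,
                  n_lpxtg = 2, seed = 33)
  )
  n_prev <- Inf
  for (th in c(1.0, 1.5, 2.0, 2.8)) {
    n_sec <- surface_summary(
      classify_proteome(lab$proteome, classifier_params(h_thresh = th))
    )$n_secreted
    expect_lte(n_sec, n_prev)
    n_prev <- n_sec
  }
})

test_that("poly-D proteins yield zero surface calls", {
  prot <- tibble::tibble(
    id = paste0("p", 1:5),
    description = "",
    sequence = strrep("D", 60 + 10 * (1:5))
  )
  expect_equal(surface_summary(classify_proteome(prot))$n_surface, 0)
})

test_that("classifier params validate and round-trip through a config file", {
  expect_error(classifier_params(h_window = 0), "positive")
  expect_error(classifier_params(sp_cleave_min = 50, sp_cleave_max = 45), "<=")
  expect_error(classifier_params(h_thresh = Inf), "finite")

  cfg <- withr::local_tempfile(fileext = ".conf")
  writeLines(c("# tuned", "h_thresh: 2.0", "sp_scan_len = 50"), cfg)
  p <- read_classifier_config(cfg)
  expect_equal(p$h_thresh, 2.0)
  expect_equal(p$sp_scan_len, 50L)
  expect_equal(p$h_window, classifier_params()$h_window)

  writeLines("h_tresh: 2.0", cfg)
  expect_error(read_classifier_config(cfg), "unknown classifier parameter")

  shipped <- system.file("extdata", "benchmark-params.conf", package = "probioprofile")
  expect_s3_class(read_classifier_config(shipped), "classifier_params")
})
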