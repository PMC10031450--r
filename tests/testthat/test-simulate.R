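test_that("generator configuration validates its inputs", {
  expect_error(generator_config(n_notes = 0), "n_notes")
  expect_error(generator_config(category_mix = c(medication_only = 1,
                                                 symptom_only = 1,
                                                 both = 1, none = 1)),
               "sum to 1")
  expect_error(generator_config(asr_error_note_rate = 1.5), "asr_error")
  cfg <- generator_config()
  expect_equal(sum(cfg$category_mix), 1)
  expect_equal(cfg$n_notes, 87L)
  expect_equal(cfg$asr_error_note_rate, 0.18)
})

test_that("identical seeds yield byte-identical corpora", {
  c1 <- generate_corpus(generator_config(n_notes = 40, seed = 99), LEX)
  c2 <- generate_corpus(generator_config(n_notes = 40, seed = 99), LEX)
  expect_identical(serialize_corpus(c1), serialize_corpus(c2))
  c3 <- generate_corpus(generator_config(n_notes = 40, seed = 100), LEX)
  expect_false(identical(serialize_corpus(c1), serialize_corpus(c3)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- stats::runif(1)
  set.seed(123)
  invisible(generate_corpus(generator_config(n_notes = 5, seed = 77), LEX))
  b <- stats::runif(1)
  expect_identical(a, b)
})

test_that("default category mix lands near the emulated corpus shares", {
  corpus <- generate_corpus(generator_config(n_notes = 87, seed = 42), LEX)
  cats <- vapply(corpus$gold, function(g) {
    n_med <- length(g$gold_instances); n_sym <- length(g$gold_symptoms)
    if (n_med > 0 && n_sym == 0) "medication_only"
    else if (n_med == 0 && n_sym > 0) "symptom_only"
    else if (n_med > 0) "both" else "none"
  }, character(1))
  obs <- table(factor(cats, levels = c("medication_only", "symptom_only",
                                       "both", "none")))
  expected <- c(17, 33, 13, 24)
  # within ~4 multinomial standard deviations of the target mix
  sds <- sqrt(87 * (expected / 87) * (1 - expected / 87))
  expect_true(all(abs(as.integer(obs) - expected) <= ceiling(4 * sds)))
})

test_that("taper notes carry one gold instance per descending rate", {
  found <- FALSE
  for (seed in 1:5) {
    corpus <- generate_corpus(generator_config(n_notes = 40, seed = seed,
                                               asr_error_note_rate = 0),
                              LEX)
    for (g in corpus$gold) {
      if (length(g$gold_instances) >= 2) {
        qty <- vapply(g$gold_instances, `[[`, numeric(1), "quantity")
        expect_true(all(diff(qty) < 0))
        expect_length(unique(vapply(g$gold_instances, `[[`, character(1),
                                    "medication")), 1)
        found <- TRUE
      }
    }
  }
  expect_true(found)
})

test_that("noise intensity zero leaves text untouched", {
  txt <- "Gave Alex 2 Benadryl at 6:00 am."
  expect_identical(apply_asr_noise(txt, 0), txt)
})

test_that("the digit-to-word swap respects dose and time atoms", {
  conf <- default_asr_confusions()
  set.seed(7)
  seen_word <- FALSE
  for (i in 1:50) {
    out <- apply_asr_noise("2", 1, conf)
    expect_true(out %in% c("2", "two"))
    if (out == "two") seen_word <- TRUE
  }
  expect_true(seen_word)
  # digits inside decimals and clock times are never word-swapped
  for (i in 1:50) {
    out <- apply_asr_noise("2.6 at 6:00", 1, conf)
    expect_false(grepl("two|six", out))
  }
})

test_that("gold is emitted at generation time, unaltered by noise", {
  cfg_quiet <- generator_config(n_notes = 30, seed = 55,
                                asr_error_note_rate = 0)
  cfg_noisy <- generator_config(n_notes = 30, seed = 55,
                                asr_error_note_rate = 1)
  g1 <- generate_corpus(cfg_quiet, LEX)
  g2 <- generate_corpus(cfg_noisy, LEX)
  expect_true(all(g2$noisy))
  # same seed, same sampled content: the gold stream is identical even
  # though every note text passed through the noise channel
  expect_equal(g2$gold, g1$gold)
  expect_false(identical(vapply(g2$notes, `[[`, character(1), "text"),
                         vapply(g1$notes, `[[`, character(1), "text")))
})

test_that("ambiguous patient names reproduce the name/medication error mode", {
  cfg <- generator_config(n_notes = 60, seed = 21, asr_error_note_rate = 0,
                          ambiguous_name_rate = 1)
  corpus <- generate_corpus(cfg, LEX)
  rep <- suppressMessages(evaluate_corpus(extract_corpus(corpus$notes, LEX),
                                          corpus$gold))$report
  expect_lt(rep$precision[rep$component == "medication"], 1)
  # recall is untouched: the real medications are still found
  expect_equal(rep$recall[rep$component == "medication"], 1)
})
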