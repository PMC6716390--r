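test_that("unigram counting collapses variants, splits senses, conserves mass", {
  h <- hand_corpus()
  uni <- count_unigrams(h$corpus, h$forms, h$inflection_map, h$polysemy_map)
  got <- setNames(uni$counts$count, uni$counts$item_id)
  expect_equal(got[names(h$expected$counts)], h$expected$counts)
  expect_equal(uni$total_tokens, h$expected$total_tokens)
  expect_equal(uni$unmapped_tokens, h$expected$unmapped)
  # mass conservation: mapped mass + unmapped tokens = total adult tokens
  expect_equal(sum(uni$counts$count) + uni$unmapped_tokens, uni$total_tokens)

  # tiny hand case from first principles
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines("ADU\tdog dogs cat", tmp)
  mini <- count_unigrams(read_chat_lite(tmp),
                         tibble::tibble(item_id = c("dog", "cat"),
                                        word_form = c("dog", "cat")),
                         tibble::tibble(variant_form = "dogs",
                                        canonical_item = "dog"))
  expect_equal(setNames(mini$counts$count, mini$counts$item_id),
               c(dog = 2, cat = 1))

  # child-filtered view of the same corpus: only the 5 CHI "dog" lines count
  kid <- count_unigrams(h$corpus, h$forms, h$inflection_map, h$polysemy_map,
                        speaker_filter = "child")
  expect_equal(sum(kid$counts$count), 5)
  expect_equal(kid$counts$count[kid$counts$item_id == "dog"], 5)

  expect_error(count_unigrams(h$corpus[0, ], h$forms), "empty")
})

test_that("log-normalized frequency implements Laplace smoothing per million", {
  expect_equal(log_normalized_frequency(0, 1e6), log(1))        # 0 -> 1
  expect_equal(log_normalized_frequency(1e6, 1e6), log(1e6))    # count = total
  # log-ratio identity: counts 3 vs 30 differ by exactly ln(10)
  lf <- log_normalized_frequency(c(3, 30), 12345)
  expect_equal(lf[2] - lf[1], log(10))
  # order-preserving above the smoothing floor
  expect_true(all(diff(log_normalized_frequency(c(1, 2, 5, 99), 1000)) > 0))
  expect_error(log_normalized_frequency(-1, 100), "nonnegative")
})

test_that("solo and final counts follow the positional definitions", {
  h <- hand_corpus()
  sf <- solo_and_final_counts(h$corpus, h$forms, h$inflection_map,
                              h$polysemy_map)
  expect_equal(setNames(sf$solo$count, sf$solo$item_id)[names(h$expected$solo)],
               h$expected$solo)
  expect_equal(setNames(sf$final$count, sf$final$item_id)[names(h$expected$final)],
               h$expected$final)

  # corpus with no multi-word utterances: all final counts are zero
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("ADU\tdog", "ADU\tcat", "ADU\tdog"), tmp)
  solo_only <- solo_and_final_counts(
    read_chat_lite(tmp),
    tibble::tibble(item_id = c("dog", "cat"), word_form = c("dog", "cat")))
  expect_equal(sum(solo_only$final$count), 0)
  expect_equal(setNames(solo_only$solo$count, solo_only$solo$item_id),
               c(dog = 2, cat = 1))
})

test_that("MLU-w averages utterance lengths and respects the threshold", {
  h <- hand_corpus()
  mlu <- compute_mlu_w(h$corpus, h$forms, h$inflection_map, h$polysemy_map)
  got <- setNames(mlu$mlu_w, mlu$item_id)
  expect_equal(got[names(h$expected$mlu)], h$expected$mlu)
  occ <- setNames(mlu$occurrences, mlu$item_id)
  expect_equal(occ[names(h$expected$occurrences)], h$expected$occurrences)

  # an item seen >= 10 times only in single-word utterances has MLU-w 1
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(rep("ADU\thi", 12), tmp)
  solo_mlu <- compute_mlu_w(read_chat_lite(tmp),
                            tibble::tibble(item_id = "hi", word_form = "hi"))
  expect_equal(solo_mlu$mlu_w, 1)
})

test_that("residualization matches hand OLS and is orthogonal", {
  # perfect linear relation: residuals all zero
  cov <- c(1, 2, 3, 4)
  expect_equal(residualize(2 * cov + 5, cov), rep(0, 4))
  # hand-computed case: slope 1.5, intercept -0.5
  expect_equal(residualize(c(0, 0, 3), c(0, 1, 2)), c(0.5, -1, 0.5))
  # orthogonality on arbitrary data
  set.seed(42)
  x <- rnorm(200); y <- 0.7 * x + rnorm(200)
  r <- residualize(y, x)
  expect_lt(abs(sum(r * x)), 1e-8 * sqrt(sum(r^2) * sum(x^2)))
  expect_lt(abs(sum(r)), 1e-8)
  expect_error(residualize(c(1, 2, 3), c(2, 2, 2)), "constant")
})

test_that("phoneme counting reads delimiter-separated transcriptions", {
  tr <- tibble::tibble(item_id = c("dog", "eye", "refrigerator"),
                       phonemes = c("d o g", "aI", "r I f r I dZ @ r eI t @ r"))
  counts <- count_phonemes(tr)
  expect_equal(setNames(counts$n_phonemes, counts$item_id),
               c(dog = 3, eye = 1, refrigerator = 12))
  expect_error(count_phonemes(tibble::tibble(item_id = "x", phonemes = "  ")),
               "empty")
})

test_that("predictor scaling standardizes and preserves missingness", {
  tab <- tibble::tibble(item_id = c("a", "b", "c"),
                        frequency = c(1, 2, 3),
                        mlu_w = c(2, NA, 6))
  scaled <- scale_predictors(tab)
  expect_equal(scaled$frequency, c(-1, 0, 1))   # sample SD of (1,2,3) is 1
  expect_true(is.na(scaled$mlu_w[2]))
  # observed cells (2, 6): mean 4, sample SD 2*sqrt(2)
  expect_equal(scaled$mlu_w[c(1, 3)], c(-1, 1) / sqrt(2))
  # mean/SD of non-missing cells after scaling
  expect_equal(mean(scaled$mlu_w, na.rm = TRUE), 0)
  expect_equal(sd(scaled$mlu_w, na.rm = TRUE), 1)
  # idempotence on an already-scaled column
  rescaled <- scale_predictors(scaled)
  expect_equal(rescaled$frequency, scaled$frequency, tolerance = 1e-12)
  # scaling metadata supports back-transformation
  meta <- attr(scaled, "scaling")
  expect_equal(meta$mean[meta$column == "frequency"], 2)
  expect_equal(meta$sd[meta$column == "frequency"], 1)
  expect_error(
    scale_predictors(tibble::tibble(frequency = c(1, 1, 1))),
    "frequency.*constant")
})

test_that("collinearity diagnostics match a brute-force OLS oracle", {
  set.seed(7)
  sigma <- matrix(c(1, 0.6, 0.2, 0.6, 1, -0.3, 0.2, -0.3, 1), 3)
  x <- MASS::mvrnorm(300, rep(0, 3), sigma)
  tab <- tibble::tibble(frequency = x[, 1], mlu_w = x[, 2], babiness = x[, 3])
  diag_out <- collinearity_diagnostics(tab,
                                       c("frequency", "mlu_w", "babiness"))
  expect_equal(diag_out$correlations, cor(x, x), ignore_attr = TRUE)
  # brute-force VIF: regress each column on the others
  for (j in 1:3) {
    r2 <- summary(lm(x[, j] ~ x[, -j]))$r.squared
    expect_equal(unname(diag_out$vif[j]), 1 / (1 - r2), tolerance = 1e-10)
  }
  # orthogonal predictors have VIF 1
  ortho <- tibble::tibble(frequency = rep(c(-1, 1), 10),
                          mlu_w = rep(c(-1, -1, 1, 1), 5))
  v <- collinearity_diagnostics(ortho, c("frequency", "mlu_w"))$vif
  expect_equal(unname(v), c(1, 1))
  # duplicated column: singular
  dup <- tibble::tibble(frequency = rnorm(30))
  dup$mlu_w <- dup$frequency
  dup$babiness <- rnorm(30)
  expect_error(collinearity_diagnostics(dup, names(dup)), "singular")
})

test_that("the assembled predictor table is scaled with full metadata", {
  lex <- generate_lexicon(80, seed = 51)
  corp <- generate_corpus(lex, n_utterances = 6000, seed = 52)
  maps <- lexacq:::lexicon_maps(lex, "lang1")
  norms <- tibble::tibble(item_id = lex$items$item_id,
                          concreteness = 3 + 0.8 * lex$items$latent_concreteness,
                          valence = 5 + 1.5 * lex$items$latent_valence,
                          arousal = 5 + 1.5 * lex$items$latent_arousal,
                          babiness = 5.5 + 1.8 * lex$items$latent_babiness)
  nph <- pmax(1L, as.integer(round(3.5 + 1.3 * lex$items$latent_n_phonemes)))
  tr <- tibble::tibble(item_id = lex$items$item_id,
                       phonemes = vapply(nph, function(k)
                         paste(rep("p", k), collapse = " "), ""))
  tab <- build_predictor_table(corp, maps$forms, norms, tr,
                               lex$items[, c("item_id", "lexical_category")],
                               maps$inflection_map, maps$polysemy_map)
  expect_setequal(c("item_id", "lexical_category",
                    lexacq:::lexacq_predictors()), names(tab))
  for (p in c("frequency", "n_phonemes", "concreteness")) {
    expect_lt(abs(mean(tab[[p]], na.rm = TRUE)), 1e-9)
    expect_equal(sd(tab[[p]], na.rm = TRUE), 1, tolerance = 1e-9)
  }
  meta <- attr(tab, "metadata")
  expect_equal(meta$normalization_base, 1e6)
  expect_true(meta$corpus_total_tokens > 0)
  expect_true(is.data.frame(meta$scaling))
})
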