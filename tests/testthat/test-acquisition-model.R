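test_that("design matrix has the documented column structure", {
  lex <- generate_lexicon(40, seed = 61)
  truth <- default_truth("lang1")
  adm <- generate_administrations(lex, truth, "lang1", 30, "production",
                                  seed = 62)
  ptab <- latent_predictor_table(lex)

  full <- build_design(adm, ptab, model_spec("production"),
                       age_range = c(8, 30))
  # intercept + age + 9 main + 9 x age + 3 contrasts + 27 x contrasts = 50
  expect_equal(ncol(full$x), 50)
  expect_equal(nrow(full$x), nrow(adm))

  main_only <- build_design(adm, ptab,
                            model_spec("production",
                                       include_age_interactions = FALSE,
                                       include_category_interactions = FALSE),
                            age_range = c(8, 30))
  expect_equal(colnames(main_only$x),
               c("(Intercept)", "age_z", lexacq:::lexacq_predictors()))

  # deviation contrast columns sum to zero across the 4 category levels
  cm <- lexacq:::category_contrasts("deviation")
  expect_equal(ncol(cm), 3)
  expect_equal(unname(colSums(cm)), rep(0, 3))

  expect_error(build_design(adm, ptab, model_spec("comprehension")),
               "no administrations")
  raw <- ptab
  raw$frequency <- raw$frequency * 10 + 50
  expect_error(build_design(adm, raw, model_spec("production")),
               "standardized")
  bad_cat <- ptab
  bad_cat$lexical_category[1] <- "Interjections"
  expect_error(build_design(adm, bad_cat, model_spec("production")),
               "unknown lexical category")
})

test_that("aggregation to word-by-age cells preserves the data", {
  lex <- generate_lexicon(20, seed = 71)
  truth <- default_truth("lang1")
  adm <- generate_administrations(lex, truth, "lang1", 60, "production",
                                  seed = 72)
  design <- build_design(adm, latent_predictor_table(lex),
                         model_spec("production",
                                    include_age_interactions = FALSE,
                                    include_category_interactions = FALSE),
                         age_range = c(8, 30))
  agg <- lexacq:::aggregate_design(design)
  expect_equal(sum(agg$n), nrow(adm))
  expect_equal(sum(agg$k), sum(adm$value))
  # each word contributes one cell per distinct age
  expect_equal(nrow(agg$x), 20 * length(unique(adm$age_months)))
})

test_that("with zero random effects the GLMM matches plain logistic regression", {
  truth <- ground_truth(
    "lang1",
    beta = c(frequency = 0.4, solo_frequency = 0.2,
             setNames(rep(0, 7), setdiff(lexacq:::lexacq_predictors(),
                                         c("frequency", "solo_frequency")))),
    beta_age = 1.5, random_intercept_sd = 0, random_slope_sd = 0,
    random_effect_corr = 0)
  lex <- generate_lexicon(40, seed = 81)
  adm <- generate_administrations(lex, truth, "lang1", 500, "production",
                                  seed = 82)
  spec <- model_spec("production", include_age_interactions = FALSE,
                     include_category_interactions = FALSE)
  design <- build_design(adm, latent_predictor_table(lex), spec,
                         age_range = c(8, 30))
  fit <- fit_glmm(design)
  ref <- glm(design$y ~ 0 + design$x, family = binomial())
  expect_equal(fit$estimate, unname(coef(ref)), tolerance = 1e-2)
})

test_that("complete separation in the fixed effects is detected", {
  lex <- generate_lexicon(20, seed = 111)
  truth <- default_truth("lang1")
  adm <- generate_administrations(lex, truth, "lang1", 50, "production",
                                  seed = 112)
  ptab <- latent_predictor_table(lex)
  # responses perfectly determined by the sign of one predictor
  det <- setNames(ptab$frequency > 0, ptab$item_id)
  adm$value <- as.integer(det[adm$item_id])
  design <- build_design(adm, ptab,
                         model_spec("production",
                                    include_age_interactions = FALSE,
                                    include_category_interactions = FALSE),
                         age_range = c(8, 30))
  expect_error(fit_glmm(design), "separation")
})

test_that("Laplace engines agree with each other", {
  truth <- default_truth("lang1")
  t_tmb <- sim_fit(truth, n_items = 30, n_children = 200, seed = 5,
                   engine = "glmmTMB")
  t_glmer <- sim_fit(truth, n_items = 30, n_children = 200, seed = 5,
                     engine = "glmer")
  expect_equal(t_tmb$estimate, t_glmer$estimate, tolerance = 5e-3)
  expect_equal(t_tmb$se, t_glmer$se, tolerance = 5e-3)
})

test_that("fixed-effect predictions are invariant to the contrast coding", {
  lex <- generate_lexicon(60, seed = 91)
  truth <- default_truth("lang1")
  adm <- generate_administrations(lex, truth, "lang1", 80, "production",
                                  seed = 92)
  ptab <- latent_predictor_table(lex)
  d_dev <- build_design(adm, ptab,
                        model_spec("production", category_coding = "deviation"),
                        age_range = c(8, 30))
  d_trt <- build_design(adm, ptab,
                        model_spec("production", category_coding = "treatment"),
                        age_range = c(8, 30))
  g_dev <- suppressWarnings(glm(d_dev$y ~ 0 + d_dev$x, family = binomial()))
  g_trt <- suppressWarnings(glm(d_trt$y ~ 0 + d_trt$x, family = binomial()))
  expect_equal(fitted(g_dev), fitted(g_trt), tolerance = 1e-6)
})

test_that("composed category effects match a cell-means refit", {
  lex <- generate_lexicon(80, seed = 101,
                          category_proportions = c(0.3, 0.3, 0.2, 0.2))
  truth <- default_truth("lang1")
  adm <- generate_administrations(lex, truth, "lang1", 120, "production",
                                  seed = 102)
  ptab <- latent_predictor_table(lex)
  spec <- model_spec("production", include_age_interactions = FALSE)
  design <- build_design(adm, ptab, spec, age_range = c(8, 30))
  g <- glm(design$y ~ 0 + design$x, family = binomial())
  # dress the glm up as a coefficient table to drive the composition
  meta <- lexacq:::term_metadata(colnames(design$x), spec$predictors)
  tab <- dplyr::bind_cols(
    tibble::tibble(language = "lang1", measure = "production"), meta,
    tibble::tibble(estimate = unname(coef(g)), se = 1, z = 0, p = 1,
                   significant = FALSE))
  attr(tab, "contrasts") <- design$contrasts
  attr(tab, "predictors") <- spec$predictors
  composed <- compose_category_effects(tab)

  # additive identity: with zero category and interaction terms the composed
  # effect is the main effect
  tab0 <- tab
  tab0$estimate[tab0$type %in% c("category", "category_interaction")] <- 0
  composed0 <- compose_category_effects(tab0)
  mains <- setNames(tab$estimate[tab$type == "main"],
                    tab$predictor[tab$type == "main"])
  expect_equal(composed0$effect, unname(mains[composed0$predictor]))

  # cell-means oracle: per-category intercepts and slopes fit directly
  cats <- lexacq:::lexacq_categories()
  item_cat <- setNames(ptab$lexical_category, ptab$item_id)
  obs_cat <- item_cat[as.character(design$word)]
  pred_cols <- design$x[, spec$predictors]
  blocks <- lapply(cats, function(cc) {
    ind <- as.numeric(obs_cat == cc)
    cbind(ind, pred_cols * ind)
  })
  x_cell <- do.call(cbind, blocks)
  colnames(x_cell) <- unlist(lapply(cats, function(cc)
    c(paste0("int_", cc), paste0(spec$predictors, "_", cc))))
  g_cell <- glm(design$y ~ 0 + design$x[, "age_z"] + x_cell,
                family = binomial())
  cell_coef <- coef(g_cell)
  names(cell_coef) <- sub("^x_cell", "", names(cell_coef))
  mu <- tab$estimate[tab$term == "(Intercept)"]
  for (i in seq_len(nrow(composed))) {
    p <- composed$predictor[i]; cc <- composed$category[i]
    # composed slope part equals the cell slope
    slope_dev <- mains[[p]] +
      sum(design$contrasts[cc, ] *
            tab$estimate[tab$type == "category_interaction" &
                         tab$predictor == p])
    expect_equal(slope_dev, unname(cell_coef[paste0(p, "_", cc)]),
                 tolerance = 1e-6)
    # intercept + composed category offset equals the cell intercept
    off_dev <- mu + sum(design$contrasts[cc, ] *
                          tab$estimate[tab$type == "category"])
    expect_equal(off_dev, unname(cell_coef[paste0("int_", cc)]),
                 tolerance = 1e-6)
  }
  expect_error(compose_category_effects(tab[tab$type != "category", ]),
               "missing model term")
})

test_that("logistic trajectories recover generating curves", {
  ages <- 8:30
  # noiseless proportions from logistic(-6 + 0.4 * age), huge per-age n
  n <- rep(1e6, length(ages))
  k <- round(n * plogis(-6 + 0.4 * ages))
  fit <- fit_logistic_trajectory(ages, k, n)
  expect_equal(fit$intercept, -6, tolerance = 1e-3)
  expect_equal(fit$slope, 0.4, tolerance = 1e-3)
  expect_true(all(diff(fit$fitted$proportion) > 0))

  flat <- fit_logistic_trajectory(ages, rep(500, length(ages)),
                                  rep(1000, length(ages)))
  expect_equal(flat$slope, 0, tolerance = 1e-8)

  falling <- fit_logistic_trajectory(c(10, 20, 30), c(80, 50, 20), rep(100, 3))
  expect_lt(falling$slope, 0)

  expect_error(fit_logistic_trajectory(c(10, 20), c(0, 0), c(50, 50)),
               "all-0 or all-1")
  expect_error(fit_logistic_trajectory(10, 5, 50), "2 age groups")
})

test_that("coefficient summaries average and count signs correctly", {
  truth <- default_truth(c("A", "B"))
  make_tab <- function(lang, est) {
    meta <- lexacq:::term_metadata(c("(Intercept)", "age_z", "frequency"),
                                   "frequency")
    dplyr::bind_cols(
      tibble::tibble(language = lang, measure = "production"), meta,
      tibble::tibble(estimate = est, se = 1, z = est, p = c(1, 1, 0.01),
                     significant = c(FALSE, FALSE, TRUE)))
  }
  one <- summarize_coefficients(list(make_tab("A", c(0, 1, 0.2))))
  expect_equal(one$mean_estimate, 0.2)
  two <- summarize_coefficients(list(make_tab("A", c(0, 1, 0.2)),
                                     make_tab("B", c(0, 1, 0.3))))
  expect_equal(two$mean_estimate, 0.25)
  expect_equal(two$n_significant, 2L)
  three <- summarize_coefficients(list(make_tab("A", c(0, 1, 0.2)),
                                       make_tab("B", c(0, 1, 0.3)),
                                       make_tab("C", c(0, 1, -0.1))))
  expect_equal(three$n_sign_consistent, 2L)
  bad <- make_tab("B", c(0, 1, 0.3))
  bad$term[3] <- "babiness"
  expect_error(summarize_coefficients(list(make_tab("A", c(0, 1, 0.2)), bad)),
               "mismatched term sets")
})
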