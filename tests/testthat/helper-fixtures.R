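# Shared fixtures, all built in code.

# A 50-adult-utterance corpus whose per-item counts, solo/final counts and
# MLU-w values were worked out by hand (see comments). Exercises inflection
# collapsing ("dogs" -> "dog"), polysemy splitting ("orange" -> two senses,
# 1/2 mass each), the single-word exclusion for final counts, the Laplace
# 0 -> 1 rule (item "bird" never occurs), and the minimum-occurrence MLU-w
# missingness rule ("cat" occurs 9 times).
hand_corpus <- function() {
  lines <- c(
    rep("ADU\tdogs", 5),              # dog: 5 solo occurrences (via variant)
    rep("ADU\tthe big dog", 10),      # dog: 10 final; the: 10; big unmapped
    rep("ADU\tcat", 3),               # cat: 3 solo
    rep("ADU\ti see the cat", 6),     # cat: 6 final; the: 6; i/see unmapped
    rep("ADU\torange", 4),            # orange: 4 solo -> 2 mass per sense
    rep("ADU\tgo go go", 2),          # go: 6 occurrences, 2 final
    rep("ADU\tyou want the ball", 20),# ball: 20 final; the: 20
    rep("CHI\tdog", 5)                # child speech: excluded by the filter
  )
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, path)
  corpus <- read_chat_lite(path)

  forms <- tibble::tibble(
    item_id = c("dog", "cat", "ball", "go", "the", "bird",
                "orange_color", "orange_fruit"),
    word_form = c("dog", "cat", "ball", "go", "the", "bird",
                  "orange", "orange"))
  inflection_map <- tibble::tibble(variant_form = "dogs",
                                   canonical_item = "dog")
  polysemy_map <- tibble::tibble(word_form = "orange",
                                 item_id = c("orange_color", "orange_fruit"))
  # Hand-derived ground truth. Adult tokens:
  #   5*1 + 10*3 + 3*1 + 6*4 + 4*1 + 2*3 + 20*4 = 152
  expected <- list(
    total_tokens = 152,
    unmapped = 62,                    # big 10 + i 6 + see 6 + you 20 + want 20
    counts = c(dog = 15, cat = 9, ball = 20, go = 6, the = 36, bird = 0,
               orange_color = 2, orange_fruit = 2),
    solo = c(dog = 5, cat = 3, ball = 0, go = 0, the = 0, bird = 0,
             orange_color = 2, orange_fruit = 2),
    final = c(dog = 10, cat = 6, ball = 20, go = 2, the = 0, bird = 0,
              orange_color = 0, orange_fruit = 0),
    # occurrence-weighted mean utterance lengths; NA when occurrences < 10
    mlu = c(dog = (5 * 1 + 10 * 3) / 15, cat = NA, ball = 4, go = NA,
            the = (10 * 3 + 6 * 4 + 20 * 4) / 36, bird = NA,
            orange_color = NA, orange_fruit = NA),
    occurrences = c(dog = 15, cat = 9, ball = 20, go = 6, the = 36, bird = 0,
                    orange_color = 2, orange_fruit = 2)
  )
  list(corpus = corpus, forms = forms, inflection_map = inflection_map,
       polysemy_map = polysemy_map, expected = expected)
}

# Predictor table holding the lexicon's latent (already standardized)
# property values, as used when testing the model layer in isolation.
latent_predictor_table <- function(lexicon) {
  tab <- lexicon$items
  names(tab) <- sub("^latent_", "", names(tab))
  tab
}

# One simulated language fit: generate administrations from `truth`, fit the
# requested model on the latent predictor table, return the coefficient
# table.
sim_fit <- function(truth, n_items = 50, n_children = 1000, seed = 1,
                    measure = "production", age_range = c(8, 30),
                    include_age_interactions = FALSE,
                    include_category_interactions = FALSE,
                    engine = "glmmTMB", lexicon = NULL) {
  if (is.null(lexicon))
    lexicon <- generate_lexicon(n_items, seed = derive_test_seed(seed, 1))
  adm <- generate_administrations(lexicon, truth, truth$languages[1],
                                  n_children, measure, age_range,
                                  seed = derive_test_seed(seed, 2))
  spec <- model_spec(measure,
                     include_age_interactions = include_age_interactions,
                     include_category_interactions = include_category_interactions)
  design <- build_design(adm, latent_predictor_table(lexicon), spec,
                         age_range = age_range)
  fit_glmm(design, engine = engine)
}

derive_test_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

# Equicorrelated multivariate normal sample (independent oracle for the
# imputation simulations).
equicorr_mvn <- function(n, p, rho, seed) {
  sigma <- matrix(rho, p, p); diag(sigma) <- 1
  withr::with_seed(seed, MASS::mvrnorm(n, rep(0, p), sigma))
}
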