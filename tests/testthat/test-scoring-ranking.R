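test_that("the grading score is correctness times certainty", {
  truth <- "Diabetic retinopathy"
  expect_identical(compute_grade("Diabetic retinopathy", 5, truth), 5L)
  expect_identical(compute_grade("Arteriosclerotic retinopathy", 5, truth), -5L)
  expect_identical(compute_grade(NOT_APPLICABLE, NA, truth), 0L)
  expect_identical(compute_grade("Diabetic retinopathy", 3, truth), 3L)
  expect_error(compute_grade("Diabetic retinopathy", NA, truth), "certainty")
  for (cert in 1:5) {
    g <- compute_grade("Diabetic retinopathy", cert, truth)
    expect_true(g >= -5 && g <= 5)
    expect_identical(sign(g), 1)
  }
})

test_that("grade_responses joins truth, grades rows and drops invalid ones", {
  resp <- data.frame(
    observer_id = "obs01", question_id = paste0("q", 1:4),
    image_id = c("26_training", "im0005", "im0004", "nope"),
    dataset = c("DRIVE", "STARE", "STARE", "X"),
    model = "netA",
    selected = c("Diabetic retinopathy", "Diabetic retinopathy",
                 NOT_APPLICABLE, "Diabetic retinopathy"),
    certainty = c(4L, 2L, NA, 5L),
    is_control = FALSE, source_question_id = NA_character_,
    stringsAsFactors = FALSE)
  expect_warning(g <- grade_responses(resp), "dropped")
  expect_identical(nrow(g), 3L)
  expect_identical(g$grade, c(4L, -2L, 0L))
  expect_identical(g$is_correct, c(1L, -1L, 0L))
})

test_that("head-to-head tallies equal an independent recount", {
  models <- study_models(4)
  qm <- latent_quality_model(models, c(0, 0.3, 0.6, 0.9), beta = 2)
  st <- simulate_stage2_study(qm, c(DRIVE = 3), simulated_observers(2),
                              seed = 5)
  tal <- tally_head_to_head(st$responses)
  r <- st$responses[!st$responses$is_control, ]
  for (i in models) for (j in models) {
    if (i == j) next
    ref <- sum(r$chosen == i &
                 (r$model_a == j | r$model_b == j) &
                 (r$model_a == i | r$model_b == i))
    expect_identical(unname(tal$w[i, j]), ref)
  }
  # w[i,j] + w[j,i] equals the number of i-vs-j responses in scope
  nij <- sum((r$model_a %in% models[1:2]) & (r$model_b %in% models[1:2]))
  expect_identical(unname(tal$w[models[1], models[2]] +
                            tal$w[models[2], models[1]]), nij)
  # empty input gives an all-zero tally
  empty <- tally_head_to_head(st$responses[0, ], models = models)
  expect_true(all(empty$w == 0L))
  # explicit count check
  mini <- data.frame(observer_id = "o", question_id = paste0("q", 1:4),
                     image_id = "i", dataset = "D",
                     model_a = "A", model_b = "B",
                     chosen = c("A", "A", "A", "B"),
                     is_control = FALSE, source_question_id = NA,
                     stringsAsFactors = FALSE)
  tm <- tally_head_to_head(mini)
  expect_identical(unname(tm$w["A", "B"]), 3L)
  expect_identical(unname(tm$w["B", "A"]), 1L)
})

test_that("Copeland +1/0/-1 scoring matches hand-enumerated majorities", {
  tal <- tally_from_counts(c("A", "B", "C"), data.frame(
    i = c("A", "B", "B", "A", "C"), j = c("B", "A", "C", "C", "A"),
    n = c(3, 1, 2, 1, 1)))
  ct <- copeland(tal)
  expect_identical(ct$score[match(c("A", "B", "C"), ct$model)],
                   c(1L, 0L, -1L))

  # Condorcet winner attains m - 1
  uni <- tally_from_counts(c("A", "B", "C"), data.frame(
    i = c("A", "A", "B"), j = c("B", "C", "C"), n = c(2, 2, 2)))
  cu <- copeland(uni)
  expect_identical(cu$score[cu$model == "A"], 2L)
  expect_identical(condorcet_winner(uni), "A")

  # all ties score zero everywhere
  z <- tally_from_counts(c("A", "B"), data.frame(i = "A", j = "B", n = 0))
  expect_identical(copeland(z)$score, c(0L, 0L))
  expect_error(copeland(tally_from_counts("A", data.frame(i = character(),
                                                          j = character(),
                                                          n = integer()))),
               "at least 2")
})

test_that("Copeland equals the exhaustive majority oracle on small tallies", {
  # every tally over 2 or 3 models with per-direction counts in 0..3
  for (w_ab in 0:3) for (w_ba in 0:3) {
    tal <- tally_from_counts(c("A", "B"), data.frame(
      i = c("A", "B"), j = c("B", "A"), n = c(w_ab, w_ba)))
    ct <- copeland(tal)
    ref <- copeland_oracle(tal$w)
    expect_identical(stats::setNames(ct$score, ct$model)[names(ref)], ref)
  }
  grid <- expand.grid(ab = 0:3, ba = 0:3, ac = 0:3, ca = 0:3,
                      bc = 0:3, cb = 0:3)
  set.seed(1)
  for (k in sample(nrow(grid), 300)) {
    g <- grid[k, ]
    tal <- tally_from_counts(c("A", "B", "C"), data.frame(
      i = c("A", "B", "A", "C", "B", "C"),
      j = c("B", "A", "C", "A", "C", "B"),
      n = unlist(g)))
    ct <- copeland(tal)
    ref <- copeland_oracle(tal$w)
    expect_identical(stats::setNames(ct$score, ct$model)[names(ref)], ref)
  }
  # random tallies over 4 and 5 models
  for (m in 4:5) for (rep in 1:100) {
    tal <- random_tally(m, 3)
    ct <- copeland(tal)
    ref <- copeland_oracle(tal$w)
    expect_identical(stats::setNames(ct$score, ct$model)[names(ref)], ref)
  }
})

test_that("Copeland scores are zero-sum, bounded, and scale-invariant", {
  set.seed(99)
  for (rep in 1:1000) {
    m <- sample(2:8, 1)
    tal <- random_tally(m)
    ct <- copeland(tal)
    expect_identical(sum(ct$score), 0L)
    expect_true(all(abs(ct$score) <= m - 1))
    # |score| = m - 1 iff every head-to-head majority is won (or lost)
    expect_identical(ct$score == m - 1, ct$wins == m - 1L)
    # invariance under positive scaling of all counts
    tal3 <- tal; tal3$w <- tal$w * 3L
    expect_identical(copeland(tal3)$score, ct$score)
  }
})

test_that("condorcet_winner agrees with brute force and detects cycles", {
  cyc <- tally_from_counts(c("A", "B", "C"), data.frame(
    i = c("A", "B", "C"), j = c("B", "C", "A"), n = c(2, 2, 2)))
  expect_identical(condorcet_winner(cyc), NA_character_)
  set.seed(5)
  for (rep in 1:50) {
    tal <- random_tally(sample(3:6, 1), 4)
    got <- condorcet_winner(tal)
    ref <- NA_character_
    for (i in seq_along(tal$models)) {
      beats <- vapply(seq_along(tal$models), function(j)
        j == i || tal$w[i, j] > tal$w[j, i], logical(1))
      if (all(beats)) { ref <- tal$models[i]; break }
    }
    expect_identical(got, ref)
  }
})

test_that("factored Copeland equals restriction to each level", {
  qm <- latent_quality_model(study_models(5), seq(0, 1, 0.25), beta = 2)
  st <- simulate_stage2_study(qm, c(DRIVE = 3, STARE = 3, CHASE = 3),
                              simulated_observers(3), seed = 17)
  r <- st$responses
  by_ds <- factored_copeland(r, "dataset")
  for (d in names(by_ds)) {
    ref <- copeland(tally_head_to_head(r[r$dataset == d, ],
                                       models = qm$models))
    expect_identical(by_ds[[d]], ref)
  }
  by_obs <- factored_copeland(r, "observer")
  expect_setequal(names(by_obs), unique(r$observer_id))

  # a single-dataset response set factors to the overall table
  one <- r[r$dataset == "DRIVE", ]
  expect_identical(factored_copeland(one, "dataset")$DRIVE,
                   copeland(tally_head_to_head(one)))

  # two observers with opposite unanimous preferences negate each other
  opp <- data.frame(observer_id = rep(c("o1", "o2"), each = 3),
                    question_id = paste0("q", 1:6), image_id = "i",
                    dataset = "D", model_a = "A", model_b = "B",
                    chosen = rep(c("A", "B"), each = 3),
                    is_control = FALSE, source_question_id = NA,
                    stringsAsFactors = FALSE)
  fo <- factored_copeland(opp, "observer")
  expect_identical(fo$o1$score[order(fo$o1$model)],
                   -fo$o2$score[order(fo$o2$model)])
})

test_that("per-class accuracy matches a manual tally and flags empty classes", {
  resp <- data.frame(
    observer_id = "obs01", question_id = paste0("q", 1:6),
    image_id = c("26_training", "25_training", "im0005", "im0005",
                 "im0004", "im0004"),
    dataset = c("DRIVE", "DRIVE", "STARE", "STARE", "STARE", "STARE"),
    model = "netA",
    selected = c("Diabetic retinopathy",            # DR correct
                 "Central artery/vein occlusion",   # DR wrong
                 "Central artery/vein occlusion",   # CAVO correct
                 NOT_APPLICABLE,                    # CAVO n/a
                 "Arteriosclerotic retinopathy",    # multi-truth: credit AR
                 "Diabetic retinopathy"),           # multi-truth wrong
    certainty = c(5L, 4L, 3L, NA, 2L, 1L),
    is_control = FALSE, source_question_id = NA_character_,
    stringsAsFactors = FALSE)
  g <- grade_responses(resp)
  pca <- per_class_accuracy(g)
  row <- function(cat) pca[pca$category == cat, ]
  expect_equal(row("Diabetic retinopathy")$accuracy, 50)        # 1 of 2
  expect_equal(row("Central artery/vein occlusion")$accuracy, 50)
  expect_equal(row("Arteriosclerotic retinopathy")$accuracy, 50) # 1 of 2
  expect_equal(row("Cilio-retinal artery occlusion")$accuracy, 0) # 0 of 2
  # the image count convention: 12 study images, 9 with DR in the truth set
  expect_equal(row("Diabetic retinopathy")$prevalence_images, 100 * 9 / 12)

  # a category with no responses is undefined, not zero
  g1 <- g[g$image_id == "26_training", ]
  pca1 <- per_class_accuracy(g1)
  expect_true(is.na(pca1[pca1$category == "Cilio-retinal artery occlusion",
                         "accuracy"]))
  # all-correct responses score 100 in every answered category
  all_ok <- g[g$is_correct == 1L, ]
  pos <- per_class_accuracy(all_ok)
  expect_true(all(pos$accuracy[pos$n_responses > 0 &
                                 pos$category %in% all_ok$selected] == 100))
})

test_that("grade summaries recount the grouped distributions", {
  obs <- simulated_observers(3, accuracy = 0.5, na_prob = 0.2)
  surveys <- build_stage1_surveys(stage1_items(), seed = 31)
  resp <- simulate_stage1_responses(obs, surveys, seed = 32)
  g <- grade_responses(resp)
  gs <- grade_summaries(g, "observer")
  for (o in unique(g$observer_id)) {
    sub <- gs$counts[gs$counts$observer_id == o, ]
    ref <- table(factor(g$grade[g$observer_id == o], levels = -5:5))
    expect_identical(sub$count[match(-5:5, sub$grade)], as.integer(ref))
    expect_identical(sum(sub$count), sum(g$observer_id == o))
  }
  sm <- gs$summary
  expect_equal(sm$median[sm$observer_id == "obs01"],
               median(g$grade[g$observer_id == "obs01"]))
  # crossed grouping covers every combination present
  gx <- grade_summaries(g, "observer_dataset")
  expect_setequal(paste(gx$summary$observer_id, gx$summary$dataset),
                  unique(paste(g$observer_id, g$dataset)))
  # a single +3 response yields a one-spike histogram
  one <- g[1, ]; one$grade <- 3L
  h <- grade_summaries(one, "observer")$counts
  expect_identical(h$count[h$grade == 3], 1L)
  expect_identical(sum(h$count), 1L)
})

test_that("rank-vs-objective alignment and rank correlations behave", {
  ct <- copeland(tally_from_counts(c("A", "B", "C", "D"), data.frame(
    i = c("A", "A", "A", "B", "B", "C"),
    j = c("B", "C", "D", "C", "D", "D"), n = 2)))
  obj_same <- data.frame(model = c("A", "B", "C", "D"),
                         value = c(0.9, 0.8, 0.7, 0.6))
  r1 <- rank_vs_objective(ct, obj_same, "spearman")
  expect_equal(r1$estimate, 1)
  expect_identical(r1$n, 4L)
  obj_rev <- data.frame(model = c("A", "B", "C", "D"),
                        value = c(0.6, 0.7, 0.8, 0.9))
  expect_equal(rank_vs_objective(ct, obj_rev, "spearman")$estimate, -1)
  expect_equal(rank_vs_objective(ct, obj_rev, "kendall")$estimate, -1)
  # no coefficient unless requested; pairs always emitted for plotting
  r0 <- rank_vs_objective(ct, obj_same)
  expect_null(r0$estimate)
  expect_identical(names(r0$pairs), c("model", "score", "value"))
  expect_error(rank_vs_objective(ct, data.frame(model = "Z", value = 1)),
               "fewer than 2")
})

test_that("response CSV round trips preserve types", {
  qm <- latent_quality_model(study_models(3), c(0, 0.5, 1), beta = 2)
  st <- simulate_stage2_study(qm, c(DRIVE = 2), simulated_observers(2),
                              seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(st$responses, f, row.names = FALSE, na = "")
  back <- read_stage2_responses(f)
  expect_identical(back$chosen, st$responses$chosen)
  expect_identical(back$is_control, st$responses$is_control)
  expect_identical(copeland(tally_head_to_head(back)),
                   copeland(tally_head_to_head(st$responses)))
  expect_error(read_stage2_responses(withr::local_tempfile(lines = "a,b",
                                                           fileext = ".csv")),
               "missing columns")
})
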