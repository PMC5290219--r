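test_that("subject-wise splits follow the rounding rule and stay disjoint", {
  ids <- sprintf("P%02d", 1:20)
  set.seed(1)
  sp <- subjectwise_split(ids, 0.90)
  expect_length(sp$train, 18L)
  expect_length(sp$test, 2L)
  expect_length(intersect(sp$train, sp$test), 0L)

  sp2 <- subjectwise_split(c("a", "b"), 0.5)
  expect_length(sp2$train, 1L)
  expect_length(sp2$test, 1L)
  expect_error(subjectwise_split(c("a", "b"), 0.9), "empty train or test")

  for (i in 1:25) {
    sp3 <- subjectwise_split(ids, runif(1, 0.3, 0.7))
    expect_length(intersect(sp3$train, sp3$test), 0L)
    expect_setequal(c(sp3$train, sp3$test), ids)
  }
})

test_that("metrics match hand-computed confusion tables", {
  perfect <- compute_metrics(c(0, 1, 1, 0), c(0, 1, 1, 0))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  # TP = 3, FP = 1, FN = 2, TN = 4
  y_true <- c(rep(1, 3), rep(0, 1), rep(1, 2), rep(0, 4))
  y_pred <- c(rep(1, 3), rep(1, 1), rep(0, 2), rep(0, 4))
  m <- compute_metrics(y_true, y_pred)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(m$accuracy, 0.7)

  all_neg <- compute_metrics(c(1, 1, 0), c(0, 0, 0))
  expect_equal(all_neg$recall, 0)
  expect_equal(all_neg$f1, 0)
})

test_that("the plan enumerates fractions and validates them", {
  plan <- split_plan()
  expect_length(plan$fractions, 9L)
  expect_equal(plan$fractions[1], 0.90)
  expect_equal(plan$fractions[9], 0.50)
  expect_error(split_plan(fractions = c(0.5, 0.9)), "decreasing")
  expect_error(split_plan(fractions = c(1.1, 0.5)), "\\(0, 1\\)")
  expect_error(split_plan(repetitions = 0), "repetitions")
})

test_that("the harness counts cells exactly and keeps the best consistent", {
  cohort <- small_preprocessed_cohort(n = 6L)
  plan <- split_plan(fractions = c(0.8, 0.5), repetitions = 2, seed = 3)
  rep1 <- run_algorithm1(cohort, snc_classifier(),
                         families = c("DE", "SMSS"), channels = c("Left1"),
                         plan = plan)
  expect_identical(rep1$step_count, 2L * 1L * 2L * 2L)
  expect_identical(nrow(rep1$cells), rep1$step_count)
  expect_equal(rep1$best$mean_accuracy, max(rep1$summary$mean_accuracy))

  # degree sweep multiplies the count
  rep2 <- run_algorithm1(cohort, snc_classifier(),
                         families = "DE", channels = "Left1",
                         plan = plan, degrees = c(0, 2, 3))
  expect_identical(rep2$step_count, 1L * 1L * 2L * 2L * 3L)

  one <- run_algorithm1(cohort, snc_classifier(), families = "DE",
                        channels = "Left1",
                        plan = split_plan(fractions = 0.5, repetitions = 1))
  expect_identical(one$step_count, 1L)
})

test_that("the harness is deterministic given its seeds", {
  cohort <- small_preprocessed_cohort(n = 6L)
  plan <- split_plan(fractions = c(0.7), repetitions = 3, seed = 9)
  a <- run_algorithm1(cohort, snc_classifier(), families = "DE",
                      channels = c("Left1", "Right1"), plan = plan)
  b <- run_algorithm1(cohort, snc_classifier(), families = "DE",
                      channels = c("Left1", "Right1"), plan = plan)
  expect_identical(a$cells, b$cells)
  expect_identical(a$best, b$best)
})

test_that("baseline adapters run interchangeably with SNC in the harness", {
  cohort <- small_preprocessed_cohort(n = 6L)
  plan <- split_plan(fractions = 0.7, repetitions = 2, seed = 5)
  for (name in c("knn", "naive_bayes", "logistic", "decision_tree")) {
    rp <- run_algorithm1(cohort, baseline_adapter(name), families = "DE",
                         channels = "Left1", plan = plan)
    expect_identical(rp$step_count, 2L)
    expect_true(all(rp$cells$accuracy[rp$cells$valid] >= 0))
  }
  expect_error(baseline_adapter("mystery"), "valid names")
})

test_that("adapters classify an easy two-cluster problem sensibly", {
  cl <- separated_clusters(n_per = 12, gap = 8, seed = 21)
  for (name in c("knn", "svm_linear", "svm_rbf", "decision_tree",
                 "random_forest", "naive_bayes", "lda", "logistic")) {
    ad <- baseline_adapter(name)
    set.seed(2)
    model <- ad$fit(cl$X, cl$y)
    acc <- mean(ad$predict(model, cl$X) == cl$y)
    expect_gt(acc, 0.9)
  }
})

test_that("segmentation splits blocks into s^d labeled sub-blocks", {
  cohort <- small_preprocessed_cohort(n = 3L)
  expect_identical(segment_cohort(cohort, 0), cohort)

  seg1 <- segment_cohort(cohort, 1, 2)
  expect_identical(nrow(seg1[[1]]$task_blocks),
                   2L * nrow(cohort[[1]]$task_blocks))
  seg2 <- segment_cohort(cohort, 2, 2)
  b0 <- cohort[[1]]$task_blocks
  b2 <- seg2[[1]]$task_blocks
  expect_identical(nrow(b2), 4L * nrow(b0))
  expect_identical(sum(b2$end - b2$start), sum(b0$end - b0$start))  # no remainder here
  expect_setequal(unique(b2$label), unique(b0$label))
  # labels inherited in position
  expect_identical(b2$label[1:4], rep(b0$label[1], 4))
  expect_error(segment_cohort(cohort, -1), "d must be")
  expect_error(segment_cohort(cohort, 1, 1), "s must be")
})

test_that("the degradation demo returns an empty table for an empty grid", {
  cohort <- small_preprocessed_cohort(n = 3L)
  tab <- segmentation_degradation_demo(cohort, snc_classifier(),
                                       depths = integer(0))
  expect_identical(nrow(tab), 0L)
})

test_that("a clean oscillation-driven cohort is depth-invariant", {
  cfg <- quiet_config(n_participants = 6, block_duration = 64,
                      blocks_per_task = 2, amplitude_1back = 0.025,
                      amplitude_2back = 0.1, left_lateralization_gain = 3,
                      task_oscillation_gain = 2.66, seed = 7)
  pp <- preprocess_cohort(generate_cohort(cfg))
  tab <- segmentation_degradation_demo(
    pp, snc_classifier(), depths = 0:2,
    plan = split_plan(fractions = 0.7, repetitions = 3, seed = 5),
    families = "DE", channels = "Left1")
  expect_true(all(tab$mean_accuracy > 0.95))
})
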