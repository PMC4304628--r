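test_that("stratified split reproduces the 502 -> 352/150 partition", {
  df <- tibble::tibble(x = rnorm(502),
                       beneficial = c(rep(TRUE, 18), rep(FALSE, 484)))
  sp <- split_train_test(df, 0.70, seed = 5)
  expect_equal(nrow(sp$train), 352)
  expect_equal(nrow(sp$test), 150)
  expect_equal(sum(sp$test$beneficial), 5) # 18 - ceiling(0.7 * 18)
  # disjoint and exhaustive
  expect_equal(nrow(sp$train) + nrow(sp$test), 502)
  key <- paste0(round(df$x, 12))
  expect_setequal(c(paste0(round(sp$train$x, 12)),
                    paste0(round(sp$test$x, 12))), key)
  # deterministic
  sp2 <- split_train_test(df, 0.70, seed = 5)
  expect_equal(sp$train, sp2$train)
})

test_that("split errors when a class cannot appear in both parts", {
  df <- tibble::tibble(x = rnorm(20),
                       beneficial = c(TRUE, rep(FALSE, 19)))
  expect_error(split_train_test(df, 0.7, seed = 1), "absent")
})

test_that("a single separating feature gets all the influence", {
  set.seed(41)
  toy <- tibble::tibble(x = runif(200, -6, 6), z = runif(200, -6, 6))
  toy$beneficial <- toy$x < 1
  m <- train_classifier(toy, features = c("x", "z"))
  expect_equal(mean((predict(m, toy) >= 0.5) == toy$beneficial), 1)
  inf <- relative_influence(m)
  expect_equal(inf$relative_influence_pct[inf$parameter == "x"], 100,
               tolerance = 1e-6)
  expect_equal(sum(inf$relative_influence_pct), 100, tolerance = 1e-9)
})

test_that("single-class training data are rejected", {
  df <- tibble::tibble(x = rnorm(30), beneficial = TRUE)
  expect_error(train_classifier(df), "single class")
})

test_that("influence always normalizes to 100%", {
  for (s in 1:3) {
    pe <- planted_ensemble(n = 300, seed = s)
    m <- train_classifier(pe, seed = s)
    expect_equal(sum(relative_influence(m)$relative_influence_pct), 100,
                 tolerance = 1e-9)
  }
})

test_that("permuted labels yield chance-level test accuracy", {
  set.seed(42)
  pe <- planted_ensemble(n = 400, positive_fraction = 0.3, seed = 2)
  pe$beneficial <- sample(pe$beneficial) # break the signal
  sp <- split_train_test(pe, seed = 2)
  m <- train_classifier(sp$train, seed = 2)
  tm <- test_metrics(m, sp$test)
  majority <- max(mean(sp$test$beneficial), 1 - mean(sp$test$beneficial))
  # binomial test that accuracy is indistinguishable from majority rate
  bt <- stats::binom.test(tm$tp + tm$tn, nrow(sp$test), p = majority)
  expect_gt(bt$p.value, 0.001)
})

test_that("permuted labels produce no stable top feature across seeds", {
  tops <- vapply(1:4, function(s) {
    pe <- planted_ensemble(n = 300, positive_fraction = 0.3, seed = 10)
    pe$beneficial <- local({set.seed(s); sample(pe$beneficial)})
    m <- train_classifier(pe, seed = s)
    relative_influence(m)$parameter[1]
  }, "")
  expect_gt(length(unique(tops)), 1)
})

test_that("planted drivers are recovered as the top influence ranks", {
  hits <- 0
  for (s in 1:5) {
    pe <- planted_ensemble(n = 500, seed = s)
    sp <- split_train_test(pe, seed = s)
    m <- train_classifier(sp$train, seed = s)
    inf <- relative_influence(m)
    if (setequal(inf$parameter[1:4], attr(pe, "informative")))
      hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("test metrics reproduce the reference confusion arithmetic", {
  # counts (TP=5, FN=1, FP=11, TN=133): TPR 5/6, FPR 11/144
  expect_equal(5 / (5 + 1), 0.8333333, tolerance = 1e-6)
  truth <- c(rep(TRUE, 6), rep(FALSE, 144))
  pred <- c(rep(TRUE, 5), FALSE, rep(TRUE, 11), rep(FALSE, 133))
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  fp <- sum(pred & !truth); tn <- sum(!pred & !truth)
  expect_equal(tp / (tp + fn), 5 / 6)
  expect_equal(fp / (fp + tn), 11 / 144)
  # perfect and all-negative predictors through the real function
  df <- planted_ensemble(n = 100, positive_fraction = 0.2, seed = 3)
  m <- train_classifier(df, seed = 3)
  tm <- test_metrics(m, df) # training data: separable, so perfect
  expect_equal(tm$tpr, 1)
  expect_equal(tm$fpr, 0)
})

test_that("enrichment fractions are exact count arithmetic", {
  labels <- c(rep("beneficial", 18), rep("harmful", 11),
              rep("insignificant", 473))
  rec <- tibble::tibble(label = labels, p = seq_along(labels))
  full <- enrichment(rec, rep(TRUE, 502))
  expect_equal(full$beneficial_fraction, 18 / 502)
  expect_equal(full$beneficial_fraction, full$overall_beneficial_fraction)
  # the reference restricted subsets: 15/37 and 15/61
  sub37 <- enrichment(rec, seq_len(502) %in% c(1:15, 19:21, 30:48))
  expect_equal(sub37$subset_size, 37)
  expect_equal(sub37$beneficial_fraction, 15 / 37)
  expect_equal(round(100 * sub37$beneficial_fraction), 41)
  sub61 <- enrichment(rec, seq_len(502) %in% c(1:15, 19:24, 100:139))
  expect_equal(sub61$beneficial_fraction, 15 / 61)
  expect_equal(round(100 * sub61$beneficial_fraction), 25)
  # empty subset flagged, not an error
  none <- enrichment(rec, rep(FALSE, 502))
  expect_true(none$empty)
})

test_that("threshold restriction behaves at the extremes", {
  rec <- tibble::tibble(label = c("beneficial", "harmful", "insignificant"),
                        R3_k2 = c(0.1, 100, 5))
  all_in <- conditional_threshold_analysis(rec, "R3_k2", Inf, "below")
  expect_equal(all_in$subset_size, 3)
  none <- conditional_threshold_analysis(rec, "R3_k2", 1e-9, "below")
  expect_true(none$empty)
  expect_error(conditional_threshold_analysis(rec, "nope", 1, "below"),
               "unknown parameter")
  lo <- conditional_threshold_analysis(rec, "R3_k2", 10, "below")
  expect_equal(lo$beneficial_fraction, 0.5)
})
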