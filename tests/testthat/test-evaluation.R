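test_that("confusion matrices tabulate truth by prediction", {
  truth <- rep(c("upward_linear", "s_shape"), c(3, 4))
  cm <- confusion(truth, truth)
  expect_equal(unname(diag(unclass(cm)[c("upward_linear", "s_shape"),
                                       c("upward_linear", "s_shape")])), c(3, 4))
  expect_equal(sum(unclass(cm)) - sum(diag(unclass(cm))), 0)

  all_s <- confusion(truth, rep("s_shape", 7))
  m <- class_metrics(all_s)
  expect_equal(m$tp[m$class == "upward_linear"], 0)
  expect_equal(m$fn[m$class == "upward_linear"], 3)
  expect_equal(m$tp[m$class == "s_shape"], 4)
  expect_equal(m$fp[m$class == "s_shape"], 3)

  expect_error(confusion(truth, rep("hill_shape", 7)), "not present")
  expect_error(confusion(truth, truth[1:3]), "equal lengths")
})

test_that("per-class metrics reproduce the printed formulas", {
  # TP=3 FP=2 FN=0 -> P 0.60, R 1.00, F1 0.75
  truth <- rep(c("a", "b"), c(3, 4))
  pred <- c("a", "a", "a", "a", "a", "b", "b")
  m <- class_metrics(confusion(truth, pred))
  a <- m[m$class == "a", ]
  expect_equal(a$precision, 0.6)
  expect_equal(a$recall, 1)
  expect_equal(a$f1, 0.75)
  # the complementary class: TP=2 FP=0 FN=2 -> P 1.00, R 0.50, F1 2/3
  b <- m[m$class == "b", ]
  expect_equal(b$precision, 1)
  expect_equal(b$recall, 0.5)
  expect_equal(b$f1, 2 / 3, tolerance = 1e-12)
})

test_that("degenerate classes follow the zero and NaN conventions", {
  cm <- confusion(c("a", "b"), c("b", "a"))
  m <- class_metrics(cm)
  expect_equal(m$precision, c(0, 0))
  expect_equal(m$recall, c(0, 0))
  expect_equal(m$f1, c(0, 0))

  cm3 <- confusion(factor(c("a", "a"), levels = c("a", "ghost")), c("a", "a"))
  expect_warning(m3 <- class_metrics(cm3), "absent")
  expect_true(is.nan(m3$f1[m3$class == "ghost"]))
})

test_that("micro-F1 equals accuracy and hits the published reconstructions", {
  truth <- rep(c("a", "b"), c(3, 4))
  expect_equal(micro_f1(confusion(truth, truth)), 1)

  # reconstructed 5-day window: TP=4 of 7 -> 8/14
  cm5 <- reconstruct_confusion(c(50, 67), c(67, 50), c(a = 3, b = 4))
  expect_equal(micro_f1(cm5), 8 / 14, tolerance = 1e-12)

  set.seed(21)
  for (i in 1:50) {
    t <- sample(c("a", "b"), 12, replace = TRUE)
    if (length(unique(t)) < 2) next
    p <- sample(c("a", "b"), 12, replace = TRUE)
    cm <- confusion(t, p)
    d <- class_metrics(cm)
    expect_equal(sum(d$fp), sum(d$fn))               # conservation
    expect_equal(micro_f1(cm), mean(t == p))         # accuracy identity
    ok <- d$precision + d$recall > 0
    expect_equal(d$f1[ok],
                 2 * d$precision[ok] * d$recall[ok] / (d$precision + d$recall)[ok])
  }
})

test_that("confusion reconstruction inverts rounded precision/recall tables", {
  # 6-day window: unique solution TP1=3 FP1=1, TP2=3 FP2=0
  cm6 <- reconstruct_confusion(c(75, 100), c(100, 75), c(p1 = 3, p2 = 4))
  expect_s3_class(cm6, "confusion_matrix")
  d <- class_metrics(cm6)
  expect_equal(d[d$class == "p1", c("tp", "fp", "fn")],
               data.frame(tp = 3, fp = 1, fn = 0), ignore_attr = TRUE)
  expect_equal(d[d$class == "p2", c("tp", "fp", "fn")],
               data.frame(tp = 3, fp = 0, fn = 1), ignore_attr = TRUE)

  # all-perfect window: diagonal (3, 4)
  cm7 <- reconstruct_confusion(c(100, 100), c(100, 100), c(p1 = 3, p2 = 4))
  expect_equal(unname(diag(unclass(cm7))), c(3, 4))
  expect_equal(sum(unclass(cm7)), 7)

  # 5-day window: 67 is round(2/3 * 100)
  cm5 <- reconstruct_confusion(c(50, 67), c(67, 50), c(p1 = 3, p2 = 4))
  d5 <- class_metrics(cm5)
  expect_equal(d5$tp, c(2, 2))
  expect_equal(d5[d5$class == "p1", "fp"], 2)
  expect_equal(d5[d5$class == "p2", "fp"], 1)

  # impossible printed values signal a transcription error
  expect_error(reconstruct_confusion(c(100, 100), c(10, 100), c(p1 = 3, p2 = 4)),
               "no integer confusion matrix")
})

test_that("recomputed published scores match the printed F1 and micro-F1", {
  rec <- recompute_reported_f1()
  # printed per-class F1 values, half-up rounded to 2 decimals
  printed <- data.frame(
    window = rep(5:8, each = 2),
    class = rep(c("upward_linear", "s_shape"), 4),
    f1 = c(0.57, 0.57, 0.86, 0.86, 1, 1, 0.75, 0.67))
  merged <- merge(rec, printed, by = c("window", "class"))
  expect_equal(round_half_up(merged$f1.x, 2), merged$f1.y)
  micro <- unique(rec[, c("window", "micro_f1")])
  expect_equal(round_half_up(micro$micro_f1[order(micro$window)], 2),
               c(0.57, 0.86, 1.00, 0.71))
})

test_that("half-up rounding matches printed-table conventions", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5)), c(1, 2, 3))
  expect_equal(round_half_up(2 / 3 * 100), 67)
  expect_equal(round_half_up(0.855, 2), 0.86)
  expect_equal(round_half_up(-0.5), -1)
})
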