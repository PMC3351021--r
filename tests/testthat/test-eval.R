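test_that("confusion summary and class metrics follow the definitions", {
  truth <- c("a", "a", "b", "b", "c")
  pred <- c("a", "b", "b", "b", "a")
  conf <- confusion_summary(truth, pred)
  m <- class_metrics(conf)
  expect_equal(m$tp[m$label == "a"], 1)
  expect_equal(m$fp[m$label == "a"], 1)
  expect_equal(m$fn[m$label == "a"], 1)
  expect_equal(m$precision[m$label == "a"], 50)
  expect_equal(m$fp[m$label == "b"], 1)
  expect_equal(attr(m, "accuracy"), 100 * 3 / 5)
  # conservation: sum tp + sum fn = total
  expect_equal(sum(conf$tp) + sum(conf$fn), attr(conf, "total"))
  # undefined precision is NA, never 0
  expect_true(is.na(m$precision[m$label == "c"]))
  # perfect confusion
  p <- class_metrics(confusion_summary(truth, truth))
  expect_true(all(p$precision == 100) && all(p$recall == 100))
  expect_equal(attr(p, "accuracy"), 100)
})

test_that("allocate_carryover is exact, proportional, and deterministic", {
  expect_equal(unname(allocate_carryover(10, c(a = 30, b = 30))), c(5, 5))
  expect_equal(unname(allocate_carryover(0, c(a = 3, b = 9))), c(0, 0))
  expect_error(allocate_carryover(-1, c(a = 1)), ">= 0")
  sizes <- c("1.1" = 81, "1.2" = 81, "1.3" = 81, "1.4" = 81,
             "1.5" = 34, "1.10" = 43, "1.16" = 35)
  alloc <- allocate_carryover(57, sizes)
  expect_equal(sum(alloc), 57)
  share <- 57 * sizes / sum(sizes)
  expect_true(all(abs(alloc - share) < 1))
  # largest-remainder, ties by label order
  expect_equal(unname(allocate_carryover(1, c(x = 10, y = 10))), c(1, 0))
})

test_that("adjusted precision/recall reduce to plain rates at zero carry-over", {
  expect_equal(adjusted_precision(40, 10, 0), 80)
  expect_equal(adjusted_recall(40, 10, 0), 80)
  expect_true(is.na(adjusted_precision(0, 0, 0)))
  # vectorized and monotone in carry-over
  cf <- 0:20
  ap <- adjusted_precision(50, 5, cf)
  expect_true(all(diff(ap) < 0))
})

test_that("evaluate_cascade propagates level-2 errors into sub-class rates", {
  # constructed world: 2 mains x 2 subs, 20 rows each, with injected routing
  # errors: 4 rows of true main 1 predicted as main 2 (FN for 1, FP for 2)
  truth <- c(rep("1.1", 20), rep("1.2", 20), rep("2.1", 20), rep("2.2", 20))
  pred_main <- c(rep(1L, 36), rep(2L, 4), rep(2L, 40))
  pred_sub <- ifelse(pred_main == as.integer(substr(truth, 1, 1)),
                     truth, paste0(pred_main, ".1"))
  pred <- data.frame(id = as.character(1:80), is_enzyme = TRUE,
                     enzyme_vote = 1, main_class = pred_main, main_vote = 1,
                     sub_class = pred_sub, sub_vote = 1,
                     stringsAsFactors = FALSE)
  m <- evaluate_cascade(pred, truth)
  expect_setequal(m$sub_class, c("1.1", "1.2", "2.1", "2.2", "overall"))
  # carry-over conservation: class-1 FN total = 4, class-2 FP total = 4
  m1 <- m[startsWith(m$sub_class, "1."), ]
  m2 <- m[startsWith(m$sub_class, "2."), ]
  expect_equal(sum(m1$carry_fn), 4)
  expect_equal(sum(m2$carry_fp), 4)
  expect_equal(sum(m1$carry_fp), 0)
  # adjusted never exceeds plain; equality iff zero carry-over
  sub <- m$sub_class != "overall"
  expect_true(all(m$new_precision[sub] <= m$precision[sub], na.rm = TRUE))
  expect_true(all(m$new_recall[sub] <= m$recall[sub], na.rm = TRUE))
  zero <- sub & m$carry_fp == 0
  expect_equal(m$new_precision[zero], m$precision[zero])
  # perfect level 2 -> adjusted equals plain everywhere
  perfect <- pred
  perfect$main_class <- as.integer(substr(truth, 1, 1))
  perfect$sub_class <- truth
  mp <- evaluate_cascade(perfect, truth)
  expect_equal(mp$new_precision, mp$precision)
  expect_equal(mp$new_recall, mp$recall)
  expect_true(all(mp$precision[mp$sub_class != "overall"] == 100))
})

test_that("roc_area is the rank statistic with its invariances", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(roc_area(scores, truth), 1)
  expect_equal(roc_area(-scores, truth), 0)
  expect_equal(roc_area(rep(0.5, 6), truth), 0.5) # all ties -> 0.5
  # invariant under strictly increasing transforms
  set.seed(9)
  s <- runif(200); y <- s + rnorm(200, sd = 0.3) > 0.5
  expect_equal(roc_area(s, y), roc_area(qlogis(s), y))
  # independent scores -> ~0.5
  expect_lt(abs(roc_area(runif(500), sample(c(TRUE, FALSE), 500, TRUE)) -
                  0.5), 0.05)
  # matrix form, degenerate class -> NA
  v <- cbind(a = c(0.9, 0.1), b = c(0.1, 0.9))
  expect_true(is.na(roc_area(v, c("a", "a"))[["b"]]))
})

test_that("metrics TSV writer mirrors the report layout", {
  m <- data.frame(sub_class = c("1.1", "overall"), size = c(10, 10),
                  tp = c(9, 9), fp = c(1, 1), fn = c(1, 1),
                  carry_fp = c(2, 2), carry_fn = c(0, 0),
                  precision = c(90, 90), new_precision = c(75, 75),
                  recall = c(90, 90), new_recall = c(90, 90))
  f <- tempfile(fileext = ".tsv")
  write_metrics(m, f, roc = c("1.1" = 0.95, overall = 0.95))
  back <- read.delim(f)
  expect_equal(names(back)[1:4], c("sub_class", "size", "fp", "carry_fp"))
  expect_equal(back$roc_area, c(0.95, 0.95))
})
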