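# small strong-preset world shared across tests (memoized in helper)
world <- small_strong()
enz <- world$labels != "non_enzyme"
small_params <- cascade_params(seed = 3,
                               level1 = forest_params(50, 15, 3),
                               level2 = forest_params(50, 7, 4),
                               level3 = forest_params(50, 7, 5))
model <- train_cascade(world$x[enz, ], world$labels[enz],
                       world$x[!enz, ], small_params)

test_that("cascade structure records levels, params and label sets", {
  expect_length(model$level3, 6)
  expect_setequal(names(model$level3), as.character(1:6))
  for (k in 1:6)
    expect_true(all(startsWith(model$level3[[as.character(k)]]$classes,
                               paste0(k, "."))))
  expect_equal(model$params$level1$ntree, 50)
  expect_equal(model$metadata$n_level1_balanced,
               min(sum(enz), sum(!enz)))
  # paper defaults
  def <- cascade_params()
  expect_equal(def$level1$ntree, 200L); expect_equal(def$level1$mtry, 25L)
  expect_equal(def$level2$mtry, 7L); expect_equal(def$level3$mtry, 7L)
  expect_equal(forest_params(200L, 5L)$mtry, 5L)
})

test_that("predictions route top-down with consistent sub-class prefixes", {
  pred <- predict(model, world$x)
  expect_equal(nrow(pred), nrow(world$x))
  ne <- !pred$is_enzyme
  expect_true(all(is.na(pred$main_class[ne])))
  expect_true(all(is.na(pred$sub_class[ne])))
  ok <- pred$is_enzyme
  expect_true(all(!is.na(pred$sub_class[ok])))
  expect_true(all(sub("\\..*$", "", pred$sub_class[ok]) ==
                    pred$main_class[ok]))
  expect_true(all(pred$enzyme_vote >= 0 & pred$enzyme_vote <= 1))
})

test_that("a main class with one sub-class becomes a flagged constant node", {
  x <- world$x[enz, ][1:60, ]
  labs <- c(rep("1.1", 15), rep("1.2", 15), rep("2.1", 30))
  m <- train_cascade(x, labs, world$x[!enz, ][1:30, ], small_params)
  expect_equal(m$metadata$constant_level3, "2")
  p <- predict(m, x)
  routed2 <- !is.na(p$main_class) & p$main_class == 2
  expect_true(all(p$sub_class[routed2] == "2.1"))
})

test_that("labels without a sub-class are rejected", {
  expect_error(train_cascade(world$x[enz, ][1:10, ],
                             rep("1", 10), world$x[!enz, ][1:10, ],
                             small_params),
               "sub-class")
})

test_that("direct model covers the training label set and non-enzyme option", {
  xe <- world$x[enz, ]
  m <- train_direct(xe, world$labels[enz], forest_params(40, 5, 2))
  expect_setequal(m$forest$classes, unique(world$labels[enz]))
  expect_false(m$includes_nonenzyme)
  m2 <- train_direct(xe, world$labels[enz], forest_params(40, 5, 2),
                     nonenzyme_x = world$x[!enz, ])
  expect_true("non_enzyme" %in% m2$forest$classes)
  pred2 <- predict(m2, world$x[!enz, ])
  expect_gt(mean(pred2 == "non_enzyme"), 0.5)
  # same seed reproducibility
  m3 <- train_direct(xe, world$labels[enz], forest_params(40, 5, 2))
  expect_identical(predict(m, xe), predict(m3, xe))
})

test_that("cross_validate conserves counts, stratifies, and flags bad k", {
  d <- blob_xy(n_per = 60, p = 4)
  cv <- cross_validate(d$x, d$y, k = 10, forest_params(40, 2, 1), seed = 2)
  expect_equal(sum(cv$confusion$tp) + sum(cv$confusion$fn), nrow(d$x))
  expect_gte(cv$accuracy, 95)
  # leave-one-out conserves counts
  tiny <- blob_xy(n_per = 12, p = 3)
  loo <- cross_validate(tiny$x, tiny$y, k = nrow(tiny$x),
                        forest_params(15, 2, 1), seed = 1)
  expect_equal(sum(loo$confusion$tp) + sum(loo$confusion$fn), nrow(tiny$x))
  expect_error(cross_validate(d$x, d$y, k = 70, forest_params(10, 2, 1)),
               "smaller k")
  expect_error(cross_validate(d$x, d$y, k = 500, forest_params(10, 2, 1)),
               "exceeds")
})

test_that("model save/load round-trips to identical predictions", {
  dir <- tempfile("model")
  save_model(model, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$type, "ec_cascade")
  back <- load_model(dir)
  expect_identical(predict(back, world$x), predict(model, world$x))
})
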