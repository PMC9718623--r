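test_that("DarkNet19 spec matches the reference layer table", {
  spec <- build_darknet19_spec(5)
  expect_equal(sum(spec$layers$kind == "conv"), 19)
  expect_equal(sum(spec$layers$kind == "maxpool"), 5)
  head_conv <- spec$layers[spec$layers$name == "head_conv", ]
  expect_equal(head_conv$filters, 5L)
  expect_equal(head_conv$kernel, 1L)
  expect_equal(spec$layers$kind[nrow(spec$layers)], "global_softmax")
  expect_equal(build_darknet19_spec(7)$layers$filters[[24]], 7L)
  expect_error(build_darknet19_spec(1), "num_classes")
})

test_that("DarkNet19 shape inference reproduces the printed output column", {
  spec <- build_darknet19_spec(5)
  sh <- infer_shapes(spec, 224)
  # printed spatial sizes, row for row
  expect_equal(sh$out_h, c(224, 112, 112, 56, 56, 56, 56, 28, 28, 28, 28,
                           14, 14, 14, 14, 14, 14, 7, 7, 7, 7, 7, 7, 7, 1))
  # channel bookkeeping through the 1x1 bottlenecks
  expect_equal(sh$out_c[sh$name == "conv18"], 1024)
  expect_equal(sh$out_c[sh$name == "head_conv"], 5)
  expect_equal(tap_dim(spec), 1024L)
})

test_that("SqueezeNet spec matches the reference fire-module table", {
  spec <- build_squeezenet_spec(5)
  expect_equal(sum(spec$layers$kind == "fire"), 8)
  fire2 <- spec$layers[spec$layers$name == "fire2", ]
  expect_equal(c(fire2$squeeze, fire2$expand1, fire2$expand3),
               c(16L, 64L, 64L))
  fire8 <- spec$layers[spec$layers$name == "fire8", ]
  expect_equal(c(fire8$squeeze, fire8$expand1, fire8$expand3),
               c(64L, 256L, 256L))
  expect_equal(spec$layers$filters[spec$layers$name == "conv10"], 5L)
  expect_equal(tap_dim(spec), 512L)
})

test_that("SqueezeNet shape inference reproduces the printed sizes at 227", {
  # the printed 111x111 stem output is consistent with a 227 input under
  # valid padding: floor((227 - 7)/2) + 1 = 111
  sh <- infer_shapes(build_squeezenet_spec(5), 227)
  expect_equal(sh$out_h[sh$name == "conv1"], 111)
  expect_equal(sh$out_h[sh$name == "maxpool1"], 55)   # floor((111-3)/2)+1
  expect_equal(sh$out_c[sh$name == "fire2"], 128)     # 64 + 64 expands
  expect_equal(sh$out_h[sh$name == "maxpool4"], 27)
  expect_equal(sh$out_c[sh$name == "fire8"], 512)
  expect_equal(sh$out_h[sh$name == "maxpool8"], 13)
  expect_equal(unlist(sh[sh$name == "fire9", c("out_h", "out_w", "out_c")],
                      use.names = FALSE), c(13, 13, 512))
  expect_equal(unlist(sh[sh$name == "avgpool10",
                         c("out_h", "out_w", "out_c")],
                      use.names = FALSE), c(1, 1, 5))
})

test_that("shape inference is pure arithmetic and flags collapsing layers", {
  sh <- infer_shapes(build_squeezenet_spec(5), 224)
  expect_equal(sh$out_h[1], 109)   # (224 - 7)/2 + 1
  expect_error(infer_shapes(build_squeezenet_spec(5), 20), "collapses")
  expect_error(infer_shapes(build_darknet19_spec(5), 0), "input_hw")
})

test_that("mock extractor is deterministic with the contracted shape", {
  s <- grain_fixture()
  ext <- mock_extractor(out_dim = 32, seed = 1)
  f <- extract_features(ext, s)
  expect_equal(dim(f), c(10, 34))
  expect_true(all(grepl("^mock:proj:", names(f)[-(1:2)])))
  expect_true(all(is.finite(as.matrix(f[, -(1:2)]))))

  # duplicated image rows give identical feature rows
  f_dup <- extract_features(ext, s[c(1, 1)])
  expect_equal(unname(as.matrix(f_dup[1, -(1:2)])),
               unname(as.matrix(f_dup[2, -(1:2)])))

  # same extractor twice: identical matrix
  f2 <- extract_features(mock_extractor(out_dim = 32, seed = 1), s)
  expect_identical(f, f2)
})

test_that("mock features inherit the fixture's class separability", {
  set.seed(1)
  s <- gen_grain_images(20, 2, 128, seed = 11)
  f <- extract_features(mock_extractor(out_dim = 32, seed = 1), s)
  u <- grainsight:::unpack_features(f)
  tr <- seq(1, 40, 2); te <- seq(2, 40, 2)
  pred <- class::knn(u$x[tr, ], u$x[te, ], factor(u$labels[tr]), k = 5)
  expect_gte(mean(pred == factor(u$labels[te])), 0.90)
})

test_that("head swap and fine-tuning honour the transfer contract", {
  s <- gen_grain_images(10, 2, 128, seed = 3)
  labels <- purrr::map_int(s, "label")

  expect_error(swap_head_and_finetune(mock_extractor(16), s, labels),
               "trainable")

  ext <- mlp_extractor(out_dim = 16, num_classes = 3, seed = 2)
  # head replacement resizes the output layer only
  swapped <- swap_head_and_finetune(ext, s, labels,
                                    list(num_classes = 2, epochs = 0))
  expect_equal(ncol(swapped$net$w[[length(swapped$net$w)]]), 2)
  # zero epochs: features identical before and after
  expect_identical(extract_features(ext, s)[, -(1:2)],
                   extract_features(swapped, s)[, -(1:2)])

  # fine-tuning all layers yields at least the random-init accuracy
  knn_holdout <- function(extractor) {
    u <- grainsight:::unpack_features(extract_features(extractor, s))
    tr <- seq(1, 20, 2); te <- seq(2, 20, 2)
    pred <- class::knn(u$x[tr, , drop = FALSE], u$x[te, , drop = FALSE],
                       factor(labels[tr]), k = 3)
    mean(pred == factor(labels[te]))
  }
  tuned <- swap_head_and_finetune(ext, s, labels,
                                  list(num_classes = 2, epochs = 150,
                                       train_layers = "all"))
  expect_gte(knn_holdout(tuned), knn_holdout(ext))
})
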