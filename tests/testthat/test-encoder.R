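# Section encoding, rotation augmentation and pooling.

enc_setup <- function() {
  fixture("enc_setup", {
    spec <- synthetic_stack_spec(width_px = 64, height_px = 64, rng_seed = 8)
    img <- with_seed(40, render_stratum_texture("VE", spec))
    patches <- normalize_patches(extract_random_patches(img, 3000, 7,
                                                        rng_seed = 2))
    wm <- fit_whitening(patches)
    dict <- learn_dictionary(apply_whitening(wm, patches), 2, 3, rng_seed = 3)
    list(img = img, wm = wm, dict = dict)
  })
}

indicator_encoding <- function(i, k, stack = "s", section = 0L) {
  structure(as.numeric(seq_len(k) == i), stack_id = stack,
            section_index = section, rotation = "0",
            class = "section_encoding")
}

test_that("encodings are unit-L2 histograms whose counts total the dense-patch count", {
  s <- enc_setup()
  e <- encode_section(s$img, s$wm, s$dict, stride = 1)
  expect_lt(abs(sqrt(sum(as.numeric(e)^2)) - 1), 1e-8)
  # recover integer counts: they must sum to (64 - 7 + 1)^2
  n_patches <- (64 - 7 + 1)^2
  counts <- as.numeric(e) * n_patches / sum(as.numeric(e))
  expect_equal(counts, round(counts), tolerance = 1e-6)
  expect_equal(sum(counts), n_patches)

  # a constant section maps every patch to one word: indicator histogram
  const <- encode_section(matrix(0.5, 32, 32), s$wm, s$dict)
  expect_equal(sum(as.numeric(const) > 0), 1)
  expect_equal(max(as.numeric(const)), 1)

  expect_error(encode_section(matrix(0.5, 5, 5), s$wm, s$dict), "smaller")
})

test_that("fast-path encoding equals the explicit whiten-then-quantize route", {
  s <- enc_setup()
  e <- encode_section(s$img, s$wm, s$dict, stride = 2)
  white <- apply_whitening(s$wm, normalize_patches(
    extract_dense_patches(s$img, 7, 2), s$wm$patch_norm_reg))
  h <- tabulate(quantize(s$dict, white), nbins = n_words(s$dict))
  expect_equal(as.numeric(e), h / sqrt(sum(h^2)), tolerance = 1e-12)
})

test_that("right-angle rotations behave as a group and tag encodings", {
  img <- matrix(1:36 / 36, 6, 6)
  expect_identical(rotate_image(rotate_image(img, 180), 180), img)
  expect_identical(rotate_image(rotate_image(img, 90), 270), img)
  expect_error(rotate_image(img, 45), "90")

  s <- enc_setup()
  encs <- encode_with_rotations(s$img, s$wm, s$dict, stride = 2)
  expect_length(encs, 4)
  expect_equal(vapply(encs, attr, "", "rotation"),
               c("0", "90", "180", "270"))
  # the 90-degree encoding is the 0-degree encoding of the rotated image
  direct <- encode_section(rotate_image(s$img, 90), s$wm, s$dict, stride = 2)
  expect_equal(as.numeric(encs[[2]]), as.numeric(direct))
  # constant (rotationally symmetric) section -> 4 identical histograms
  const4 <- encode_with_rotations(matrix(0.2, 32, 32), s$wm, s$dict)
  for (i in 2:4) {
    expect_equal(as.numeric(const4[[i]]), as.numeric(const4[[1]]))
  }
  expect_error(encode_with_rotations(matrix(0, 10, 12), s$wm, s$dict),
               "square")
})

test_that("rotation pooling averages, renormalises and validates", {
  e1 <- indicator_encoding(1, 9)
  e2 <- indicator_encoding(2, 9)
  pooled <- pool_rotations(list(e1, e1, e2, e2))
  expect_equal(as.numeric(pooled),
               (as.numeric(e1) + as.numeric(e2)) / sqrt(2))
  expect_equal(attr(pooled, "rotation"), "POOLED")
  expect_lt(abs(sqrt(sum(as.numeric(pooled)^2)) - 1), 1e-12)
  # idempotence on identical histograms
  expect_equal(as.numeric(pool_rotations(list(e1, e1, e1, e1))),
               as.numeric(e1))
  # plain average when renormalisation is disabled
  expect_equal(as.numeric(pool_rotations(list(e1, e1, e2, e2),
                                         renormalize = FALSE)),
               (as.numeric(e1) + as.numeric(e2)) / 2)
  expect_error(pool_rotations(list(e1, e1, e2)), "4 rotation")
  other <- indicator_encoding(1, 9, section = 3L)
  expect_error(pool_rotations(list(e1, e1, e2, other)), "different sections")
})

test_that("stack encoding keeps rotations as rows for training, pools for prediction", {
  s <- enc_setup()
  stk <- depth_stack(list(s$img, rotate_image(s$img, 90)), stack_id = "stk")
  train <- encode_stack(stk, s$wm, s$dict, stride = 2, pool = FALSE)
  expect_equal(nrow(train$x), 8)  # 2 sections x 4 rotations
  expect_equal(train$meta$rotation, rep(c("0", "90", "180", "270"), 2))
  test <- encode_stack(stk, s$wm, s$dict, stride = 2, pool = TRUE)
  expect_equal(nrow(test$x), 2)
  expect_true(all(test$meta$rotation == "POOLED"))
  expect_equal(test$meta$section_index, 0:1)
})
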