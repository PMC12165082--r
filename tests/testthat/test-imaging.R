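test_that("tiling covers with a ceil grid, pads remainders, and inverts", {
  img <- array(runif(2048 * 1024 * 3), dim = c(1024, 2048, 3))
  tl <- tile_wsi(img)
  expect_equal(nrow(tl), 2)
  expect_equal(tl$ox, c(0, 1024))
  expect_equal(tl$oy, c(0, 0))
  expect_equal(tl$pad_x, c(0, 0))

  img2 <- array(runif(1500 * 1024 * 3), dim = c(1024, 1500, 3))
  tl2 <- tile_wsi(img2)
  expect_equal(nrow(tl2), 2)
  expect_equal(tl2$pad_x, c(0, 1024 - 476))

  # reassembling the unpadded regions reproduces the raster bit-exactly
  rec <- array(0, dim = dim(img2))
  for (i in seq_len(nrow(tl2))) {
    ylen <- 1024 - tl2$pad_y[i]; xlen <- 1024 - tl2$pad_x[i]
    rec[tl2$oy[i] + seq_len(ylen), tl2$ox[i] + seq_len(xlen), ] <-
      tl2$pixels[[i]][seq_len(ylen), seq_len(xlen), ]
  }
  expect_identical(rec, img2)
  expect_error(tile_wsi(array(0, dim = c(0, 5, 3))), "empty")
})

test_that("iou matches hand-computed areas", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 2, 2), c(10, 10, 2, 2)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 0, 2, 2)), 1 / 3)
  expect_error(iou(c(0, 0, 0, 2), c(0, 0, 2, 2)), "degenerate")
})

test_that("nms keeps the confident box and suppresses overlaps", {
  one <- tibble::tibble(x = 0, y = 0, w = 10, h = 10, confidence = 0.9)
  expect_equal(nrow(nms_filter(one)), 1)

  two <- tibble::tibble(x = c(0, 0), y = c(0, 0), w = c(10, 10), h = c(10, 10),
                        confidence = c(0.9, 0.8))
  kept <- nms_filter(two)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$confidence, 0.9)

  # at or below the confidence floor is dropped
  low <- tibble::tibble(x = 0, y = 0, w = 10, h = 10, confidence = 0.3)
  expect_equal(nrow(nms_filter(low)), 0)
})

test_that("nms equals the exhaustive suppression oracle on random boxes", {
  brute_nms <- function(boxes, conf_min = 0.3, iou_max = 0.5) {
    boxes <- boxes[boxes$confidence > conf_min, , drop = FALSE]
    boxes <- boxes[order(boxes$confidence, decreasing = TRUE), , drop = FALSE]
    kept <- list()
    for (i in seq_len(nrow(boxes))) {
      suppressed <- FALSE
      for (k in kept) {
        if (iou(boxes[i, ], k) > iou_max) suppressed <- TRUE
      }
      if (!suppressed) kept[[length(kept) + 1]] <- boxes[i, ]
    }
    if (length(kept)) dplyr::bind_rows(kept) else boxes[0, ]
  }
  set.seed(13)
  for (rep in 1:30) {
    n <- sample(1:25, 1)
    boxes <- tibble::tibble(
      x = runif(n, 0, 80), y = runif(n, 0, 80),
      w = runif(n, 5, 40), h = runif(n, 5, 40),
      confidence = runif(n)
    )
    got <- nms_filter(boxes)
    oracle <- brute_nms(boxes)
    expect_equal(got, oracle)
    if (nrow(got) > 1) {
      pair_ious <- utils::combn(nrow(got), 2, function(ij) {
        iou(got[ij[1], ], got[ij[2], ])
      })
      expect_true(all(pair_ious <= 0.5))
    }
  }
})

test_that("detection loss matches its closed forms", {
  box <- tibble::tibble(x = 0, y = 0, w = 2, h = 2)
  perfect <- detection_loss(box, box)
  expect_equal(perfect$iou, 0)

  disjoint <- detection_loss(box, tibble::tibble(x = 10, y = 10, w = 2, h = 2))
  expect_equal(disjoint$iou, 1)

  third <- detection_loss(box, tibble::tibble(x = 1, y = 0, w = 2, h = 2))
  expect_equal(third$iou, 8 / 9)

  # no foreground pairs: IoU term 0 by convention; BCE terms still count
  none <- detection_loss(box[0, ], box[0, ],
                         obj_logits = c(0, 0), obj_targets = c(1, 0))
  expect_equal(none$iou, 0)
  expect_equal(none$obj, log(2), tolerance = 1e-12)
  expect_equal(none$total, log(2), tolerance = 1e-12)

  # total is the lambda-weighted sum
  mixed <- detection_loss(box, tibble::tibble(x = 1, y = 0, w = 2, h = 2),
                          obj_logits = 5, obj_targets = 1,
                          cls_logits = -5, cls_targets = 0, lambda_reg = 0.5)
  expect_equal(mixed$total, 0.5 * 8 / 9 + mixed$obj + mixed$cls)
  expect_error(detection_loss(box, box[0, ]), "same number")
})

test_that("dice+bce loss matches the closed form", {
  # confident perfect prediction: dice term ~0
  logits <- matrix(c(50, 50, -50, -50), 2, 2)
  truth <- matrix(c(1, 1, 0, 0), 2, 2)
  l <- dice_bce_loss(logits, truth)
  expect_equal(l$dice, 1, tolerance = 1e-9)
  expect_lt(l$total, 1e-9)

  # confident complementary masks: dice coefficient 0, dice term 1
  comp <- dice_bce_loss(-logits, truth)
  expect_equal(comp$dice, 0, tolerance = 1e-9)

  # uniform 0.5 prediction on a half-ones mask, n pixels:
  # dice = 2*(0.5*n/2)/(0.5n + n/2) = 1/2; bce = log 2
  n <- 16
  half <- dice_bce_loss(rep(0, n), rep(c(1, 0), each = n / 2))
  expect_equal(half$dice, 0.5, tolerance = 1e-12)
  expect_equal(half$bce, log(2), tolerance = 1e-12)
  expect_equal(half$total, log(2) + 0.5, tolerance = 1e-9)
  expect_error(dice_bce_loss(rep(0, 4), rep(1, 5)), "shape")
})

test_that("size routing splits at the 90 px boundary, ties to small", {
  mk <- function(side) {
    m <- matrix(FALSE, 300, 300)
    m[10 + seq_len(side), 10 + seq_len(side)] <- TRUE
    m
  }
  expect_equal(route_by_size(mk(60)), "small")
  expect_equal(route_by_size(mk(200)), "large")
  expect_equal(route_by_size(mk(90)), "small")
  expect_equal(route_by_size(mk(91)), "large")
  expect_error(route_by_size(matrix(FALSE, 10, 10)), "empty")
})

test_that("background removal is idempotent", {
  cell <- render_cell(cell_render_spec("small"), seed = 5)
  once <- remove_background(cell$image, cell$mask)
  twice <- remove_background(once, cell$mask)
  expect_identical(once, twice)
})
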