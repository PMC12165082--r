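test_that("rendered cells fit their size-class crops", {
  large <- render_cell(cell_render_spec("large"), seed = 1)
  bb <- etcscreen:::mask_bbox(large$mask)
  expect_equal(dim(large$image), c(254, 254, 3))
  expect_gt(max(bb$w, bb$h), 90)
  expect_lte(max(bb$w, bb$h), 254)

  small <- render_cell(cell_render_spec("small"), seed = 1)
  bb <- etcscreen:::mask_bbox(small$mask)
  expect_equal(dim(small$image), c(90, 90, 3))
  expect_lte(max(bb$w, bb$h), 90)
})

test_that("identical spec and seed render bit-identical cells", {
  spec <- sample_cell_spec(TRUE, "large", seed = 7)
  expect_identical(render_cell(spec, seed = 3), render_cell(spec, seed = 3))
  expect_false(identical(render_cell(spec, seed = 3)$image,
                         render_cell(spec, seed = 4)$image))
})

test_that("malignant renders have higher nucleus/cell area ratio on average", {
  measure <- function(malignant) {
    vapply(1:200, function(i) {
      cell <- render_cell(sample_cell_spec(malignant, "small",
                                           seed = 5000 * malignant + i),
                          seed = 6000 * malignant + i)
      pal <- default_palette()
      nd <- etcscreen:::color_distance(cell$image, pal$nucleus)
      cd <- etcscreen:::color_distance(cell$image, pal$cytoplasm)
      sum(cell$mask & nd < cd) / sum(cell$mask)
    }, numeric(1))
  }
  mal <- measure(TRUE)
  ben <- measure(FALSE)
  expect_gt(mean(mal), mean(ben))
  # distributions overlap: neither class is perfectly separable
  expect_gt(max(ben), min(mal))
})

test_that("slides carry exact label bookkeeping and stay inside bounds", {
  sl <- render_slide(slide_spec(n_cells = 40, etc_fraction = 10,
                                junk_fraction = 0.25, patch_grid = c(2, 2),
                                seed = 6))
  ann <- sl$annotations
  expect_equal(sum(ann$malignant), round(40 * 10 / 100))
  expect_equal(sum(ann$is_cell), 40)
  expect_equal(dim(sl$wsi)[1:2], c(2048, 2048))
  expect_true(all(ann$x >= 0 & ann$y >= 0 &
                    ann$x + ann$w <= 2048 & ann$y + ann$h <= 2048))
  # junk objects carry their QC category as the label
  expect_true(all(ann$label[!ann$is_cell] %in% junk_categories()))
  # masks decode to the annotated box shape
  m <- rle_decode(ann$mask_rle[1])
  expect_equal(dim(m), c(ann$h[1], ann$w[1]))
})

test_that("an empty slide is background only", {
  sl <- render_slide(slide_spec(n_cells = 0, junk_fraction = 0, seed = 2))
  expect_equal(nrow(sl$annotations), 0)
  expect_equal(dim(sl$wsi), c(1024, 1024, 3))
})

test_that("slides are seed-deterministic and overfull slides fail", {
  a <- render_slide(slide_spec(25, 20, seed = 9))
  b <- render_slide(slide_spec(25, 20, seed = 9))
  expect_identical(a$wsi, b$wsi)
  expect_identical(a$annotations, b$annotations)
  expect_error(render_slide(slide_spec(900, 0, seed = 1)), "could not place")
})

test_that("cohort simulation is deterministic with class-conditional fractions", {
  a <- simulate_cohort(5, 5, seed = 3)
  b <- simulate_cohort(5, 5, seed = 3)
  expect_identical(a$true_etc_fraction, b$true_etc_fraction)
  expect_identical(a$truth, b$truth)
  expect_true(all(a$true_etc_fraction[a$truth == "cancer"] > 0))
  expect_true(mean(a$true_etc_fraction[a$truth == "control"] == 0) >= 0.5)
})
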