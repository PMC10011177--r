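test_that("stimulus specs validate their geometry", {
  expect_error(stimulus_spec("sparkles"), class = "wavsal_config_error")
  expect_error(stimulus_spec("color_popout", grid = c(1, 1)),
               class = "wavsal_config_error")
  expect_error(stimulus_spec("color_popout", target_cell = c(9, 9)),
               class = "wavsal_config_error")
})

test_that("uniform stimuli are constant and yield zero saliency", {
  st <- render_stimulus(stimulus_spec("uniform", frame = c(96L, 128L)))
  expect_equal(length(unique(as.vector(st$image))), 1)
  expect_null(st$target_box)
  out <- suppressWarnings(
    run_model(st$image, model_config(version = 2,
                                     working_size = c(96L, 128L))))
  expect_true(all(out$saliency$values == 0))
})

test_that("stimuli render deterministically from their spec", {
  a <- render_stimulus(stimulus_spec("noise", seed = 33, frame = c(64L, 64L)))
  b <- render_stimulus(stimulus_spec("noise", seed = 33, frame = c(64L, 64L)))
  expect_identical(a$image, b$image)
  c1 <- render_stimulus(stimulus_spec("conjunction_popout"))
  c2 <- render_stimulus(stimulus_spec("conjunction_popout"))
  expect_identical(c1$image, c2$image)
})

test_that("the color pop-out target dominates the RG opponency channel", {
  spec <- stimulus_spec("color_popout")
  st <- render_stimulus(spec)
  rg <- compute_opponency(st$image)$RG
  boxes <- grid_boxes(spec)
  e <- vapply(boxes, function(b) box_energy(rg, b$box), 0)
  tgt <- which(vapply(boxes, `[[`, TRUE, "is_target"))
  expect_gt(e[tgt], 1.5 * max(e[-tgt]))
})

test_that("the conjunction target is unique only in medium-level channels", {
  spec <- stimulus_spec("conjunction_popout")
  st <- render_stimulus(spec)
  fs <- extract_features(st$image, "full")
  boxes <- grid_boxes(spec)
  tgt <- which(vapply(boxes, `[[`, TRUE, "is_target"))
  unique_in <- function(nm) {
    e <- vapply(boxes, function(b) box_energy(fs$channels[[nm]], b$box), 0)
    e[tgt] > 1.05 * max(e[-tgt])
  }
  low <- c("I", "RG", "BY", sprintf("O%d.I", 0:7))
  med <- sprintf("O%d.%s", rep(0:7, 2), rep(c("RG", "BY"), each = 8))
  expect_false(any(vapply(low, unique_in, TRUE)))
  expect_true(any(vapply(med, unique_in, TRUE)))
})

test_that("fixation sampling respects the target box and the seed", {
  box <- c(10, 20, 30, 50)
  fix <- sample_fixations(box, c(60, 80), n_on_target = 25,
                          n_background = 0, seed = 4)
  expect_equal(nrow(fix$points), 25)
  expect_true(all(fix$points[, 1] >= 10 & fix$points[, 1] <= 20))
  expect_true(all(fix$points[, 2] >= 30 & fix$points[, 2] <= 50))
  again <- sample_fixations(box, c(60, 80), 25, 0, seed = 4)
  expect_identical(fix$points, again$points)
  # on-target fraction is exact by construction; background points avoid
  # the box
  mixed <- sample_fixations(box, c(60, 80), 400, 100, seed = 5)
  inside <- mixed$points[, 1] >= 10 & mixed$points[, 1] <= 20 &
            mixed$points[, 2] >= 30 & mixed$points[, 2] <= 50
  expect_equal(sum(inside), 400)
  expect_equal(sum(!inside), 100)
  expect_error(sample_fixations(c(0, 9, 1, 5), c(8, 8), 1, 0),
               class = "wavsal_input_error")
})

test_that("the fixture suite is complete and reproducible", {
  s1 <- make_fixture_suite(seed = 5, frame = c(96L, 160L))
  expect_gte(length(s1), 7)
  expect_setequal(names(s1),
                  c("uniform", "noise", "color_popout", "orientation_popout",
                    "conjunction_popout", "fine_texture", "large_blob"))
  s2 <- make_fixture_suite(seed = 5, frame = c(96L, 160L))
  for (nm in names(s1)) {
    expect_identical(s1[[nm]]$image, s2[[nm]]$image)
    expect_identical(s1[[nm]]$fixations$points, s2[[nm]]$fixations$points)
  }
  # fixtures with a target concentrate fixations on it
  for (nm in c("color_popout", "fine_texture", "large_blob")) {
    fx <- s1[[nm]]
    b <- fx$target_box
    inside <- fx$fixations$points[, 1] >= b[1] &
              fx$fixations$points[, 1] <= b[2] &
              fx$fixations$points[, 2] >= b[3] &
              fx$fixations$points[, 2] <= b[4]
    expect_gt(mean(inside), 0.5)
  }
})
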