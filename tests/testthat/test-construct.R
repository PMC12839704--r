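test_that("the color mask whitens red-family tones and nothing else", {
  px <- array(1, dim = c(300, 300, 3))
  px[10, 10, ] <- c(0, 0, 1)          # pure blue
  px[20, 20, ] <- c(1, 0, 0)          # pure red
  px[30, 30, ] <- c(0.5, 0, 0)        # maroon
  px[40, 40, ] <- c(1, 0.75, 0.8)     # pink
  px[50, 50, ] <- c(0.3, 0.3, 0.3)    # dark gray
  out <- mask_post_bd_colors(make_page(px))$pixels
  expect_identical(out[10, 10, ], c(0, 0, 1))
  expect_identical(out[20, 20, ], c(1, 1, 1))
  expect_identical(out[30, 30, ], c(1, 1, 1))
  expect_identical(out[40, 40, ], c(1, 1, 1))
  expect_identical(out[50, 50, ], c(0.3, 0.3, 0.3))
  # no red-family pixel survives a post-BD page
  masked <- mask_post_bd_colors(cough_report_with_post_bd())$pixels
  expect_false(any(masked[, , 1] > 0.9 & masked[, , 2] < 0.3 &
                     masked[, , 3] < 0.3))
})

test_that("surviving regions match the brute-force component oracle", {
  # hand-built page: blobs only in the bottom half (rows 201-400)
  page <- blob_page(400, 300, list(
    list(rows = 240:279, cols = 40:89),     # area 2000
    list(rows = 300:339, cols = 150:219),   # area 2800
    list(rows = 360:368, cols = 260:268)))  # area 81, filtered out
  cfg <- construct_config(area_min = 100L)
  regions <- extract_curve_regions(page, cfg)
  # oracle: binarize the bottom half, label 8-connected, drop area < 100
  gray <- 0.299 * page$pixels[201:400, , 1] + 0.587 * page$pixels[201:400, , 2] +
    0.114 * page$pixels[201:400, , 3]
  lab <- oracle_label_components(gray < 0.5)
  boxes <- oracle_component_boxes(lab)
  boxes <- boxes[boxes[, "area"] >= 100, , drop = FALSE]
  boxes <- boxes[order(-boxes[, "area"]), ]
  boxes[, c("top", "bottom")] <- boxes[, c("top", "bottom")] + 200 # page coords
  got <- rbind(regions$vt$box, regions$fv$box)
  got <- got[order(-c(sum(regions$vt$crop > 0), sum(regions$fv$crop > 0))), ]
  expect_equal(unname(got), unname(boxes[1:2, 1:4]))
  # vt is the leftmost region under the default layout convention
  expect_lt(regions$vt$box[2], regions$fv$box[2])
})

test_that("the area filter is strictly less-than", {
  # all blobs in the bottom half (rows > 300) of a 600-row page
  big <- list(rows = 320:399, cols = 20:99)          # area 6400
  at_thr <- list(rows = 420:444, cols = 150:189)     # 25 x 40 = 1000
  below <- list(rows = 420:446, cols = 150:186)      # 27 x 37 = 999
  r <- extract_curve_regions(blob_page(600, 300, list(big, at_thr)))
  expect_identical(sum(r$fv$crop > 0) + sum(r$vt$crop > 0), 7400L)
  expect_error(extract_curve_regions(blob_page(600, 300, list(big, below))),
               "fewer than 2")
  expect_error(extract_curve_regions(blob_page(600, 300, list())),
               "fewer than 2")
})

test_that("panel composition is 700x500, binary, and ordered vt over fv", {
  r <- extract_curve_regions(blob_page(400, 300, list(
    list(rows = 240:279, cols = 40:89),
    list(rows = 300:339, cols = 150:219))), construct_config(area_min = 100L))
  comp <- compose_panel(r$vt$crop, r$fv$crop)
  expect_identical(dim(comp$panel), c(700L, 500L))
  expect_true(all(comp$panel %in% c(0, 255)))
  fg <- which(comp$panel > 0, arr.ind = TRUE)
  vt_rows <- fg[fg[, 1] <= 350, 1]; fv_rows <- fg[fg[, 1] > 350, 1]
  expect_lt(mean(vt_rows), 350)
  expect_gte(mean(fv_rows), 350)
  # oversized crop is scaled down without clipping
  huge <- matrix(255, 900, 900)
  comp2 <- compose_panel(huge, r$fv$crop)
  expect_identical(dim(comp2$panel), c(700L, 500L))
  expect_gt(sum(comp2$panel[1:350, ] > 0), 0)
  expect_error(compose_panel(matrix(0, 5, 5), r$fv$crop), "empty")
})

test_that("demographic frame sections encode normalized values as grays", {
  panel <- matrix(0, 700, 500)
  enc <- encode_demographics_frame(panel, case_demo)
  expect_identical(dim(enc$framed), c(700L, 700L))
  expect_identical(unname(enc$frame_grays), c(255, 121, 20))
  # sections are constant blocks at the expected rows
  expect_true(all(enc$framed[1:234, 501:700] == 255))
  expect_true(all(enc$framed[235:467, 501:700] == 121))
  expect_true(all(enc$framed[468:700, 501:700] == 20))
  expect_identical(unname(encode_demographics_frame(
    panel, list(sex = "man", age = 10, bmi = 15))$frame_grays), c(0, 0, 0))
  # monotone, and clamped (with a warning) outside the bounds
  grays <- vapply(seq(10, 84, by = 2), function(a)
    encode_demographics_frame(panel,
                              list(sex = "man", age = a, bmi = 20))$frame_grays[["age"]],
    numeric(1))
  expect_true(all(diff(grays) >= 0))
  expect_warning(
    g <- encode_demographics_frame(panel, list(sex = "man", age = 99,
                                               bmi = 20))$frame_grays,
    "clamped")
  expect_identical(g[["age"]], 255)
})

test_that("finalization yields a 224x224 three-channel input", {
  framed <- matrix(37, 700, 700)
  net <- finalize_construct(framed)
  expect_identical(dim(net), c(224L, 224L, 3L))
  expect_identical(net[, , 1], net[, , 2])
  expect_identical(net[, , 1], net[, , 3])
  expect_true(all(abs(net - 37) < 1e-9))  # resize preserves constants
})

test_that("build_construct runs end to end on a rendered report", {
  r <- clean_report()
  gc1 <- build_construct(r$page, r$demographics)
  expect_identical(dim(gc1$network_input), c(224L, 224L, 3L))
  expect_identical(unname(gc1$frame_grays), c(255, 121, 20))
  # deterministic: identical page + demographics -> identical construct
  gc2 <- build_construct(r$page, r$demographics)
  expect_identical(gc1$network_input, gc2$network_input)
  # failure carries the stage name
  blank <- make_page(array(1, dim = c(400, 300, 3)))
  expect_error(build_construct(blank, case_demo), "extract")
})

test_that("page-space annotation boxes map into the construct", {
  r <- cough_report()
  gc1 <- build_construct(r$page, r$demographics)
  box <- map_page_box_to_construct(gc1, r$artifact_annotation)
  expect_false(is.null(box))
  expect_true(all(box >= 0 & box <= 224))
  expect_gt(box[3], box[1]); expect_gt(box[4], box[2])
  # the artifact lies in the flow-volume sub-panel (bottom half of construct)
  expect_gt((box[1] + box[3]) / 2, 112)
  # a box outside both curve regions does not map
  expect_null(map_page_box_to_construct(gc1, c(0, 0, 10, 10)))
})
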