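# Data pipeline: preprocessing constants, augmentation, splits, offline
# balancing, leakage detection.

test_that("preprocessing centers the channel means exactly", {
  img <- array(0, c(10, 10, 3))
  img[, , 1] <- 0.485; img[, , 2] <- 0.456; img[, , 3] <- 0.406
  out <- preprocess_image(img, size = 10)
  expect_equal(out, array(0, c(10, 10, 3)), tolerance = 1e-12)
})

test_that("a white image maps to the stated per-channel values", {
  img <- array(1, c(8, 8, 3))
  out <- preprocess_image(img, size = 8)
  expect_equal(out[1, 1, ], c(0.515 / 0.229, 0.544 / 0.224, 0.594 / 0.225),
               tolerance = 1e-9)
})

test_that("preprocess resizes any input to (size, size, 3)", {
  set.seed(1)
  img <- array(runif(30 * 50 * 3), c(30, 50, 3))
  out <- preprocess_image(img, size = 24)
  expect_equal(dim(out), c(24, 24, 3))
})

test_that("grayscale files are replicated to 3 channels with a warning and
           unreadable paths raise an informative error", {
  td <- withr::local_tempdir()
  gpath <- file.path(td, "gray.png")
  EBImage::writeImage(matrix(runif(64), 8, 8), gpath)
  expect_warning(img <- read_image(gpath), "replicated")
  expect_equal(dim(img), c(8, 8, 3))
  expect_equal(img[, , 1], img[, , 3])
  expect_error(read_image(file.path(td, "missing.png")), "missing.png")
})

test_that("augmentation is seed-reproducible and stays in [0, 1]", {
  set.seed(2)
  img <- array(runif(12 * 12 * 3), c(12, 12, 3))
  a1 <- augment_image(img, seed = 42)
  a2 <- augment_image(img, seed = 42)
  a3 <- augment_image(img, seed = 43)
  expect_identical(a1, a2)
  expect_false(identical(a1, a3))
  expect_true(all(a1 >= 0 & a1 <= 1))
  expect_equal(dim(a1), dim(img))
})

test_that("horizontal flips occur with frequency 0.5 over many seeds", {
  img <- array(0, c(4, 6, 3))
  img[, 1, ] <- 1                        # asymmetric marker column
  flipped <- vapply(1:1000, function(s) {
    # neutralize jitter and blur so only the flips act
    out <- augment_image(img, seed = s, jitter = 0, sigma_range = c(1e-9, 1e-9))
    out[1, 6, 1] > 0.5                   # marker moved to the other side
  }, logical(1))
  expect_lt(abs(mean(flipped) - 0.5), 0.05)
})

# small synthetic index for split/balancing tests
fake_index <- function(counts) {
  recs <- lapply(names(counts), function(cl)
    data.frame(image_id = sprintf("%s/im%04d.png", cl, seq_len(counts[[cl]])),
               path = sprintf("/data/%s/im%04d.png", cl, seq_len(counts[[cl]])),
               class_label = cl, origin = "real", parent_id = NA_character_,
               subset = "unassigned"))
  do.call(rbind, recs)
}

test_that("an 80:10:10 split of 400 balanced images gives 320/40/40,
           stratified and disjoint", {
  idx <- fake_index(c(a = 100, b = 100, c = 100, d = 100))
  out <- split_holdout(idx, c(train = .8, val = .1, test = .1), seed = 3)
  expect_equal(as.vector(table(out$subset)[c("train", "val", "test")]),
               c(320, 40, 40))
  for (cl in c("a", "b", "c", "d")) {
    sub <- out[out$class_label == cl, ]
    expect_equal(sum(sub$subset == "train"), 80)
    expect_equal(sum(sub$subset == "val"), 10)
  }
  expect_equal(sort(out$image_id), sort(idx$image_id))
  expect_error(split_holdout(idx, c(train = .8, val = .1, test = .2)),
               "sum to 1")
})

test_that("split proportions are preserved per class (counting oracle)", {
  set.seed(4)
  idx <- fake_index(c(x = 57, y = 143, z = 29))
  out <- split_holdout(idx, c(train = .7, val = .2, test = .1), seed = 9)
  for (cl in c("x", "y", "z")) {
    n <- sum(idx$class_label == cl)
    got <- table(out$subset[out$class_label == cl])
    expect_lte(abs(got[["train"]] - 0.7 * n), 1)
    expect_lte(abs(got[["val"]] - 0.2 * n), 1)
  }
})

test_that("balancing requires the split to exist (split-then-augment order)", {
  idx <- fake_index(c(a = 10))
  expect_error(plan_balancing(idx, 100), "split, then augment")
})

test_that("balancing reproduces the published per-class augmented counts", {
  # 101 real images at target 2000 (70:20:10) -> 1899 augmented;
  # 1509 real -> 491 augmented
  idx <- fake_index(c(csc = 101, dr = 1509))
  idx <- split_holdout(idx, c(train = .7, val = .2, test = .1), seed = 1)
  plan <- plan_balancing(idx, 2000, seed = 1)
  pc <- plan$per_class
  expect_equal(pc$augmented_needed[pc$class_label == "csc"], 1899)
  expect_equal(pc$augmented_needed[pc$class_label == "dr"], 491)
  expect_equal(plan$subset_targets, c(train = 1400L, val = 400L, test = 200L))
  # row identity: real + augmented = target for every class
  expect_equal(pc$real_count + pc$augmented_needed, rep(2000, 2))
})

test_that("classes at or above target need no augmentation; empty classes error", {
  idx <- fake_index(c(big = 2500, ok = 10))
  idx$subset <- "train"
  plan <- plan_balancing(idx, 2000, ratios = c(train = 1), seed = 1)
  expect_equal(plan$per_class$augmented_needed[plan$per_class$class_label == "big"], 0)
  idx2 <- fake_index(c(a = 5))
  idx2$subset <- "train"
  idx2$class_label[1:5] <- "a"
  # a class present in labels but with zero real rows
  idx3 <- rbind(idx2, data.frame(image_id = "b/x.png", path = "/b/x.png",
                                 class_label = "b", origin = "augmented",
                                 parent_id = "a/im0001.png", subset = "train"))
  expect_error(plan_balancing(idx3, 10, ratios = c(train = 1)), "no real images")
})

test_that("round-robin parent assignment spreads copies evenly", {
  idx <- fake_index(c(a = 3))
  idx$subset <- "train"
  plan <- plan_balancing(idx, 10, ratios = c(train = 1), seed = 2)
  copies <- table(plan$aug_records$parent_id)
  expect_equal(sum(copies), 7)
  expect_lte(max(copies) - min(copies), 1)       # 3,2,2
  expect_true(all(grepl("#aug\\d+$", plan$aug_records$image_id)))
})

test_that("apply_balancing yields a leakage-clean index hitting the target", {
  idx <- fake_index(c(a = 30, b = 80))
  idx <- split_holdout(idx, c(train = .7, val = .2, test = .1), seed = 5)
  plan <- plan_balancing(idx, 100, seed = 5)
  bal <- apply_balancing(idx, plan)
  expect_equal(as.vector(table(bal$class_label)), c(100, 100))
  expect_equal(nrow(verify_no_leakage(bal)), 0)
})

test_that("a subset-moved augmented record is reported with both ids", {
  idx <- fake_index(c(a = 20))
  idx <- split_holdout(idx, c(train = .5, val = .25, test = .25), seed = 1)
  plan <- plan_balancing(idx, 40, ratios = c(train = .5, val = .25, test = .25),
                         seed = 1)
  bal <- apply_balancing(idx, plan)
  i <- which(bal$origin == "augmented")[1]
  bal$subset[i] <- setdiff(c("train", "val", "test"), bal$subset[i])[1]
  v <- verify_no_leakage(bal)
  expect_equal(nrow(v), 1)
  expect_equal(v$image_id, bal$image_id[i])
  expect_match(v$problem, bal$parent_id[i], fixed = TRUE)
})

test_that("randomized leakage fuzz: every injected violation is detected", {
  set.seed(6)
  for (rep in 1:5) {
    idx <- fake_index(c(a = 15, b = 25))
    idx <- split_holdout(idx, c(train = .6, val = .2, test = .2), seed = rep)
    plan <- plan_balancing(idx, 40, ratios = c(train = .6, val = .2, test = .2),
                           seed = rep)
    bal <- apply_balancing(idx, plan)
    aug_rows <- which(bal$origin == "augmented")
    n_bad <- sample(1:4, 1)
    bad <- sample(aug_rows, n_bad)
    for (i in bad)
      bal$subset[i] <- setdiff(c("train", "val", "test"), bal$subset[i])[1]
    v <- verify_no_leakage(bal)
    expect_setequal(v$image_id, bal$image_id[bad])
  }
})
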