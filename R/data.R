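# Image-directory ingestion, preprocessing, augmentation, split protocols
# and leakage-safe offline class balancing.
#
# Index invariant: every augmented record's subset equals its parent's
# subset, so variants of one source image can never straddle a split.

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_STD <- c(0.229, 0.224, 0.225)

#' Read an image file as an (H, W, 3) array in [0, 1]
#'
#' PNG and JPEG are supported.  Grayscale images are replicated to three
#' channels with a warning; an alpha channel is dropped.
#'
#' @param path image file path.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image file '%s'", path))
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop(sprintf("failed to decode image '%s': %s", path,
                                 conditionMessage(e))))
  a <- as.array(img)
  if (length(dim(a)) == 2L) {
    warning(sprintf("grayscale image '%s' replicated to 3 channels", path),
            call. = FALSE)
    a <- array(rep(a, 3L), c(dim(a), 3L))
  }
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 1L) {
    warning(sprintf("grayscale image '%s' replicated to 3 channels", path),
            call. = FALSE)
    a <- array(rep(a, 3L), c(dim(a)[1:2], 3L))
  }
  aperm(a, c(2, 1, 3))        # EBImage stores (x, y, c); we use (H, W, C)
}

#' Per-channel normalization with the standard constants
#'
#' `(x - mean) / std` with mean (0.485, 0.456, 0.406) and
#' std (0.229, 0.224, 0.225) per channel, after the image is in `[0, 1]`.
#'
#' @param img `(H, W, 3)` array in `[0, 1]`.
#' @export
normalize_image <- function(img) {
  for (ch in 1:3) img[, , ch] <- (img[, , ch] - IMAGENET_MEAN[ch]) / IMAGENET_STD[ch]
  img
}

#' Preprocess an image for the model
#'
#' Reads (if given a path), resizes to `size x size` pixels (bilinear,
#' aspect ratio not preserved), scales to `[0, 1]` and applies
#' [normalize_image()].
#'
#' @param image path or `(H, W, 3)` array in `[0, 1]`.
#' @param size output side length in pixels.
#' @param normalize apply the per-channel normalization.
#' @return `(size, size, 3)` array.
#' @export
preprocess_image <- function(image, size = 224L, normalize = TRUE) {
  img <- if (is.character(image)) read_image(image) else image
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an (H, W, 3) image")
  if (dim(img)[1] != size || dim(img)[2] != size)
    img <- as.array(EBImage::resize(img, w = size, h = size))
  if (normalize) img <- normalize_image(img)
  img
}

# 3-tap separable Gaussian blur with replicated edges (the light
# augmentation blur; the faithfulness baseline uses blur_baseline())
blur3 <- function(img, sigma) {
  w <- exp(-c(1, 0, 1) / (2 * sigma^2)); w <- w / sum(w)
  one <- function(m) {
    up <- m[c(1, seq_len(nrow(m) - 1)), , drop = FALSE]
    dn <- m[c(seq_len(nrow(m) - 1) + 1, nrow(m)), , drop = FALSE]
    m2 <- w[1] * up + w[2] * m + w[3] * dn
    lf <- m2[, c(1, seq_len(ncol(m2) - 1)), drop = FALSE]
    rt <- m2[, c(seq_len(ncol(m2) - 1) + 1, ncol(m2)), drop = FALSE]
    w[1] * lf + w[2] * m2 + w[3] * rt
  }
  for (ch in seq_len(dim(img)[3])) img[, , ch] <- one(img[, , ch])
  img
}

#' Stochastic training augmentation
#'
#' Composition of random horizontal flip (p = 0.5), vertical flip
#' (p = 0.5), color jitter (brightness, contrast and saturation factors
#' drawn from `1 +- jitter`) and a light Gaussian blur (3x3 kernel, sigma
#' uniform in `sigma_range`).  Reproducible per seed; output stays in
#' `[0, 1]` and keeps its shape.
#'
#' @param img `(H, W, 3)` array in `[0, 1]`.
#' @param seed RNG seed.
#' @param jitter color-jitter half-width.
#' @param sigma_range blur sigma range.
#' @export
augment_image <- function(img, seed, jitter = 0.2, sigma_range = c(0.1, 2.0)) {
  withr::with_seed(as.integer(seed), {
    if (stats::runif(1) < 0.5) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
    if (stats::runif(1) < 0.5) img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
    img <- img * stats::runif(1, 1 - jitter, 1 + jitter)          # brightness
    m <- mean(img)
    img <- (img - m) * stats::runif(1, 1 - jitter, 1 + jitter) + m # contrast
    gray <- array(rep((img[, , 1] + img[, , 2] + img[, , 3]) / 3, 3), dim(img))
    img <- gray + (img - gray) * stats::runif(1, 1 - jitter, 1 + jitter)
    img <- blur3(img, stats::runif(1, sigma_range[1], sigma_range[2]))
  })
  pmin(pmax(img, 0), 1)
}

#' Index a class-per-subdirectory image tree
#'
#' Scans `root/<class>/<image>` for PNG/JPEG files and builds the dataset
#' index: one record per image with `image_id` (the relative path),
#' `path`, `class_label`, `origin` (`"real"`), `parent_id` (`NA` for real
#' images) and `subset` (`"unassigned"`).
#'
#' @param root dataset root directory.
#' @return a `data.frame` index.
#' @export
dataset_index <- function(root) {
  if (!dir.exists(root)) stop(sprintf("dataset root '%s' does not exist", root))
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) stop("no class subdirectories found")
  recs <- lapply(classes, function(cl) {
    files <- sort(list.files(file.path(root, cl),
                             pattern = "\\.(png|jpe?g)$", ignore.case = TRUE))
    if (length(files) == 0) return(NULL)
    data.frame(image_id = file.path(cl, files),
               path = file.path(root, cl, files),
               class_label = cl, origin = "real", parent_id = NA_character_,
               subset = "unassigned")
  })
  do.call(rbind, recs)
}

# largest-remainder apportionment of n into parts proportional to ratios
apportion <- function(n, ratios) {
  raw <- n * ratios / sum(ratios)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Assign train/validation/test subsets by stratified holdout
#'
#' Splits real images per class into the named ratios (largest-remainder
#' apportionment) under a seeded shuffle.
#'
#' @param index a [dataset_index()] (real images only).
#' @param ratios named numeric vector summing to 1, e.g.
#'   `c(train = .8, val = .1, test = .1)`.
#' @param seed RNG seed.
#' @return the index with `subset` filled in.
#' @export
split_holdout <- function(index, ratios = c(train = 0.8, val = 0.1, test = 0.1),
                          seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("split ratios must sum to 1")
  if (is.null(names(ratios))) stop("ratios must be named")
  if (any(index$origin != "real"))
    stop("split_holdout expects an index of real images only (split before augmenting)")
  withr::with_seed(as.integer(seed), {
    for (cl in unique(index$class_label)) {
      rows <- sample(which(index$class_label == cl))
      counts <- apportion(length(rows), ratios)
      index$subset[rows] <- rep(names(ratios), counts)
    }
  })
  index
}

#' Plan offline augmentation balancing
#'
#' For each class and subset, computes how many augmented samples are
#' needed to reach that subset's share of `target_per_class` (shares by
#' largest-remainder apportionment of the split ratios, e.g. 2000 at
#' 70:20:10 gives 1400/400/200), and assigns copies round-robin over a
#' seeded shuffle of the subset's real images.  Balancing strictly
#' follows splitting: unassigned subsets are an error, and every planned
#' copy inherits its parent's subset.
#'
#' @param index an index with subsets assigned.
#' @param target_per_class total images per class after balancing.
#' @param ratios subset shares of the target (default: observed subset
#'   proportions rounded via apportionment of the named split ratios).
#' @param seed RNG seed for the parent shuffle.
#' @return an `AugmentationPlan`: list with `per_class` (real/target/
#'   augmented totals), `per_subset` (the same per class and subset) and
#'   `aug_records` (one row per planned copy, ids `parent#augN`).
#' @export
plan_balancing <- function(index, target_per_class,
                           ratios = c(train = 0.7, val = 0.2, test = 0.1),
                           seed = 1L) {
  if (any(index$subset == "unassigned"))
    stop("balancing requires subsets to be assigned first (split, then augment)")
  real <- index[index$origin == "real", , drop = FALSE]
  classes <- sort(unique(index$class_label))
  zero <- setdiff(classes, unique(real$class_label))
  if (length(zero) > 0)
    stop(sprintf("class '%s' has no real images to augment from", zero[1]))
  subset_targets <- apportion(target_per_class, ratios)
  names(subset_targets) <- names(ratios)
  per_subset <- list(); aug <- list()
  withr::with_seed(as.integer(seed), {
    for (cl in classes) for (ss in names(ratios)) {
      parents <- real$image_id[real$class_label == cl & real$subset == ss]
      r <- length(parents)
      tgt <- subset_targets[[ss]]
      need <- max(0L, tgt - r)
      per_subset[[length(per_subset) + 1L]] <-
        data.frame(class_label = cl, subset = ss, real_count = r,
                   target_count = tgt, augmented_needed = need)
      if (need > 0L) {
        if (r == 0L)
          stop(sprintf("class '%s' has no real images in subset '%s'", cl, ss))
        ord <- sample(parents)
        par <- rep(ord, length.out = need)        # round-robin copies
        copy_no <- stats::ave(seq_along(par), par, FUN = seq_along)
        aug[[length(aug) + 1L]] <-
          data.frame(image_id = sprintf("%s#aug%d", par, copy_no),
                     parent_id = par, class_label = cl, subset = ss,
                     origin = "augmented")
      }
    }
  })
  per_subset <- do.call(rbind, per_subset)
  per_class <- do.call(rbind, lapply(split(per_subset, per_subset$class_label),
    function(d) data.frame(class_label = d$class_label[1],
                           real_count = sum(d$real_count),
                           target_count = sum(d$target_count),
                           augmented_needed = sum(d$augmented_needed))))
  rownames(per_class) <- NULL
  structure(list(per_class = per_class, per_subset = per_subset,
                 aug_records = if (length(aug)) do.call(rbind, aug) else NULL,
                 target_per_class = target_per_class,
                 subset_targets = subset_targets),
            class = "augmentation_plan")
}

#' Apply an augmentation plan to an index
#'
#' Appends the planned augmented records (paths inherit the parent's
#' path; materialize with [materialize_balanced()] to write files).
#'
#' @param index the index the plan was built from.
#' @param plan an [plan_balancing()] result.
#' @export
apply_balancing <- function(index, plan) {
  if (is.null(plan$aug_records)) return(index)
  ar <- plan$aug_records
  ar$path <- index$path[match(ar$parent_id, index$image_id)]
  rbind(index, ar[, names(index)])
}

#' Write augmented images to disk
#'
#' Materializes every planned copy by augmenting its parent image
#' (seeded per copy) and writing a PNG under
#' `out_dir/<subset>/<class>/`.
#'
#' @param index index containing the parent records.
#' @param plan an [plan_balancing()] result.
#' @param out_dir output directory.
#' @param seed base seed; copy `i` uses `seed + i`.
#' @return invisible data frame of written files.
#' @export
materialize_balanced <- function(index, plan, out_dir, seed = 1L) {
  ar <- plan$aug_records
  if (is.null(ar)) return(invisible(NULL))
  written <- character(nrow(ar))
  for (i in seq_len(nrow(ar))) {
    parent <- index[index$image_id == ar$parent_id[i], ]
    img <- read_image(parent$path)
    aug <- augment_image(img, seed = seed + i)
    dir <- file.path(out_dir, ar$subset[i], ar$class_label[i])
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fn <- file.path(dir, paste0(gsub("[/#]", "_", ar$image_id[i]), ".png"))
    EBImage::writeImage(EBImage::Image(aperm(aug, c(2, 1, 3)),
                                       colormode = "Color"), fn)
    written[i] <- fn
  }
  invisible(data.frame(image_id = ar$image_id, path = written))
}

#' Check an index for split leakage
#'
#' Returns (rather than raises) the violations: augmented records whose
#' subset differs from their parent's, records with missing parents, and
#' duplicated ids.
#'
#' @param index a dataset index.
#' @return data frame of violations (zero rows when clean) with columns
#'   `image_id`, `parent_id`, `problem`.
#' @export
verify_no_leakage <- function(index) {
  v <- list()
  dup <- index$image_id[duplicated(index$image_id)]
  for (d in unique(dup))
    v[[length(v) + 1L]] <- data.frame(image_id = d, parent_id = NA_character_,
                                      problem = "duplicate image_id")
  augd <- index[index$origin == "augmented", , drop = FALSE]
  if (nrow(augd) > 0) {
    pidx <- match(augd$parent_id, index$image_id)
    for (i in seq_len(nrow(augd))) {
      if (is.na(pidx[i])) {
        v[[length(v) + 1L]] <- data.frame(image_id = augd$image_id[i],
                                          parent_id = augd$parent_id[i],
                                          problem = "missing parent")
      } else if (!identical(index$subset[pidx[i]], augd$subset[i])) {
        v[[length(v) + 1L]] <- data.frame(
          image_id = augd$image_id[i], parent_id = augd$parent_id[i],
          problem = sprintf("augmented record in subset '%s' but parent '%s' in '%s'",
                            augd$subset[i], augd$parent_id[i],
                            index$subset[pidx[i]]))
      }
    }
  }
  if (length(v) == 0)
    data.frame(image_id = character(), parent_id = character(),
               problem = character())
  else do.call(rbind, v)
}
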