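#' Generate a synthetic two-class cell-image set
#'
#' Renders microscopy-like single-cell images for two classes that mimic
#' the morphology contrast between normal lymphocytes and ALL blast
#' cells: `"Normal"` images contain a smaller, round nucleus with a
#' smooth boundary (low-harmonic radial perturbation), while `"ALL"`
#' images contain a larger nucleus with an irregular boundary
#' (high-amplitude, higher-order radial harmonics).  The nucleus is a
#' filled region defined by the radial function
#' \eqn{r(\theta) = r_0 (1 + \sum_k a_k \sin(k\theta + \phi_k))} on a
#' noisy bright background.  `separability` scales the between-class gap
#' in nucleus size and boundary irregularity: at 1 the classes are easy
#' to tell apart from two shape features; at 0 both classes are drawn
#' from the identical distribution.
#'
#' @param n_per_class Number of images per class (exact class balance).
#' @param image_size Side length of the square images (pixels),
#'   default 128.
#' @param separability Class-separation parameter in `[0, 1]`, default 1.
#' @param noise_sd Standard deviation of the Gaussian background noise,
#'   default 0.02.
#' @param seed Master seed; the output is pixel-identical for identical
#'   arguments.
#' @param split_ratio Fraction of images assigned (stratified) to the
#'   training split, default 0.85; the remainder is tagged
#'   `"preliminary_test"`.
#' @return A `"labeled_image_set"`: list with `images` (list of
#'   `H x W x 3` arrays with values in `[0, 1]`), `image_ids`, `labels`
#'   (`"ALL"`/`"Normal"`), and `split` (`"train"`/`"preliminary_test"`).
#' @examples
#' cells <- synthetic_cells(4, image_size = 48, seed = 1)
#' table(cells$labels, cells$split)
#' @export
synthetic_cells <- function(n_per_class, image_size = 128L,
                            separability = 1, noise_sd = 0.02,
                            seed = 1L, split_ratio = 0.85) {
  if (n_per_class < 0) stop("'n_per_class' must be >= 0", call. = FALSE)
  if (separability < 0 || separability > 1) {
    stop("'separability' must lie in [0, 1]", call. = FALSE)
  }
  if (split_ratio < 0 || split_ratio > 1) {
    stop("'split_ratio' must lie in [0, 1]", call. = FALSE)
  }
  n <- 2L * as.integer(n_per_class)
  labels <- rep(c("ALL", "Normal"), each = n_per_class)
  if (n == 0L) {
    return(labeled_image_set(list(), character(0L), character(0L),
                             character(0L)))
  }
  images <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      render_cell(labels[i], image_size, separability, noise_sd)
    })
  })
  split <- with_seed(seed + 1L, {
    s <- character(n)
    for (cls in c("ALL", "Normal")) {
      idx <- which(labels == cls)
      n_tr <- round(split_ratio * length(idx))
      tr <- sample(idx, n_tr)
      s[idx] <- "preliminary_test"
      s[tr] <- "train"
    }
    s
  })
  ids <- sprintf("img%05d", seq_len(n))
  labeled_image_set(images, ids, labels, split)
}

# Render one cell image: noisy bright background plus a filled nucleus
# whose boundary is r(theta) = r0 * (1 + sum_k a_k sin(k theta + phi_k)).
# The ALL class gets a larger r0 and larger, higher-order harmonics, both
# scaled by `sep`; at sep = 0 the two classes are identically distributed.
render_cell <- function(label, size, sep, noise_sd) {
  h <- as.integer(size)
  base_r0 <- 0.16 * h
  base_amp <- 0.035
  if (label == "ALL") {
    r0 <- base_r0 * (1 + 0.30 * sep) * stats::rnorm(1L, 1, 0.05)
    n_harm <- 3L + round(3 * sep)
    amp <- (base_amp + 0.10 * sep) * stats::runif(n_harm, 0.5, 1)
    kk <- sample(2:9, n_harm)
  } else {
    r0 <- base_r0 * stats::rnorm(1L, 1, 0.05)
    n_harm <- 3L
    amp <- base_amp * stats::runif(n_harm, 0.5, 1)
    kk <- sample(2:4, n_harm)
  }
  phi <- stats::runif(n_harm, 0, 2 * pi)
  cx <- h / 2 + stats::rnorm(1L, 0, 0.03 * h)
  cy <- h / 2 + stats::rnorm(1L, 0, 0.03 * h)

  xs <- matrix(seq_len(h), h, h) - cx
  ys <- matrix(seq_len(h), h, h, byrow = TRUE) - cy
  theta <- atan2(ys, xs)
  rr <- r0 * (1 + Reduce(`+`, lapply(seq_len(n_harm), function(j) {
    amp[j] * sin(kk[j] * theta + phi[j])
  })))
  mask <- sqrt(xs^2 + ys^2) <= rr

  bg <- 0.88
  shade <- stats::runif(1L, -0.04, 0.04)
  nucleus_rgb <- c(0.45, 0.32, 0.62) + shade
  img <- array(0, dim = c(h, h, 3L))
  for (ch in 1:3) {
    plane <- matrix(bg, h, h)
    plane[mask] <- nucleus_rgb[ch]
    plane <- plane + matrix(stats::rnorm(h * h, 0, noise_sd), h, h)
    img[, , ch] <- pmin(pmax(plane, 0), 1)
  }
  img
}

#' Construct a labeled image set
#'
#' The container moved through the whole pipeline: a list of `H x W x 3`
#' arrays (values in `[0, 1]`) with unique image ids, one binary label per
#' image, and a dataset-split tag.
#'
#' @param images List of numeric arrays.
#' @param image_ids Unique character ids.
#' @param labels Class labels, `"ALL"` or `"Normal"`.
#' @param split Split tags, `"train"` or `"preliminary_test"`.
#' @return An object of class `"labeled_image_set"`.
#' @export
labeled_image_set <- function(images, image_ids, labels, split) {
  if (length(images) != length(image_ids) ||
      length(images) != length(labels) ||
      length(images) != length(split)) {
    stop("images, image_ids, labels, and split must have equal length",
         call. = FALSE)
  }
  if (anyDuplicated(image_ids)) {
    stop("image ids must be unique", call. = FALSE)
  }
  check_labels(labels, "'labels'")
  structure(
    list(images = images, image_ids = as.character(image_ids),
         labels = as.character(labels), split = as.character(split)),
    class = "labeled_image_set"
  )
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat("Labeled image set:", length(x$images), "image(s)\n")
  if (length(x$images) > 0L) {
    d <- dim(x$images[[1L]])
    cat("  image shape:", paste(d, collapse = " x "), "\n")
    print(table(label = x$labels, split = x$split))
  }
  invisible(x)
}

#' Subset a labeled image set by split tag
#'
#' @param data A `"labeled_image_set"`.
#' @param split `"train"` or `"preliminary_test"`.
#' @return The subset as a `"labeled_image_set"`.
#' @export
subset_split <- function(data, split) {
  idx <- which(data$split == split)
  labeled_image_set(data$images[idx], data$image_ids[idx],
                    data$labels[idx], data$split[idx])
}

#' Shape features of the nucleus in each image
#'
#' Segments the (dark) nucleus by thresholding the grey-level image,
#' keeps the largest connected component, and measures two features used
#' to characterise the class contrast: the nucleus area fraction and the
#' boundary roughness (perimeter^2 / (4 pi area), 1 for a perfect
#' circle).  Segmentation and shape measurement use EBImage.
#'
#' @param data A `"labeled_image_set"`.
#' @param threshold Grey-level threshold separating nucleus from
#'   background, default 0.7.
#' @return A `data.frame` with columns `image_id`, `label`, `area`
#'   (fraction of image pixels), and `roughness`.
#' @export
cell_features <- function(data, threshold = 0.7) {
  stopifnot(inherits(data, "labeled_image_set"))
  feats <- t(vapply(data$images, function(img) {
    grey <- (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
    mask <- EBImage::bwlabel(grey < threshold)
    if (max(mask) == 0L) return(c(area = 0, roughness = NA_real_))
    sizes <- tabulate(mask[mask > 0L])
    biggest <- which.max(sizes)
    sh <- EBImage::computeFeatures.shape(mask)
    area_px <- sh[biggest, "s.area"]
    perim <- sh[biggest, "s.perimeter"]
    c(area = area_px / length(grey),
      roughness = perim^2 / (4 * pi * area_px))
  }, numeric(2L)))
  data.frame(image_id = data$image_ids, label = data$labels,
             area = feats[, "area"], roughness = feats[, "roughness"],
             stringsAsFactors = FALSE)
}

#' Two-feature midpoint-threshold classifier
#'
#' A deliberately simple reference classifier over the [cell_features()]
#' measurements: each feature votes `"ALL"` if the value exceeds the
#' midpoint between the two class means (computed on a training table),
#' and the image is called `"ALL"` if either feature votes `"ALL"` with
#' the larger standardised margin.  Used to quantify class separability
#' of generated data.
#'
#' @param train,test Feature tables from [cell_features()].
#' @return Character vector of predicted labels for `test`.
#' @export
threshold_classify <- function(train, test) {
  score <- function(tab, feature) {
    mu <- tapply(tab[[feature]], tab$label, mean, na.rm = TRUE)
    sdv <- stats::sd(tab[[feature]], na.rm = TRUE)
    list(mid = mean(mu[c("ALL", "Normal")]),
         sign = if (mu["ALL"] >= mu["Normal"]) 1 else -1,
         sd = if (is.na(sdv) || sdv == 0) 1 else sdv)
  }
  sa <- score(train, "area")
  sr <- score(train, "roughness")
  za <- sa$sign * (test$area - sa$mid) / sa$sd
  zr <- sr$sign * (test$roughness - sr$mid) / sr$sd
  zr[is.na(zr)] <- 0
  ifelse(za + zr > 0, "ALL", "Normal")
}
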