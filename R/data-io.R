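# Frames are (rows, cols, channels) arrays in [0, 1]; masks are
# (rows, cols) matrices in {0, 1}. EBImage stores images width-first,
# so reading and writing transpose between the two conventions.

list_image_files <- function(dir)
  sort(list.files(dir, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE))

read_frame <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  d <- dim(img)
  if (length(d) == 2L) img <- array(img, c(d, 1L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  aperm(img, c(2, 1, 3))
}

write_frame <- function(frame, path) {
  if (length(dim(frame)) == 2L) {
    img <- t(frame)
  } else {
    img <- EBImage::Image(aperm(frame, c(2, 1, 3)), colormode = "Color")
  }
  EBImage::writeImage(img, path)
  invisible(path)
}

read_mask <- function(path) {
  m <- read_frame(path)
  m <- m[, , 1L]
  mx <- max(m)
  if (mx == 0) matrix(0, nrow(m), ncol(m)) else (m >= 0.5 * mx) * 1
}

#' Index a paired image/mask dataset
#'
#' Scans the two folders of the Kvasir-SEG layout (one folder of frames,
#' one of ground-truth masks, identical filenames) and returns the
#' validated, filename-sorted pairing. Any frame without a mask, or mask
#' without a frame, raises an error naming the orphans.
#'
#' @param images_dir,masks_dir Folder paths.
#' @return An object of class `dataset_index`: a data frame with columns
#'   `name`, `image`, `mask`.
#' @export
index_dataset <- function(images_dir, masks_dir) {
  if (!dir.exists(images_dir)) stop("no such directory: ", images_dir, call. = FALSE)
  if (!dir.exists(masks_dir)) stop("no such directory: ", masks_dir, call. = FALSE)
  imgs <- list_image_files(images_dir)
  msks <- list_image_files(masks_dir)
  only_img <- setdiff(imgs, msks)
  only_msk <- setdiff(msks, imgs)
  if (length(only_img) || length(only_msk))
    stop("unpaired files — images without masks: [",
         paste(only_img, collapse = ", "), "]; masks without images: [",
         paste(only_msk, collapse = ", "), "]", call. = FALSE)
  idx <- data.frame(name = imgs,
                    image = file.path(images_dir, imgs),
                    mask = file.path(masks_dir, imgs),
                    stringsAsFactors = FALSE)
  structure(idx, class = c("dataset_index", "data.frame"),
            source_layout = "paired-folders")
}

#' Split a dataset index into train and test parts
#'
#' Draws a seeded random partition with `round(train_fraction * n)`
#' training pairs; the split is disjoint, exhaustive, and identical for
#' identical seeds. The global RNG state is left untouched.
#'
#' @param index A [index_dataset()] result.
#' @param train_fraction Fraction of pairs assigned to training,
#'   strictly between 0 and 1 (default 0.70).
#' @param seed Integer seed of the partition.
#' @return List with `train` and `test`, both `dataset_index` objects.
#' @export
split_dataset <- function(index, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(index, "dataset_index"))
  n <- nrow(index)
  if (n < 2L) stop("need at least 2 pairs to split", call. = FALSE)
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  n_train <- round(train_fraction * n)
  tr <- sort(sample.int(n, n_train))
  keep <- function(rows) {
    out <- index[rows, , drop = FALSE]
    rownames(out) <- NULL
    structure(out, class = c("dataset_index", "data.frame"),
              source_layout = attr(index, "source_layout"))
  }
  list(train = keep(tr), test = keep(setdiff(seq_len(n), tr)))
}

#' Load one frame/mask pair at the network input size
#'
#' Reads the pair, resizes the frame bilinearly and the mask with
#' nearest-neighbour interpolation (then re-binarises at half the mask
#' maximum), so the mask stays strictly binary through the resize. Pairs
#' already at the target size pass through pixel-identically.
#'
#' @param pair One row of a `dataset_index` (or a list with `image` and
#'   `mask` paths).
#' @param target_h,target_w Output size in pixels.
#' @return List with `image` (`(h, w, c)` array in `[0, 1]`) and `mask`
#'   (`(h, w)` matrix in `{0, 1}`).
#' @export
load_and_resize <- function(pair, target_h, target_w) {
  img <- tryCatch(read_frame(pair$image),
                  error = function(e) stop("cannot read frame ", pair$image,
                                           ": ", conditionMessage(e), call. = FALSE))
  msk <- tryCatch(read_mask(pair$mask),
                  error = function(e) stop("cannot read mask ", pair$mask,
                                           ": ", conditionMessage(e), call. = FALSE))
  if (nrow(img) != target_h || ncol(img) != target_w) {
    native <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
    img <- aperm(EBImage::imageData(
      EBImage::resize(native, w = target_w, h = target_h,
                      filter = "bilinear")), c(2, 1, 3))
    img <- pmin(pmax(img, 0), 1)
  }
  if (nrow(msk) != target_h || ncol(msk) != target_w) {
    m <- EBImage::imageData(EBImage::resize(EBImage::Image(t(msk)),
                                            w = target_w, h = target_h,
                                            filter = "none"))
    msk <- t(m)
    mx <- max(msk)
    msk <- if (mx == 0) matrix(0, target_h, target_w) else (msk >= 0.5 * mx) * 1
  }
  list(image = img, mask = msk)
}

# interior erosion with the 8-neighbourhood, outside the frame counting
# as background: a mask pixel is boundary iff any 3x3 neighbour is 0
mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  er <- matrix(1, h, w)
  for (di in 0:2) for (dj in 0:2)
    er <- pmin(er, pad[(1L + di):(h + di), (1L + dj):(w + dj)])
  (mask == 1) & (er == 0)
}

#' Overlay prediction and ground-truth contours on a frame
#'
#' Draws the one-pixel boundary of the predicted mask in blue and of the
#' ground-truth mask in red over the original frame, the standard visual
#' check of segmentation quality. Where the two boundaries coincide the
#' ground-truth red is drawn on top.
#'
#' @param frame `(h, w, 3)` array in `[0, 1]`.
#' @param gt_mask,pred_mask Binary `(h, w)` masks.
#' @return The annotated `(h, w, 3)` frame.
#' @export
render_overlay <- function(frame, gt_mask, pred_mask) {
  d <- dim(frame)
  if (length(d) != 3L || d[3] != 3L)
    stop("frame must be (h, w, 3)", call. = FALSE)
  if (!identical(dim(gt_mask), d[1:2]) || !identical(dim(pred_mask), d[1:2]))
    stop("masks must match the frame's spatial dimensions", call. = FALSE)
  out <- frame
  pb <- mask_boundary(pred_mask)
  gb <- mask_boundary(gt_mask)
  paint <- function(out, sel, col) {
    for (ch in 1:3) {
      pl <- out[, , ch]
      pl[sel] <- col[ch]
      out[, , ch] <- pl
    }
    out
  }
  out <- paint(out, pb, c(0, 0, 1))  # prediction: blue
  out <- paint(out, gb, c(1, 0, 0))  # ground truth: red
  out
}
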