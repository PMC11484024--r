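#' Configuration for the synthetic toy-histology generator
#'
#' Describes a seeded dataset of small RGB patches containing 1--3 irregular
#' "tissue" regions on a light background, together with ground-truth masks
#' and the multi-hot image-level labels derived from them. The generator
#' mimics the structure of patch-level lung-tissue datasets (a few texturally
#' and chromatically distinct classes, most patches containing one or two of
#' them) without any real-data download.
#'
#' @param n_images number of patches to generate.
#' @param height,width patch size in pixels (at least 32).
#' @param n_classes number of foreground tissue classes K (default 3,
#'   mimicking tumor / stroma / normal).
#' @param class_palette (K+1) x 3 integer matrix of base RGB colours, row 1 =
#'   background, rows 2..K+1 = classes 1..K. The default colours are
#'   well-separated (pairwise RGB distance >= 100) so that a small network
#'   can learn them at desk scale.
#' @param texture_noise_sd standard deviation of the additive Gaussian pixel
#'   noise, in 0..255 RGB units (default 12).
#' @param blob_count_range integer vector \code{c(min, max)}: number of tissue
#'   regions per image. \code{c(0, 0)} produces empty background-only scenes.
#' @param label_mix_probs named numeric vector of probabilities over multi-hot
#'   patterns; names are patterns like \code{"110"} (class 1 and 2 present).
#'   Must sum to 1. The default follows the label frequencies of a public
#'   lung-adenocarcinoma patch dataset, where tumor+stroma co-occurrence
#'   dominates: 110 : 0.5347, 001 : 0.1816, 010 : 0.1666, 100 : 0.1171.
#' @param seed integer seed; identical (config, seed) gives byte-identical
#'   datasets.
#' @return an object of class \code{synth_config}.
#' @export
synth_config <- function(n_images = 100L, height = 64L, width = 64L,
                         n_classes = 3L, class_palette = NULL,
                         texture_noise_sd = 12, blob_count_range = c(1L, 3L),
                         label_mix_probs = NULL, seed = 1L) {
  K <- as.integer(n_classes)
  if (K < 1L) stop("n_classes must be >= 1")
  if (height < 32L || width < 32L) stop("height and width must be >= 32")
  if (is.null(class_palette)) {
    base <- rbind(
      c(235, 235, 235),  # background: near-white, like unstained slide area
      c(60,  90, 200),   # class 1 (tumor-like): blue
      c(70, 180,  80),   # class 2 (stroma-like): green
      c(220, 180, 60),   # class 3 (normal-like): yellow
      c(170, 60, 170),   # extra classes, if requested
      c(60, 180, 190))
    if (K + 1L > nrow(base)) stop("default palette supports at most 5 classes")
    class_palette <- base[seq_len(K + 1L), , drop = FALSE]
  }
  class_palette <- as.matrix(class_palette)
  if (nrow(class_palette) != K + 1L || ncol(class_palette) != 3L)
    stop("class_palette must be a (n_classes + 1) x 3 matrix")
  if (is.null(label_mix_probs)) {
    if (K == 3L) {
      # observed pattern counts 5393 / 1832 / 1680 / 1181 among 10086
      label_mix_probs <- c(`110` = 5393, `001` = 1832,
                           `010` = 1680, `100` = 1181) / 10086
    } else {
      pats <- diag(1L, K)
      nm <- apply(pats, 1L, paste0, collapse = "")
      label_mix_probs <- stats::setNames(rep(1 / K, K), nm)
    }
  }
  if (abs(sum(label_mix_probs) - 1) > 1e-9)
    stop("label_mix_probs must sum to 1")
  if (is.null(names(label_mix_probs)) ||
      any(nchar(names(label_mix_probs)) != K) ||
      any(!grepl("^[01]+$", names(label_mix_probs))))
    stop("label_mix_probs names must be K-character 0/1 pattern strings")
  structure(list(n_images = as.integer(n_images), height = as.integer(height),
                 width = as.integer(width), n_classes = K,
                 class_palette = class_palette,
                 texture_noise_sd = texture_noise_sd,
                 blob_count_range = as.integer(blob_count_range),
                 label_mix_probs = label_mix_probs, seed = as.integer(seed)),
            class = "synth_config")
}

#' Read a synthetic-data configuration from a YAML file
#'
#' Keys mirror the arguments of [synth_config()]; \code{class_palette} may be
#' given as a list of 3-element RGB vectors and \code{label_mix_probs} as a
#' pattern -> probability mapping.
#'
#' @param path YAML file path.
#' @return a \code{synth_config}.
#' @export
synth_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$class_palette))
    y$class_palette <- do.call(rbind, y$class_palette)
  if (!is.null(y$label_mix_probs))
    y$label_mix_probs <- unlist(y$label_mix_probs)
  do.call(synth_config, y)
}

# one irregular region: radial bump modulated by a smoothed random field,
# thresholded at a quantile so the area is controlled but the boundary is not
# a circle (dense-CRF refinement is only exercised by irregular edges).
synth_blob_mask <- function(H, W) {
  cy <- stats::runif(1, 0.2 * H, 0.8 * H)
  cx <- stats::runif(1, 0.2 * W, 0.8 * W)
  radius <- stats::runif(1, 0.14, 0.26) * min(H, W)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  bump <- exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * radius^2))
  g <- matrix(stats::rnorm(49), 7, 7)
  gs <- nn_resize_bilinear(array(g, c(7, 7, 1)), H, W)[, , 1]
  score <- bump + 0.30 * gs
  frac <- stats::runif(1, 0.05, 0.16)
  score > stats::quantile(score, 1 - frac)
}

#' Generate a seeded synthetic toy-histology dataset
#'
#' Each patch is a background-coloured canvas on which irregular blobs are
#' painted with per-class base colours; Gaussian texture noise is added and
#' the image quantised to 8-bit RGB. The ground-truth mask records the
#' painted class id per pixel (0 = background) and the multi-hot image label
#' is derived from the mask, so label consistency holds by construction:
#' \code{label[k] == 1} iff class k covers at least one pixel.
#'
#' @param config a [synth_config()].
#' @return list of patches of class \code{camseg_dataset}; each patch is a
#'   list with \code{image} (H x W x 3 integer array, 0..255), \code{label}
#'   (0/1 integer vector of length K) and \code{gt_mask} (H x W integer
#'   matrix over 0..K).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  K <- config$n_classes; H <- config$height; W <- config$width
  pal <- config$class_palette
  pats <- names(config$label_mix_probs)
  with_seed(config$seed, {
    patches <- vector("list", config$n_images)
    for (n in seq_len(config$n_images)) {
      mask <- matrix(0L, H, W)
      bmax <- config$blob_count_range[2]
      if (bmax > 0L) {
        pat <- pats[sample.int(length(pats), 1L,
                               prob = config$label_mix_probs)]
        present <- which(strsplit(pat, "")[[1]] == "1")
        nb <- sample(seq(config$blob_count_range[1], bmax), 1L)
        nb <- max(nb, length(present))
        cls <- c(present,
                 present[sample.int(length(present), max(0L, nb - length(present)),
                                    replace = TRUE)])
        for (b in seq_len(nb)) {
          region <- synth_blob_mask(H, W)
          mask[region] <- cls[b]
        }
        # late blobs can fully overwrite an earlier class; repaint a small
        # guaranteed disc so the sampled pattern is realised exactly
        for (k in present) {
          if (!any(mask == k)) {
            cy <- stats::runif(1, 6, H - 5); cx <- stats::runif(1, 6, W - 5)
            yy <- matrix(seq_len(H), H, W)
            xx <- matrix(seq_len(W), H, W, byrow = TRUE)
            mask[(yy - cy)^2 + (xx - cx)^2 <= 16] <- k
          }
        }
      }
      img <- array(0, c(H, W, 3))
      for (ch in 1:3) img[, , ch] <- matrix(pal[mask + 1L, ch], H, W)
      img <- img + stats::rnorm(length(img), sd = config$texture_noise_sd)
      img <- array(as.integer(round(pmin(pmax(img, 0), 255))), c(H, W, 3))
      label <- vapply(seq_len(K), function(k) as.integer(any(mask == k)),
                      integer(1))
      patches[[n]] <- list(image = img, label = label, gt_mask = mask)
    }
    structure(patches, class = "camseg_dataset", n_classes = K)
  })
}

#' Write a dataset to disk as PNGs plus a CSV manifest
#'
#' Images are written as RGB PNG, masks as 8-bit grayscale PNG holding the
#' raw label values (0..K and 255), and the manifest lists one row per image
#' with the file names and the K binary label columns, in the dialect read
#' back by [read_dataset()].
#'
#' @param patches a \code{camseg_dataset} (or plain list of patches).
#' @param out_dir output directory (created if missing).
#' @return the manifest path, invisibly usable by [read_dataset()].
#' @export
write_dataset <- function(patches, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  K <- length(patches[[1]]$label)
  rows <- vector("list", length(patches))
  for (n in seq_along(patches)) {
    p <- patches[[n]]
    img_file <- sprintf("img_%04d.png", n)
    png::writePNG(p$image / 255, file.path(out_dir, img_file))
    mask_file <- NA_character_
    if (!is.null(p$gt_mask)) {
      mask_file <- sprintf("mask_%04d.png", n)
      write_mask(p$gt_mask, file.path(out_dir, mask_file))
    }
    rows[[n]] <- data.frame(filename = img_file, mask = mask_file,
                            t(stats::setNames(p$label,
                                              paste0("label_", seq_len(K)))))
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  path
}

#' Read a dataset written by [write_dataset()]
#'
#' @param manifest path to a \code{manifest.csv} (or the directory holding it).
#' @return a \code{camseg_dataset} list of patches.
#' @export
read_dataset <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.csv")
  man <- utils::read.csv(manifest)
  dir <- dirname(manifest)
  lab_cols <- grep("^label_", names(man), value = TRUE)
  K <- length(lab_cols)
  patches <- vector("list", nrow(man))
  for (n in seq_len(nrow(man))) {
    img <- png::readPNG(file.path(dir, man$filename[n]))
    img <- array(as.integer(round(img * 255)), dim(img))
    gt <- NULL
    if (!is.null(man$mask) && !is.na(man$mask[n]))
      gt <- read_mask(file.path(dir, man$mask[n]))
    patches[[n]] <- list(image = img,
                         label = as.integer(unlist(man[n, lab_cols])),
                         gt_mask = gt)
  }
  structure(patches, class = "camseg_dataset", n_classes = K)
}
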