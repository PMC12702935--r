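# ---------------------------------------------------------------------------
# Synthetic multi-organ phantoms: each image is one background region plus
# 3-8 "organ" regions of differing size, intensity and boundary smoothness,
# with additive Gaussian noise -- the statistical shape of multi-organ CT /
# cardiac MRI slices, with known ground truth and no download.
# ---------------------------------------------------------------------------

#' Phantom generator specification
#'
#' @param image_size square image side in pixels
#' @param n_organs number of foreground organ classes (3-8)
#' @param organ_axis_frac range of organ semi-axis lengths as a fraction of
#'   the image side
#' @param organ_intensity range of mean organ intensities; organ `k` gets an
#'   evenly spaced mean inside it, so classes are distinguishable by
#'   intensity
#' @param organ_texture_sd within-organ intensity standard deviation
#' @param background_intensity mean background intensity
#' @param noise_sd additive Gaussian pixel noise standard deviation
#' @param boundary `"smooth"` for exact ellipses or `"perturbed"` (default)
#'   for radially modulated ellipses with rougher boundaries
#' @param boundary_amp relative amplitude of the radial modulation
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(image_size = 64L,
                         n_organs = 4L,
                         organ_axis_frac = c(0.10, 0.22),
                         organ_intensity = c(0.35, 0.95),
                         organ_texture_sd = 0.02,
                         background_intensity = 0.12,
                         noise_sd = 0.02,
                         boundary = c("perturbed", "smooth"),
                         boundary_amp = 0.15) {
  boundary <- match.arg(boundary)
  if (n_organs < 3L || n_organs > 8L) stop("n_organs must be in 3..8")
  if (any(organ_axis_frac <= 0) || organ_axis_frac[1] > organ_axis_frac[2]) {
    stop("organ_axis_frac must be an increasing positive range")
  }
  structure(list(image_size = as.integer(image_size),
                 n_organs = as.integer(n_organs),
                 n_classes = as.integer(n_organs) + 1L,
                 organ_axis_frac = organ_axis_frac,
                 organ_intensity = organ_intensity,
                 organ_texture_sd = organ_texture_sd,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd,
                 boundary = boundary,
                 boundary_amp = boundary_amp),
            class = "phantom_spec")
}

# Run fn with a private, seeded RNG stream; the caller's stream is restored.
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Generate one phantom image and its label map
#'
#' Organs are drawn in class order as (optionally radially perturbed)
#' ellipses at random centres, sizes and orientations; later organs
#' overwrite earlier ones, and a draw in which any organ class ends up
#' fully occluded is retried (up to 100 attempts).  The image is the
#' per-class intensity plus within-organ texture and global Gaussian noise,
#' clamped to `[0, 1]`.  Output is deterministic per `(spec, seed)`.
#'
#' @param spec a [phantom_spec()]
#' @param seed integer seed for this phantom
#' @return list with `image` (matrix in `[0, 1]`) and `label` (integer
#'   matrix with values `0..n_organs`)
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed, function() {
    S <- spec$image_size
    k <- spec$n_organs
    means <- seq(spec$organ_intensity[1], spec$organ_intensity[2],
                 length.out = k)
    xs <- matrix(rep(seq_len(S), each = S), S, S)   # column coordinate
    ys <- matrix(rep(seq_len(S), times = S), S, S)  # row coordinate
    for (attempt in seq_len(100L)) {
      label <- matrix(0L, S, S)
      for (org in seq_len(k)) {
        ax <- stats::runif(2, spec$organ_axis_frac[1],
                           spec$organ_axis_frac[2]) * S
        margin <- max(ax) * (1 + spec$boundary_amp)
        if (1 + margin >= S - margin) {
          stop("phantom generation failed: organ axes too large for the image")
        }
        cx <- stats::runif(1, 1 + margin, S - margin)
        cy <- stats::runif(1, 1 + margin, S - margin)
        th <- stats::runif(1, 0, pi)
        dx <- xs - cx; dy <- ys - cy
        u <- (cos(th) * dx + sin(th) * dy) / ax[1]
        v <- (-sin(th) * dx + cos(th) * dy) / ax[2]
        r <- sqrt(u * u + v * v)
        rad <- 1
        if (spec$boundary == "perturbed") {
          ang <- atan2(v, u)
          coef <- stats::runif(3, -1, 1)
          phase <- stats::runif(3, 0, 2 * pi)
          mod <- coef[1] * cos(2 * ang + phase[1]) +
            coef[2] * cos(3 * ang + phase[2]) +
            coef[3] * cos(4 * ang + phase[3])
          rad <- 1 + spec$boundary_amp * mod / 3
        }
        label[r <= rad] <- org
      }
      if (length(unique(as.vector(label))) == k + 1L) break
      if (attempt == 100L) {
        stop("phantom generation failed: an organ class could not be placed")
      }
    }
    image <- matrix(spec$background_intensity, S, S)
    for (org in seq_len(k)) {
      inside <- label == org
      image[inside] <- means[org] +
        stats::rnorm(sum(inside), 0, spec$organ_texture_sd)
    }
    if (spec$noise_sd > 0) {
      image <- image + matrix(stats::rnorm(S * S, 0, spec$noise_sd), S, S)
    }
    image <- pmin(pmax(image, 0), 1)
    list(image = image, label = label)
  })
}

#' Augmentation specification
#'
#' Horizontal and vertical flips each with probability 0.5 and a rotation
#' drawn uniformly from a symmetric degree range.
#'
#' @param p_hflip,p_vflip flip probabilities
#' @param rotation_deg symmetric rotation range in degrees
#' @export
augment_spec <- function(p_hflip = 0.5, p_vflip = 0.5,
                         rotation_deg = c(-10, 10)) {
  if (any(c(p_hflip, p_vflip) < 0) || any(c(p_hflip, p_vflip) > 1)) {
    stop("flip probabilities must lie in [0, 1]")
  }
  if (abs(rotation_deg[1] + rotation_deg[2]) > 1e-9) {
    stop("rotation range must be symmetric about zero")
  }
  structure(list(p_hflip = p_hflip, p_vflip = p_vflip,
                 rotation_deg = rotation_deg),
            class = "augment_spec")
}

# Rotate about the image centre; bilinear for intensities, nearest for
# labels; zero / background padding outside the source support.
rotate_pair <- function(image, label, angle_deg) {
  S <- nrow(image)
  th <- angle_deg * pi / 180
  cx <- (S + 1) / 2
  xs <- matrix(rep(seq_len(S), each = S), S, S) - cx
  ys <- matrix(rep(seq_len(S), times = S), S, S) - cx
  sx <- cos(th) * xs + sin(th) * ys + cx
  sy <- -sin(th) * xs + cos(th) * ys + cx
  # bilinear sample of image
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  at <- function(r, c) {
    ok <- r >= 1 & r <= S & c >= 1 & c <= S
    v <- matrix(0, S, S)
    v[ok] <- image[cbind(r[ok], c[ok])]
    v
  }
  img <- (1 - fy) * (1 - fx) * at(y0, x0) +
    (1 - fy) * fx * at(y0, x0 + 1) +
    fy * (1 - fx) * at(y0 + 1, x0) +
    fy * fx * at(y0 + 1, x0 + 1)
  # nearest-neighbour sample of label
  rn <- round(sy); cn <- round(sx)
  ok <- rn >= 1 & rn <= S & cn >= 1 & cn <= S
  lab <- matrix(0L, S, S)
  lab[ok] <- label[cbind(rn[ok], cn[ok])]
  list(image = img, label = lab)
}

#' Apply the augmentation pipeline to one image/label pair
#'
#' The same geometric transform is applied to both: flips drawn
#' independently at their probabilities and a rotation drawn uniformly from
#' the configured range, bilinear for the image and nearest-neighbour for
#' the label (which therefore can never invent a class).
#'
#' @param image intensity matrix
#' @param label integer label matrix
#' @param spec an [augment_spec()]
#' @param seed integer seed for this draw
#' @return list with transformed `image` and `label`
#' @export
augment <- function(image, label, spec = augment_spec(), seed = 1L) {
  stopifnot(inherits(spec, "augment_spec"))
  if (!identical(dim(image), dim(label))) stop("paired shapes must match")
  with_seed(seed, function() {
    if (stats::runif(1) < spec$p_hflip) {
      image <- image[, rev(seq_len(ncol(image)))]
      label <- label[, rev(seq_len(ncol(label)))]
    }
    if (stats::runif(1) < spec$p_vflip) {
      image <- image[rev(seq_len(nrow(image))), ]
      label <- label[rev(seq_len(nrow(label))), ]
    }
    ang <- stats::runif(1, spec$rotation_deg[1], spec$rotation_deg[2])
    if (abs(ang) > 1e-12) {
      out <- rotate_pair(image, label, ang)
    } else {
      out <- list(image = image, label = label)
    }
    out
  })
}

# Per-item seed derived from a master seed by counter, so item i is
# reproducible independently of how many items are generated.
item_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %%
               (.Machine$integer.max - 1)) + 1L
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` image/label pairs as 8-bit PNG files plus an RDS bundle with
#' the exact double-precision arrays, and a JSON manifest recording files,
#' spec, seed and the train/val/test split (floor rule: `floor(f_train n)`
#' and `floor(f_val n)`, remainder to test).  Re-running with the same
#' arguments reproduces identical data.
#'
#' @param n number of phantoms
#' @param spec a [phantom_spec()]
#' @param seed master seed; per-item seeds are derived by counter
#' @param out_dir output directory (created if needed)
#' @param split named fractions for train/val/test
#' @return the manifest, invisibly (also written to `manifest.json`)
#' @export
make_dataset <- function(n, spec = phantom_spec(), seed = 1L,
                         out_dir, split = c(train = 0.7, val = 0.1,
                                            test = 0.2)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_train <- floor(split[["train"]] * n)
  n_val <- floor(split[["val"]] * n)
  assignment <- c(rep("train", n_train), rep("val", n_val),
                  rep("test", n - n_train - n_val))
  items <- vector("list", n)
  arrays <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(spec, item_seed(seed, i))
    img_file <- sprintf("img_%04d.png", i)
    lab_file <- sprintf("lab_%04d.png", i)
    png::writePNG(ph$image, file.path(out_dir, img_file))
    png::writePNG(ph$label / 255, file.path(out_dir, lab_file))
    items[[i]] <- list(id = sprintf("case_%04d", i), image = img_file,
                       label = lab_file, split = assignment[i],
                       seed = item_seed(seed, i))
    arrays[[i]] <- ph
  }
  saveRDS(arrays, file.path(out_dir, "bundle.rds"))
  manifest <- list(n = n, seed = seed, spec = unclass(spec),
                   split_rule = "floor(f_train*n), floor(f_val*n), remainder to test",
                   split_fractions = as.list(split),
                   bundle = "bundle.rds", items = items)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a dataset written by [make_dataset()]
#'
#' @param dir dataset directory
#' @param split optional split name to filter (`"train"`, `"val"`, `"test"`)
#' @param exact use the RDS bundle (exact arrays) rather than the 8-bit PNGs
#' @return list with `images` (list of matrices), `labels` (list of integer
#'   matrices), `ids`, and the `manifest`
#' @export
read_dataset <- function(dir, split = NULL, exact = TRUE) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  keep <- seq_along(manifest$items)
  if (!is.null(split)) {
    keep <- keep[vapply(manifest$items, function(it) it$split, "") == split]
  }
  if (exact && file.exists(file.path(dir, manifest$bundle))) {
    arrays <- readRDS(file.path(dir, manifest$bundle))
    images <- lapply(arrays[keep], `[[`, "image")
    labels <- lapply(arrays[keep], `[[`, "label")
  } else {
    images <- lapply(keep, function(i) {
      png::readPNG(file.path(dir, manifest$items[[i]]$image))
    })
    labels <- lapply(keep, function(i) {
      m <- png::readPNG(file.path(dir, manifest$items[[i]]$label))
      matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
    })
  }
  list(images = images, labels = labels,
       ids = vapply(manifest$items[keep], function(it) it$id, ""),
       manifest = manifest)
}

#' Threshold segmenter that inverts the noiseless phantom rendering
#'
#' Assigns each pixel the class whose rendered mean intensity is nearest.
#' On noiseless phantoms with distinct class intensities this recovers the
#' label map exactly, which validates the generator/metric plumbing end to
#' end.
#'
#' @param image intensity matrix
#' @param spec the [phantom_spec()] used to render it
#' @return integer label matrix
#' @export
oracle_segmenter <- function(image, spec) {
  means <- c(spec$background_intensity,
             seq(spec$organ_intensity[1], spec$organ_intensity[2],
                 length.out = spec$n_organs))
  idx <- apply(abs(outer(as.vector(image), means, "-")), 1L, which.min)
  matrix(as.integer(idx - 1L), nrow(image), ncol(image))
}
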