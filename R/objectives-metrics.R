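# ---------------------------------------------------------------------------
# Training objective (cross-entropy + soft Dice, halved sum) and evaluation
# metrics (Dice similarity coefficient, Hausdorff distance) with per-class
# reporting.
# ---------------------------------------------------------------------------

as_probmap <- function(p) {
  d <- dim(p)
  if (is.null(d) || length(d) < 3L) stop("probability map must be (H,W,M[,N])")
  if (length(d) == 3L) dim(p) <- c(d, 1L)
  p
}

as_labelmap <- function(y) {
  d <- dim(y)
  if (is.null(d)) stop("label map must be (H,W[,N])")
  if (length(d) == 2L) dim(y) <- c(d, 1L)
  y
}

#' Pixel-wise cross-entropy loss
#'
#' Mean over all pixels of `-log p` at the true class.
#'
#' @param p probability array `(H, W, M, N)` (or `(H, W, M)`), per-pixel
#'   softmax-normalised
#' @param y integer label array `(H, W, N)` (or `(H, W)`) with values in
#'   `[0, M)`
#' @param clamp lower clamp on probabilities before the log
#' @return non-negative scalar
#' @examples
#' p <- array(0.25, c(2, 2, 4))        # uniform over 4 classes
#' y <- array(0L, c(2, 2))
#' cross_entropy_loss(p, y)            # log(4)
#' @export
cross_entropy_loss <- function(p, y, clamp = 1e-12) {
  p <- as_probmap(p); y <- as_labelmap(y)
  d <- dim(p); M <- d[3]
  if (any(y < 0) || any(y >= M)) {
    stop(sprintf("label values must lie in [0, %d)", M))
  }
  P <- d[1] * d[2]; N <- d[4]
  pm <- array(p, c(P, M, N))
  s <- 0
  for (n in seq_len(N)) {
    idx <- cbind(seq_len(P), as.vector(y[, , n]) + 1L, n)
    s <- s - sum(log(pmax(pm[idx], clamp)))
  }
  s / (P * N)
}

#' Per-class soft Dice coefficients
#'
#' For class `c`: `(2 * sum(p_c * y_c) + eps) / (sum(p_c) + sum(y_c) + eps)`
#' with sums over all pixels (and batch elements).
#'
#' @inheritParams cross_entropy_loss
#' @param eps smoothing added to numerator and denominator
#' @return numeric vector of length `M` (classes in label order `0..M-1`)
#' @export
soft_dice_per_class <- function(p, y, eps = 1e-5) {
  p <- as_probmap(p); y <- as_labelmap(y)
  d <- dim(p); M <- d[3]; P <- d[1] * d[2]; N <- d[4]
  pm <- array(p, c(P, M, N))
  out <- numeric(M)
  for (c in seq_len(M)) {
    I <- 0; PS <- 0; YS <- 0
    for (n in seq_len(N)) {
      yc <- as.vector(y[, , n]) == (c - 1L)
      pc <- pm[, c, n]
      I <- I + sum(pc[yc]); PS <- PS + sum(pc); YS <- YS + sum(yc)
    }
    out[c] <- (2 * I + eps) / (PS + YS + eps)
  }
  out
}

#' Soft Dice loss
#'
#' `1 - soft Dice`, averaged over the selected classes (all classes
#' including background by default).  Zero for a perfect hard prediction
#' (up to the smoothing term), approaching one for disjoint masks.
#'
#' @inheritParams soft_dice_per_class
#' @param classes integer vector of class labels (`0`-based) to average
#'   over; `NULL` means all classes
#' @return scalar in `[0, 1]`
#' @export
dice_loss <- function(p, y, classes = NULL, eps = 1e-5) {
  dc <- soft_dice_per_class(p, y, eps)
  sel <- if (is.null(classes)) seq_along(dc) else classes + 1L
  mean(1 - dc[sel])
}

#' Combined segmentation loss
#'
#' `(L_CE + L_Dice) / 2`.
#'
#' @inheritParams dice_loss
#' @return non-negative scalar
#' @export
total_loss <- function(p, y, classes = NULL, eps = 1e-5) {
  (cross_entropy_loss(p, y) + dice_loss(p, y, classes, eps)) / 2
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`.  Two empty masks agree perfectly and
#' score 1; one empty mask against a non-empty one scores 0.
#'
#' @param a,b logical (or 0/1) arrays of identical shape
#' @return scalar in `[0, 1]`
#' @export
dsc_metric <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes must match")
  a <- as.logical(a); b <- as.logical(b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Boundary pixels of a binary mask
#'
#' A foreground pixel is a boundary pixel if any of its 8 neighbours (or
#' the image border) is background.
#'
#' @param mask logical matrix
#' @return logical matrix marking boundary pixels
#' @export
mask_boundary <- function(mask) {
  mask <- mask > 0
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  interior <- matrix(TRUE, H, W)
  for (dh in -1:1) for (dw in -1:1) {
    if (dh == 0 && dw == 0) next
    interior <- interior & pad[2:(H + 1L) + dh, 2:(W + 1L) + dw]
  }
  mask & !interior
}

as_points <- function(x) {
  if (is.matrix(x) && !is.logical(x) && ncol(x) == 2L) return(x)
  if (is.logical(x) || all(x %in% c(0, 1))) {
    return(which(matrix(as.logical(x), nrow(x), ncol(x)), arr.ind = TRUE))
  }
  stop("point set must be an n x 2 coordinate matrix or a binary mask")
}

#' Hausdorff distance between two point sets
#'
#' The maximum over both directions of the maximum-over-one-set of the
#' minimum Euclidean distance to the other set.  Symmetric; zero iff the
#' sets are equal.  Inputs may be `n x 2` coordinate matrices or binary
#' masks (whose foreground pixel coordinates are used).
#'
#' @param a,b point sets
#' @return non-negative scalar, in pixel units for mask input
#' @export
hausdorff <- function(a, b) {
  A <- as_points(a); B <- as_points(b)
  if (nrow(A) == 0L || nrow(B) == 0L) {
    stop("Hausdorff distance is undefined for an empty point set")
  }
  D <- sqrt(outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2)
  max(max(apply(D, 1L, min)), max(apply(D, 2L, min)))
}

#' Per-class segmentation metrics for one case
#'
#' Scores each class's binary mask by Dice coefficient and boundary
#' Hausdorff distance.  Interior points never attain the max-min, so the
#' boundary and the full foreground set give the same HD; boundary
#' extraction just bounds the cost.  Means are taken over foreground
#' classes; classes whose HD is undefined (an empty mask on either side)
#' are excluded from the HD mean and counted.
#'
#' @param pred,ref integer label matrices `(H, W)` with values in `[0, M)`
#' @param n_classes number of classes `M`; inferred from the data if `NULL`
#' @return object of class `metric_report`: a list with `per_class` (data
#'   frame: class, dsc, hd, hd_defined), `mean_dsc`, `mean_hd` and
#'   `n_hd_undefined`, means over foreground classes
#' @export
evaluate_case <- function(pred, ref, n_classes = NULL) {
  if (!identical(dim(pred), dim(ref))) stop("label map shapes must match")
  M <- n_classes %||% (max(pred, ref) + 1L)
  cls <- seq_len(M) - 1L
  dsc <- numeric(M); hd <- rep(NA_real_, M); def <- logical(M)
  for (i in seq_len(M)) {
    pa <- pred == cls[i]; ra <- ref == cls[i]
    dsc[i] <- dsc_metric(pa, ra)
    if (any(pa) && any(ra)) {
      hd[i] <- hausdorff(mask_boundary(pa), mask_boundary(ra))
      def[i] <- TRUE
    }
  }
  fg <- seq_len(M)[-1]
  hd_fg <- hd[fg][def[fg]]
  structure(list(
    per_class = data.frame(class = cls, dsc = dsc, hd = hd,
                           hd_defined = def),
    mean_dsc = mean(dsc[fg]),
    mean_hd = if (length(hd_fg)) mean(hd_fg) else NA_real_,
    n_hd_undefined = sum(!def[fg])
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report: mean foreground DSC %.4f, mean HD %s (%d undefined)\n",
              x$mean_dsc,
              if (is.na(x$mean_hd)) "NA" else sprintf("%.3f", x$mean_hd),
              x$n_hd_undefined))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Write a set of case reports as CSV (one row per case and class)
#' @param reports named list of `metric_report` objects (names = case ids)
#' @param path output CSV file
#' @export
reports_to_csv <- function(reports, path) {
  rows <- do.call(rbind, lapply(names(reports), function(id) {
    df <- reports[[id]]$per_class
    cbind(case_id = id, df)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write summary metrics as JSON
#' @param reports named list of `metric_report` objects
#' @param path output JSON file
#' @export
reports_to_json <- function(reports, path) {
  mean_dsc <- mean(vapply(reports, function(r) r$mean_dsc, numeric(1)))
  hds <- vapply(reports, function(r) r$mean_hd, numeric(1))
  out <- list(
    n_cases = length(reports),
    mean_dsc = mean_dsc,
    mean_hd = if (all(is.na(hds))) NA else mean(hds, na.rm = TRUE),
    cases = lapply(reports, function(r) {
      list(mean_dsc = r$mean_dsc, mean_hd = r$mean_hd,
           n_hd_undefined = r$n_hd_undefined)
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
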