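# ---------------------------------------------------------------------------
# SGD training loop with momentum and weight decay, batched evaluation.
# ---------------------------------------------------------------------------

sgd_step <- function(params, lr, momentum = 0.9, weight_decay = 1e-4) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad + weight_decay * p$value
    v <- if (is.null(p$momentum)) g else momentum * p$momentum + g
    p$momentum <- v
    p$value <- p$value - lr * v
  }
  invisible(params)
}

# Stack a list of (H,W) matrices into an (H,W,C,N) array with C channels
# (the grayscale phantom is replicated across input channels).
stack_images <- function(images, in_channels = 3L) {
  S <- nrow(images[[1]])
  N <- length(images)
  x <- array(0, c(S, S, in_channels, N))
  for (n in seq_len(N)) {
    for (c in seq_len(in_channels)) x[, , c, n] <- images[[n]]
  }
  x
}

stack_labels <- function(labels) {
  S <- nrow(labels[[1]])
  N <- length(labels)
  y <- array(0L, c(S, S, N))
  for (n in seq_len(N)) y[, , n] <- labels[[n]]
  y
}

#' Train a model with SGD
#'
#' Minimises the combined cross-entropy + soft Dice objective with
#' stochastic gradient descent (momentum 0.9, learning rate 0.01, weight
#' decay 1e-4 by default).  One epoch is one shuffled pass over the
#' training pairs; `max_steps` optionally caps the total step count.
#' Augmentation, when given, is applied on the fly with per-step derived
#' seeds, so a run is fully reproducible from `(config, seed)`.
#'
#' @param model an `hs_model`
#' @param images list of intensity matrices
#' @param labels list of integer label matrices
#' @param epochs number of passes over the data
#' @param batch_size images per step
#' @param lr,momentum,weight_decay SGD hyperparameters
#' @param schedule `"constant"` (default) or `"poly"`
#'   (`lr * (1 - step/total)^0.9`)
#' @param max_steps optional cap on total steps
#' @param augment_spec optional [augment_spec()] applied on the fly
#' @param seed seed for shuffling and augmentation
#' @param include_background include the background class in the Dice term
#' @param verbose print per-epoch mean losses
#' @return data frame with one row per step: step, epoch, loss, ce, dice, lr
#' @export
fit_model <- function(model, images, labels, epochs = 1L, batch_size = 4L,
                      lr = 0.01, momentum = 0.9, weight_decay = 1e-4,
                      schedule = c("constant", "poly"), max_steps = NULL,
                      augment_spec = NULL, seed = 1L,
                      include_background = TRUE, verbose = FALSE) {
  schedule <- match.arg(schedule)
  params <- module_params(model)
  n <- length(images)
  steps_per_epoch <- ceiling(n / batch_size)
  total_steps <- epochs * steps_per_epoch
  if (!is.null(max_steps)) total_steps <- min(total_steps, max_steps)
  hist <- data.frame(step = integer(0), epoch = integer(0), loss = numeric(0),
                     ce = numeric(0), dice = numeric(0), lr = numeric(0))
  step <- 0L
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (b in seq_len(steps_per_epoch)) {
      if (step >= total_steps) break
      step <- step + 1L
      idx <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, n)]
      imgs <- images[idx]
      labs <- labels[idx]
      if (!is.null(augment_spec)) {
        for (j in seq_along(idx)) {
          aug <- augment(imgs[[j]], labs[[j]], augment_spec,
                         seed = item_seed(seed, step * 1000L + j))
          imgs[[j]] <- aug$image
          labs[[j]] <- aug$label
        }
      }
      x <- tensor_const(stack_images(imgs, model$cfg$in_channels))
      y <- stack_labels(labs)
      cur_lr <- if (schedule == "poly") {
        lr * (1 - (step - 1) / total_steps)^0.9
      } else {
        lr
      }
      zero_grads(params)
      logits <- graph_forward(model, x, training = TRUE)
      loss <- op_seg_loss(logits, y, include_background)
      if (!is.finite(as.numeric(loss$value))) {
        stop(sprintf("non-finite loss at step %d (ce=%.4g dice=%.4g); aborting",
                     step, loss$ce, loss$dice))
      }
      backward(loss)
      sgd_step(params, cur_lr, momentum, weight_decay)
      hist[step, ] <- list(step, ep, as.numeric(loss$value), loss$ce,
                           loss$dice, cur_lr)
    }
    if (verbose) {
      epo <- hist$epoch == ep
      message(sprintf("epoch %d: mean loss %.4f (ce %.4f, dice %.4f)",
                      ep, mean(hist$loss[epo]), mean(hist$ce[epo]),
                      mean(hist$dice[epo])))
    }
    if (step >= total_steps) break
  }
  hist
}

#' Evaluate a model on a set of image/label pairs
#'
#' Runs batched forward passes in evaluation mode (running batch-norm
#' statistics) and scores each case with [evaluate_case()].
#'
#' @param model an `hs_model`
#' @param images list of intensity matrices
#' @param labels list of integer label matrices
#' @param ids optional case identifiers
#' @param batch_size forward batch size
#' @return named list of `metric_report` objects
#' @export
evaluate_model <- function(model, images, labels, ids = NULL,
                           batch_size = 8L) {
  n <- length(images)
  ids <- ids %||% sprintf("case_%04d", seq_len(n))
  M <- model$cfg$num_classes
  reports <- vector("list", n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- stack_images(images[idx], model$cfg$in_channels)
    pred <- predict_labels(model, x)
    for (j in seq_along(idx)) {
      reports[[idx[j]]] <- evaluate_case(pred[, , j], labels[[idx[j]]], M)
    }
  }
  names(reports) <- ids
  reports
}

#' Mean foreground Dice over a set of case reports
#' @param reports list of `metric_report` objects
#' @return scalar mean of per-case mean foreground DSC
#' @export
mean_dsc <- function(reports) {
  mean(vapply(reports, function(r) r$mean_dsc, numeric(1)))
}
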