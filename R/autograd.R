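#' @useDynLib hybridseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Minimal reverse-mode autograd over plain R arrays.
#
# A tensor is an environment holding a value, its graph parents and a
# backward closure that maps the incoming gradient to one gradient per
# parent.  Gradients are only propagated through subgraphs that reach a
# parameter ("needs"), so inference-only branches carry no tape cost.
# ---------------------------------------------------------------------------

new_tensor <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$needs <- FALSE
  for (p in parents) if (p$needs) { e$needs <- TRUE; break }
  e$backfn <- if (e$needs) backfn else NULL
  class(e) <- "hs_tensor"
  e
}

#' Create a learnable parameter tensor
#'
#' @param value numeric array with the initial value
#' @param name optional identifier used in checkpoints and layer tables
#' @return a tensor marked as requiring gradients
#' @keywords internal
tensor_param <- function(value, name = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- list()
  e$backfn <- NULL
  e$needs <- TRUE
  e$is_param <- TRUE
  e$name <- name
  e$momentum <- NULL
  class(e) <- "hs_tensor"
  e
}

tensor_const <- function(value) new_tensor(value)

as_value <- function(x) if (inherits(x, "hs_tensor")) x$value else x

is_tensor <- function(x) inherits(x, "hs_tensor")

wrap_tensor <- function(x) if (is_tensor(x)) x else tensor_const(x)

#' Backpropagate gradients from a scalar loss tensor
#'
#' Performs a depth-first topological sort of the reachable graph and then
#' applies each node's backward closure in reverse order, accumulating
#' gradients on parameters (`$grad`).
#'
#' @param root tensor holding a scalar value
#' @keywords internal
backward <- function(root) {
  topo <- vector("list", 512L)
  k <- 0L
  stamp <- new.env(parent = emptyenv())
  visit <- function(t) {
    if (identical(t$.stamp, stamp)) return(invisible())
    t$.stamp <- stamp
    if (t$needs) for (p in t$parents) visit(p)
    k <<- k + 1L
    if (k > length(topo)) length(topo) <<- 2L * k
    topo[[k]] <<- t
    invisible()
  }
  visit(root)
  topo <- topo[seq_len(k)]
  for (t in topo) t$grad <- NULL
  root$grad <- array(1, dim = dim(root$value) %||% 1L)
  for (t in rev(topo)) {
    if (is.null(t$backfn) || is.null(t$grad)) next
    gs <- t$backfn(t$grad)
    for (i in seq_along(t$parents)) {
      g <- gs[[i]]
      if (is.null(g)) next
      p <- t$parents[[i]]
      if (!p$needs) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (!isTRUE(t$is_param)) t$grad <- NULL  # free intermediate grads
  }
  invisible(root)
}

# Zero accumulated gradients on a list of parameters.
zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}
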