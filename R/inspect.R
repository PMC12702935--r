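# ---------------------------------------------------------------------------
# Per-layer parameter / multiply-accumulate reporting.
# ---------------------------------------------------------------------------

# One forward probe records each conv's output spatial size and each token
# module's token count in its meta; the table is then computed analytically.
probe_model <- function(model) {
  S <- model$cfg$input_size
  x <- array(0, c(S, S, model$cfg$in_channels, 1L))
  invisible(model_forward(model, x))
}

layer_macs <- function(m) {
  meta <- m$meta
  ty <- meta$type %||% m$kind
  if (identical(ty, "conv2d") && !is.null(meta$last_out_hw)) {
    return(meta$macs_per_px * prod(meta$last_out_hw))
  }
  if (identical(ty, "msa") && !is.null(meta$last_tokens)) {
    TT <- meta$last_tokens; D <- meta$dim
    dh <- D / meta$heads
    return(4 * TT * D * D + 2 * TT * TT * dh * meta$heads)
  }
  if (identical(ty, "mlp") && !is.null(meta$last_tokens)) {
    return(2 * meta$last_tokens * meta$dim * meta$hidden)
  }
  if (identical(ty, "eca")) {
    return((meta$out_ch %||% 0) * (meta$k %||% 0))
  }
  0
}

walk_layers <- function(m, prefix = "") {
  rows <- list()
  if (length(m$params)) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = sub("\\.$", "", prefix),
      type = m$meta$type %||% m$kind,
      params = sum(vapply(m$params, function(p) length(p$value), numeric(1))),
      macs = layer_macs(m))
  }
  for (nm in names(m$children)) {
    rows <- c(rows, list(walk_layers(m$children[[nm]],
                                     paste0(prefix, nm, "."))))
  }
  do.call(rbind, rows)
}

#' Per-layer parameter and MAC table
#'
#' Runs one probe forward pass at the configured input size to record
#' output resolutions, then tabulates every parameter-bearing layer with
#' its learnable-scalar count and multiply-accumulate count (per batch
#' element; 1 MAC = 1 multiply + 1 add).  The parameter column sums to
#' [count_parameters()] of the model.
#'
#' @param model an `hs_model`
#' @return data frame with columns name, type, params, macs
#' @export
layer_table <- function(model) {
  probe_model(model)
  tab <- walk_layers(model$net)
  rownames(tab) <- NULL
  tab
}
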