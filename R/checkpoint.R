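GRUD_CHECKPOINT_VERSION <- "1.0"

#' Save / load a trained checkpoint
#'
#' A checkpoint bundles, for every region, the generator weights and
#' normalisation statistics together with the architecture configuration
#' and the site metadata (positions, alleles, training-panel MAF), so a
#' pre-trained model is self-describing and can impute new samples without
#' panel access. Serialised with R's native RDS format; a `version` field
#' guards compatibility.
#'
#' @param checkpoint a `grud_checkpoint`.
#' @param path file path (conventionally `.grud`).
#' @return `load_checkpoint` returns the checkpoint; `save_checkpoint`
#'   returns `path` invisibly.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "grud_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "grud_checkpoint"))
    stop("not a grud checkpoint: ", path)
  if (!identical(ck$version, GRUD_CHECKPOINT_VERSION))
    stop("checkpoint version ", ck$version, " not supported (expected ",
         GRUD_CHECKPOINT_VERSION, ")")
  ck
}

#' @export
print.grud_checkpoint <- function(x, ...) {
  n_reg <- sum(!vapply(x$region_models, is.null, logical(1)))
  cat(sprintf("grud_checkpoint v%s: %d region(s), %d observed / %d unobserved sites\n",
              x$version, n_reg, length(x$observed_idx),
              length(x$unobserved_idx)))
  ep <- vapply(x$region_models, function(m)
    if (is.null(m)) NA_integer_ else m$epochs_run, integer(1))
  cat(sprintf("  gamma %.2f; epochs per region: %s\n",
              x$gen_config$gamma, paste(ep, collapse = ", ")))
  invisible(x)
}
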