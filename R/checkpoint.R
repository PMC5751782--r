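# Single-file model checkpoints: a versioned container holding the
# configuration, every named parameter array, the vocabularies and the
# lexicon, written with R serialization.

CHECKPOINT_FORMAT <- "mcnn-checkpoint"
CHECKPOINT_VERSION <- 1L

#' Save a fitted model to a single checkpoint file
#'
#' @param object A fitted `mcnn` model.
#' @param path Output path.
#' @export
save_mcnn <- function(object, path) {
  stopifnot(inherits(object, "mcnn"))
  saveRDS(list(format = CHECKPOINT_FORMAT, version = CHECKPOINT_VERSION,
               model = object), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_mcnn()].
#' @return The fitted `mcnn` model.
#' @export
load_mcnn <- function(path) {
  x <- readRDS(path)
  if (!is.list(x) || !identical(x$format, CHECKPOINT_FORMAT)) {
    stop("not an mcnn checkpoint: ", path)
  }
  if (x$version > CHECKPOINT_VERSION) {
    stop("checkpoint version ", x$version, " is newer than supported")
  }
  x$model
}
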