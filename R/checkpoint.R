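CHECKPOINT_FORMAT <- "OCRscan-model"
CHECKPOINT_VERSION <- 1L

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized file holding the format tag and
#' version, the full [OCRModelSpec], the fitted weights and the training
#' history; a save/load round trip reproduces the model exactly.
#'
#' @param model an [OCRModel].
#' @param path checkpoint file path.
#' @return \code{saveModel}: invisibly, \code{path}; \code{loadModel}: an
#'   [OCRModel].
#' @export
saveModel <- function(model, path) {
    stopifnot(is(model, "OCRModel"))
    spec <- model@spec
    specList <- lapply(stats::setNames(nm = methods::slotNames(spec)),
                       function(s) methods::slot(spec, s))
    saveRDS(list(format = CHECKPOINT_FORMAT, version = CHECKPOINT_VERSION,
                 spec = specList, weights = model@weights,
                 history = model@history, trained = model@trained),
            path)
    invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
    if (!file.exists(path)) stop("checkpoint not found: ", path)
    obj <- readRDS(path)
    if (!identical(obj$format, CHECKPOINT_FORMAT))
        stop("'", path, "' is not an OCRscan model checkpoint")
    if (obj$version > CHECKPOINT_VERSION)
        stop("checkpoint version ", obj$version,
             " is newer than this package supports (",
             CHECKPOINT_VERSION, ")")
    spec <- do.call(ocrModelSpec, obj$spec)
    methods::new("OCRModel", spec = spec, weights = obj$weights,
                 history = obj$history, trained = obj$trained)
}
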