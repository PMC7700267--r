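#' @keywords internal
#' @importFrom randomForest randomForest
#' @importFrom e1071 svm
#' @importFrom mclust densityMclust
#' @importFrom class knn
#' @importFrom xgboost xgb.train xgb.DMatrix
#' @importFrom igraph make_empty_graph add_edges components
#' @importFrom stats predict
"_PACKAGE"

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a master seed. Keeps all child
# seeds inside the 32-bit integer range.
derive_seed <- function(master, stream, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(master) * 48271 + h * 1103 + index * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(stage, image_id, ...) {
  info <- c(...)
  msg <- sprintf("[%s] image=%s %s", stage, image_id,
                 paste(names(info), unname(info), sep = "=", collapse = " "))
  message(msg)
  invisible(msg)
}
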