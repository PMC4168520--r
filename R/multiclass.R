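#' One-versus-rest multiclass MKL-SVM
#'
#' Trains one binary MKL-SVM per class (that class relabeled +1, all others
#' -1); prediction assigns each sample to the class whose binary model gives
#' the largest real-valued decision score, ties broken in favour of the
#' earliest class in `class_labels` order.
#'
#' @param X feature matrix (samples in rows).
#' @param y class labels (factor, character or numeric; 2 or more classes).
#' @param specs kernel bank specification.
#' @param settings [mkl_settings()].
#' @param ... passed on to [mkl_fit()] (`standardize`, `normalize_kernels`).
#' @return object of class `ovr_model` with `class_labels` and a list of
#'   fitted binary `models` in the same order.
#' @export
fit_ovr <- function(X, y, specs = default_kernel_bank(),
                    settings = mkl_settings(), ...) {
  X <- as.matrix(X)
  class_labels <- if (is.factor(y)) levels(droplevels(y)) else sort(unique(y))
  if (length(class_labels) < 2) stop("need at least two classes")
  y_chr <- as.character(y)
  counts <- table(y_chr)
  small <- names(counts)[counts < 2]
  if (length(small))
    stop(sprintf("class '%s' has fewer than 2 training rows", small[1]))
  models <- lapply(class_labels, function(cl) {
    yk <- ifelse(y_chr == as.character(cl), 1, -1)
    mkl_fit(X, yk, specs = specs, settings = settings, ...)
  })
  names(models) <- as.character(class_labels)
  structure(list(class_labels = class_labels, models = models),
            class = "ovr_model")
}

#' Per-class decision scores of a one-versus-rest model
#'
#' @param model fitted [fit_ovr()] model.
#' @param X_new new samples (rows).
#' @return n x K matrix of decision scores, columns in `class_labels` order.
#' @export
ovr_scores <- function(model, X_new) {
  stopifnot(inherits(model, "ovr_model"))
  scores <- vapply(model$models, decision_function,
                   numeric(nrow(as.matrix(X_new))), X_new = X_new)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  colnames(scores) <- as.character(model$class_labels)
  scores
}

#' @describeIn ovr_scores predicted class labels (argmax of the scores).
#' @export
predict_ovr <- function(model, X_new) {
  scores <- ovr_scores(model, X_new)
  idx <- apply(scores, 1, which.max)     # which.max: first max wins ties
  model$class_labels[idx]
}

#' @export
#' @param object,newdata,... S3 predict method arguments.
#' @rdname ovr_scores
predict.ovr_model <- function(object, newdata, ...) predict_ovr(object, newdata)

#' Pooled kernel-weight report across the binary sub-problems
#'
#' Collects the learned kernel weights of every class-vs-rest model into
#' one table (rows = binary problems, columns = kernels), the package's
#' analogue of boxplotting weights pooled over classification problems.
#'
#' @param model an `ovr_model` (or a single `mkl_model`).
#' @return matrix of kernel weights with kernel descriptions as column names.
#' @export
kernel_weight_report <- function(model) {
  models <- if (inherits(model, "ovr_model")) model$models else list(model)
  W <- do.call(rbind, lapply(models, `[[`, "d"))
  colnames(W) <- vapply(models[[1]]$specs, format, character(1))
  rownames(W) <- names(models) %||% NULL
  W
}

#' @export
print.ovr_model <- function(x, ...) {
  cat(sprintf("<ovr_model> %d classes: %s\n", length(x$class_labels),
              paste(x$class_labels, collapse = ", ")))
  invisible(x)
}
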