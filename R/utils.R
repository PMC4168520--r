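#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stream-specific child seed from a master seed (kept < 2^31).
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + stream * 9973) %% 2147483647
}

check_finite <- function(x, what = deparse(substitute(x))) {
  if (!all(is.finite(x)))
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

#' Fit a z-score standardizer on training rows
#'
#' Constant columns get unit scale so they map to zero rather than NaN.
#' @noRd
fit_standardizer <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(std, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

#' Feature matrix container
#'
#' Rectangular numeric feature table with per-row class labels, the shared
#' output type of [wpe_features()] and [gc_features()] and the input of the
#' cross-validation harness.
#'
#' @param values numeric matrix, trials in rows, features in columns.
#' @param labels vector of class labels, one per row.
#' @param subjects optional subject identifiers, one per row (enables
#'   subject-wise cross-validation folds).
#' @param provenance optional character tag describing the feature path.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels, subjects = NULL, provenance = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("feature values must be numeric")
  if (nrow(values) != length(labels))
    stop("labels length must equal the number of feature rows")
  if (!all(is.finite(values)))
    stop("feature matrix contains non-finite values")
  if (!is.null(subjects) && length(subjects) != nrow(values))
    stop("subjects length must equal the number of feature rows")
  structure(list(values = values, labels = labels, subjects = subjects,
                 provenance = provenance),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features (%s)\n",
              nrow(x$values), ncol(x$values), x$provenance %||% "unlabelled"))
  cat("classes:", paste(names(table(x$labels)), table(x$labels),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}
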