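# Condition helpers: every user-facing failure carries a class so the CLI
# can map it to an exit code (input 2, coverage 3, degenerate 4).

.stopWith <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "subtypePCA_error")))
}

.stopFormat     <- function(fmt, ...) .stopWith("subtypeFormatError", fmt, ...)
.stopDimension  <- function(fmt, ...) .stopWith("subtypeDimensionError", fmt, ...)
.stopLabel      <- function(fmt, ...) .stopWith("subtypeLabelError", fmt, ...)
.stopCoverage   <- function(fmt, ...) .stopWith("subtypeCoverageError", fmt, ...)
.stopDegenerate <- function(fmt, ...) .stopWith("subtypeDegenerateError", fmt, ...)
.stopParameter  <- function(fmt, ...) .stopWith("subtypeParameterError", fmt, ...)
.stopBuild      <- function(fmt, ...) .stopWith("subtypeBuildError", fmt, ...)

# Contract for every expression matrix in the package: numeric, finite,
# uniquely named genes (rows) and samples (columns).
.checkExprMatrix <- function(m, what = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    .stopFormat("%s must be a numeric matrix", what)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    .stopFormat("%s must have gene rownames and sample colnames", what)
  if (anyDuplicated(rownames(m)))
    .stopWith("subtypeUniquenessError", "%s has duplicate gene ids: %s", what,
              paste(unique(rownames(m)[duplicated(rownames(m))]),
                    collapse = ", "))
  if (anyDuplicated(colnames(m)))
    .stopWith("subtypeUniquenessError", "%s has duplicate sample ids: %s",
              what,
              paste(unique(colnames(m)[duplicated(colnames(m))]),
                    collapse = ", "))
  if (!all(is.finite(m)))
    .stopFormat("%s contains non-finite values (NA/NaN/Inf)", what)
  invisible(m)
}

# Population (divide by n) or sample (n - 1) standard deviation.
.sdDiv <- function(x, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  n <- length(x)
  if (n == 0L) .stopParameter("cannot take sd of an empty vector")
  mu <- mean(x)
  ss <- sum((x - mu)^2)
  if (divisor == "n") sqrt(ss / n)
  else {
    if (n < 2L) .stopParameter("sd with divisor n-1 needs >= 2 values")
    sqrt(ss / (n - 1L))
  }
}
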