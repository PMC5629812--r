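#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rgamma sd cor prcomp qchisq qt lm coef vcov
#'   pf setNames complete.cases quantile var dist fft mvfft
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so simulation functions are pure in (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

log_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# population (divide-by-n) standard deviation
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Moore-Penrose pseudoinverse of a symmetric PSD matrix; eigenvalues below
# tol * max are treated as the null space and excluded.
sym_pinv <- function(M, tol = 1e-10) {
  e <- eigen(M, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) stopf("z-score undefined: zero variance")
  (x - mean(x)) / s
}
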