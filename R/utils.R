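#' @importFrom stats quantile rnorm runif median setNames
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

# round-half-up to integer percent; base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_allseq <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# checks that a value is a single positive number
check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_allseq("'%s' must be a single positive number (got %s)",
                name, paste(format(x), collapse = ","))
  invisible(x)
}
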