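#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{expr} under \code{set.seed(seed)} and restores the caller's
#' random-number state afterwards, so seeded helpers do not perturb the
#' global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed below 2^31 from a parent seed and an index.
derive_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 9973) %% 2147483587 + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ISO-8601 date parsing that yields NA (never an error) on malformed input.
parse_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(as.character(x), format = "%Y-%m-%d")
}
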