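#' Derive a reproducible child seed
#'
#' Every stochastic stage of the package draws its randomness from a child
#' seed derived deterministically from a global seed plus a stage label, so
#' any stage can be rerun in isolation and adding stages never perturbs the
#' randomness of existing ones.
#'
#' @param seed Integer global seed.
#' @param ... Stage labels (character or numeric scalars); coerced to a
#'   single label string.
#' @return An integer in `[0, 2^31 - 2]`.
#' @examples
#' child_seed(1, "split")
#' child_seed(1, "oversample", 2)
#' @export
child_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(x) paste(format(x), collapse = "/"),
                  character(1))
  label <- paste(parts, collapse = "::")
  h <- 0
  for (cc in utf8ToInt(label)) h <- (h * 31 + cc) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483647)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% 2147483647L)
  code
}
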