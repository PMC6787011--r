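#' @importFrom stats predict
NULL

#' Derive a child seed from a master seed
#'
#' Deterministic integer hash of the master seed and a label, kept in
#' `[1, 2^31 - 2]` so it is always a valid `set.seed()` argument. Used so that
#' every cell of the experimental design gets an independent, reproducible
#' stream, and adding design cells never perturbs the others.
#'
#' @param master Integer master seed.
#' @param ... Labels (coerced to character) identifying the design cell.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  label <- paste(c(as.character(master), vapply(list(...), as.character, "")),
                 collapse = "/")
  h <- 2166136261
  for (code in utf8ToInt(label)) {
    h <- (h * 16777619) %% 2147483647
    h <- (h + code) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# inverse logit on the safe side for large |x|
.invlogit <- function(x) stats::plogis(x)
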