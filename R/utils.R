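#' Beta/M-value transforms
#'
#' DNA methylation beta values live in \[0,1\]; the M-value is their logit2
#' transform, `m = log2(beta / (1 - beta))`, which is unbounded and closer to
#' Gaussian. `ilogit2()` is the inverse, `beta = 1 / (1 + 2^(-m))`. The pair is
#' a bijection on (0,1).
#'
#' @param beta numeric vector or matrix of beta values in (0,1).
#' @param m numeric vector or matrix of M-values.
#' @return The transformed values, same shape as the input.
#' @export
logit2 <- function(beta) log2(beta / (1 - beta))

#' @rdname logit2
#' @export
ilogit2 <- function(m) 1 / (1 + 2^(-m))

# Clip p-values away from 0 and 1 before probit transforms; the lower bound
# keeps qnorm finite, the upper keeps z > -inf.
clip_p <- function(p, lo = 1e-300, hi = 1 - 1e-16) {
  pmin(pmax(p, lo), hi)
}

# Evaluate expr with a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standard module colour aliases, in size order; grey is reserved for the
# unassigned label 0.
module_colors <- function(k) {
  base <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta"
  )
  if (k <= length(base)) base[seq_len(k)]
  else c(base, paste0("module", seq.int(length(base) + 1L, k)))
}
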