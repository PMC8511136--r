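#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' seeded package routines never disturb the global stream. A `NULL` seed
#' evaluates `code` under the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible 31-bit sub-seed from a master seed and an index.
.sub_seed <- function(seed, index) {
  ((as.numeric(seed) %% 100000) * 20011 + as.numeric(index) * 7919 + 1) %%
    2147483647
}

# 31-bit polynomial rolling hash of a character scalar (config
# fingerprints in file headers; avoids a digest dependency).
.fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
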