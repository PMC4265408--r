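# Small shared numeric helpers.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding to `digits` decimals, used for every
#' reported percentage and ratio so printed summaries match the usual
#' half-up convention rather than R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return Rounded numeric vector.
#' @examples
#' roundHalfUp(c(0.125, 0.135), 2)  # 0.13 0.14
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Single-linkage grouping from an edge list over 1..n; returns component ids.
singleLinkage <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, 1L)
}
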