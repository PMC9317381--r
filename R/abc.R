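#' Computed ABC analysis
#'
#' Item categorization adapted from economics: a nonnegative importance
#' vector is split into the "important few" (set A), an intermediate set
#' B, and the "trivial many" (set C). Items are sorted in descending
#' order and the cumulative contribution curve is built over the points
#' (effort = cumulative item fraction, yield = cumulative value
#' fraction), running concave and nondecreasing from (0,0) to (1,1). The
#' A|B boundary is the curve point closest (Euclidean) to the ideal point
#' (0,1); the B|C boundary is the break-even point where the interpolated
#' curve's slope first drops to 1 or below, constrained not to precede
#' the A|B boundary. Ties in value keep the stable input order.
#'
#' @param values nonnegative numeric vector, at least 3 items, not all
#'   zero; names (if any) are carried through.
#' @return object of class `abc_result`: `order` (item indices by
#'   descending value), `curve` (data.frame effort/yield including the
#'   origin), `ab_boundary`, `bc_boundary` (counts of items in A and in
#'   A+B), and `sets` (factor A/B/C in input order).
#' @export
abc_analysis <- function(values) {
  n <- length(values)
  if (n < 3) stop("at least 3 items required")
  if (anyNA(values) || any(values < 0)) stop("values must be nonnegative")
  if (all(values == 0)) stop("all-zero vector")
  ord <- order(-values)  # stable: ties keep input order
  v <- values[ord]
  effort <- seq_len(n) / n
  yield <- cumsum(v) / sum(v)
  curve <- data.frame(effort = c(0, effort), yield = c(0, yield))

  d2 <- curve$effort^2 + (1 - curve$yield)^2
  ab <- which.min(d2) - 1L  # index into items, 0 allowed in principle
  slopes <- n * v / sum(v)  # slope of each interpolated segment
  first_flat <- which(slopes <= 1 + 1e-12)[1]
  bc <- if (is.na(first_flat)) n else first_flat - 1L
  bc <- max(bc, ab)
  ab <- max(ab, 0L)

  sets <- rep("C", n)
  if (ab > 0) sets[ord[seq_len(ab)]] <- "A"
  if (bc > ab) sets[ord[(ab + 1):bc]] <- "B"
  sets <- factor(sets, levels = c("A", "B", "C"))
  names(sets) <- names(values)
  structure(list(order = ord, curve = curve,
                 ab_boundary = as.integer(ab), bc_boundary = as.integer(bc),
                 sets = sets),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf("abc_result: %d items -> A: %d, B: %d, C: %d\n",
              length(x$sets), sum(x$sets == "A"), sum(x$sets == "B"),
              sum(x$sets == "C")))
  invisible(x)
}

#' Items in ABC set A
#'
#' Convenience projection of [abc_analysis()]: the indices (or names,
#' when the input is named) of the "important few".
#'
#' @param values nonnegative numeric vector as for [abc_analysis()].
#' @return integer indices of set-A items, or their names if available.
#' @export
abc_set_a <- function(values) {
  res <- abc_analysis(values)
  idx <- which(res$sets == "A")
  if (!is.null(names(values))) names(values)[idx] else idx
}
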