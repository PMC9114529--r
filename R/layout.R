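#' Micropattern layout for a periodic row of cells
#'
#' Describes which cells of the periodic row sit on ligand-functionalized
#' lines and how much ligand the lines carry. The simulated row spans the
#' region between the mid-lines of two adjacent printed stripes, so the
#' default geometry places the on-line cells as two contiguous blocks at the
#' two ends of the row (half of each flanking line), with the off-line cells
#' in between. Both a Dll4 and a Jag1 line content are carried; published
#' stripe experiments use one nonzero ligand at a time, but the layout
#' permits both.
#'
#' @param M Number of cells in the periodic row (`>= 2`).
#' @param n_on Number of cells on lines (default `M / 2`, i.e. half the
#'   cells). Ignored when `on_line` is given.
#' @param d_line Dll4 content on the lines (molecules, `>= 0`).
#' @param j_line Jag1 content on the lines (molecules, `>= 0`).
#' @param on_line Optional logical vector of length `M` giving the on-line
#'   mask explicitly.
#' @return An object of class `ns_layout` with fields `M`, `on_line`,
#'   `d_line`, `j_line`.
#' @examples
#' pattern_layout(12, d_line = 3000)$on_line
#' @export
pattern_layout <- function(M = 12, n_on = M %/% 2, d_line = 0, j_line = 0,
                           on_line = NULL) {
  if (!is.numeric(M) || length(M) != 1L || M < 2 || M != round(M))
    stop("M must be a single integer >= 2", call. = FALSE)
  M <- as.integer(M)
  if (is.null(on_line)) {
    on_line <- edge_block_mask(M, n_on)
  } else {
    if (!is.logical(on_line) || length(on_line) != M || anyNA(on_line))
      stop("on_line must be a logical vector of length M without NAs",
           call. = FALSE)
  }
  if (!is.numeric(d_line) || length(d_line) != 1L || !is.finite(d_line) ||
      d_line < 0)
    stop("d_line must be a single number >= 0", call. = FALSE)
  if (!is.numeric(j_line) || length(j_line) != 1L || !is.finite(j_line) ||
      j_line < 0)
    stop("j_line must be a single number >= 0", call. = FALSE)
  structure(list(M = M, on_line = on_line,
                 d_line = as.numeric(d_line), j_line = as.numeric(j_line)),
            class = "ns_layout")
}

# n_on cells split into two blocks at the row ends, as symmetric as possible
# (the row is flanked by half of each of the two neighbouring lines)
edge_block_mask <- function(M, n_on) {
  if (!is.numeric(n_on) || length(n_on) != 1L || n_on < 0 || n_on > M ||
      n_on != round(n_on))
    stop("n_on must be an integer in [0, M]", call. = FALSE)
  n_on <- as.integer(n_on)
  on <- rep(FALSE, M)
  head_n <- n_on %/% 2L
  tail_n <- n_on - head_n
  if (head_n > 0L) on[seq_len(head_n)] <- TRUE
  if (tail_n > 0L) on[(M - tail_n + 1L):M] <- TRUE
  on
}

#' @export
print.ns_layout <- function(x, ...) {
  cat(sprintf("Pattern layout: M = %d cells, %d on lines (D_line = %g, J_line = %g molecules)\n",
              x$M, sum(x$on_line), x$d_line, x$j_line))
  cat("  row: ", paste(ifelse(x$on_line, "#", "."), collapse = ""),
      "   (# = on line, periodic)\n", sep = "")
  invisible(x)
}
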