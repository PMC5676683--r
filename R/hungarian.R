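# Linear assignment (Hungarian algorithm).
#
# O(n^3) shortest-augmenting-path formulation with row/column potentials.
# Rectangular matrices are padded internally with a large sentinel cost so
# that |rows| != |cols| is handled; padded pairings are reported as NA.

#' Solve the linear assignment problem
#'
#' Finds the assignment minimizing the total cost over a (possibly
#' rectangular) cost matrix. The algorithm is deterministic, so equal-cost
#' optima always resolve the same way for the same input.
#'
#' @param cost numeric matrix of finite costs (rows = agents, cols = tasks).
#' @return Integer vector of length `nrow(cost)`; entry `i` is the column
#'   assigned to row `i`, or `NA` if row `i` is unassigned (only possible
#'   when `nrow > ncol`).
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost)) cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L || nc == 0L) return(rep(NA_integer_, nr))
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  n <- max(nr, nc)
  sentinel <- (max(abs(cost)) + 1) * n
  a <- matrix(sentinel, n, n)
  a[seq_len(nr), seq_len(nc)] <- cost
  # potentials u, v and column matching p; arrays are 1-shifted so that
  # index 1 plays the role of the virtual column/row 0
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- a[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0L:n) {
        jj <- j + 1L
        if (used[jj]) {
          u[p[jj] + 1L] <- u[p[jj] + 1L] + delta
          v[jj] <- v[jj] - delta
        } else minv[jj] <- minv[jj] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match <- rep(NA_integer_, nr)
  for (j in seq_len(n)) {
    i <- p[j + 1L]
    if (i >= 1L && i <= nr && j <= nc) match[i] <- j
  }
  match
}
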