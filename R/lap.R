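# Linear assignment problem solver (Jonker-Volgenant shortest augmenting
# path with dual potentials, O(n^3)). Used by the particle linker; an
# exhaustive-enumeration oracle covers it in the test suite.

#' Solve a square linear assignment problem (minimization)
#'
#' @param cost Square numeric cost matrix (finite values).
#' @return Integer vector `a` with `a[i]` = column assigned to row `i`.
#' @keywords internal
#' @export
lap_solve <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n)            # row potentials, 1..n
  v <- numeric(n + 1L)       # column potentials, columns 0..n at j+1
  p <- integer(n + 1L)       # p[j+1] = row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- cost[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used) - 1L
      rows <- p[usedj + 1L]
      u[rows] <- u[rows] + delta
      v[usedj + 1L] <- v[usedj + 1L] - delta
      minv[free] <- minv[free] - delta
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
  out <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) out[p[j + 1L]] <- j
  out
}

# Gated frame-to-frame matching with births/deaths: returns for each row
# (source) the matched column (target) or NA. Link i-j is allowed when
# cost[i,j] <= gate_cost; unmatched sources/targets pay gate_cost each.
lap_match_gated <- function(cost, gate_cost) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  if (n1 == 0L || n2 == 0L) return(rep(NA_integer_, n1))
  forbid <- 1e8 * max(gate_cost, 1)
  C <- cost
  C[C > gate_cost] <- forbid
  M <- matrix(forbid, n1 + n2, n1 + n2)
  M[seq_len(n1), seq_len(n2)] <- C
  M[cbind(seq_len(n1), n2 + seq_len(n1))] <- gate_cost
  M[cbind(n1 + seq_len(n2), seq_len(n2))] <- gate_cost
  M[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0
  a <- lap_solve(M)
  match <- a[seq_len(n1)]
  match[match > n2] <- NA_integer_
  ifelse(!is.na(match) & cost[cbind(seq_len(n1), match)] <= gate_cost,
         match, NA_integer_)
}
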