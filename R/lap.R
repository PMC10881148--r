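# Linear-assignment matching for track linking.
#
# The LAP-tracker formulation used here: candidate links carry cost d^2 and
# links with d > max_dist are forbidden; leaving a detection unlinked costs
# b = max_dist^2 per side. Minimising total cost is equivalent to a
# maximum-weight bipartite matching with edge weights (2b - d^2), all
# strictly positive for admissible links, solved exactly with the
# Kuhn-Munkres algorithm (igraph).

# cost: numeric matrix (rows = sources, cols = targets), Inf = forbidden.
# b: the non-link alternative cost. Returns an integer vector of length
# nrow(cost): matched column index or NA.
lap_match <- function(cost, b) {
  nr <- nrow(cost); nc <- ncol(cost)
  out <- rep(NA_integer_, nr)
  if (nr == 0L || nc == 0L) return(out)
  idx <- which(is.finite(cost), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(out)
  # lexicographic edge order for reproducibility
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  w <- 2 * b - cost[idx]
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nr), rep(TRUE, nc)),
    edges = as.vector(rbind(idx[, 1], nr + idx[, 2]))
  )
  m <- igraph::max_bipartite_match(g, weights = w)$matching
  matched <- m[seq_len(nr)]
  ok <- !is.na(matched)
  out[ok] <- as.integer(matched[ok]) - nr
  out
}

# Brute-force minimum-cost matching by enumeration (oracle for tests and a
# fallback path; exponential, use only for small problems).
lap_match_bruteforce <- function(cost, b) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- NULL
  best_cost <- Inf
  assign_rec <- function(i, used, match) {
    if (i > nr) {
      tot <- 0
      for (r in seq_len(nr)) {
        tot <- tot + if (is.na(match[r])) b else cost[r, match[r]]
      }
      tot <- tot + b * (nc - sum(!is.na(match)))
      if (tot < best_cost - 1e-12) {
        best_cost <<- tot
        best <<- match
      }
      return(invisible())
    }
    assign_rec(i + 1L, used, match) # leave row i unmatched
    for (j in seq_len(nc)) {
      if (!used[j] && is.finite(cost[i, j])) {
        used[j] <- TRUE; match[i] <- j
        assign_rec(i + 1L, used, match)
        used[j] <- FALSE; match[i] <- NA_integer_
      }
    }
  }
  if (nr > 0L) assign_rec(1L, rep(FALSE, nc), rep(NA_integer_, nr))
  else best <- integer(0)
  best
}
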