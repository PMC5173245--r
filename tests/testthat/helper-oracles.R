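# Independent oracles used by the correspondence tests: plain exhaustive
# enumeration over one-to-one assignments of admissible left/right pairs,
# maximising match count first and total cost (dE + dy - S) second.
# Written independently of match_features(); keep it dumb.

oracle_costs <- function(left, right, max_disparity, window) {
  out <- list()
  for (i in seq_len(nrow(left))) {
    for (j in seq_len(nrow(right))) {
      if (abs(left$y[i] - right$y[j]) > window) next
      if (abs(left$x[i] - right$x[j]) > max_disparity) next
      de <- abs(left$energy_E[i] - right$energy_E[j]) /
        max(left$energy_E[i], right$energy_E[j])
      dy <- abs(left$y[i] - right$y[j]) / window
      out[[length(out) + 1]] <- data.frame(
        il = i, ir = j, cost = de + dy - right$metric_S[j])
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

oracle_assign <- function(left, right, max_disparity, window) {
  tab <- oracle_costs(left, right, max_disparity, window)
  if (is.null(tab)) return(NULL)
  best <- list(n = -1L, cost = Inf, rows = integer())
  nl <- nrow(left)
  explore <- function(i, used_r, rows, cost) {
    if (i > nl) {
      n <- length(rows)
      if (n > best$n || (n == best$n && cost < best$cost)) {
        best <<- list(n = n, cost = cost, rows = rows)
      }
      return()
    }
    cand <- which(tab$il == i)
    for (k in cand) {
      if (!(tab$ir[k] %in% used_r)) {
        explore(i + 1, c(used_r, tab$ir[k]), c(rows, k), cost + tab$cost[k])
      }
    }
    explore(i + 1, used_r, rows, cost)
  }
  explore(1L, integer(), integer(), 0)
  tab[best$rows, , drop = FALSE]
}

# random feature tables; `spread_y` controls epipolar contention
random_features <- function(n, seed, spread_y = 40) {
  set.seed(seed)
  data.frame(id = seq_len(n),
             x = stats::runif(n, 5, 95),
             y = stats::runif(n, 5, spread_y),
             r = stats::runif(n, 2, 10),
             metric_S = stats::runif(n, 0.3, 1),
             energy_E = stats::runif(n, 10, 500))
}
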