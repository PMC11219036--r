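# Exhaustive minimum-total-distance assignment oracle (matches first by
# count of links, then by total distance).
brute_assignment <- function(cost, gate) {
  n <- nrow(cost); m <- ncol(cost)
  best <- NULL; best_key <- c(-Inf, Inf)
  cols <- c(seq_len(m), rep(NA, max(0, n - m)))
  perm_all <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perm_all(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  for (p in unique(perm_all(cols))) {
    tot <- 0; nlink <- 0
    for (i in seq_len(n)) {
      j <- p[i]
      if (!is.na(j) && cost[i, j] <= gate) {
        tot <- tot + cost[i, j]; nlink <- nlink + 1
      }
    }
    key <- c(nlink, tot)
    if (key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2] - 1e-12)) {
      best_key <- key; best <- p
    }
  }
  list(n_links = best_key[1], total = best_key[2])
}
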