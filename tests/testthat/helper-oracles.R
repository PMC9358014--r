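# Independent brute-force oracles used across the suite.

# Nx/Lx by explicit descending scan, no shortcuts shared with the package
oracle_nx <- function(lengths, x) {
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  acc <- 0
  for (i in seq_along(s)) {
    acc <- acc + s[i]
    if (acc >= total * x / 100) return(list(N = s[i], L = i))
  }
}

# minimal >= ceil(fraction*n) containment window by exhaustive enumeration
# over all (start, end) pairs anchored on marker boundaries
oracle_min_window <- function(markers, fraction) {
  s <- markers$start; e <- markers$end
  n <- length(s)
  k <- ceiling(fraction * n)
  best <- NULL
  for (st in sort(unique(s))) {
    for (en in sort(unique(e))) {
      if (en < st) next
      n_in <- sum(s >= st & e <= en)
      if (n_in < k) next
      len <- en - st
      if (is.null(best) || len < best$len ||
          (len == best$len && st < best$start))
        best <- list(start = st, end = en, len = len)
    }
  }
  best
}

# log10 likelihood ratio of a 2x2 table by direct multinomial likelihoods
oracle_lod_2x2 <- function(tab) {
  n <- sum(tab)
  p_sat <- tab / n
  ll_sat <- sum(ifelse(tab > 0, tab * log(p_sat), 0))
  p_row <- rowSums(tab) / n
  p_col <- colSums(tab) / n
  p_ind <- outer(p_row, p_col)
  ll_ind <- sum(ifelse(tab > 0, tab * log(p_ind), 0))
  (ll_sat - ll_ind) / log(10)
}

# connected components by plain union-find over an edge list of node names
oracle_components <- function(nodes, from, to) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(from)) {
    ra <- find(from[i]); rb <- find(to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# canonical form of a partition for comparison
canon_partition <- function(groups) {
  sorted <- lapply(groups, sort)
  keys <- vapply(sorted, paste, character(1), collapse = ",")
  unname(sorted[order(keys)])
}
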