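# Independent oracles used across tests: deliberately naive O(n^2) / full
# enumeration implementations, kept separate from the package's algorithms.

# brute-force distance clustering: all maximal runs with adjacent gaps <= L
bruteClusters <- function(chrom, pos, L) {
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]
  out <- list()
  cur <- 1L
  for (i in seq_along(pos)[-1L]) {
    if (chrom[i] == chrom[i - 1L] && pos[i] - pos[i - 1L] <= L) {
      cur <- c(cur, i)
    } else {
      if (length(cur) >= 2L) out[[length(out) + 1L]] <- o[cur]
      cur <- i
    }
  }
  if (length(cur) >= 2L) out[[length(out) + 1L]] <- o[cur]
  out
}

# all probe pairs within `window`, O(n^2)
brutePairs <- function(chrom, pos, window) {
  n <- length(pos)
  res <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (chrom[i] == chrom[j] && abs(pos[i] - pos[j]) <= window)
      res[[length(res) + 1L]] <- c(i, j, abs(pos[i] - pos[j]))
  }
  if (!length(res)) return(data.frame(i = integer(), j = integer(),
                                      distance = numeric()))
  m <- do.call(rbind, res)
  data.frame(i = m[, 1], j = m[, 2], distance = m[, 3])
}

# exhaustive hypergeometric upper tail: enumerate every n-subset of 1:N
# with successes 1:K and count overlaps >= k
enumHyperP <- function(k, n, K, N) {
  subs <- utils::combn(N, n)
  hits <- colSums(subs <= K)
  mean(hits >= k)
}

# O(n*m) interval overlap count on 1-based closed coordinates
bruteOverlapCount <- function(rchrom, rstart, rend, ichrom, istart, iend) {
  cnt <- 0L
  for (i in seq_along(rstart)) {
    hit <- FALSE
    for (j in seq_along(istart)) {
      if (rchrom[i] == ichrom[j] && rstart[i] <= iend[j] &&
          istart[j] <= rend[i]) hit <- TRUE
    }
    cnt <- cnt + hit
  }
  cnt
}

# random manifest for property tests
randomManifest <- function(n, n_chroms = 2, max_gap = 3000) {
  chrom <- sort(sample(paste0("chr", seq_len(n_chroms)), n, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(i)
    cumsum(sample(seq_len(max_gap), length(i), replace = TRUE))),
    use.names = FALSE)
  makeManifest(sprintf("p%04d", seq_len(n)), chrom, pos)
}
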