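# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain double loops and explicit counting only.

ms_brute <- function(points) {
  n <- nrow(points)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + 1 / sqrt(sum((points[i, ] - points[j, ])^2))
    }
  }
  total / (n * (n - 1) / 2)
}

entropy_brute <- function(column, scheme = class_scheme()) {
  counts <- numeric(7)
  for (ch in toupper(column)) {
    k <- scheme[ch]
    if (!is.na(k)) counts[k] <- counts[k] + 1
  }
  if (sum(counts) == 0) return(NA_real_)
  p <- counts / sum(counts)
  s <- 0
  for (k in 1:7) if (p[k] > 0) s <- s - p[k] * log(p[k])
  s
}

kl_brute <- function(column, background, scheme = class_scheme()) {
  counts <- numeric(7)
  for (ch in toupper(column)) {
    k <- scheme[ch]
    if (!is.na(k)) counts[k] <- counts[k] + 1
  }
  p <- counts / sum(counts)
  s <- 0
  for (k in 1:7) if (p[k] > 0) s <- s + p[k] * log(p[k] / background[k])
  s
}

overlap_brute <- function(members, interface) {
  common <- 0
  for (r in interface) if (r %in% members) common <- common + 1
  100 * common / length(interface)
}

enrichment_brute <- function(cons_aa, int_aa) {
  aa <- sort(unique(names(class_scheme())))
  out <- setNames(rep(NA_real_, length(aa)), aa)
  for (x in aa) {
    ni <- sum(int_aa == x)
    if (ni > 0) {
      out[x] <- (sum(cons_aa == x) / length(cons_aa)) / (ni / length(int_aa))
    }
  }
  out
}

# naive average-linkage clustering: recomputes every inter-cluster average
# distance from the raw point-pair distances at each step
avl_brute <- function(points, threshold) {
  n <- nrow(points)
  d <- as.matrix(dist(points))
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_len(length(clusters) - 1)) {
      for (b in (a + 1):length(clusters)) {
        avg <- mean(d[clusters[[a]], clusters[[b]]])
        if (avg < best_d) { best_d <- avg; best <- c(a, b) }
      }
    }
    if (best_d > threshold) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lapply(clusters, function(ix) sort(rownames(points)[ix]))
}

rand_points <- function(n, seed, scale = 30) {
  set.seed(seed)
  m <- matrix(runif(3 * n, 0, scale), ncol = 3)
  rownames(m) <- sprintf("A:%d", seq_len(n))
  m
}

rand_column <- function(n, seed, letters = names(class_scheme())) {
  set.seed(seed)
  sample(letters, n, replace = TRUE)
}

# canonical form of a partition for comparison
canon_partition <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, `[`, "", 1))]
}
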