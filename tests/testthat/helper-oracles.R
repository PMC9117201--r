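# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately brute-force implementations that share no code
# with the package internals.

# --- geometry ---------------------------------------------------------------

# Haversine on a 6371 km sphere, scalar.
oracle_haversine <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam / 2)^2
  2 * 6371 * asin(sqrt(a))
}

# Exhaustive MST length by enumerating all labelled spanning trees of the
# complete graph via Pruefer sequences (n <= 8).
oracle_mst_length <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(0)
  d <- outer(seq_len(n), seq_len(n), function(i, j) {
    oracle_haversine(lon[i], lat[i], lon[j], lat[j])
  })
  if (n == 2) return(d[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    edges <- pruefer_to_edges(seqs[r, ], n)
    len <- sum(d[edges])
    if (len < best) best <- len
  }
  best
}

pruefer_to_edges <- function(pr, n) {
  degree <- rep(1L, n)
  for (v in pr) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1, 2)
  k <- 1L
  pr <- as.integer(pr)
  for (v in pr) {
    leaf <- min(which(degree == 1L))
    edges[k, ] <- c(leaf, v); k <- k + 1L
    degree[leaf] <- degree[leaf] - 1L
    degree[v] <- degree[v] - 1L
  }
  last <- which(degree == 1L)
  edges[k, ] <- last
  edges
}

# Exhaustive search over all sequences of tip removals (any tip, not just
# smallest-tally) recording every visited state; returns the best achievable
# |length - target|. Cells: data frame with cell/lon/lat/tally.
oracle_best_trim <- function(cells, target, masked = character(0)) {
  best <- abs(oracle_mst_length(cells$lon, cells$lat) - target)
  recurse <- function(df) {
    if (nrow(df) < 2) return()
    d <- outer(seq_len(nrow(df)), seq_len(nrow(df)), function(i, j) {
      oracle_haversine(df$lon[i], df$lat[i], df$lon[j], df$lat[j])
    })
    # MST degree via Prim
    n <- nrow(df)
    intree <- c(TRUE, rep(FALSE, n - 1))
    deg <- rep(0L, n)
    while (!all(intree)) {
      dd <- d[intree, !intree, drop = FALSE]
      k <- which(dd == min(dd), arr.ind = TRUE)[1, ]
      from <- which(intree)[k[1]]; to <- which(!intree)[k[2]]
      deg[from] <- deg[from] + 1L; deg[to] <- deg[to] + 1L
      intree[to] <- TRUE
    }
    tips <- which(deg == 1L & !(df$cell %in% masked))
    for (i in tips) {
      sub <- df[-i, , drop = FALSE]
      len <- oracle_mst_length(sub$lon, sub$lat)
      best <<- min(best, abs(len - target))
      recurse(sub)
    }
  }
  recurse(cells)
  best
}

# --- rarefaction ------------------------------------------------------------

# Mean distinct species over all size-m subsamples (enumeration, n <= 8).
oracle_rarefied_richness <- function(ab, m) {
  inds <- rep(seq_along(ab), ab)
  subs <- utils::combn(length(inds), m)
  mean(apply(subs, 2, function(s) length(unique(inds[s]))))
}

# P(the (m+1)-th individual belongs to a species absent from the first m),
# enumerated over subsets x next individual; 1 minus this is the expected
# coverage of a size-m subsample.
oracle_expected_coverage <- function(ab, m) {
  inds <- rep(seq_along(ab), ab)
  n <- length(inds)
  subs <- utils::combn(n, m)
  novel <- 0; total <- 0
  for (k in seq_len(ncol(subs))) {
    s <- subs[, k]
    rest <- setdiff(seq_len(n), s)
    novel <- novel + sum(!(inds[rest] %in% inds[s]))
    total <- total + length(rest)
  }
  1 - novel / total
}

# --- population-level birth-death (independent of the lineage-level code) --
# Gillespie on the population count; returns c(total species ever, extant).
oracle_bd_counts <- function(root_age, lambda, mu) {
  t <- root_age; n <- 1L; total <- 1L
  while (t > 0 && n > 0) {
    rate <- n * (lambda + mu)
    if (rate == 0) break
    t <- t - stats::rexp(1, rate)
    if (t <= 0) break
    if (stats::runif(1) < lambda / (lambda + mu)) {
      n <- n + 1L; total <- total + 1L
    } else {
      n <- n - 1L
    }
  }
  c(total = total, extant = if (t <= 0) n else 0L)
}

# --- misc -------------------------------------------------------------------

# Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Tiny occurrence table builder.
toy_occurrences <- function() {
  tibble::tibble(
    taxon = c("Ammonoidea_a", "Ammonoidea_b", "Bivalvia_a", "Bivalvia_b"),
    fad = c(252, 251, 250, 249.5),
    lad = c(250, 249, 247, 249.5),
    lon = c(10, 12, -5, 100),
    lat = c(40, 41, -10, 5),
    locality = c("L1", "L1", "L2", "L3"),
    abundance = c(3, 1, 2, 1))
}
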