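# shared helpers: tiny generators and oracles used across test files

# canonical unordered-pair keys for edge-set comparison
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# edge keys of a network_pair layer, as feature indices within `ids`
net_edge_key <- function(edges, ids) {
  if (nrow(edges) == 0) return(character())
  edge_key(match(edges$node_a, ids), match(edges$node_b, ids))
}

# brute-force BH step-up: independent double-loop oracle
bh_brute <- function(p, m) {
  ord <- order(p)
  ps <- p[ord]
  k <- length(p)
  adj <- numeric(k)
  for (i in seq_len(k)) {
    cands <- vapply(i:k, function(j) ps[j] * m / j, numeric(1))
    adj[i] <- min(1, cands)   # imputed p = 1 at ranks > k never lowers this
  }
  out <- numeric(k)
  out[ord] <- adj
  out
}

# two Gaussian clusters separated by delta pooled SDs along every feature
separated_clusters <- function(n_per = 20, p = 5, delta = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, mean = delta), n_per))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = rep(c(0, 1), each = n_per))
}

subset_abundance_test <- function(M, features) {
  metdiffnet:::subset_abundance(M, features = features)
}

# small autoscaled null matrix with labels independent of X
null_labeled <- function(n = 20, p = 5, seed = 1) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = rep_len(c(0, 1), n))
}
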