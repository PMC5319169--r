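# Shared fixtures and independent mini-oracles used across the suite.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent affine-gap local-alignment DP (score only), written directly
# from the recurrences; oracle for the C++ implementation
sw_score_oracle <- function(a, b, reward = 5, penalty = -4, go = 8, ge = 6) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    s <- if (av[i] == bv[j]) reward else penalty
    X[i + 1, j + 1] <- max(H[i, j + 1] - go - ge, X[i, j + 1] - ge)
    Y[i + 1, j + 1] <- max(H[i + 1, j] - go - ge, Y[i + 1, j] - ge)
    H[i + 1, j + 1] <- max(0, max(H[i, j], X[i, j], Y[i, j]) + s)
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

# mutate a sequence to a target identity (substitutions only)
mutate_seq <- function(x, identity, seed = 1) {
  set.seed(seed)
  v <- strsplit(x, "")[[1]]
  n <- length(v)
  k <- round((1 - identity) * n)
  pos <- sample.int(n, k)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# brute-force pruning oracle: sum over all internal-node state
# assignments (no rate variation); tree must be rooted binary or the
# ape unrooted representation (root = first internal node)
brute_force_lnl <- function(tree, aln, Q, pi) {
  P <- lapply(tree$edge.length, function(t) {
    e <- eigen(diag(sqrt(pi)) %*% Q %*% diag(1 / sqrt(pi)), symmetric = TRUE)
    diag(1 / sqrt(pi)) %*% e$vectors %*% diag(exp(e$values * t)) %*%
      t(e$vectors) %*% diag(sqrt(pi))
  })
  states <- do.call(rbind, strsplit(toupper(unlist(aln)), ""))
  st <- matrix(match(states, c("A", "C", "G", "T")), nrow = length(aln))
  rownames(st) <- names(aln)
  st <- st[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  total <- 0
  for (site in seq_len(ncol(st))) {
    lik <- 0
    grid <- as.matrix(expand.grid(rep(list(1:4), nint)))
    for (g in seq_len(nrow(grid))) {
      assign_state <- function(node) {
        if (node <= ntip) st[node, site] else grid[g, node - ntip]
      }
      p <- pi[grid[g, 1]]
      for (e in seq_len(nrow(tree$edge))) {
        a <- assign_state(tree$edge[e, 1])
        b <- assign_state(tree$edge[e, 2])
        p <- p * P[[e]][a, b]
      }
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

# small 4-taxon tree reused by several phylo tests
tree4 <- function() ape::read.tree(text = "((a:0.1,b:0.2):0.15,c:0.12,d:0.3);")
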