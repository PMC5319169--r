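# Goldman-Yang codon-model machinery shared by the simulator and the
# maximum-likelihood estimators: rate matrix construction, spectral
# transition probabilities for a reversible Q, synonymous/nonsynonymous
# flux decomposition, and a generic Felsenstein pruning engine that is
# also used by the 4-state nucleotide models.

# cached table of single-nucleotide codon neighbours among the 61 sense
# codons: columns i, j (codon indices), transition, synonymous
.codon_pairs <- function() {
  if (!is.null(.mr_cache$codon_pairs)) return(.mr_cache$codon_pairs)
  cods <- sense_codons()
  aas <- codon_aa(cods)
  mat <- do.call(rbind, strsplit(cods, "", fixed = TRUE))
  out <- NULL
  n <- length(cods)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    diffs <- which(mat[i, ] != mat[j, ])
    if (length(diffs) == 1L) {
      a <- mat[i, diffs]; b <- mat[j, diffs]
      out <- rbind(out, c(i, j, as.integer(.is_transition(a, b)),
                          as.integer(aas[i] == aas[j])))
    }
  }
  colnames(out) <- c("i", "j", "transition", "synonymous")
  storage.mode(out) <- "integer"
  .mr_cache$codon_pairs <- out
  out
}

#' Goldman-Yang (GY94) instantaneous rate matrix
#'
#' Rates are zero for changes of more than one nucleotide; a single-step
#' change to codon j has rate `pi[j]`, multiplied by `kappa` for
#' transitions and by `omega` for nonsynonymous changes.
#'
#' @param kappa transition/transversion rate ratio (> 0)
#' @param omega dN/dS ratio (>= 0)
#' @param pi codon frequencies over the 61 sense codons (sum to 1)
#' @param normalize scale so the expected rate is 1 substitution per codon
#'   per unit time
#' @return 61 x 61 rate matrix (rows/cols in [sense_codons()] order)
#' @export
gy94_rate_matrix <- function(kappa = 2, omega = 1, pi = rep(1 / 61, 61),
                             normalize = TRUE) {
  if (kappa <= 0) stop("kappa must be > 0")
  if (omega < 0) stop("omega must be >= 0")
  if (length(pi) != 61L || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be 61 frequencies summing to 1")
  pr <- .codon_pairs()
  Q <- matrix(0, 61L, 61L, dimnames = list(sense_codons(), sense_codons()))
  rate <- ifelse(pr[, "transition"] == 1L, kappa, 1) *
    ifelse(pr[, "synonymous"] == 1L, 1, omega)
  Q[pr[, 1:2, drop = FALSE]] <- rate * pi[pr[, "j"]]
  Q[pr[, 2:1, drop = FALSE]] <- rate * pi[pr[, "i"]]
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    mu <- -sum(pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

# spectral decomposition of a reversible rate matrix: returns the pieces
# needed to form P(t) = A %*% (exp(values * t) * B)
.rev_eigen <- function(Q, pi) {
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))   # sym = D^1/2 Q D^-1/2
  B <- (B + t(B)) / 2          # symmetrize against rounding
  e <- eigen(B, symmetric = TRUE)
  A <- e$vectors / sp          # D^-1/2 V  (rows scaled)
  Binv <- t(e$vectors * sp)    # V^T D^1/2
  list(values = e$values, A = A, B = Binv)
}

# transition probability matrix from a .rev_eigen decomposition
.pmat <- function(eig, t) {
  P <- eig$A %*% (exp(eig$values * t) * eig$B)
  P[P < 0] <- 0
  P
}

#' Synonymous/nonsynonymous flux decomposition of a GY94 model
#'
#' Returns the proportions of substitution flux that are synonymous and
#' nonsynonymous, plus the per-codon numbers of synonymous and
#' nonsynonymous sites (3 x the flux proportions of the neutral
#' `omega = 1` model), from which `dN` and `dS` follow:
#' `dS = t * rhoS / S`, `dN = t * rhoN / N` for a branch of length `t`
#' expected substitutions per codon.
#'
#' @inheritParams gy94_rate_matrix
#' @return list with `rhoS`, `rhoN`, `S`, `N`
#' @export
gy94_flux <- function(kappa, omega, pi = rep(1 / 61, 61)) {
  pr <- .codon_pairs()
  base <- ifelse(pr[, "transition"] == 1L, kappa, 1) *
    (pi[pr[, "i"]] * pi[pr[, "j"]])       # pi_i q_ij + pi_j q_ji combined
  syn <- pr[, "synonymous"] == 1L
  uS <- 2 * sum(base[syn])
  uN <- 2 * sum(base[!syn])
  tot <- uS + omega * uN
  tot1 <- uS + uN
  list(rhoS = uS / tot, rhoN = omega * uN / tot,
       S = 3 * uS / tot1, N = 3 * uN / tot1)
}

# dN, dS for a branch of t expected substitutions/codon under (kappa, omega)
.dnds_from_t <- function(t, kappa, omega, pi = rep(1 / 61, 61)) {
  fl <- gy94_flux(kappa, omega, pi)
  list(dS = t * fl$rhoS / fl$S, dN = t * fl$rhoN / fl$N)
}

#' F3x4 codon frequencies from observed sequences
#'
#' Positional nucleotide frequencies multiplied across the three codon
#' positions, renormalized over the 61 sense codons.
#'
#' @param codon_rows character matrix or list of codon vectors
#' @return numeric vector of 61 frequencies
#' @export
f3x4_frequencies <- function(codon_rows) {
  cods <- unlist(codon_rows, use.names = FALSE)
  cods <- cods[!is.na(cods) & cods != "---"]
  if (!length(cods)) return(rep(1 / 61, 61))
  m <- do.call(rbind, strsplit(cods, "", fixed = TRUE))
  f <- vapply(1:3, function(p) {
    tab <- table(factor(m[, p], levels = .NUC))
    as.numeric(tab) / sum(tab)
  }, numeric(4L))  # 4 x 3
  sc <- do.call(rbind, strsplit(sense_codons(), "", fixed = TRUE))
  pi <- f[match(sc[, 1L], .NUC), 1L] * f[match(sc[, 2L], .NUC), 2L] *
    f[match(sc[, 3L], .NUC), 3L]
  pi <- pmax(pi, 1e-10)
  pi / sum(pi)
}

# ---- generic pruning engine ---------------------------------------------

# compress alignment columns to unique site patterns
# states: integer matrix (ntaxa x nsites), NA = unknown/gap
.compress_patterns <- function(states) {
  key <- apply(states, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  patt <- states[, u, drop = FALSE]
  w <- as.numeric(table(factor(key, levels = key[u])))
  list(patt = patt, w = w, index = match(key, key[u]))
}

# per-pattern log-likelihood by Felsenstein pruning (scaling per node).
# tree: phylo; P_edge: list over rows of tree$edge of nstate x nstate
# transition matrices; patt: ntip x npat integer states (rows ordered as
# tree$tip.label); pi: root frequencies.
.prune_loglik <- function(tree, P_edge, patt, pi) {
  ntip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  ord <- match(paste(post$edge[, 1L], post$edge[, 2L]),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  p <- patt
  p[is.na(p)] <- 0L
  storage.mode(p) <- "integer"
  cpp_prune(p, post$edge, P_edge[ord], ntip, pi)
}

# convert aligned codon rows (character matrix taxa x sites) to integer
# state matrix over sense codons (NA for gaps/unknown)
.codon_states_matrix <- function(codmat) {
  idx <- match(codmat, sense_codons())
  matrix(idx, nrow = nrow(codmat), dimnames = dimnames(codmat))
}
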