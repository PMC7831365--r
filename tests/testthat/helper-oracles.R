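# Independent oracles used across tests. These deliberately avoid the
# package's likelihood/scan code paths: brute-force enumeration for the
# pruning algorithm, a Nei-Gojobori-style pathway counter for realized
# dN/dS, and base-R matrix exponentials for transition probabilities.

uniform_pi <- function() stats::setNames(rep(1 / 61, 61), sense_codons())

# GY94 generator built from scratch (string comparisons, no shared code
# with the package's C++ rate-matrix builder), scaled to mean rate 1
oracle_Q <- function(kappa, omega, pi) {
  sc <- sense_codons()
  aa <- translate_codons(sc)
  n <- 61
  Q <- matrix(0, n, n)
  split_sc <- do.call(rbind, strsplit(sc, ""))
  ts_pair <- function(a, b) paste0(a, b) %in% c("AG", "GA", "CT", "TC")
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    d <- which(split_sc[i, ] != split_sc[j, ])
    if (length(d) != 1) next
    r <- pi[j]
    if (ts_pair(split_sc[i, d], split_sc[j, d])) r <- r * kappa
    if (aa[i] != aa[j]) r <- r * omega
    Q[i, j] <- r
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(pi * -diag(Q))
}

oracle_expm <- function(Q, pi, t) {
  s <- sqrt(pi)
  S <- diag(s) %*% Q %*% diag(1 / s)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  diag(1 / s) %*% e$vectors %*% diag(exp(e$values * t)) %*% t(e$vectors) %*% diag(s)
}

# brute-force likelihood: explicit sum over all ancestral-state
# assignments (61^n_internal terms), feasible only for tiny trees
oracle_loglik <- function(aln, tree, kappa, omega, pi) {
  Q <- oracle_Q(kappa, omega, pi)
  Ps <- lapply(tree$edge.length, function(t) oracle_expm(Q, pi, t))
  st <- matrix(match(codon_matrix(aln), sense_codons()),
               nrow = nrow(aln$mat), dimnames = list(rownames(aln$mat), NULL))
  st <- st[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(1:61), nint)))
  total <- 0
  for (site in seq_len(ncol(st))) {
    # one likelihood term per internal-state assignment (row of `grid`);
    # root is node ntip + 1, i.e. grid column 1
    p <- as.numeric(pi[grid[, 1]])
    for (i in seq_len(nrow(tree$edge))) {
      a_node <- tree$edge[i, 1]; b_node <- tree$edge[i, 2]
      a <- grid[, a_node - ntip]
      b <- if (b_node <= ntip) {
        if (is.na(st[b_node, site])) next  # missing codon: sums to factor 1
        rep(st[b_node, site], nrow(grid))
      } else grid[, b_node - ntip]
      p <- p * Ps[[i]][cbind(a, b)]
    }
    total <- total + log(sum(p))
  }
  total
}

# Nei-Gojobori-style counting of synonymous/nonsynonymous sites and
# pathway-averaged differences between two codon sequences
ng_sites <- function(codon) {
  sc <- sense_codons()
  aa <- translate_codons(codon)
  chars <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), chars[p])) {
    alt <- chars
    alt[p] <- nt
    altc <- paste(alt, collapse = "")
    if (altc %in% sc && translate_codons(altc) == aa) syn <- syn + 1 / 3
  }
  c(S = syn, N = 3 - syn)
}

all_orders <- function(d) {
  if (length(d) == 1) return(list(d))
  out <- list()
  for (i in seq_along(d))
    for (rest in all_orders(d[-i]))
      out[[length(out) + 1]] <- c(d[i], rest)
  out
}

ng_path_diffs <- function(c1, c2) {
  sc <- sense_codons()
  if (c1 == c2) return(c(Sd = 0, Nd = 0))
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  d <- which(ch1 != ch2)
  acc <- c(Sd = 0, Nd = 0)
  used <- 0
  for (path in all_orders(d)) {
    cur <- ch1; sd <- 0; nd <- 0; ok <- TRUE
    for (pos in path) {
      nxt <- cur
      nxt[pos] <- ch2[pos]
      curc <- paste(cur, collapse = "")
      nxtc <- paste(nxt, collapse = "")
      if (!(nxtc %in% sc)) { ok <- FALSE; break }   # path through a stop
      if (translate_codons(curc) == translate_codons(nxtc)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { acc <- acc + c(Sd = sd, Nd = nd); used <- used + 1 }
  }
  if (used == 0) return(c(Sd = NA_real_, Nd = NA_real_))
  acc / used
}

# realized dN/dS between two aligned gap-free codon sequences
ng_dnds <- function(seq1, seq2) {
  n <- nchar(seq1) %/% 3
  S <- N <- Sd <- Nd <- 0
  for (k in seq_len(n)) {
    c1 <- substr(seq1, 3 * k - 2, 3 * k)
    c2 <- substr(seq2, 3 * k - 2, 3 * k)
    if (!c1 %in% sense_codons() || !c2 %in% sense_codons()) next
    s1 <- ng_sites(c1)
    s2 <- ng_sites(c2)
    S <- S + (s1[["S"]] + s2[["S"]]) / 2
    N <- N + (s1[["N"]] + s2[["N"]]) / 2
    dd <- ng_path_diffs(c1, c2)
    if (!anyNA(dd)) { Sd <- Sd + dd[["Sd"]]; Nd <- Nd + dd[["Nd"]] }
  }
  (Nd / N) / (Sd / S)
}

row_string <- function(aln, tx) paste(aln$mat[tx, ], collapse = "")
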