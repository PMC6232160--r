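# Independent brute-force oracles and small fixtures shared by the suite.

random_seq <- function(n, letters = c("A", "C", "G", "U")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Exhaustive maximum base-pairing (AU/GC/GU, min loop 3) by plain
# interval recursion -- independent of the package's DP traceback.
oracle_max_pairs <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  can <- function(x, y)
    paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      if (can(ch[k], ch[j])) {
        v <- (if (k > i) rec(i, k - 1L) else 0L) + 1L +
          (if (k + 1L <= j - 1L) rec(k + 1L, j - 1L) else 0L)
        if (v > best) best <- v
      }
    }
    best
  }
  rec(1L, length(ch))
}

# Exhaustive minimum-penalty duplex alignment under the plant-target
# scheme (mismatch 1, G:U 0.5, indel 2; doubled at miRNA positions 2-13;
# insertions weighted by the next miRNA position), by memoized recursion.
oracle_duplex <- function(mirna, site) {
  q <- strsplit(mirna, "")[[1]]
  r <- rev(strsplit(site, "")[[1]])
  m <- length(q); n <- length(r)
  w <- function(i) if (i >= 2 && i <= 13) 2 else 1
  pc <- function(a, b) {
    if (paste0(a, b) %in% c("AU", "UA", "GC", "CG")) 0
    else if (paste0(a, b) %in% c("GU", "UG")) 0.5
    else 1
  }
  memo <- matrix(NA_real_, m + 1L, n + 1L)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    v <- if (i == 0L && j == 0L) {
      0
    } else {
      best <- Inf
      if (i > 0L && j > 0L)
        best <- min(best, rec(i - 1L, j - 1L) + pc(q[i], r[j]) * w(i))
      if (i > 0L) best <- min(best, rec(i - 1L, j) + 2 * w(i))
      if (j > 0L) best <- min(best, rec(i, j - 1L) + 2 * w(min(i + 1L, m)))
      best
    }
    memo[i + 1L, j + 1L] <<- v
    v
  }
  rec(m, n)
}

# Biostrings substitution matrix matching the blastn-like scoring.
blast_submat <- function() {
  m <- matrix(-3, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                        c("A", "C", "G", "U")))
  diag(m) <- 2
  m
}

# Least-squares best topology among all unrooted trees (exhaustive
# enumeration; oracle for neighbor joining on additive matrices).
ls_best_topology <- function(d) {
  taxa <- rownames(d)
  n <- length(taxa)
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  pairs <- t(utils::combn(n, 2))
  dv <- d[pairs]
  desc_tips <- function(tr, node) {
    if (node <= n) return(node)
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips, tr = tr))
  }
  best_rss <- Inf; best_tree <- NULL
  for (k in seq_along(trees)) {
    tr <- trees[[k]]   # [[ restores tip labels of the compressed multiPhylo
    # an edge lies on the path between two tips iff it separates them
    X <- matrix(0, nrow(pairs), nrow(tr$edge))
    for (e in seq_len(nrow(tr$edge))) {
      below <- desc_tips(tr, tr$edge[e, 2])
      X[, e] <- xor(pairs[, 1] %in% below, pairs[, 2] %in% below)
    }
    fit <- stats::lm.fit(X, dv)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) { best_rss <- rss; best_tree <- tr }
  }
  list(tree = best_tree, rss = best_rss)
}

same_topology <- function(a, b) {
  ua <- if (ape::is.rooted(a)) ape::unroot(a) else a
  ub <- if (ape::is.rooted(b)) ape::unroot(b) else b
  ape::dist.topo(ua, ub) == 0
}

small_sim_config <- function(seed = 11, ...) {
  simulation_config(seed = seed, n_implants = 6, n_decoys = 4,
                    n_hard_negatives = 3, n_families = 3,
                    family_size_range = c(3, 3), n_target_mrnas = 6, ...)
}

# a 21-nt mature with U at 8, C at 5, A at 10/11, G at 15/18 so wobble
# and mismatch cases can be planted at known weights
fixture_mirna <- function() "UAGGCACUGAAGGAGCUGCAU"
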