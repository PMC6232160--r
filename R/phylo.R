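kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Progressive multiple alignment of a sequence family
#'
#' Pairwise profile-profile Needleman-Wunsch with affine gaps (match 2,
#' mismatch -1, gap open -4, extend -1 per column) merged along an
#' average-linkage guide tree built on shared k-mer distances. Deterministic; suitable for the short precursor
#' families this package aligns. Output rows keep the input order.
#'
#' @param seqs named character vector (>= 2 sequences).
#' @param k guide-tree k-mer length.
#' @return character matrix of aligned single characters (gap `-`), one
#'   named row per sequence; all rows equal length.
#' @export
progressive_align <- function(seqs, k = 5) {
  if (length(seqs) < 2L) stop("progressive alignment needs >= 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  sets <- lapply(seqs, kmer_set, k = k)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      D[i, j] <- D[j, i] <-
        1 - shared / max(1L, min(length(sets[[i]]), length(sets[[j]])))
    }
  }
  if (n == 2L) {
    merged <- .align_profiles(.as_profile(seqs[1]), .as_profile(seqs[2]))
  } else {
    guide <- stats::hclust(stats::as.dist(D), method = "average")
    profiles <- vector("list", nrow(guide$merge))
    leaf <- function(i) .as_profile(seqs[i])
    for (m in seq_len(nrow(guide$merge))) {
      a <- guide$merge[m, 1]; b <- guide$merge[m, 2]
      A <- if (a < 0) leaf(-a) else profiles[[a]]
      B <- if (b < 0) leaf(-b) else profiles[[b]]
      profiles[[m]] <- .align_profiles(A, B)
    }
    merged <- profiles[[nrow(guide$merge)]]
  }
  merged[names(seqs), , drop = FALSE]
}

.as_profile <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(unlist(seqs)), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

.profile_freq <- function(P) {
  letters5 <- c("A", "C", "G", "U", "-")
  f <- vapply(seq_len(ncol(P)), function(j)
    vapply(letters5, function(b) mean(P[, j] == b), numeric(1)),
    numeric(5))
  rownames(f) <- letters5
  f
}

.align_profiles <- function(A, B, match = 2, mismatch = -1,
                            gap_open = -4, gap_extend = -1) {
  letters5 <- c("A", "C", "G", "U", "-")
  S <- matrix(mismatch, 5, 5, dimnames = list(letters5, letters5))
  diag(S) <- match
  S["-", ] <- gap_open / 2; S[, "-"] <- gap_open / 2; S["-", "-"] <- 0
  fA <- .profile_freq(A); fB <- .profile_freq(B)
  col_score <- t(fA) %*% S %*% fB
  la <- ncol(A); lb <- ncol(B)
  NEG <- -1e18
  # Gotoh: M diagonal state, X gap in B (consume A), Y gap in A (consume B)
  M <- matrix(NEG, la + 1L, lb + 1L)
  X <- matrix(NEG, la + 1L, lb + 1L)
  Y <- matrix(NEG, la + 1L, lb + 1L)
  tbM <- matrix(0L, la + 1L, lb + 1L)
  tbX <- matrix(0L, la + 1L, lb + 1L)
  tbY <- matrix(0L, la + 1L, lb + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(la)) X[i + 1L, 1L] <- gap_open + gap_extend * i
  for (j in seq_len(lb)) Y[1L, j + 1L] <- gap_open + gap_extend * j
  tbX[-1L, 1L] <- 1L; tbY[1L, -1L] <- 2L
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      xo <- M[i, j + 1L] + gap_open + gap_extend
      xe <- X[i, j + 1L] + gap_extend
      if (xe > xo) { X[i + 1L, j + 1L] <- xe; tbX[i + 1L, j + 1L] <- 1L }
      else { X[i + 1L, j + 1L] <- xo; tbX[i + 1L, j + 1L] <- 0L }
      yo <- M[i + 1L, j] + gap_open + gap_extend
      ye <- Y[i + 1L, j] + gap_extend
      if (ye > yo) { Y[i + 1L, j + 1L] <- ye; tbY[i + 1L, j + 1L] <- 2L }
      else { Y[i + 1L, j + 1L] <- yo; tbY[i + 1L, j + 1L] <- 0L }
      prev <- c(M[i, j], X[i, j], Y[i, j])
      t <- which.max(prev) - 1L
      M[i + 1L, j + 1L] <- prev[t + 1L] + col_score[i, j]
      tbM[i + 1L, j + 1L] <- t
    }
  }
  finals <- c(M[la + 1L, lb + 1L], X[la + 1L, lb + 1L], Y[la + 1L, lb + 1L])
  state <- which.max(finals) - 1L
  path <- integer(0); i <- la; j <- lb
  while (i > 0L || j > 0L) {
    if (state == 0L) {
      path <- c(path, 1L)
      t <- tbM[i + 1L, j + 1L]
      i <- i - 1L; j <- j - 1L
      state <- t
    } else if (state == 1L) {
      path <- c(path, 2L)
      t <- tbX[i + 1L, j + 1L]
      i <- i - 1L
      state <- if (t == 1L) 1L else 0L
    } else {
      path <- c(path, 3L)
      t <- tbY[i + 1L, j + 1L]
      j <- j - 1L
      state <- if (t == 2L) 2L else 0L
    }
  }
  path <- rev(path)
  out <- matrix("-", nrow(A) + nrow(B), length(path))
  rownames(out) <- c(rownames(A), rownames(B))
  ia <- 0L; jb <- 0L
  ar <- seq_len(nrow(A)); br <- nrow(A) + seq_len(nrow(B))
  for (p in seq_along(path)) {
    t <- path[p]
    if (t != 3L) { ia <- ia + 1L; out[ar, p] <- A[, ia] }
    if (t != 2L) { jb <- jb + 1L; out[br, p] <- B[, jb] }
  }
  out
}

#' Pairwise p-distances of an alignment
#'
#' Proportion of differing sites per pair, with pairwise deletion of gap
#' sites; a pair without any comparable site is an error.
#'
#' @param msa aligned character matrix (rows = taxa) from
#'   [progressive_align()].
#' @return symmetric distance matrix with taxon dimnames.
#' @export
p_distance <- function(msa) {
  n <- nrow(msa)
  taxa <- rownames(msa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      comp <- msa[i, ] != "-" & msa[j, ] != "-"
      if (!any(comp)) {
        stop("no comparable sites between ", taxa[i], " and ", taxa[j])
      }
      d[i, j] <- d[j, i] <- mean(msa[i, comp] != msa[j, comp])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration (Q-matrix joins, standard
#' branch-length formulas). Negative branch lengths are clamped to zero
#' (count recorded in attribute `n_clamped`); ties in the Q matrix are
#' broken deterministically by taxon label order (each cluster is
#' represented by its lexicographically smallest leaf). Returns an
#' unrooted `phylo` tree.
#'
#' @param d symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return an [ape] `phylo` object.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  if (!all(is.finite(d))) stop("distances must be finite")
  if (is.null(rownames(d))) stop("distance matrix needs taxon names")
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs >= 3 taxa")
  clamped <- 0L
  bl <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; x <- 0 }
    sprintf("%.10g", x)
  }
  nodes <- rownames(d)          # newick fragment per active cluster
  leaders <- rownames(d)        # smallest leaf label per cluster
  D <- d
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    minq <- min(Q)
    cand <- which(Q <= minq + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(leaders[cand[, 1]], leaders[cand[, 2]]),
                 pmax(leaders[cand[, 1]], leaders[cand[, 2]]))
    pick <- cand[order(key)[1L], ]
    i <- pick[1]; j <- pick[2]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    newnode <- paste0("(", nodes[i], ":", bl(vi), ",",
                      nodes[j], ":", bl(vj), ")")
    newleader <- min(leaders[i], leaders[j])
    others <- setdiff(seq_len(m), c(i, j))
    nd <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D2 <- D[others, others, drop = FALSE]
    D2 <- rbind(cbind(D2, nd), c(nd, 0))
    nodes <- c(nodes[others], newnode)
    leaders <- c(leaders[others], newleader)
    rownames(D2) <- colnames(D2) <- leaders
    D <- D2
  }
  x <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  y <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  z <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- paste0("(", nodes[1], ":", bl(x), ",", nodes[2], ":", bl(y),
                   ",", nodes[3], ":", bl(z), ");")
  tree <- ape::read.tree(text = newick)
  attr(tree, "n_clamped") <- clamped
  tree
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Columns of the alignment are resampled with replacement; the NJ tree is
#' rebuilt per replicate and each internal edge of the reference tree gets
#' the percentage of replicates containing its bipartition (via
#' `ape::prop.clades`). A replicate whose resampled columns leave some
#' pair without comparable sites is redrawn. Reproducible from `seed`.
#'
#' @param msa aligned character matrix (>= 4 columns).
#' @param replicates bootstrap replicates (default 1000).
#' @param seed optional RNG seed.
#' @return the reference `phylo` tree with supports (percent) as
#'   `node.label` and numeric attribute `supports`.
#' @export
nj_bootstrap <- function(msa, replicates = 1000, seed = NULL) {
  if (ncol(msa) < 4L) stop("alignment must have >= 4 columns")
  if (!is.null(seed)) set.seed(seed)
  ref <- neighbor_joining(p_distance(msa))
  trees <- vector("list", replicates)
  done <- 0L; guard <- 0L
  while (done < replicates && guard < 10L * replicates) {
    guard <- guard + 1L
    cols <- sample.int(ncol(msa), replace = TRUE)
    t <- tryCatch(neighbor_joining(p_distance(msa[, cols, drop = FALSE])),
                  error = function(e) NULL)
    if (!is.null(t)) { done <- done + 1L; trees[[done]] <- t }
  }
  trees <- trees[seq_len(done)]
  class(trees) <- "multiPhylo"
  cnt <- ape::prop.clades(ref, trees, rooted = FALSE)
  supports <- 100 * cnt / done
  ref$node.label <- ifelse(is.na(supports), "",
                           sprintf("%.0f", supports))
  attr(ref, "supports") <- supports
  ref
}

#' Write / read a tree with supports as Newick
#'
#' Thin wrappers over `ape::write.tree` / `ape::read.tree`; bootstrap
#' supports travel as internal node labels.
#'
#' @param tree a `phylo` object.
#' @param path file path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
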