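test_that("progressive alignment handles identity and single indels", {
  set.seed(210)
  s <- random_seq(80)
  msa <- progressive_align(c(a = s, b = s, c = s))
  expect_equal(ncol(msa), 80)
  expect_true(all(msa != "-"))
  # one internal deletion produces one contiguous gap block
  del <- paste0(substr(s, 1, 39), substr(s, 45, 80))
  msa2 <- progressive_align(c(a = s, b = del))
  expect_equal(ncol(msa2), 80)
  gaps <- which(msa2["b", ] == "-")
  expect_length(gaps, 5)
  expect_equal(gaps, seq(min(gaps), min(gaps) + 4))
  # column count never drops below the longest input
  seqs <- setNames(replicate(4, random_seq(sample(60:90, 1))),
                   paste0("s", 1:4))
  expect_gte(ncol(progressive_align(seqs)), max(nchar(seqs)))
  expect_error(progressive_align(c(a = s)), ">= 2")
})

test_that("p-distances use pairwise deletion of gap sites", {
  msa <- rbind(a = c("A", "C", "-", "G"),
               b = c("A", "C", "U", "G"))
  d <- p_distance(msa)
  expect_equal(d["a", "b"], 0)          # 3 comparable sites, all equal
  msa["b", 1] <- "U"
  expect_equal(p_distance(msa)["a", "b"], 1 / 3)
  msa2 <- rbind(a = c("A", "-", "A"), b = c("-", "C", "-"))
  expect_error(p_distance(msa2), "comparable")
  msa3 <- rbind(a = c("A", "C", "G", "U"), b = c("A", "C", "U", "G"))
  expect_equal(p_distance(msa3)["a", "b"], 0.5)
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  d <- matrix(c(0, 2, 4,
                2, 0, 6,
                4, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                      tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], 0)
  expect_equal(bl[["B"]], 2)
  expect_equal(bl[["C"]], 4)
  expect_error(neighbor_joining(d[1:2, 1:2]), ">= 3")
  d[1, 2] <- d[2, 1] <- Inf
  expect_error(neighbor_joining(d), "finite")
})

test_that("NJ recovers generating topologies of additive matrices", {
  set.seed(220)
  for (n in 4:6) {
    for (rep in 1:3) {
      gen <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
      d <- ape::cophenetic.phylo(gen)
      d <- d[sort(rownames(d)), sort(colnames(d))]
      mine <- neighbor_joining(d)
      expect_true(same_topology(mine, gen))
      # exhaustive least-squares enumeration agrees
      ls <- ls_best_topology(d)
      expect_lt(ls$rss, 1e-12)
      expect_true(same_topology(ls$tree, gen))
      # and the reference NJ implementation concurs
      expect_true(same_topology(mine, ape::nj(d)))
    }
  }
})

test_that("NJ clamps negative branch lengths and keeps tie-breaks stable", {
  d <- matrix(c(0, 1, 1, 1,
                1, 0, 1, 1,
                1, 1, 0, 1,
                1, 1, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
  tr2 <- neighbor_joining(d[c(3, 1, 4, 2), c(3, 1, 4, 2)])
  expect_true(same_topology(tr, tr2))
})

test_that("bootstrap supports are 100 for perfectly consistent columns", {
  # every column splits {a,b} from {c,d}: the split must get full support
  msa <- rbind(a = rep("A", 12), b = rep("A", 12),
               c = rep("C", 12), d = rep("C", 12))
  tr <- nj_bootstrap(msa, replicates = 50, seed = 1)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
})

test_that("a planted clade earns high bootstrap support", {
  set.seed(230)
  base <- random_seq(80)
  mutn <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(ch), k)
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "U"), ch[p])[1]
    paste(ch, collapse = "")
  }
  other <- mutn(base, 25)
  seqs <- c(a1 = mutn(base, 1), a2 = mutn(base, 1), a3 = mutn(base, 1),
            a4 = mutn(base, 2),
            b1 = mutn(other, 1), b2 = mutn(other, 1), b3 = mutn(other, 2))
  msa <- progressive_align(seqs)
  tr <- nj_bootstrap(msa, replicates = 200, seed = 2)
  # find the internal edge whose bipartition separates the b clade
  want <- sort(match(c("b1", "b2", "b3"), tr$tip.label))
  wantc <- sort(setdiff(seq_along(tr$tip.label), want))
  pp <- ape::prop.part(tr)
  idx <- which(vapply(pp, function(x)
    identical(sort(x), want) || identical(sort(x), wantc), logical(1)))
  expect_gte(length(idx), 1)
  expect_gte(max(attr(tr, "supports")[idx]), 95)
})

test_that("trees round-trip through Newick with supports intact", {
  set.seed(240)
  seqs <- setNames(replicate(5, random_seq(60)), paste0("t", 1:5))
  tr <- nj_bootstrap(progressive_align(seqs), replicates = 30, seed = 3)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_true(same_topology(tr, back))
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  o1 <- tr$edge.length[order(tr$edge.length)]
  o2 <- back$edge.length[order(back$edge.length)]
  expect_equal(o1, o2, tolerance = 1e-9)
  expect_equal(sort(back$node.label), sort(tr$node.label))
})
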