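test_that("neighbor joining solves the three-taxon case exactly", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(as_distance_matrix(D))
  Dm <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(unname(Dm), unname(D), tolerance = 1e-9)
})

test_that("neighbor joining recovers random additive metrics", {
  skip_if_not_installed("phangorn")
  for (s in 1:12) {
    tm <- random_tree_metric(s, sample(5:12, 1))
    tr <- nj_tree(tm$d)
    expect_equal(phangorn::RF.dist(ape::unroot(tm$tree), ape::unroot(tr)), 0,
                 info = paste("seed", s))
    Dm <- ape::cophenetic.phylo(tr)
    Dm <- Dm[rownames(tm$d$d), colnames(tm$d$d)]
    expect_lt(max(abs(Dm - tm$d$d)), 1e-6)
  }
  expect_error(nj_tree(as_distance_matrix(matrix(0, 2, 2))), "3 taxa")
})

test_that("alignment-set distances separate native and carrier groups", {
  aln <- generate_alignment_set(n_native = 5, n_carrier = 5, n_donor = 1,
                                length = 800, native_carrier_divergence = 0.08,
                                donor_carrier_diffs = 2, seed = 19)
  dm <- distance_matrix(aln)
  tr <- nj_tree(dm)
  # the deepest split puts all natives on one side
  longest <- which.max(tr$edge.length)
  sub <- ape::extract.clade(tr, tr$edge[longest, 2])$tip.label
  groups <- list(sub, setdiff(tr$tip.label, sub))
  natives <- grep("native", tr$tip.label, value = TRUE)
  on_one_side <- vapply(groups, function(gp) {
    all(natives %in% gp) && !any(grepl("carrier|donor", gp))
  }, TRUE)
  expect_true(any(on_one_side))
})

test_that("NeighborNet reproduces tree splits on additive metrics", {
  skip_if_not_installed("phangorn")
  for (s in c(2, 5, 9)) {
    tm <- random_tree_metric(s, 8)
    ss <- neighbornet(tm$d)
    fitted <- split_system_distances(ss)
    expect_lt(max(abs(fitted - tm$d$d)), 1e-6)
    # number of positive splits equals the tree's branch count
    expect_equal(length(ss$splits), 2L * 8L - 3L)
  }
})

test_that("conflicting splits of a box metric are both recovered", {
  # distances generated from trivial splits (weight 1 each) plus the two
  # incompatible splits {a,b} and {b,c} with weights 0.6 and 0.4
  taxa <- c("a", "b", "c", "d")
  splits <- list("a", "b", "c", "d", c("a", "b"), c("b", "c"))
  wts <- c(1, 1, 1, 1, 0.6, 0.4)
  D <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  for (i in 1:3) for (j in (i + 1):4) {
    sep <- vapply(splits, function(sp) {
      xor(taxa[i] %in% sp, taxa[j] %in% sp)
    }, TRUE)
    D[i, j] <- D[j, i] <- sum(wts[sep])
  }
  ss <- neighbornet(as_distance_matrix(D))
  key <- vapply(ss$splits, function(s) paste(sort(ss$taxa[s]), collapse = ","),
                "")
  norm_key <- function(x) {
    # normalize each split to the side not containing taxon d
    vapply(strsplit(x, ","), function(sp) {
      if ("d" %in% sp) paste(sort(setdiff(taxa, sp)), collapse = ",")
      else paste(sort(sp), collapse = ",")
    }, "")
  }
  key <- norm_key(key)
  expect_true("a,b" %in% key)
  expect_true("b,c" %in% key)
  expect_equal(ss$weights[key == "a,b"], 0.6, tolerance = 1e-8)
  expect_equal(ss$weights[key == "b,c"], 0.4, tolerance = 1e-8)
  expect_lt(max(abs(split_system_distances(ss) - D)), 1e-8)
})

test_that("duplicate taxa get no separating split weight", {
  tm <- random_tree_metric(4, 6)
  D <- tm$d$d
  D <- cbind(rbind(D, D[1, ]), c(D[, 1], 0))   # duplicate first taxon
  nm <- c(rownames(tm$d$d), "dup")
  dimnames(D) <- list(nm, nm)
  ss <- neighbornet(as_distance_matrix(D))
  i_dup <- which(ss$taxa == "dup"); i_orig <- 1L
  sep_w <- vapply(seq_along(ss$splits), function(k) {
    s <- ss$splits[[k]]
    if (xor(i_dup %in% s, i_orig %in% s)) ss$weights[k] else 0
  }, 0)
  expect_lt(sum(sep_w), 1e-8)
})

test_that("cluster cohesion separates planted groups and is scale invariant", {
  set.seed(25)
  n <- 10
  D <- matrix(runif(n * n, 0.4, 0.5), n, n)
  D[1:5, 1:5] <- runif(25, 0, 0.02)
  D[6:10, 6:10] <- runif(25, 0, 0.02)
  D <- (D + t(D)) / 2; diag(D) <- 0
  dimnames(D) <- list(paste0("h", 1:n), paste0("h", 1:n))
  lab <- rep(c(TRUE, FALSE), each = 5)
  cc <- cluster_cohesion(as_distance_matrix(D), lab, n_perm = 199, seed = 2)
  expect_gt(cc$score, 0.9)
  expect_lt(cc$p_value, 0.05)
  # rescaling invariance
  cc2 <- cluster_cohesion(as_distance_matrix(10 * D), lab, n_perm = 199,
                          seed = 2)
  expect_equal(cc2$score, cc$score)
  # random labels: score near zero
  set.seed(31)
  Dr <- matrix(runif(n * n, 0.3, 0.5), n, n); Dr <- (Dr + t(Dr)) / 2
  diag(Dr) <- 0; dimnames(Dr) <- dimnames(D)
  ccr <- cluster_cohesion(as_distance_matrix(Dr), lab, n_perm = 199, seed = 3)
  expect_lt(abs(ccr$score), 0.15)
  expect_error(cluster_cohesion(as_distance_matrix(D), rep(TRUE, n)),
               "non-empty")
})

test_that("tree and split exports are readable text", {
  tm <- random_tree_metric(6, 6)
  tr <- nj_tree(tm$d)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  expect_s3_class(ape::read.tree(f), "phylo")
  ss <- neighbornet(tm$d)
  f2 <- withr::local_tempfile(fileext = ".nex")
  write_splits_nexus(ss, f2)
  txt <- readLines(f2)
  expect_true(any(grepl("BEGIN Splits;", txt)))
  expect_equal(sum(grepl("^\\[\\d+, size", txt)), length(ss$splits))
})
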