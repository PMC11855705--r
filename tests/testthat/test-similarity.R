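test_that("edit_distance matches the recursive oracle and known values", {
  expect_identical(edit_distance("ACGT", "ACGT"), 0L)
  expect_identical(edit_distance("AAAA", "CCCC"), 4L)
  expect_identical(edit_distance("A", ""), 1L)
  expect_identical(edit_distance("AC", "ACGT"), 2L)
  strings <- all_strings(c("A", "C"), 3L) # exhaustive at short lengths
  for (a in strings) {
    for (b in strings) {
      expect_identical(edit_distance(a, b), lev_recursive(a, b))
    }
  }
  # longer spot checks against the oracle
  withr::with_seed(5, {
    for (i in 1:25) {
      a <- paste(sample(c("A", "C"), sample(4:6, 1), replace = TRUE), collapse = "")
      b <- paste(sample(c("A", "C"), sample(4:6, 1), replace = TRUE), collapse = "")
      expect_identical(edit_distance(a, b), lev_recursive(a, b))
    }
  })
})

test_that("edit_distance is symmetric and satisfies the triangle inequality", {
  withr::with_seed(11, {
    strs <- replicate(12, paste(sample(c("A", "C", "G", "T"), sample(3:8, 1), replace = TRUE), collapse = ""))
  })
  for (i in seq_along(strs)) {
    for (j in seq_along(strs)) {
      expect_identical(edit_distance(strs[i], strs[j]), edit_distance(strs[j], strs[i]))
      for (k in seq_along(strs)) {
        expect_lte(
          edit_distance(strs[i], strs[k]),
          edit_distance(strs[i], strs[j]) + edit_distance(strs[j], strs[k])
        )
      }
    }
  }
})

test_that("sequence similarity is 1 - trans/(len_i + len_j)", {
  ss <- sequence_similarity_matrix(sequence_set(c("a", "b", "c"), c("AAAA", "CCCC", "AAAA")))
  expect_equal(ss$S[1, 2], 1 - 4 / 8)
  expect_equal(ss$S[1, 3], 1)
  expect_equal(diag(ss$S), setNames(rep(1, 3), c("a", "b", "c")))
  ss2 <- sequence_similarity_matrix(sequence_set(c("x", "y"), c("AC", "ACGT")))
  expect_equal(ss2$S[1, 2], 1 - 2 / 6)
  expect_error(sequence_set(c("x", "y"), c("AC", "")), "empty sequence.*y")
})

test_that("tanimoto handles identity, disjoint support, and the all-zero convention", {
  v <- c(1, 0, 1, 1)
  expect_equal(tanimoto(v, v), 1)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length mismatch")
  expect_warning(z <- tanimoto(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(z, 1)
})

test_that("drug similarity matrix holds all pairwise Tanimoto coefficients", {
  fps <- fingerprint_set(c("d1", "d2", "d3"),
                         rbind(c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 1, 1, 0)))
  sd <- drug_similarity_matrix(fps)
  expect_equal(sd$S[1, 2], 1 / 3)
  expect_equal(sd$S[1, 3], 2 / 3)
  expect_equal(sd$S[2, 3], 2 / 3)
  all_same <- drug_similarity_matrix(fingerprint_set(letters[1:3], matrix(1, 3, 4)))
  expect_equal(unname(all_same$S), matrix(1, 3, 3))
  disjoint <- drug_similarity_matrix(
    fingerprint_set(letters[1:3], rbind(c(1,0,0), c(0,1,0), c(0,0,1)))
  )
  expect_equal(unname(disjoint$S), diag(3))
})

test_that("GIP kernel matches hand computation and basic identities", {
  A <- association_matrix(diag(2), c("c1", "c2"), c("d1", "d2"))
  g <- gip_kernel(A, "circRNA")
  # mean squared profile norm = 1, eta = 1, |IP1 - IP2|^2 = 2
  expect_equal(g$S[1, 2], exp(-2))
  expect_equal(diag(g$S), setNames(c(1, 1), c("c1", "c2")))
  # identical profiles -> similarity exactly 1
  A2 <- association_matrix(rbind(c(1, 0), c(1, 0), c(0, 1)),
                           c("c1", "c2", "c3"), c("d1", "d2"))
  g2 <- gip_kernel(A2, "circRNA")
  expect_equal(g2$S[1, 2], 1)
  # drug axis uses columns; brute-force check
  gd <- gip_kernel(A2, "drug")
  pc <- t(A2$A)
  eta <- 1 / mean(rowSums(pc^2))
  expect_equal(gd$S[1, 2], exp(-eta * sum((pc[1, ] - pc[2, ])^2)))
  # all-zero association matrix: bandwidth undefined
  zero <- association_matrix(matrix(0L, 2, 2), c("a", "b"), c("x", "y"))
  expect_error(gip_kernel(zero, "circRNA"), "bandwidth undefined")
})

test_that("GIP bandwidth scales with eta_prime", {
  A <- association_matrix(diag(3), letters[1:3], LETTERS[1:3])
  g1 <- gip_kernel(A, "circRNA", eta_prime = 1)
  g2 <- gip_kernel(A, "circRNA", eta_prime = 2)
  expect_equal(g2$S[1, 2], g1$S[1, 2]^2) # exp(-2eta d2) = exp(-eta d2)^2
})

test_that("GIP kernels are positive semidefinite on random binary matrices", {
  withr::with_seed(99, {
    for (rep in 1:50) {
      m <- sample(2:30, 1)
      n <- sample(2:30, 1)
      A <- matrix(rbinom(m * n, 1, runif(1, 0.1, 0.6)), m, n)
      if (all(rowSums(A) == 0) || all(colSums(A) == 0)) next
      am <- association_matrix(
        A, sprintf("c%d", 1:m), sprintf("d%d", 1:n)
      )
      axis <- if (rep %% 2 == 0) "circRNA" else "drug"
      if (axis == "circRNA" && all(rowSums(A) == 0)) next
      if (axis == "drug" && all(colSums(A) == 0)) next
      G <- gip_kernel(am, axis)
      expect_gte(min(eigen(G$S, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
    }
  })
})

test_that("fuse_similarity takes the mean where the base is nonzero, else the kernel", {
  ids <- c("a", "b", "c")
  SSm <- matrix(c(1, 0.4, 0, 0.4, 1, 0, 0, 0, 1), 3, 3)
  GSm <- matrix(c(1, 0.6, 0.2, 0.6, 1, 0.8, 0.2, 0.8, 1), 3, 3)
  SS <- similarity_matrix(SSm, ids, "SSC")
  GS <- similarity_matrix(GSm, ids, "GSC")
  fused <- fuse_similarity(SS, GS)
  expect_equal(fused$S[1, 2], 0.5)       # mean branch
  expect_equal(fused$S[1, 3], 0.2)       # zero base -> kernel value
  expect_equal(fused$role, "SC")
  # idempotence when both inputs agree
  same <- fuse_similarity(GS, GS)
  expect_equal(same$S, GS$S)
  # reduces to GS when the base is zero off-diagonal
  Z <- similarity_matrix(diag(3), ids, "SSC")
  red <- fuse_similarity(Z, GS)
  off <- upper.tri(GSm)
  expect_equal(red$S[off], GSm[off])
  expect_error(fuse_similarity(SS, similarity_matrix(diag(2), c("a", "b"), "GSC")),
               "shape and id ordering")
})

test_that("similarity matrices satisfy symmetry, range, and unit diagonal", {
  fx <- tiny_sim_fixture(3L)
  mats <- list(
    sequence_similarity_matrix(fx$sim$seqs),
    drug_similarity_matrix(fx$sim$fps),
    gip_kernel(fx$sim$assoc, "circRNA"),
    gip_kernel(fx$sim$assoc, "drug"),
    fx$sims$SC,
    fx$sims$SD
  )
  for (m in mats) {
    expect_lt(max(abs(m$S - t(m$S))), 1e-9)
    expect_gte(min(m$S), 0)
    expect_lte(max(m$S), 1)
    expect_equal(max(abs(diag(m$S) - 1)), 0)
  }
})

test_that("permuting input order permutes similarity rows and columns consistently", {
  fx <- tiny_sim_fixture(8L, n_circ = 10L, n_drug = 8L)
  seqs <- fx$sim$seqs
  perm <- withr::with_seed(1, sample(length(seqs$ids)))
  seqs_p <- sequence_set(seqs$ids[perm], seqs$seqs[perm])
  S <- sequence_similarity_matrix(seqs)$S
  Sp <- sequence_similarity_matrix(seqs_p)$S
  expect_equal(unname(Sp), unname(S[perm, perm]))
  # same equivariance for the GIP kernel under row permutation of A
  A <- fx$sim$assoc
  Ap <- association_matrix(A$A[perm, ], A$circ_ids[perm], A$drug_ids)
  expect_equal(unname(gip_kernel(Ap, "circRNA")$S),
               unname(gip_kernel(A, "circRNA")$S[perm, perm]))
})
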