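test_that("alignment splitting partitions sequences by group", {
  aln <- c(s1 = "ACD", s2 = "ACE", s3 = "GHD", s4 = "GHE")
  gm <- data.frame(sequence_id = paste0("s", 1:4),
                   group = c("x", "x", "y", "y"))
  g <- split_alignment(aln, gm)
  expect_equal(nrow(g$a), 2)
  expect_equal(nrow(g$b), 2)
  expect_equal(ncol(g$a), 3)

  gm_bad <- gm[1:3, ]
  expect_error(split_alignment(aln, gm_bad), "s4")

  g2 <- split_alignment(aln, gm, region = c(2, 3))
  expect_equal(ncol(g2$a), 2)
  expect_equal(g2$offset, 2L)
})

test_that("column frequencies count residues, skip gaps, and smooth", {
  f <- column_frequencies(c("A", "A", "A", "A"))
  expect_equal(unname(f["A"]), 1)
  expect_equal(sum(f), 1)

  f2 <- column_frequencies(c("A", "A", "G", "-"))
  expect_equal(unname(f2["A"]), 2 / 3)
  expect_equal(unname(f2["G"]), 1 / 3)

  # pseudocount formula for an unobserved residue
  eps <- 0.37; n <- 4
  f3 <- column_frequencies(c("A", "A", "G", "C"), pseudocount = eps)
  expect_equal(unname(f3["W"]), eps / (n + 20 * eps), tolerance = 1e-12)
  expect_equal(sum(f3), 1, tolerance = 1e-12)

  expect_true(all(is.na(column_frequencies(c("-", "-")))))
})

test_that("KL divergence satisfies its defining identities", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(kl_divergence(p, p), 0)
  # (1,0) vs (0.5,0.5) without smoothing evaluates to ln 2
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  # asymmetric in general
  q <- c(0.5, 0.25, 0.25)
  expect_false(isTRUE(all.equal(kl_divergence(p, q), kl_divergence(q, p))))
  expect_gte(kl_divergence(p, q), 0)
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "pseudocount")
  expect_error(kl_divergence(c(0.9, 0.2), c(0.5, 0.5)), "sum to 1")
})

test_that("planted column classes are ranked as the contract demands", {
  sim <- simulate_alignment(n_a = 10, n_b = 10, seed = 31)
  g <- split_alignment(sim$alignment, sim$group_map)
  prof <- kldiv_profile(g)
  expect_equal(nrow(prof), length(sim$classes))
  expect_true(all(prof$kldiv >= 0))

  cls <- split(prof$kldiv, sim$classes)
  # conserved-different columns outrank every other column
  expect_gt(min(cls$conserved_different), max(cls$conserved_same))
  expect_gt(min(cls$conserved_different), max(cls$one_variable))
  expect_gt(min(cls$conserved_different), max(cls$both_variable))
  # identically conserved columns score near zero
  expect_lt(max(cls$conserved_same), 0.05)
  # one-conserved columns sit between
  expect_gt(mean(cls$one_variable), mean(cls$conserved_same))
})

test_that("uniformly random columns score near zero for large groups", {
  sim <- simulate_alignment(n_a = 400, n_b = 400,
                            classes = rep("both_variable", 30), seed = 32)
  g <- split_alignment(sim$alignment, sim$group_map)
  prof <- kldiv_profile(g)
  expect_lt(mean(prof$kldiv), 0.1)
})

test_that("profiles are invariant to sequence order and to duplication", {
  sim <- simulate_alignment(n_a = 6, n_b = 6, seed = 33)
  g <- split_alignment(sim$alignment, sim$group_map)
  base <- kldiv_profile(g, pseudocount = 0.25)

  # permute sequences within groups
  gp <- g
  gp$a <- gp$a[sample(nrow(gp$a)), , drop = FALSE]
  gp$b <- gp$b[rev(seq_len(nrow(gp$b))), , drop = FALSE]
  expect_equal(kldiv_profile(gp, pseudocount = 0.25)$kldiv, base$kldiv,
               tolerance = 1e-12)

  # duplicate every sequence of a group, scaling the pseudocount with it
  gd <- g
  gd$a <- rbind(gd$a, gd$a)
  half <- kldiv_profile(g, pseudocount = 0.25)
  dbl <- kldiv_profile(gd, pseudocount = 0.5)
  # group b unchanged: its frequencies must use the same eps for equality
  fa_half <- attr(half, "freq_a"); fa_dbl <- attr(dbl, "freq_a")
  expect_equal(fa_dbl, fa_half, tolerance = 1e-12)
})

test_that("KL direction switch and symmetric variant behave as documented", {
  sim <- simulate_alignment(n_a = 5, n_b = 9, seed = 34)
  g <- split_alignment(sim$alignment, sim$group_map)
  ba <- kldiv_profile(g, direction = "b_vs_a")
  ab <- kldiv_profile(g, direction = "a_vs_b")
  js <- kldiv_profile(g, direction = "symmetric")
  expect_false(isTRUE(all.equal(ba$kldiv, ab$kldiv)))
  expect_true(all(js$kldiv >= 0 & js$kldiv <= log(2) + 1e-12))
  expect_equal(attr(ba, "direction"), "b_vs_a")
})

test_that("gap-dominated columns are flagged and reference mapping counts residues", {
  aln <- c(r1 = "M-KL", r2 = "M-KL", t1 = "MAK-", t2 = "M-KV")
  gm <- data.frame(sequence_id = c("r1", "r2", "t1", "t2"),
                   group = c("g1", "g1", "g2", "g2"))
  prof <- kldiv_profile(split_alignment(aln, gm), reference = "t1")
  expect_equal(prof$flag[2], "all_gap")
  expect_true(is.na(prof$kldiv[2]))
  # t1 = M A K - : residue numbers 1,2,3 then gap
  expect_equal(prof$ref_residue, c(1L, 2L, 3L, NA))
})
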