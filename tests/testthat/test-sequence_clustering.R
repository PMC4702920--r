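test_that("identity is counted over the shorter sequence with free end gaps", {
  a <- global_align("ACDEFGHIKL", "ACDEFGHIKL")
  expect_equal(a$identity, 1.0)
  expect_equal(nrow(a$matched), 10)

  expect_equal(global_align("ACDEFGHIKL", "ACDEFGHIKV")$identity, 0.9)

  # N-terminal extension costs nothing: 6 matched pairs over min length 6
  a <- global_align("ACDEFG", "XXACDEFG")
  expect_equal(nrow(a$matched), 6)
  expect_equal(a$identity, 1.0)
  expect_equal(a$matched$i, 1:6)
  expect_equal(a$matched$j, 3:8)

  # X never counts as a match even against X
  expect_equal(global_align("AXXG", "AXXG")$identity, 0.5)
  expect_error(global_align("", "ACD"), "non-empty")
})

test_that("identity is symmetric and matched pairs never cross", {
  set.seed(5)
  for (k in 1:8) {
    a <- paste(random_aa(sample(30:60, 1), k), collapse = "")
    b <- paste(random_aa(sample(30:60, 1), k + 100), collapse = "")
    ab <- global_align(a, b); ba <- global_align(b, a)
    expect_equal(ab$identity, ba$identity)
    if (nrow(ab$matched) > 1) {
      expect_true(all(diff(ab$matched$i) > 0))
      expect_true(all(diff(ab$matched$j) > 0))
    }
  }
})

test_that("restrict_to_resolved drops pairs with unresolved partners", {
  a <- global_align("ACDEFGHIKL", "ACDEFGHIKL")
  all_true <- rep(TRUE, 10)
  expect_equal(restrict_to_resolved(a, all_true, all_true)$matched, a$matched)

  mb <- all_true; mb[4] <- FALSE
  r <- restrict_to_resolved(a, all_true, mb)
  expect_equal(nrow(r$matched), 9)
  expect_false(4 %in% r$matched$j)
  expect_equal(r$identity, 1.0)           # 9 matches over min resolved 9

  r0 <- restrict_to_resolved(a, rep(FALSE, 10), all_true)
  expect_equal(nrow(r0$matched), 0)
  expect_error(restrict_to_resolved(a, rep(TRUE, 9), all_true),
               "mask length mismatch")
})

test_that("chains cluster by 95% identity against the founding representative", {
  base <- random_aa(100, 1)
  mutate <- function(aa, k) {
    aa2 <- aa
    pos <- seq(3, by = 7, length.out = k)
    for (p in pos) aa2[p] <- setdiff(c("A", "G", "V", "L"), aa2[p])[1]
    aa2
  }
  rec <- function(id, aa) toy_chain(id, aa)
  near <- rec("nearA", mutate(base, 4))    # 96% identity to base
  far  <- rec("far_A", mutate(base, 6))    # 94% identity to base
  ref  <- rec("baseA", base)
  other <- rec("othrA", random_aa(80, 99))

  cls <- cluster_chains(list(ref, near, far, other))
  sizes <- sort(vapply(cls, function(c) length(c$members), 0L))
  expect_equal(sizes, c(1L, 1L, 2L))
  with_ref <- cls[[which(vapply(cls, function(c) "baseA" %in% names(c$members), NA))]]
  expect_setequal(names(with_ref$members), c("baseA", "nearA"))
})

test_that("two identical chains and one unrelated chain form two clusters", {
  a1 <- toy_chain("dup1A", random_aa(50, 2))
  a2 <- toy_chain("dup2A", random_aa(50, 2))
  u  <- toy_chain("unrlA", random_aa(50, 77))
  cls <- cluster_chains(list(a1, a2, u))
  expect_length(cls, 2)
  expect_setequal(vapply(cls, function(c) length(c$members), 0L), c(2L, 1L))
})

test_that("analyzability needs more than 3 members", {
  three <- make_cluster_fixture(c(0, 10, 20), n_res = 20)
  four  <- make_cluster_fixture(c(0, 10, 20, 30), n_res = 20)
  expect_false(cluster_chains(three)[[1]]$analyzable)
  expect_true(cluster_chains(four)[[1]]$analyzable)
  cl3 <- cluster_chains(three)[[1]]
  expect_error(summarize_cluster(cl3, pairwise_rmsd_matrix(cl3)),
               "not analyzable")
})

test_that("clustering is invariant to input order", {
  set.seed(9)
  base <- random_aa(60, 3)
  recs <- c(make_cluster_fixture(c(0, 5, 10, 15), n_res = 30),
            list(toy_chain("solo1", base), toy_chain("solo2", random_aa(40, 4))))
  sig <- function(cls) {
    m <- lapply(cls, function(c) sort(names(c$members)))
    m[order(vapply(m, `[`, "", 1))]
  }
  ref <- sig(cluster_chains(recs))
  for (k in 1:3) {
    expect_equal(sig(cluster_chains(sample(recs))), ref)
  }
})

test_that("the master is the longest, then most complete, then smallest id", {
  mk <- function(id, n, resolved = rep(TRUE, n))
    toy_chain(id, random_aa(n, 10), resolved)
  cl <- structure(list(members = setNames(
    list(mk("aaa1A", 100), mk("aaa2A", 120), mk("aaa3A", 110)),
    c("aaa1A", "aaa2A", "aaa3A"))), class = "flex_cluster")
  expect_equal(select_master(cl), "aaa2A")

  r90 <- c(rep(TRUE, 90), rep(FALSE, 10))
  r95 <- c(rep(TRUE, 95), rep(FALSE, 5))
  cl <- structure(list(members = setNames(
    list(mk("bbb1A", 100, r90), mk("bbb2A", 100, r95)),
    c("bbb1A", "bbb2A"))), class = "flex_cluster")
  expect_equal(select_master(cl), "bbb2A")

  cl <- structure(list(members = list(soloA = mk("soloA", 30))),
                  class = "flex_cluster")
  expect_equal(select_master(cl), "soloA")
})

test_that("msMSA maps members onto master positions, gapping what is not comparable", {
  # identical fully resolved chains -> identity mapping everywhere
  recs <- make_cluster_fixture(c(0, 0, 0, 0), n_res = 20)
  cl <- build_msmsa(cluster_chains(recs)[[1]])
  for (id in colnames(cl$msa)) expect_equal(cl$msa[, id], 1:40)

  # unresolved loop 15-18 in one member -> those master columns gapped for it
  recs <- make_cluster_fixture(c(0, 0, 0, 0), n_res = 20,
                               mask = list("3" = c(15, 18)))
  cl <- build_msmsa(cluster_chains(recs)[[1]])
  expect_true(all(is.na(cl$msa[15:18, "hg03A"])))
  expect_equal(cl$msa[c(1:14, 19:40), "hg03A"], c(1:14, 19:40))

  # N-terminal truncation -> leading master columns gapped for that member
  full <- make_hinge_conformer(25, 0, source_id = "fullA")
  tr <- chain_record("truncA", full$aa[11:50], full$xyz[11:50, ])
  cl <- structure(list(members = list(fullA = full, truncA = tr),
                       master_id = "fullA", analyzable = FALSE, msa = NULL),
                  class = "flex_cluster")
  cl <- build_msmsa(cl)
  expect_true(all(is.na(cl$msa[1:10, "truncA"])))
  expect_equal(cl$msa[11:50, "truncA"], 1:40)
})

test_that("master-member mapping composed with its inverse is the identity", {
  recs <- make_cluster_fixture(c(0, 20, 40, 60), n_res = 25, noise_sigma = 0.2,
                               mask = list("2" = c(10, 14), "4" = c(30, 33)))
  cl <- build_msmsa(cluster_chains(recs)[[1]])
  master <- cl$members[[cl$master_id]]
  for (id in names(cl$members)) {
    fwd <- cl$msa[, id]                       # master pos -> member pos
    back <- align_chains(cl$members[[id]], master)  # member -> master
    inv <- rep(NA_integer_, length(cl$members[[id]]$aa))
    inv[back$matched$i] <- back$matched$j
    shared <- which(!is.na(fwd))
    expect_equal(inv[fwd[shared]], shared)
  }
})

test_that("match_sequence ranks ingested chains by identity above the floor", {
  recs <- list(toy_chain("abcdA", random_aa(50, 21)),
               toy_chain("wxyzA", random_aa(50, 22)))
  names(recs) <- c("abcdA", "wxyzA")
  hits <- match_sequence(recs$abcdA$sequence, recs)
  expect_equal(hits$source_id[1], "abcdA")
  expect_equal(hits$identity[1], 1.0)

  none <- match_sequence(paste(rep("W", 40), collapse = ""), recs, floor = 0.3)
  expect_equal(nrow(none), 0)

  # equal-identity hits come out in lexicographic order
  dup <- list(toy_chain("bbbbA", random_aa(30, 23)),
              toy_chain("aaaaA", random_aa(30, 23)))
  hits <- match_sequence(dup[[1]]$sequence, dup)
  expect_equal(hits$source_id, c("aaaaA", "bbbbA"))
  expect_error(match_sequence("", recs), "empty query")
})
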