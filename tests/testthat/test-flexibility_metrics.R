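test_that("a member identical to the master has an all-zero local track", {
  m <- make_hinge_conformer(20, 0)
  s <- make_hinge_conformer(20, 0, source_id = "hng1A")
  tr <- local_rmsd_track(m, s)
  expect_true(all(!is.na(tr)))
  expect_true(all(tr < 1e-9))
})

test_that("a pure hinge rotation peaks only in windows straddling the hinge", {
  n <- 30
  m <- make_hinge_conformer(n, 0)
  s <- make_hinge_conformer(n, 50, source_id = "hng1A")
  cfg <- profile_config(window = 10)
  tr <- local_rmsd_track(m, s, cfg = cfg)
  # windows fully inside either rigid domain superpose exactly
  inside1 <- 1:(n - 9)              # windows [1..n-9] end before the hinge
  inside2 <- (n + 10):(2 * n - 9)   # positions covered only by domain-2 windows
  expect_true(all(tr[inside1] < 1e-9))
  expect_true(all(tr[inside2] < 1e-9))
  straddle <- (n - 3):(n + 4)       # positions seen mostly by hinge-spanning windows
  expect_true(all(tr[straddle] > 0.1))
  # direct recomputation oracle for one hinge-spanning window
  w <- (n - 4):(n + 5)
  expected <- kabsch_superpose(m$xyz[w, ], s$xyz[w, ])$rmsd
  covering <- lapply((n - 4):(n - 4), function(s0) s0:(s0 + 9))
  expect_gt(expected, 0.1)
  # position n-4 + 9 = n+5 is covered only by windows overlapping the hinge;
  # check the mean-over-windows rule at a position covered by one window
  one_window_pos <- 1
  expect_equal(tr[one_window_pos],
               kabsch_superpose(m$xyz[1:10, ], s$xyz[1:10, ])$rmsd,
               tolerance = 1e-12)
})

test_that("unresolved member residues knock out the affected windows", {
  n_res <- 40
  recs <- make_cluster_fixture(c(0, 0), n_res = n_res,
                               mask = list("2" = c(50, 55)))
  m <- recs$hg01A; s <- recs$hg02A
  tr <- local_rmsd_track(m, s, cfg = profile_config(window = 10))
  expect_true(all(is.na(tr[50:55])))
  # positions reachable only through windows touching 50-55 are undefined too:
  # defined positions are those covered by a complete window avoiding 50-55
  defined <- rep(FALSE, 2 * n_res)
  for (s0 in 1:(2 * n_res - 9)) {
    idx <- s0:(s0 + 9)
    if (!any(idx %in% 50:55)) defined[idx] <- TRUE
  }
  expect_equal(!is.na(tr), defined)
})

test_that("average profile is the member mean with undefined handling", {
  tracks <- cbind(m1 = c(1, 1, NA), m2 = c(3, 3, 4))
  cl <- structure(list(members = list(), master_id = "xA"),
                  class = "flex_cluster")
  prof <- average_profile(cl, tracks = tracks)
  expect_equal(unname(prof$mean_local_rmsd), c(2, 2, 4))
  expect_equal(unname(prof$n_contributing), c(2L, 2L, 1L))

  prof2 <- average_profile(cl, tracks = tracks,
                           cfg = profile_config(min_members_per_window = 2))
  expect_true(is.na(prof2$mean_local_rmsd[3]))

  # all members identical to the master -> all-zero profile
  recs <- make_cluster_fixture(c(0, 0, 0, 0), n_res = 20)
  cl <- build_msmsa(cluster_chains(recs)[[1]])
  prof3 <- average_profile(cl)
  expect_true(all(prof3$mean_local_rmsd < 1e-9, na.rm = TRUE))
  expect_equal(ncol(prof3$member_tracks), 3)   # master excluded
})

test_that("difference distance maps vanish under rigid motion and antisymmetrize", {
  a <- make_hinge_conformer(20, 30)
  b_xyz <- apply_rigid(a$xyz, rotation_from_angles(0.4, 1.1, 2.2), c(5, -3, 8))
  b <- chain_record("hng1A", a$aa, b_xyz)
  set.seed(12)
  expect_lt(max(abs(difference_distance_map(a, b)$values)), 1e-8)

  c_ <- make_hinge_conformer(20, 60, source_id = "hng2A")
  d_ac <- difference_distance_map(a, c_)
  d_ca <- difference_distance_map(c_, a)
  expect_equal(d_ac$values, -d_ca$values)
  expect_true(all(diag(d_ac$values) == 0))
})

test_that("hinge DDM has near-zero domain blocks and a nonzero cross block", {
  n <- 20
  a <- make_hinge_conformer(n, 0)
  b <- make_hinge_conformer(n, 60, source_id = "hng1A")
  v <- difference_distance_map(a, b)$values
  dom1 <- 1:n; dom2 <- (n + 1):(2 * n)
  expect_lt(max(abs(v[dom1, dom1])), 1e-9)
  expect_lt(max(abs(v[dom2, dom2])), 1e-9)
  expect_gt(max(abs(v[dom1, dom2])), 1.0)
})

test_that("contact map overlap is 1 on self, symmetric, in [0,1], and matches a set oracle", {
  a <- make_hinge_conformer(25, 0)
  b <- make_hinge_conformer(25, 55, source_id = "hng1A")
  cfg <- contact_config()
  expect_equal(contact_map_overlap(a, a, cfg = cfg), 1.0)

  cab <- contact_map_overlap(a, b, cfg = cfg)
  cba <- contact_map_overlap(b, a, cfg = cfg)
  expect_equal(cab, cba)
  expect_gte(cab, 0); expect_lt(cab, 1)

  # brute-force set-arithmetic oracle over explicit contact pair lists
  contacts <- function(x) {
    out <- character(0)
    n <- nrow(x$xyz)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (j - i >= cfg$min_seq_sep &&
          sqrt(sum((x$xyz[i, ] - x$xyz[j, ])^2)) <= cfg$cutoff)
        out <- c(out, paste(i, j))
    }
    out
  }
  ca <- contacts(a); cb <- contacts(b)
  expect_equal(cab, 2 * length(intersect(ca, cb)) / (length(ca) + length(cb)))
})

test_that("cluster summaries classify flexibility by maximum RMSD", {
  expect_equal(classify_flexibility(0.3), "rigid")
  expect_equal(classify_flexibility(1.5), "intermediate")
  expect_equal(classify_flexibility(4.29), "flexible")
  expect_equal(classify_flexibility(0.5), "intermediate")  # boundaries inclusive
  expect_equal(classify_flexibility(3.0), "intermediate")

  recs <- make_cluster_fixture(c(0, 15, 30, 60), n_res = 15)
  cl <- build_msmsa(cluster_chains(recs)[[1]])
  rm_ <- pairwise_rmsd_matrix(cl)
  summ <- summarize_cluster(cl, rm_)
  expect_equal(summ$size, 4)
  expect_equal(summ$max_rmsd, rm_$max_rmsd)
  expect_equal(summ$most_dissimilar_pair, rm_$most_dissimilar)
  expect_true(summ$min_cmo <= summ$avg_cmo && summ$avg_cmo <= 1)
  expect_gte(summ$min_cmo, 0)
  expect_equal(summ$flexibility_class, classify_flexibility(rm_$max_rmsd))
})

test_that("members are ranked by the peak of their local track", {
  recs <- make_cluster_fixture(c(0, 5, 40), n_res = 20)
  cl <- structure(list(members = recs, master_id = "hg01A",
                       analyzable = TRUE, msa = NULL), class = "flex_cluster")
  prof <- average_profile(cl)
  expect_equal(top_diverse_members(prof, top = 2)[1], "hg03A")
  expect_equal(top_diverse_members(prof, top = 1), "hg03A")
})
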