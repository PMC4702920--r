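test_that("a minimal one-chain PDB parses into a fully resolved record", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f, list(A = list(seqres = c("MET", "ALA", "GLY"),
                                  ca = helix_ca(1:3, c("MET", "ALA", "GLY")))))
  recs <- read_chain_records(f)
  expect_length(recs, 1)
  r <- recs[[1]]
  expect_equal(length(r$aa), 3)
  expect_equal(r$sequence, "MAG")
  expect_true(all(r$resolved))
})

test_that("SEQRES residues without ATOM coordinates come out unresolved", {
  f <- withr::local_tempfile(fileext = ".pdb")
  sr <- c("MET", "ALA", "GLY", "CYS", "LYS")
  ca <- helix_ca(1:5, sr)[c(1, 2, 4, 5), ]
  write_mini_pdb(f, list(A = list(seqres = sr, ca = ca)))
  r <- read_chain_records(f)[[1]]
  expect_equal(r$resolved, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(disorder_segments(r), data.frame(start = 3L, end = 3L))
  expect_true(all(is.na(r$xyz[3, ])))
})

test_that("files with several chains yield one record per chain with suffixed ids", {
  f <- withr::local_tempfile(pattern = "twoc", fileext = ".pdb")
  write_mini_pdb(f, list(A = list(seqres = rep("ALA", 4), ca = helix_ca(1:4)),
                         B = list(seqres = rep("GLY", 4),
                                  ca = helix_ca(1:4, rep("GLY", 4)))))
  recs <- read_chain_records(f)
  expect_length(recs, 2)
  ids <- vapply(recs, `[[`, "", "source_id")
  expect_true(all(endsWith(ids, c("A", "B"))))
  expect_equal(recs[[2]]$sequence, "GGGG")
})

test_that("non-PDB text is rejected naming the offending line", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("this is not a pdb file", "at all"), f)
  expect_error(read_chain_records(f), "not a pdb file")
})

test_that("PDB round trip preserves sequence, resolved mask and coordinates", {
  for (seed in 1:3) {
    aa <- random_aa(40, seed)
    resolved <- rep(TRUE, 40)
    resolved[sample(40, 6)] <- FALSE
    rec <- toy_chain(sprintf("rt%02dA", seed), aa, resolved)
    f <- withr::local_tempfile(fileext = ".pdb")
    write_chain_pdb(rec, f)
    back <- read_chain_records(f)[[1]]
    expect_equal(back$sequence, rec$sequence)
    expect_equal(back$resolved, rec$resolved)
    expect_lt(max(abs(back$xyz - rec$xyz), na.rm = TRUE), 1e-3)
  }
})

test_that("quality filters keep exactly the chains passing all three rules", {
  cfg <- quality_filter_config()
  # boundary: exactly 25 residues is too short, 26 is kept
  short  <- toy_chain("aaaaA", random_aa(25, 1))
  barely <- toy_chain("bbbbA", random_aa(26, 2))
  out <- apply_quality_filters(list(short, barely), cfg)
  expect_equal(names(out$kept), "bbbbA")
  expect_equal(out$rejected$reason, "too_short")

  # a run of 21 unknowns rejects; 20 passes
  aa21 <- random_aa(300, 3); aa21[100:120] <- "X"
  aa20 <- random_aa(300, 4); aa20[100:119] <- "X"
  out <- apply_quality_filters(list(toy_chain("ccccA", aa21),
                                    toy_chain("ddddA", aa20)), cfg)
  expect_equal(names(out$kept), "ddddA")
  expect_equal(out$rejected$reason, "unknown_run")

  # 26 resolved C-alphas kept, 25 rejected
  res26 <- c(rep(TRUE, 26), rep(FALSE, 74))
  res25 <- c(rep(TRUE, 25), rep(FALSE, 75))
  out <- apply_quality_filters(list(toy_chain("eeeeA", random_aa(100, 5), res26),
                                    toy_chain("ffffA", random_aa(100, 6), res25)),
                               cfg)
  expect_equal(names(out$kept), "eeeeA")
  expect_equal(out$rejected$reason, "too_few_ca")

  expect_equal(apply_quality_filters(list(), cfg)$kept, list())
})

test_that("tightening any filter threshold never enlarges the kept set", {
  set.seed(42)
  pool <- lapply(1:12, function(k) {
    n <- sample(20:60, 1)
    aa <- random_aa(n, k)
    if (runif(1) < 0.5) aa[seq(5, min(n, 5 + sample(15:25, 1)))] <- "X"
    resolved <- runif(n) > 0.2
    toy_chain(sprintf("mc%02dA", k), aa, resolved)
  })
  base <- quality_filter_config(min_residues = 22, max_unknown_run = 18,
                                min_ca = 15)
  kept0 <- names(apply_quality_filters(pool, base)$kept)
  tighter <- list(quality_filter_config(30, 18, 15),
                  quality_filter_config(22, 10, 15),
                  quality_filter_config(22, 18, 25))
  for (cfg in tighter) {
    kept1 <- names(apply_quality_filters(pool, cfg)$kept)
    expect_true(all(kept1 %in% kept0))
  }
})

test_that("disorder segments exactly tile the unresolved complement", {
  r <- toy_chain("tileA", random_aa(5, 7), c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(disorder_segments(r), data.frame(start = c(1L, 5L), end = c(2L, 5L)))
  expect_equal(nrow(disorder_segments(toy_chain("fullA", random_aa(6, 8)))), 0)
  allf <- chain_record("noneA", random_aa(4, 9), matrix(NA_real_, 4, 3))
  expect_equal(disorder_segments(allf), data.frame(start = 1L, end = 4L))

  set.seed(11)
  for (k in 1:10) {
    mask <- runif(30) > 0.4
    if (!any(mask)) mask[1] <- TRUE
    r <- toy_chain("rndtA", random_aa(30, 20 + k), mask)
    segs <- disorder_segments(r)
    covered <- unlist(apply(segs, 1, function(s) s[1]:s[2], simplify = FALSE))
    expect_setequal(covered, which(!mask))
    if (nrow(segs) > 1) expect_true(all(diff(segs$start) > 0))
  }
})

test_that("chain JSON serialization round-trips records", {
  recs <- make_cluster_fixture(c(0, 30), n_res = 15,
                               mask = list("2" = c(5, 8)))
  f <- withr::local_tempfile(fileext = ".json")
  write_chains_json(recs, f)
  back <- read_chains_json(f)
  expect_equal(names(back), names(recs))
  expect_equal(back[[2]]$resolved, recs[[2]]$resolved)
  expect_equal(back[[1]]$xyz, recs[[1]]$xyz, tolerance = 1e-8)
})

test_that("secondary-structure labels attach and unresolved positions force D", {
  r <- toy_chain("sslbA", random_aa(6, 30), c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  r <- set_ss_labels(r, c("H", "H", "L", "E", "E", "L"))
  expect_equal(r$ss, c("H", "H", "D", "E", "E", "L"))
  expect_error(set_ss_labels(r, rep("Q", 6)), "invalid ss label")
})
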