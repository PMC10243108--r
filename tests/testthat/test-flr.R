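# prefix re-computation oracle for the decoy FLR
brute_flr <- function(decoy_flag, ratio) {
  n <- length(decoy_flag)
  run <- numeric(n)
  for (i in seq_len(n)) {
    D <- sum(decoy_flag[seq_len(i)])
    run[i] <- if (D == 0) 0 else if (i - D == 0) 1 else min(1, D * ratio / (i - D))
  }
  q <- run
  for (i in rev(seq_len(n - 1))) q[i] <- min(q[i], q[i + 1])
  list(running = run, q = q)
}

test_that("conservative flagging marks every site of a decoy-bearing PSM", {
  r <- make_records(psm_rows("p1", "SATYK", c(1, 2, 4), c(0.9, 0.2, 0.8)))
  expect_true(all(mark_conservative_decoys(r)$decoy_flag))
  r2 <- make_records(psm_rows("p1", "SVTYK", c(1, 3), c(0.9, 0.8)))
  expect_false(any(mark_conservative_decoys(r2)$decoy_flag))
  # per-PSM scope: only the decoy-bearing PSM of a peptidoform is flagged
  r3 <- make_records(
    psm_rows("p1", "SATYK", c(1, 2), c(0.9, 0.1)),
    psm_rows("p2", "SATYK", 1, 0.8)
  )
  f <- mark_conservative_decoys(r3)
  expect_true(all(f$decoy_flag[f$psm_id == "p1"]))
  expect_false(any(f$decoy_flag[f$psm_id == "p2"]))
})

test_that("ranking is score-descending with alphabetical residue-blind ties", {
  r <- make_records(
    psm_rows("p1", "CCSK", 3, 0.9, protein = "P2"),
    psm_rows("p2", "AASK", 3, 0.9),
    psm_rows("p3", "TTTK", 1, 0.95, protein = "P3")
  )
  ranked <- rank_sites(r)
  expect_equal(ranked$peptide, c("TTTK", "AASK", "CCSK"))
  # permutation invariance
  set.seed(3)
  for (i in 1:5) {
    perm <- r[sample.int(nrow(r)), ]
    expect_equal(rank_sites(perm)$psm_id, ranked$psm_id)
  }
})

test_that("residue counting yields T, A and their ratio", {
  cnt <- count_residues("STAY")
  expect_equal(cnt$T, 3)
  expect_equal(cnt$A, 1)
  expect_equal(cnt$ratio, 3)
  expect_error(count_residues("STYSTY"), "no decoy residues")
  # over records: unique peptides only
  r <- make_records(psm_rows("p1", "SSTAYK", 1, 0.9),
                    psm_rows("p2", "SSTAYK", 1, 0.8))
  expect_equal(count_residues(r)$T, 4)
  expect_equal(count_residues(r)$A, 1)
  # FASTA route
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">p1 test protein", "MKSTAYSTA", ">p2", "GGSSA"), fa)
  cfa <- count_residues(fa)   # p1: S2 T2 Y1 A2; p2: S2 A1
  expect_equal(cfa$T, 7)
  expect_equal(cfa$A, 3)
})

test_that("decoy FLR follows the reconstructed formula with decoys removed", {
  # 10 ranked sites, conservative decoys at ranks 4 and 9, T/A = 2
  flag <- rep(FALSE, 10)
  flag[c(4, 9)] <- TRUE
  ranked <- data.frame(peptide = letters[1:10], site_pos = 1:10,
                       score = seq(1, 0.1, length.out = 10),
                       decoy_flag = flag, is_decoy_site = flag)
  out <- compute_decoy_flr(ranked, T = 2, A = 1)
  expect_equal(out$running_flr[10], (2 * 2) / (10 - 2))
  oracle <- brute_flr(flag, 2)
  expect_equal(out$running_flr, oracle$running)
  expect_equal(out$q_flr, oracle$q)

  # no decoys anywhere: FLR identically zero
  none <- ranked
  none$decoy_flag <- none$is_decoy_site <- FALSE
  expect_true(all(compute_decoy_flr(none, 2, 1)$running_flr == 0))

  # all-decoy prefix pins the running FLR at 1
  all_first <- ranked
  all_first$decoy_flag <- c(TRUE, TRUE, rep(FALSE, 8))
  expect_equal(compute_decoy_flr(all_first, 2, 1)$running_flr[1:2], c(1, 1))

  # Gold-class arithmetic pattern: 5 decoys, ratio 2.262, 2090 targets
  expect_equal(5 * 2.262 / 2090, 0.0054, tolerance = 0.01)
})

test_that("running FLR equals prefix recomputation on random small lists", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(1:20, 1)
    flag <- runif(n) < 0.3
    ratio <- runif(1, 0.5, 4)
    ranked <- data.frame(peptide = replicate(n, paste(sample(LETTERS, 4), collapse = "")),
                         site_pos = seq_len(n), score = sort(runif(n), decreasing = TRUE),
                         decoy_flag = flag, is_decoy_site = flag)
    out <- compute_decoy_flr(ranked, T = ratio, A = 1)
    oracle <- brute_flr(flag, ratio)
    expect_equal(out$running_flr, oracle$running)
    expect_equal(out$q_flr, oracle$q)
    expect_true(all(diff(out$q_flr) >= -1e-12))
  }
})

test_that("thresholding is nested and never reports decoy residues", {
  sim <- default_fixture()
  fit <- ptm_flr(sim$records, adjust = FALSE, collapse = "none")
  t1 <- threshold_at(fit, 0.01)
  t5 <- threshold_at(fit, 0.05)
  t10 <- threshold_at(fit, 0.10)
  key <- function(d) paste(d$psm_id, d$site_pos)
  expect_true(all(key(t1) %in% key(t5)))
  expect_true(all(key(t5) %in% key(t10)))
  expect_false(any(t10$is_decoy_site))
  # alpha = 1 returns every target row
  expect_equal(nrow(threshold_at(fit, 1)), sum(!fit$table$is_decoy_site))
  # alpha below the minimum q: empty (decoy at rank 1 makes min q positive)
  flag <- c(TRUE, FALSE, FALSE)
  small <- compute_decoy_flr(data.frame(peptide = c("A", "B", "C"),
                                        site_pos = 1:3, decoy_flag = flag,
                                        is_decoy_site = flag), T = 2, A = 1)
  expect_gt(min(small$q_flr), 0)
  expect_equal(nrow(threshold_at(small, min(small$q_flr) / 2)), 0L)
})

test_that("ground-truth FLR counts incorrect reported sites", {
  ranked <- data.frame(is_decoy_site = rep(FALSE, 10))
  expect_equal(compute_real_flr(ranked, rep(TRUE, 10)), rep(0, 10))
  correct <- rep(TRUE, 10)
  correct[c(4, 8)] <- FALSE
  expect_equal(compute_real_flr(ranked, correct)[10], 0.2)
  expect_error(compute_real_flr(ranked, correct[1:5]), "every ranked record")
  # decoy rows are not part of the reported denominator
  ranked2 <- data.frame(is_decoy_site = c(FALSE, TRUE, FALSE, FALSE))
  real <- compute_real_flr(ranked2, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(real[4], 1 / 3)
})
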