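test_that("exact and rigidly moved copies match at zero RMSD", {
  h <- make_ref_hypothesis()
  fs <- fs_on_hypothesis(h)
  m <- match_to_hypothesis(fs, h)
  expect_equal(m$rmsd, 0, tolerance = 1e-9)
  expect_equal(m$matched_fraction, 1)

  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)  # 90 deg about z
  moved <- fs
  moved$features <- lapply(fs$features, function(f) {
    f$position <- as.numeric(R %*% f$position) + c(10, 0, 0)
    if (!is.null(f$direction)) f$direction <- as.numeric(R %*% f$direction)
    f
  })
  m2 <- match_to_hypothesis(moved, h)
  expect_equal(m2$rmsd, 0, tolerance = 1e-9)
})

test_that("a single displaced feature gives the closed-form RMSD", {
  h <- make_ref_hypothesis()
  fs <- fs_on_hypothesis(h)
  fs$features[[2]]$position <- fs$features[[2]]$position + c(0, 0, 2)
  m <- match_to_hypothesis(fs, h, rmsd_max = Inf)
  expect_equal(m$rmsd, oracle_match_rmsd(fs, h), tolerance = 1e-6)
  # displacement d on one of n points after optimal superposition:
  # rmsd = d * sqrt((1 - 1/n) / n) is an upper-bound closed form met here
  # because re-fitting can only lower it; the oracle is authoritative
  expect_lte(m$rmsd, 2 * sqrt((1 - 1 / 4) / 4) + 1e-9)
})

test_that("matching equals brute-force correspondence search on random cases", {
  set.seed(11)
  for (case in 1:40) {
    rc <- random_match_case()
    m <- match_to_hypothesis(rc$fs, rc$h, rmsd_max = Inf)
    o <- oracle_match_rmsd(rc$fs, rc$h)
    if (is.null(o)) expect_null(m) else expect_equal(m$rmsd, o, tolerance = 1e-6)
  }
})

test_that("the RMSD gate discards bad matches and partial matching relaxes coverage", {
  h <- make_ref_hypothesis()
  fs <- fs_on_hypothesis(h)
  fs$features[[1]]$position <- fs$features[[1]]$position + c(0, 0, 8)
  expect_null(match_to_hypothesis(fs, h, rmsd_max = 1.0))
  mp <- match_to_hypothesis(fs, h, rmsd_max = 1.0, allow_partial = TRUE)
  expect_false(is.null(mp))
  expect_equal(mp$matched_fraction, 0.75)
})

test_that("screen score reproduces its plug-in values", {
  h <- make_ref_hypothesis()
  fs <- fs_on_hypothesis(h)
  m <- match_to_hypothesis(fs, h)
  expect_equal(screen_score(m, h), 1.0, tolerance = 1e-9)
  # complete match at the gate with perfect vectors: (1 + 0 + 1) / 3
  m_at_gate <- m
  m_at_gate$rmsd <- 1.0
  expect_equal(screen_score(m_at_gate, h, rmsd_max = 1.0), 2 / 3, tolerance = 1e-9)
  expect_equal(screen_score(m_at_gate, h, rmsd_max = 1.0, scale = 3), 2,
               tolerance = 1e-9)
})

test_that("median screen score decays with planted coordinate noise", {
  h <- make_ref_hypothesis()
  med_score <- vapply(c(0.1, 0.4, 0.8), function(sig) {
    set.seed(100 + round(sig * 10))
    scores <- vapply(1:50, function(i) {
      fs <- fs_on_hypothesis(h, sprintf("m%d", i))
      fs$features <- lapply(fs$features, function(f) {
        f$position <- f$position + rnorm(3, 0, sig); f
      })
      m <- match_to_hypothesis(fs, h, rmsd_max = Inf)
      screen_score(m, h, rmsd_max = 2)
    }, numeric(1))
    median(scores)
  }, numeric(1))
  expect_true(all(diff(med_score) < 0))
})

test_that("TPS_S aggregation sums hypotheses and collapses protomers by maximum", {
  df <- data.frame(molecule_id = c("m1", "m1", "m2", "m3"),
                   hypothesis_id = c("h1", "h2", "h1", "h2"),
                   score = c(0.8, 0.4, 0.5, 0.1))
  sm <- aggregate_tpss(df)
  expect_equal(unname(sm$tpss["m1"]), 1.2, tolerance = 1e-9)

  prot <- data.frame(molecule_id = c("m1", "m1", "m2"),
                     protomer = c(1, 2, 1),
                     hypothesis_id = "h1",
                     score = c(0.8, 0.6, 0.2))
  smp <- aggregate_tpss(prot)
  expect_equal(unname(smp$tpss["m1"]), 0.8, tolerance = 1e-9)

  dup <- data.frame(molecule_id = c("m1", "m1"), hypothesis_id = "h1",
                    score = c(1, 2))
  expect_error(aggregate_tpss(dup), "duplicated")
  expect_true(all(sm$tpss == rowSums(sm$score_matrix)))
})

test_that("docking threshold equals mean plus two sample SDs with inclusive selection", {
  tpss <- c(a = 1, b = 2, c = 3, d = 4, e = 10)
  thr <- docking_threshold(tpss)
  expect_equal(thr$mean_tpss, 4)
  expect_equal(thr$sd_tpss, sd(c(1, 2, 3, 4, 10)))
  expect_equal(thr$d_threshold, 4 + 2 * sd(c(1, 2, 3, 4, 10)), tolerance = 1e-9)
  expect_equal(round(thr$d_threshold, 4), 11.0711)
  expect_length(thr$selected, 0)

  flat <- docking_threshold(c(x = 5, y = 5, z = 5))
  expect_equal(flat$d_threshold, 5)
  expect_identical(flat$selected, c("x", "y", "z"))
  expect_error(docking_threshold(c(a = 1)), "at least 2")
})

test_that("threshold selection is affine-invariant", {
  set.seed(2)
  tpss <- setNames(rexp(30), sprintf("m%02d", 1:30))
  base <- docking_threshold(tpss)
  for (ab in list(c(2, 0), c(0.5, 3), c(10, -1))) {
    tr <- docking_threshold(ab[1] * tpss + ab[2])
    expect_equal(tr$d_threshold, ab[1] * base$d_threshold + ab[2], tolerance = 1e-9)
    expect_identical(tr$selected, base$selected)
  }
})

test_that("first-pass filter keeps top-N per hypothesis and demands multi-model hits", {
  df <- data.frame(molecule_id = c("X", "Y", "X", "Z"),
                   hypothesis_id = c("h1", "h1", "h2", "h2"),
                   rmsd = c(0.2, 0.3, 0.4, 0.1))
  expect_identical(first_pass_filter(df, top_n = 10, min_hypotheses = 2), "X")

  ties <- data.frame(molecule_id = c("b", "a"), hypothesis_id = "h1",
                     rmsd = c(0.5, 0.5))
  got <- first_pass_filter(ties, top_n = 1, min_hypotheses = 1)
  expect_identical(got, "a")

  many <- data.frame(molecule_id = sprintf("m%02d", 1:10),
                     hypothesis_id = "h1", rmsd = (1:10) / 10)
  expect_length(first_pass_filter(many, top_n = 5, min_hypotheses = 1), 5)
  expect_error(first_pass_filter(many, top_n = 0), "top_n")
})

test_that("selection always equals its defining rule under mutation", {
  set.seed(31)
  tpss <- setNames(runif(20, 0, 10), sprintf("m%02d", 1:20))
  for (i in 1:25) {
    tpss[sample(20, 1)] <- runif(1, 0, 12)
    thr <- docking_threshold(tpss)
    expect_identical(thr$selected,
                     names(tpss)[tpss >= mean(tpss) + 2 * sd(tpss)])
  }
})

test_that("planted actives outrank decoys by TPS_S", {
  sp <- planted_spec(seed = 13, sigma = 0.3, n_actives = 4,
                     n_decoys_per_active = 10)
  ps <- gen_planted_set(sp)
  hy <- generate_hypotheses(ps$actives)
  sl <- screen_library(c(ps$actives, ps$decoys), hy)
  tp <- sl$screen_matrix$tpss
  auc <- roc_auc(tp[grep("^active", names(tp))], tp[grep("^decoy", names(tp))])
  expect_gte(auc, 0.9)
})
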