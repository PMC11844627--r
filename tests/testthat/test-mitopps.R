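test_that("the worked 3-pathway micro-example reproduces its exact values", {
  s <- matrix(c(2, 1, 1, 1, 1, 1), 3, 2,
              dimnames = list(paste0("P", 1:3), c("S1", "S2")))
  # cross-checked against the literal double-sum oracle before freezing
  expect_equal(unclass(mitopps_oracle(s))["P1", "S1"], 4 / 3)
  p <- compute_mitopps(s)
  expect_equal(unname(p["P1", "S1"]), 4 / 3, tolerance = 1e-15)
  expect_equal(unname(p["P1", "S2"]), 2 / 3, tolerance = 1e-15)
  expect_equal(unname(p["P2", "S1"]), 5 / 6, tolerance = 1e-15)
})

test_that("vectorized mitoPPS equals the naive triple-loop oracle", {
  for (seed in 1:10) {
    s <- random_scores(10, 6, seed = seed)
    expect_equal(unclass(compute_mitopps(s))[, ], mitopps_oracle(s),
                 tolerance = 1e-12)
  }
})

test_that("shared profiles up to per-sample scalars give mitoPPS of exactly 1", {
  profile <- c(5, 1, 0.2, 40, 7)
  s <- outer(profile, c(1, 3, 0.01, 250))
  dimnames(s) <- list(paste0("P", 1:5), paste0("S", 1:4))
  p <- compute_mitopps(s)
  expect_equal(unclass(p)[, ], matrix(1, 5, 4, dimnames = dimnames(s)),
               tolerance = 1e-12)
})

test_that("each pathway's mitoPPS averages to 1 across samples (reference = all)", {
  for (seed in c(2, 13)) {
    s <- random_scores(12, 9, seed = seed)
    p <- compute_mitopps(s)
    expect_lt(max(abs(rowMeans(unclass(p)) - 1)), 1e-9)
  }
})

test_that("mitoPPS is invariant to scaling any single sample's scores", {
  s <- random_scores(8, 5, seed = 31)
  base <- unclass(compute_mitopps(s))
  for (c_ in c(0.1, 3, 1000)) {
    s2 <- s
    s2[, 2] <- s2[, 2] * c_
    expect_lt(max(abs(unclass(compute_mitopps(s2)) - base)), 1e-12)
  }
})

test_that("raising one (sample, pathway) score strictly raises its mitoPPS", {
  s <- random_scores(7, 4, seed = 8)
  before <- unclass(compute_mitopps(s))["P3", "S2"]
  s2 <- s
  s2["P3", "S2"] <- s2["P3", "S2"] * 1.25
  after <- unclass(compute_mitopps(s2))["P3", "S2"]
  expect_gt(after, before)
})

test_that("control-referenced mitoPPS generalizes the all-sample variant", {
  s <- random_scores(9, 6, seed = 55)
  all_ref <- compute_mitopps(s)
  ctrl_all <- control_referenced_mitopps(s, control_ids = colnames(s))
  expect_equal(unclass(ctrl_all)[, ], unclass(all_ref)[, ], tolerance = 1e-15)

  controls <- c("S1", "S2", "S3")
  p <- control_referenced_mitopps(s, control_ids = controls)
  # mean-1 invariant holds over the control subset, not over all samples
  expect_lt(max(abs(rowMeans(unclass(p)[, controls]) - 1)), 1e-9)

  # a sample matching the control average-ratio profile scores 1 everywhere
  profile <- c(4, 1, 9, 0.5)
  s2 <- outer(profile, c(1, 2, 5, 0.3))
  dimnames(s2) <- list(paste0("P", 1:4), c("c1", "c2", "c3", "test"))
  p2 <- control_referenced_mitopps(s2, control_ids = c("c1", "c2", "c3"))
  expect_equal(unname(unclass(p2)[, "test"]), rep(1, 4), tolerance = 1e-12)
})

test_that("control-referenced planted doubling matches the brute-force oracle", {
  cfg <- synthetic_config(
    n_samples = 12, groups = rep(c("ctrl", "treated"), each = 6),
    priorities = list(treated = c("MitoGroupA > PathA1 > LeafA1a" = 2)),
    sigma = 0.1, seed = 202)
  d <- generate_synthetic(cfg)
  sc <- score_pathways(d$expr, d$hierarchy)
  controls <- d$samples$sample_id[d$samples$group == "ctrl"]
  p <- control_referenced_mitopps(sc, control_ids = controls)
  oracle <- mitopps_oracle(unclass(sc), reference = controls)
  expect_equal(unclass(p)[, ], oracle, tolerance = 1e-12)
  # treated group prioritizes the planted leaf: the doubled ratio is damped
  # only by the cross-terms of the remaining pathways
  treated <- d$samples$sample_id[d$samples$group == "treated"]
  planted_mean <- mean(unclass(p)["MitoGroupA > PathA1 > LeafA1a", treated])
  expect_gt(planted_mean, 1.5)
})

test_that("nonfinite scores exclude the offending sample with a report", {
  s <- random_scores(6, 4, seed = 77)
  s["P2", "S3"] <- 0
  expect_equal(finite_check(s), list(S3 = "P2"))
  p <- compute_mitopps(s)
  expect_false("S3" %in% colnames(p))
  expect_equal(attr(p, "excluded"), list(S3 = "P2"))
  # retained samples are unaffected by the exclusion
  expect_equal(unclass(p)[, ], mitopps_oracle(s[, c("S1", "S2", "S4")]),
               tolerance = 1e-12)
  expect_error(compute_mitopps(s, on_nonfinite = "error"), "S3")
  eps <- compute_mitopps(s, on_nonfinite = "epsilon")
  expect_true("S3" %in% colnames(eps))
  expect_true(all(is.finite(eps)))
  expect_length(finite_check(random_scores(5, 3, seed = 1)), 0L)
})

test_that("derived scales map correctly: percent, log10, dynamic range", {
  m <- matrix(c(2.1, 0.35, 1, 10), 4, 1,
              dimnames = list(paste0("P", 1:4), "S1"))
  pct <- prioritization_percent(m)
  expect_equal(unname(pct[, 1]), c(110, -65, 0, 900))
  lg <- log10_mitopps(m)
  expect_equal(unname(lg[c("P3", "P4"), 1]), c(0, 1))
  expect_equal(10^lg[, ], m[, ], tolerance = 1e-12)

  dm <- matrix(c(0.5, 1, 2, 1, 1, 1), 2, 3, byrow = TRUE,
               dimnames = list(c("spread", "flat"), paste0("S", 1:3)))
  dr <- dynamic_range(dm)
  expect_equal(unname(dr["spread"]), 1.5)
  expect_equal(unname(dr["flat"]), 0)
  expect_equal(unname(dynamic_range(dm, samples = c("S1", "S2"))["spread"]), 0.5)
  expect_error(dynamic_range(dm, samples = character(0)), "non-empty")
})

test_that("pathways with no finite score are dropped with a warning", {
  s <- random_scores(5, 4, seed = 4)
  s["P5", ] <- NA_real_
  expect_warning(p <- compute_mitopps(s), "dropped")
  expect_false("P5" %in% rownames(p))
  expect_equal(unclass(p)[, ], mitopps_oracle(s[1:4, ]), tolerance = 1e-12)
})
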