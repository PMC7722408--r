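test_that("ramped delay scan finds the onset at the analytic critical delay
           with no hysteresis", {
  p <- bg_params()
  # 0.1 ms resolution around T0; stop below the second (cortical-loop)
  # crossing at 4.21 ms, beyond which the attractor is no longer the simple
  # near-onset limit cycle
  grid <- seq(2.8, 4.2, length.out = 15)
  sc <- ramp_scan(p, "T", grid, direction = "both", duration = 2000, settle = 2500)
  expect_s3_class(sc, "bg_scan")
  T0 <- attr(sc, "analytic_critical")
  expect_equal(T0, 3.6807, tolerance = 1e-3)

  step <- diff(grid)[1]
  up <- sc[sc$direction == "up", ]
  dn <- sc[sc$direction == "down", ]
  dn <- dn[order(dn$value), ]
  onset_up <- min(up$value[up$kind == "oscillation"])
  expect_lte(abs(onset_up - T0), step + 1e-9)           # within one grid step
  onset_dn <- min(dn$value[dn$kind == "oscillation"])
  # supercritical: the two ramps locate the same onset (no hysteresis loop);
  # the slowly decaying transient can smear the down-ramp by a grid step or two
  expect_lte(abs(onset_dn - onset_up), 2 * step + 1e-9)
  # away from the critical slowing-down region the diagrams coincide
  far <- abs(up$value - T0) > 2.5 * step
  expect_equal(up$kind[far], dn$kind[far])
  expect_equal(up$amplitude[far], dn$amplitude[far], tolerance = 0.05)
  # amplitude grows with the delay past onset
  osc <- up[up$kind == "oscillation", ]
  expect_gt(nrow(osc), 3)
  expect_true(all(diff(osc$amplitude) > -1e-6))
})

test_that("weight scans reproduce the single-onset and two-onset windows", {
  p <- bg_params(T = 3.6807)
  # STN->GPe weight: one onset, amplitude grows with the weight
  g1 <- seq(1.6, 4.4, length.out = 15)
  s1 <- ramp_scan(p, "w_SG", g1, duration = 1500, settle = 2000)
  k1 <- rle(s1$kind)$values
  expect_identical(k1, c("fixed_point", "oscillation"))
  osc1 <- s1[s1$kind == "oscillation", ]
  expect_gt(utils::tail(osc1$amplitude, 1), osc1$amplitude[1])

  # cortex->STN weight: oscillation confined to a middle window
  g2 <- seq(2, 24, length.out = 23)
  s2 <- ramp_scan(p, "w_CS", g2, duration = 1500, settle = 2000)
  k2 <- rle(s2$kind)$values
  expect_identical(k2, c("fixed_point", "oscillation", "fixed_point"))
  osc2 <- s2$amplitude[s2$kind == "oscillation"]
  expect_gt(max(osc2), osc2[1])              # rises then falls back to zero
  expect_gt(max(osc2), utils::tail(osc2, 1))
})

test_that("codimension-two map separates the healthy and oscillatory regions", {
  p <- bg_params(T = 3.6807)
  m <- hopf_boundary_2d(p, "w_SG", "w_CS",
                        x_grid = seq(0.5, 5, length.out = 10),
                        y_grid = seq(1, 14, length.out = 10))
  expect_s3_class(m, "bg_map")
  # small w_CS or small w_SG: always the healthy (stable) state
  expect_true(all(m$stable[m$x <= 1] == TRUE))
  expect_true(all(m$stable[m$y <= 2.5] == TRUE))
  expect_true(any(!m$stable))
  b <- attr(m, "boundary")
  expect_gt(nrow(b), 0)

  # boundary correctness: stepping across a refined boundary point flips the verdict
  bi <- b[1, ]
  stab_at <- function(wcs) {
    pp <- p; pp$w_SG <- bi$x; pp$w_CS <- wcs
    T0 <- attr(critical_delays(linearize(pp)), "T0")
    is.na(T0) || pp$T < T0
  }
  eps <- 0.15
  expect_false(stab_at(bi$y + eps) == stab_at(bi$y - eps))
})

test_that("analysis-mode and simulation-mode verdicts agree cell by cell", {
  p <- bg_params(T = 5)
  xg <- seq(4, 10, length.out = 6)
  yg <- c(2, 3.2, 4.4)
  ma <- hopf_boundary_2d(p, "w_CS", "w_SG", xg, yg, mode = "analysis")
  ms <- hopf_boundary_2d(p, "w_CS", "w_SG", xg, yg, mode = "simulation",
                         duration = 1200, settle = 1800)
  # the modes must place the onset boundary within one cell of each other
  for (yv in yg) {
    ba <- which(!ma$stable[ma$y == yv])
    bs <- which(!ms$stable[ms$y == yv])
    first_a <- if (length(ba)) min(ba) else Inf
    first_s <- if (length(bs)) min(bs) else Inf
    expect_lte(abs(first_a - first_s), 1)
  }
})

test_that("frequency profile at strong cortical drive orders gamma, beta, alpha", {
  p <- bg_params()
  prof <- frequency_profile(p, T_grid = c(2, 3, 4, 6, 9, 13, 17, 22, 28),
                            w_CS_fixed = 8.0, duration = 1500, settle = 2000)
  expect_identical(names(prof)[1:3], c("T", "frequency", "band"))
  bands <- prof$band[prof$band != "steady"]
  expect_identical(unique(bands), intersect(c("gamma", "beta", "alpha", "slow"),
                                            unique(bands)))
  # steady region precedes the gamma onset; frequency decreases with delay
  expect_identical(prof$band[1], "steady")
  expect_identical(bands[1], "gamma")
  expect_true("beta" %in% bands && "alpha" %in% bands)
  f <- prof$frequency[!is.na(prof$frequency)]
  expect_true(all(diff(f) < 0))
})

test_that("fixture generation is deterministic, admissible, and crossing-rich", {
  f1 <- generate_fixtures(123, 12)
  f2 <- generate_fixtures(123, 12)
  expect_identical(f1, f2)
  f3 <- generate_fixtures(124, 12)
  expect_false(identical(f1, f3))
  for (i in seq_len(nrow(f1))) {
    expect_silent(validate_bg_params(fixture_params(f1, i)))
  }
  expect_gte(mean(f1$has_crossing), 0.3)
  # members 1 and 2 are the reference set and the mid-range completion
  expect_equal(fixture_params(f1, 1)$M_E, bg_params()$M_E)
  expect_equal(fixture_params(f1, 2)$M_E, 65)
})

test_that("tidiers and autoplot methods produce well-formed objects", {
  rep <- hopf_report(bg_params(), normal_form = TRUE)
  g <- glance(rep)
  expect_identical(nrow(g), 1L)
  expect_true(all(c("mu2", "beta2", "T2", "direction") %in% names(g)))
  td <- tidy(rep$normal_form)
  expect_identical(td$term[1:4], c("g20", "g11", "g02", "g21"))

  tr <- simulate_bg(bg_params(T = 8), duration = 300, thin = 10L)
  expect_s3_class(autoplot(tr), "ggplot")
  sc <- ramp_scan(bg_params(), "T", seq(3, 4.4, length.out = 6),
                  duration = 800, settle = 1200)
  expect_s3_class(autoplot(sc), "ggplot")
  m <- hopf_boundary_2d(bg_params(T = 4), "w_SG", "w_CS",
                        seq(1, 4, length.out = 4), seq(3, 9, length.out = 4))
  expect_s3_class(autoplot(m), "ggplot")
})
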