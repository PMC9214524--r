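p_med <- dynamics_params()  # median couplings, noise off
fp0 <- field_params()

test_that("uncoupled droplets cross the trail on a straight path at constant speed", {
  p0 <- dynamics_params(alpha_c0 = 0, omega_c0 = 0)
  ev <- simulate_event(pi / 3, 10, p0, fp0)
  expect_identical(ev$outcome, "crossing")
  tr <- ev$trajectory
  # straight: heading never changes
  expect_equal(tr$nx, rep(tr$nx[1], nrow(tr)), tolerance = 1e-12)
  step_len <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) / diff(tr$t)
  expect_equal(step_len, rep(25, length(step_len)), tolerance = 1e-9)
})

test_that("a very old trail is crossed with negligible turning", {
  ev <- simulate_event(pi / 4, 5e5, p_med, fp0)
  expect_identical(ev$outcome, "crossing")
  expect_lt(ev$max_turn_rate, 1e-3)
})

test_that("a reflecting event shows the speed dip before the turning point", {
  ev <- simulate_event(pi / 4, 10, p_med, fp0)
  expect_identical(ev$outcome, "reflection")
  s <- ev$series
  i_turn <- which.min(s$d)         # turning point: closest approach
  i_vmin <- which.min(s$V)         # speed minimum
  expect_lt(i_vmin, i_turn)        # dip before the turning point
  dip <- 25 - min(s$V)
  expect_gt(dip, 0.2)              # alpha > 0 slows the approach
  # recovery after the turning point: most of the dip is regained
  expect_gt(s$V[nrow(s) - 5], min(s$V) + 0.5 * dip)
  expect_gt(min(s$d), 0)           # never reaches the centre
})

test_that("with alpha = 0 the speed is constant through a reflection", {
  p <- dynamics_params(alpha_c0 = 0, omega_c0 = 7e3)
  ev <- simulate_event(pi / 4, 10, p, fp0)
  tr <- ev$trajectory
  step_speed <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) / diff(tr$t)
  expect_equal(step_speed, rep(25, length(step_speed)), tolerance = 1e-9)
})

test_that("classification follows the entry/exit side convention", {
  # straight line through the trail
  straight <- data.frame(x = seq(-300, 300, by = 10),
                         y = seq(300, -300, by = -10))
  expect_identical(classify_event(straight), "crossing")
  # symmetric turnaround with minimum d = +15 um
  th <- seq(0, pi, length.out = 101)
  turn <- data.frame(x = -200 * cos(th), y = 15 + 285 * sin(th))
  expect_identical(classify_event(turn), "reflection")
  # marginal path dipping to y = -1e-9 then returning: boundary convention
  marg <- data.frame(x = seq_len(101),
                     y = c(seq(250, -1e-9, length.out = 51),
                           seq(-1e-9, 250, length.out = 51))[-51])
  expect_identical(classify_event(marg), "reflection")
  # never exits the band
  stuck <- data.frame(x = seq_len(50), y = rep(10, 50))
  expect_identical(classify_event(stuck), "unresolved")
})

test_that("classification respects an arbitrary trail line", {
  tl <- list(origin = c(100, 100), dir = c(1, 1))
  d0 <- seq(300, -300, length.out = 61) / sqrt(2)
  path <- data.frame(x = 100 + d0, y = 100 - d0)  # perpendicular crossing
  expect_identical(classify_event(path, tl), "crossing")
})

test_that("the separatrix is monotone in the couplings and absent without torque", {
  th <- c(40, 55, 70) * pi / 180
  s1 <- separatrix(th, p_med, fp0, bracket = c(1, 400))
  p2 <- dynamics_params(omega_c0 = 2 * p_med$omega_c0)
  s2 <- separatrix(th, p2, fp0, bracket = c(1, 400))
  ok <- !is.na(s1$delta_t_star) & !is.na(s2$delta_t_star)
  expect_true(any(ok))
  expect_true(all(s2$delta_t_star[ok] >= s1$delta_t_star[ok]))
  # delta_t_star non-increasing in theta (noise-free model)
  dts <- s1$delta_t_star[!is.na(s1$delta_t_star)]
  expect_true(all(diff(dts) <= 0))
  # no torque, never reflects
  s0 <- separatrix(th, dynamics_params(omega_c0 = 0, alpha_c0 = 0), fp0,
                   bracket = c(1, 60))
  expect_true(all(is.na(s0$delta_t_star)))
})

test_that("the rotational-noise band evaluates to sqrt(2 D_r d_max / (V0 sin theta))", {
  # hand evaluation at normal incidence: T = 220/25 = 8.8 s,
  # delta_theta = sqrt(2 * 0.01 * 8.8) = sqrt(0.176)
  s <- separatrix(pi / 2, dynamics_params(omega_c0 = 0, alpha_c0 = 0, V0 = 25),
                  fp0, bracket = c(1, 2))
  expect_equal(s$delta_theta, sqrt(0.176), tolerance = 1e-12)
  expect_equal(s$delta_theta, 0.420, tolerance = 2e-3)
})

test_that("outcome switches from reflection to crossing exactly once in delta_t", {
  lags <- exp(seq(log(2), log(600), length.out = 100))
  out <- vapply(lags, function(dt) {
    simulate_event(pi / 3, dt, p_med, fp0)$outcome
  }, character(1))
  runs <- rle(out)
  expect_identical(runs$values, c("reflection", "crossing"))
})

test_that("max turn rate decreases with the time lag at fixed incidence", {
  rates <- vapply(c(5, 30, 120, 400), function(dt) {
    simulate_event(pi / 3, dt, p_med, fp0)$max_turn_rate
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("crossing becomes more likely with both time lag and incidence angle", {
  diag <- interaction_diagram(c(30, 55, 80) * pi / 180, c(5, 60, 400), p_med, fp0)
  cross_frac_by_lag <- tapply(diag$outcome == "crossing", diag$delta_t, mean)
  expect_true(all(diff(cross_frac_by_lag) >= 0))
  cross_frac_by_th <- tapply(diag$outcome == "crossing", diag$theta_inc, mean)
  expect_true(all(diff(cross_frac_by_th) >= 0))
})

test_that("mirror-image geometry yields the mirror-image trajectory", {
  fp <- field_params()
  var0 <- 2 * fp$D * 30
  C0 <- fp$q / sqrt(2 * pi * var0)
  up <- cappsim:::cpp_sim_gauss_trail(0, 220, -pi / 3, 25, 3e4, 7e3, 0, 0,
                                      0.02, C0, var0, 0, 220, 20000L, 1L)
  dn <- cappsim:::cpp_sim_gauss_trail(0, -220, pi / 3, 25, 3e4, 7e3, 0, 0,
                                      0.02, C0, var0, 0, 220, 20000L, 1L)
  expect_equal(up$path[, "x"], dn$path[, "x"], tolerance = 1e-12)
  expect_equal(up$path[, "y"], -dn$path[, "y"], tolerance = 1e-12)
})

test_that("constructed geometries are detected with the right angle and lag", {
  # two straight lines crossing at 90 deg, passage times 0 and 30 s
  tA <- seq(-20, 20, by = 0.5)
  A <- data.frame(droplet_id = "L", t = tA, x = 25 * tA, y = 0)
  tB <- seq(10, 50, by = 0.5)
  B <- data.frame(droplet_id = "F", t = tB, x = 0, y = -25 * (tB - 30))
  evs <- detect_interactions(rbind(A, B))
  tab <- events_table(evs)
  tab <- tab[tab$leader_id == "L", ]
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$theta_inc, pi / 2, tolerance = 1e-6)
  expect_equal(tab$delta_t, 30, tolerance = 1e-6)
  expect_identical(tab$outcome, "crossing")

  # parallel lines 300 um apart: beyond d_max, no events
  B2 <- data.frame(droplet_id = "F", t = tA + 30, x = 25 * tA, y = 300)
  expect_length(detect_interactions(rbind(A, B2)), 0L)
})

test_that("a synthetic reflecting event is recovered on re-ingestion", {
  pair <- gen_event_pair(pi / 4, 10, p_med, fp0, position_noise = 1, seed = 5)
  evs <- detect_interactions(pair)
  tab <- events_table(evs)
  tab <- tab[tab$leader_id == "1" & tab$follower_id == "2", ]
  expect_gte(nrow(tab), 1L)
  best <- which.min(abs(tab$delta_t - 10))
  expect_equal(tab$theta_inc[best], pi / 4, tolerance = 2 * pi / 180)
  expect_equal(tab$delta_t[best], 10, tolerance = 1)
  expect_identical(tab$outcome[best], "reflection")
})
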