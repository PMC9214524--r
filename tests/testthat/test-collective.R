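# scaled-down study boxes: same densities as the experiments, smaller N
cfg_dense <- function(density = 7.4, duration = 240, seed_box = 1500,
                      p = dynamics_params(dt = 0.05, D_r = 0.01)) {
  collective_config(box_size = seed_box, number_density = density,
                    duration = duration, dynamics = p, save_every = 20L)
}

test_that("a single droplet with couplings on runs straight over its own trail", {
  # dilute limit n = 0.025 mm^-2: one droplet in a 6.3 mm box
  cfg <- collective_config(box_size = 6300, number_density = 0.025,
                           duration = 120, dynamics = dynamics_params(dt = 0.05),
                           save_every = 20L)
  expect_identical(cfg$N, 1L)
  sim <- simulate_collective(cfg, seed = 4)
  tr <- sim$trajectories
  # straight: lateral deviation from the initial heading is negligible
  ux <- tr$nx[1]; uy <- tr$ny[1]
  lateral <- abs(-(tr$x - tr$x[1]) * uy + (tr$y - tr$y[1]) * ux)
  expect_lt(max(lateral), 1e-6)
  # the droplet is marginally pushed forward by its own aged trail, so the
  # displacement slightly exceeds the bare ballistic V0 * T
  disp <- sqrt((tr$x - tr$x[1])^2 + (tr$y - tr$y[1])^2)
  expect_gte(max(disp), 25 * 120)
  expect_lt(max(disp), 25 * 120 * 1.05)
  m <- ensemble_msd(sim)
  expect_true(all(m$exponent[!is.na(m$exponent)] > 1.8))
})

test_that("MSD oracles: stationary, ballistic, and diffusive ensembles", {
  tgrid <- seq(0, 50, by = 1)
  still <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(droplet_id = i, t = tgrid, x = i * 10, y = -i * 5)
  }))
  m0 <- ensemble_msd(still)
  expect_true(all(m0$msd == 0))

  ball <- do.call(rbind, lapply(1:8, function(i) {
    th <- 2 * pi * i / 8
    data.frame(droplet_id = i, t = tgrid,
               x = 25 * tgrid * cos(th), y = 25 * tgrid * sin(th))
  }))
  mb <- ensemble_msd(ball)
  expect_equal(mb$msd, 625 * tgrid^2, tolerance = 1e-12)
  expect_true(all(abs(mb$exponent[-1] - 2) < 1e-9))

  set.seed(11)
  D <- 30
  dt <- 0.5
  tg <- seq(0, 100, by = dt)
  walk <- do.call(rbind, lapply(1:400, function(i) {
    data.frame(droplet_id = i, t = tg,
               x = cumsum(c(0, stats::rnorm(length(tg) - 1, 0, sqrt(2 * D * dt)))),
               y = cumsum(c(0, stats::rnorm(length(tg) - 1, 0, sqrt(2 * D * dt)))))
  }))
  mw <- ensemble_msd(walk)
  late <- mw$lag >= 20
  expect_equal(mean(mw$msd[late] / (4 * D * mw$lag[late])), 1, tolerance = 0.1)
})

test_that("caging detection recovers the structure of constructed curves", {
  # piecewise local exponent 2 -> 0 -> 1 with known break lags
  lag <- exp(seq(log(1), log(1000), length.out = 80))
  i1 <- findInterval(20, lag)
  i2 <- findInterval(200, lag)
  lmsd <- numeric(80)
  llag <- log(lag)
  lmsd[1:i1] <- 2 * llag[1:i1]
  lmsd[(i1 + 1):i2] <- lmsd[i1]
  lmsd[(i2 + 1):80] <- lmsd[i2] + (llag[(i2 + 1):80] - llag[i2])
  curve <- data.frame(lag = lag, msd = exp(lmsd))
  # detection grid matched to the curve's own log spacing
  cg <- detect_caging(curve, exponent_window = 3L,
                      points_per_decade = log(10) / diff(llag)[1])
  step <- diff(llag)[1]
  expect_lt(abs(log(cg$crossover_to_caging) - log(lag[i1])), 1.5 * step)
  expect_lt(abs(log(cg$crossover_to_escape) - log(lag[i2])), 1.5 * step)
  expect_equal(cg$plateau_height, exp(lmsd[i1]), tolerance = 0.05)

  # pure ballistic: no caging
  bal <- data.frame(lag = lag, msd = 625 * lag^2)
  expect_true(is.na(detect_caging(bal)$crossover_to_caging))

  # constant curve: plateau from the first lag onward
  flat <- data.frame(lag = lag, msd = rep(1e4, 80))
  cgf <- detect_caging(flat)
  expect_equal(cgf$crossover_to_caging, lag[1])
  expect_equal(cgf$plateau_height, 1e4)
})

test_that("trail interactions suppress transport at high density", {
  sim <- simulate_collective(cfg_dense(7.4), seed = 2)
  m <- ensemble_msd(sim)

  p0 <- dynamics_params(dt = 0.05, alpha_c0 = 0, omega_c0 = 0)
  sim0 <- simulate_collective(cfg_dense(7.4, p = p0), seed = 2)
  m0 <- ensemble_msd(sim0)

  # uncoupled droplets stay ballistic; coupled ones turn subdiffusive
  expect_true(is.na(detect_caging(m0)$crossover_to_caging))
  expect_true(all(m0$exponent[!is.na(m0$exponent)] > 1.8))
  sub <- detect_caging(m, threshold = 1)
  expect_false(is.na(sub$crossover_to_caging))
  late <- which.max(m$lag)
  expect_lt(m$msd[late], 0.5 * m0$msd[late])
})

test_that("trajectories alternate persistent runs and localized episodes at high density", {
  sim <- simulate_collective(cfg_dense(7.4), seed = 2)
  tr <- sim$trajectories
  one <- tr[tr$droplet_id == 1L, ]
  idx <- seq(1L, nrow(one), by = 50L)  # 50 s windows
  net <- sqrt(diff(one$x[idx])^2 + diff(one$y[idx])^2)
  # both mobile windows and strongly localized windows occur
  expect_gt(max(net), 600)
  expect_lt(min(net), 400)
})

test_that("denser systems arrest earlier and at a smaller displacement scale", {
  # onset: first lag at which the ensemble MSD has fallen to half the
  # ballistic reference V0^2 lag^2 (robust for small Monte-Carlo ensembles);
  # cage scale: the MSD level at that crossover
  onset <- scale_ <- numeric(0)
  for (dens in c(1.8, 3.7, 7.4)) {
    vals <- sapply(1:3, function(s) {
      m <- ensemble_msd(simulate_collective(cfg_dense(dens, seed_box = 2000),
                                            seed = s))
      i <- which(m$lag > 0 & m$msd < 0.5 * 625 * m$lag^2)[1L]
      if (is.na(i)) c(max(m$lag), m$msd[which.max(m$lag)]) else
        c(m$lag[i], m$msd[i])
    })
    onset <- c(onset, mean(vals[1, ]))
    scale_ <- c(scale_, mean(vals[2, ]))
  }
  expect_true(all(diff(onset) < 0))
  expect_true(all(diff(scale_) < 0))
})

test_that("identical configurations and seeds reproduce bit-identical tables", {
  cfg <- cfg_dense(3.7, duration = 60)
  a <- simulate_collective(cfg, seed = 9)
  b <- simulate_collective(cfg, seed = 9)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$trails, b$trails)
  c2 <- simulate_collective(cfg, seed = 10)
  expect_false(identical(a$trajectories, c2$trajectories))
})

test_that("the collective field agrees with the R-level superposition", {
  fp <- field_params()
  tt <- seq(0, 40, by = 0.4)  # 10 um spacing at 25 um/s: below ds_max
  tr1 <- trail_record(1L, t = tt, x = 200 + 25 * tt, y = 300 + 40 * sin(tt / 6))
  tr2 <- trail_record(2L, t = tt + 2, x = 1200 - 20 * tt, y = 500 + 10 * tt)
  segs <- do.call(rbind, lapply(list(tr1, tr2), function(tr) {
    n <- nrow(tr)
    cbind(x = (tr$x[-1] + tr$x[-n]) / 2, y = (tr$y[-1] + tr$y[-n]) / 2,
          t = (tr$t[-1] + tr$t[-n]) / 2,
          ds = sqrt(diff(tr$x)^2 + diff(tr$y)^2))
  }))
  pts <- cbind(c(400, 800, 1100), c(350, 450, 520))
  out <- cappsim:::cpp_field_at(pts, 60, segs, 2L, fp$q, fp$D, fp$t_off,
                                fp$T_mem, fp$R_max, 0)
  for (i in 1:3) {
    ref <- field_superposition(pts[i, ], 60, list(tr1, tr2), fp)
    expect_equal(out[i, 1], ref$c, tolerance = 1e-10)
    expect_equal(out[i, 2], ref$grad[1], tolerance = 1e-10)
    expect_equal(out[i, 3], ref$grad[2], tolerance = 1e-10)
  }
})

test_that("spatiotemporal neighbourhood windows include and exclude correctly", {
  tg <- seq(0, 100, by = 5)
  focal <- data.frame(droplet_id = "A", t = tg, x = 0, y = 0)
  nb <- data.frame(droplet_id = "B",
                   t = c(30, 10, 50), x = c(100, 100, 500), y = 0)
  out <- neighborhood_history(rbind(focal, nb), "A")
  # at focal_t = 50: B at t=30 (100 um, 20 s earlier) is inside both windows
  sel <- out[out$focal_t == 50, ]
  expect_true(30 %in% sel$t)
  # at focal_t = 75: B at t=10 is 65 s earlier, outside the time window
  expect_false(10 %in% out[out$focal_t == 75, ]$t)
  # the distant sample never qualifies
  expect_false(500 %in% out$x)
  expect_error(neighborhood_history(rbind(focal, nb), "Z"), "no trajectory")
  none <- neighborhood_history(focal, "A")
  expect_identical(nrow(none), 0L)
})

test_that("simulated spatial steps respect the kinematic bound", {
  sim <- simulate_collective(cfg_dense(3.7, duration = 60), seed = 5)
  tr <- sim$trajectories
  p <- sim$config$dynamics
  for (id in unique(tr$droplet_id)[1:3]) {
    one <- tr[tr$droplet_id == id, ]
    step <- sqrt(diff(one$x)^2 + diff(one$y)^2)
    dt_s <- diff(one$t)
    # allowance for the chemotactic force on top of self-propulsion
    expect_true(all(step <= (p$V0 + 10) * dt_s + 1e-9))
  }
})

test_that("the exploratory 3D mode integrates unit orientations in a periodic box", {
  cfg <- suppressWarnings(
    collective_config(dimension = 3, box_size = 1000, number_density = 22,
                      duration = 30,
                      dynamics = dynamics_params(dt = 0.05, D_r = 0.01),
                      save_every = 20L))
  expect_identical(cfg$N, 22L)
  sim <- simulate_collective(cfg, seed = 1)
  tr <- sim$trajectories
  expect_true(all(c("z", "nz") %in% names(tr)))
  expect_lt(max(abs(sqrt(tr$nx^2 + tr$ny^2 + tr$nz^2) - 1)), 1e-9)
  expect_identical(simulate_collective(cfg, seed = 1)$trajectories, tr)
  m <- ensemble_msd(sim)
  expect_true(all(m$msd >= 0) && m$msd[1] == 0)
})
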