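# Structural model: infusion input, closed-form solver, exposure metrics.

test_that("infusion_rate sums amount/duration over active events", {
  s1 <- infusion_schedule(0, 0.25, 2000)
  expect_equal(infusion_rate(s1, 0.1), 8000)
  expect_equal(infusion_rate(s1, 0.3), 0)
  s2 <- infusion_schedule(c(0, 0.25), c(0.25, 8), c(2000, 1000))
  expect_equal(infusion_rate(s2, 4), 125)
  # overlapping events: rates add
  s3 <- infusion_schedule(c(0, 0), c(1, 2), c(100, 100))
  expect_equal(infusion_rate(s3, 0.5), 150)
  # window is half-open: the rate at an event end belongs to the next event
  expect_equal(infusion_rate(s2, 0.25), 125)
})

test_that("schedule validation rejects bad events and grids", {
  expect_error(infusion_schedule(0, 0, 100), "duration")
  expect_error(infusion_schedule(0, 1, -5), "amount")
  expect_error(infusion_schedule(-1, 1, 5), "start")
  expect_error(solve_profile(med_params(), ld_only(), c(2, 1)),
               "increasing")
  bad <- unclass(med_params())
  bad["CL"] <- -1
  expect_error(solve_profile(bad, ld_only(), c(0, 1)), "positive")
})

test_that("empty schedule gives an all-zero profile", {
  prof <- solve_profile(med_params(), infusion_schedule(numeric(0),
                                                        numeric(0),
                                                        numeric(0),
                                                        horizon_h = 10),
                        times = c(0, 1, 5, 10))
  expect_equal(prof$c_plasma, rep(0, 4))
  expect_equal(prof$c_elf, rep(0, 4))
})

test_that("continuous infusion converges to the closed-form steady state", {
  p <- med_params()
  # 1 g per 8 h back-to-back: constant 125 mg/h
  prof <- solve_profile(p, plain_ci(1000, horizon = 400), times = c(399, 400))
  expect_equal(prof$c_plasma[2], 125 / 11.219, tolerance = 1e-6)
  prof2 <- solve_profile(p, plain_ci(2000, horizon = 400), times = c(400))
  expect_equal(prof2$c_elf[1],
               (250 / 11.219) * (10.143 * 18.539) / (25.614 * 19.424),
               tolerance = 1e-6)
  # steady_state() agrees with the long-run solver
  ss <- steady_state(p, 250)
  expect_equal(unname(ss["css_plasma"]), prof2$c_plasma[1],
               tolerance = 1e-6)
  expect_equal(unname(ss["css_elf"]), prof2$c_elf[1], tolerance = 1e-6)
  expect_equal(steady_state(p, 0), c(css_plasma = 0, css_elf = 0))
  # no transfer into ELF -> zero ELF steady state
  p2 <- unclass(p); p2["K13"] <- 1e-9
  expect_equal(unname(steady_state(p2, 250)["css_elf"]), 0,
               tolerance = 1e-6)
})

test_that("analytic and numeric solutions agree on random parameter draws", {
  sched <- regimen_preset("2g_ld_2g_q8h_ci")
  tt <- seq(0, 72, by = 1.5)
  for (p in random_params(5, seed = 11)) {
    a <- solve_profile(p, sched, tt)
    b <- solve_profile(p, sched, tt, method = "ode")
    expect_lt(max(abs(a$c_plasma - b$c_plasma) /
                    pmax(abs(b$c_plasma), 1e-6)), 1e-6)
    expect_lt(max(abs(a$c_elf - b$c_elf) / pmax(abs(b$c_elf), 1e-6)), 1e-6)
  }
})

test_that("mass is conserved when clearance is negligible", {
  p <- unclass(med_params())
  p["CL"] <- 1e-8
  tt <- c(0.1, 0.25, 1, 4, 8)
  prof <- solve_profile(p, infusion_schedule(0, 0.25, 2000), tt)
  infused <- pmin(tt, 0.25) * 8000
  expect_equal(rowSums(prof$amounts), infused, tolerance = 1e-6)
})

test_that("profiles superpose: LD + CI equals LD profile plus CI profile", {
  p <- med_params()
  tt <- seq(0, 24, by = 0.5)
  both <- solve_profile(p, regimen_preset("2g_ld_1g_q8h_ci",
                                          horizon_h = 24), tt)
  ld <- solve_profile(p, ld_only(), tt)
  ci <- solve_profile(p, infusion_schedule(0.25 + 8 * (0:2), rep(8, 3),
                                           rep(1000, 3)), tt)
  expect_equal(both$c_plasma, ld$c_plasma + ci$c_plasma, tolerance = 1e-8)
  expect_equal(both$c_elf, ld$c_elf + ci$c_elf, tolerance = 1e-8)
  # and doubling every dose doubles every concentration
  half <- solve_profile(p, regimen_preset("2g_ld_1g_q8h_ci",
                                          horizon_h = 24), tt)
  dbl <- solve_profile(p, infusion_schedule(c(0, 0.25 + 8 * (0:2)),
                                            c(0.25, rep(8, 3)),
                                            c(4000, rep(2000, 3))), tt)
  expect_equal(dbl$c_plasma, 2 * half$c_plasma, tolerance = 1e-8)
})

test_that("auc_trapezoid matches simple geometry and the mass closed form", {
  expect_equal(auc_trapezoid(c(10, 10), c(0, 24)), 240)
  expect_equal(auc_trapezoid(c(0, 10), c(0, 10)), 50)
  expect_error(auc_trapezoid(1:3, 1:2), "length")
  # total plasma AUC of a single dose equals Dose/CL (linear system)
  p <- med_params()
  tt <- seq(0, 80, by = 0.02)
  prof <- solve_profile(p, ld_only(), tt)
  expect_equal(auc_trapezoid(prof$c_plasma, tt), 2000 / p[["CL"]],
               tolerance = 1e-3)
})

test_that("daily_average_auc and penetration_ratio follow their formulas", {
  expect_equal(daily_average_auc(720, 72), 240)
  expect_equal(daily_average_auc(240, 24), 240)
  expect_equal(daily_average_auc(100, 48), 50)
  expect_error(daily_average_auc(100, 0), "> 0")
  expect_equal(penetration_ratio(100, 100), 100)
  expect_equal(penetration_ratio(84.1, 287.6), 29.24, tolerance = 1e-3)
  expect_error(penetration_ratio(10, 0), "> 0")
})

test_that("steady-state AUC ratio equals the closed-form penetration", {
  p <- med_params()
  expect_equal(steady_state_penetration(p),
               100 * (10.143 * 18.539) / (25.614 * 19.424),
               tolerance = 1e-12)
  # AUC-based ratio over a post-steady-state window agrees within 0.5%
  sched <- plain_ci(2000, horizon = 72)
  tt <- seq(0, 72, by = 0.1)
  prof <- solve_profile(p, sched, tt)
  ratio <- penetration_ratio(auc_window(prof, 48, 72, "elf"),
                             auc_window(prof, 48, 72, "plasma"))
  expect_equal(ratio, steady_state_penetration(p), tolerance = 5e-3)
})
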