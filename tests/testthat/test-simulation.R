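test_that("the integrator reproduces exponential decay to closed form", {
  # dy/dt = -y as a one-species degradation reaction; 1 s at dt = 0.01 s
  tr <- integrate_rk4(decay_model(rate = 1), 1, duration = 1 / 3600,
                      dt = 0.01, output_stride = 1)
  expect_equal(tr$y[1], 1)
  expect_lt(abs(tr$y[nrow(tr)] - exp(-1)), 1e-9)
})

test_that("a zero right-hand side leaves the state constant", {
  m <- list(k = numeric(0), sub1 = integer(0), sub2 = integer(0),
            Si = integer(0), Sj = integer(0), Sx = numeric(0),
            species = c("a", "b"))
  tr <- integrate_rk4(m, c(0.3, 0.7), duration = 1, dt = 1,
                      output_stride = 600)
  expect_true(all(tr$a == 0.3) && all(tr$b == 0.7))
})

test_that("step-halving error on the full network scales like dt^4", {
  p <- ref_params()
  st <- equilibrate(p, nfkb_protocol(t_equilibrate = 33))
  m <- nfkb_model(p, TR = 1)
  run <- function(dt) {
    tr <- integrate_rk4(m, st, duration = 2, dt = dt, output_stride = 240)
    as.matrix(tr[, m$species])
  }
  y4 <- run(4); y2 <- run(2); y1 <- run(1)
  e42 <- max(abs(y4 - y2))
  e21 <- max(abs(y2 - y1))
  # classical RK4: halving dt shrinks the error ~16x
  expect_gt(e42 / e21, 8)
  expect_lt(e42 / e21, 40)
  # and the dt = 1 curve is converged to high relative accuracy
  expect_lt(e21 / max(abs(y1)), 1e-6)
})

test_that("stimulation protocols compose exactly", {
  p <- ref_params()
  pr_ab <- nfkb_protocol(TR = 1, t_equilibrate = 2, t_stimulate = 2, dt = 5)
  st0 <- suppressWarnings(equilibrate(p, pr_ab))
  full <- simulate_response(p, pr_ab, state0 = st0)
  pr_a <- nfkb_protocol(TR = 1, t_equilibrate = 2, t_stimulate = 1, dt = 5)
  first <- simulate_response(p, pr_a, state0 = st0)
  mid <- stats::setNames(as.numeric(first[nrow(first), nfkb_species()$species]),
                         nfkb_species()$species)
  second <- simulate_response(p, pr_a, state0 = mid)
  sp <- nfkb_species()$species
  chained <- rbind(as.matrix(first[-nrow(first), sp]),
                   as.matrix(second[, sp]))
  expect_identical(unname(as.matrix(full[, sp])), unname(chained))
})

test_that("total NF-kB stays at 0.06 along stimulated trajectories", {
  p <- ref_params()
  tr <- ref_trajectory()
  tot <- nfkb_total(tr, p)
  expect_lt(max(abs(tot - p[["NFkB_total"]])) / p[["NFkB_total"]], 1e-9)
})

test_that("equilibration starts cytoplasmic and settles near steady state", {
  p <- ref_params()
  # no IKK source: the kinase module stays empty
  p0 <- p; p0[["Kprod"]] <- 0
  class(p0) <- class(p)
  eq0 <- suppressWarnings(equilibrate(p0, nfkb_protocol(t_equilibrate = 5,
                                                        dt = 5)))
  expect_equal(unname(eq0[c("IKKn", "IKKa", "IKKi")]), rep(0, 3))

  eq33 <- suppressWarnings(equilibrate(p))
  # resting NF-kB is cytoplasm-sequestered: nuclear share is tiny
  bound_cyt <- eq33[["IkBa_NFkB"]] + eq33[["IkBb_NFkB"]] + eq33[["IkBe_NFkB"]]
  expect_lt(eq33[["NFkBn"]], 1e-3 * bound_cyt)
  # doubling the pre-run changes no species drastically (slow IkBe
  # turnover leaves a residual drift of a few percent)
  eq66 <- suppressWarnings(equilibrate(p, nfkb_protocol(t_equilibrate = 66)))
  rel <- abs(eq66 - eq33) / pmax(abs(eq66), 1e-12)
  expect_lt(max(rel), 0.1)
  expect_lt(stats::median(rel), 0.01)
  # a strict tolerance reports the residual drift
  expect_warning(equilibrate(p, warn_tol = 1e-9), "not converged")
})

test_that("TR = 0 leaves nuclear NF-kB at its pre-stimulus level", {
  p <- ref_params()
  tr <- suppressWarnings(simulate_response(p, nfkb_protocol(TR = 0,
                                                            t_stimulate = 2)))
  expect_lt(diff(range(tr$NFkBn)) / tr$NFkBn[1], 0.02)
})

test_that("TR = 1 gives a damped first peak followed by decline", {
  tr <- ref_trajectory()
  f <- extract_features(tr)
  expect_gt(f$first_maximum, 10 * f$steady_state)
  expect_true(f$first_translocation_time > 0.2 &&
                f$first_translocation_time < 1.5)
  expect_equal(classify_pattern(f), "damped_oscillation")
})

test_that("the nominal column oscillates faster than the fitted column", {
  second_peak <- function(col) {
    p <- nfkb_parameters(col)
    tr <- suppressWarnings(
      simulate_response(p, nfkb_protocol(TR = 1, t_stimulate = 10)))
    pk <- detect_peaks(tr$time_h, tr$NFkBn)
    pk$time_h[pk$type == "peak"][2]
  }
  t_nom <- second_peak("nominal")
  t_fit <- second_peak("fitted")
  # the nominal constants give a 3.2x larger IKK pool (Kprod/Kdeg) and a
  # markedly earlier return of nuclear NF-kB; frequency-sensitive
  # statistics therefore depend strongly on the column choice
  expect_lt(t_nom, 3.6)
  expect_gt(t_fit, 4.2)
})

test_that("the compiled integrator agrees with an adaptive stiff solver", {
  skip_if_not_installed("deSolve")
  p <- ref_params()
  st <- equilibrate(p)
  m <- nfkb_model(p, TR = 1)
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    v <- m$k
    h1 <- m$sub1 > 0; v[h1] <- v[h1] * y[m$sub1[h1]]
    h2 <- m$sub2 > 0; v[h2] <- v[h2] * y[m$sub2[h2]]
    dy <- numeric(length(y))
    for (tpl in seq_along(m$Si)) {
      dy[m$Si[tpl]] <- dy[m$Si[tpl]] + m$Sx[tpl] * v[m$Sj[tpl]]
    }
    list(dy)
  }
  times <- seq(0, 2 * 3600, by = 600)
  ls <- deSolve::ode(y = unname(st[m$species]), times = times, func = rhs,
                     parms = NULL, method = "lsoda",
                     rtol = 1e-10, atol = 1e-14)
  ours <- integrate_rk4(m, st[m$species], duration = 2, dt = 1,
                        output_stride = 600)
  for (j in seq_along(m$species)) {
    a <- ls[, j + 1]; b <- ours[[m$species[j]]]
    expect_lt(max(abs(a - b)), 1e-6 * max(max(abs(a)), 1e-12))
  }
})

test_that("dose-response sweeps are monotone, sigmoidal and reversible", {
  p <- ref_params()
  dr <- suppressWarnings(dose_response(p, nfkb_tr_grid(points_per_decade = 3)))
  expect_s3_class(dr, "nfkb_dose_response")
  expect_true(!is.unsorted(dr$forward))
  h <- hysteresis(dr)
  expect_false(h$hysteresis)
  expect_lt(h$max_rel_gap, 0.05)
  low <- dr$forward[dr$TR > 0][1]
  high <- dr$forward[which.max(dr$TR)]
  expect_gt(log10(high / low), 2.5)

  # degenerate grid: the response equals the equilibrated level
  dr0 <- suppressWarnings(dose_response(p, 0))
  eq <- suppressWarnings(equilibrate(p))
  expect_lt(abs(dr0$forward[1] - eq[["NFkBn"]]) / eq[["NFkBn"]], 0.05)
  expect_lt(abs(dr0$backward[1] - dr0$forward[1]) / dr0$forward[1], 0.05)

  expect_error(dose_response(p, numeric(0)), "empty")
  expect_error(dose_response(p, c(0.1, 0.01)), "ascending")
})
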