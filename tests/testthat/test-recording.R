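test_that("sum vector is the per-sample Euclidean magnitude", {
  expect_equal(compute_sv(recording(1, 0, 0))$values, 1)
  expect_equal(compute_sv(recording(0.6, 0.8, 0))$values, 1)
  set.seed(1)
  ax <- rnorm(50); ay <- rnorm(50); az <- rnorm(50)
  rec <- recording(ax, ay, az)
  # element-wise square/sum/sqrt oracle
  expected <- vapply(seq_len(50), function(i)
    sqrt(ax[i]^2 + ay[i]^2 + az[i]^2), numeric(1))
  expect_equal(compute_sv(rec)$values, expected, tolerance = 1e-12)
  expect_identical(compute_sv(rec)$fs, rec$fs)
})

test_that("sum vector is invariant under axis rotations", {
  set.seed(7)
  ax <- rnorm(40); ay <- rnorm(40); az <- rnorm(40)
  sv0 <- compute_sv(recording(ax, ay, az))$values
  for (i in 1:5) {
    R <- random_rotation()
    rot <- R %*% rbind(ax, ay, az)
    sv1 <- compute_sv(recording(rot[1, ], rot[2, ], rot[3, ]))$values
    expect_equal(sv1, sv0, tolerance = 1e-9)
  }
})

test_that("recording validates its invariants", {
  expect_error(recording(numeric(0), numeric(0), numeric(0)), "at least one")
  expect_error(recording(1:3, 1:2, 1:3), "identical length")
  expect_error(recording(1, 1, 1, fs = 0), "positive integer")
  expect_error(recording(3, 0, 0, range_g = 2), "sensor range")
  expect_silent(recording(1.9, 0, 0, range_g = 2))
})

test_that("active-period criterion is a strict range test", {
  expect_false(is_active_period(sv_series(rep(1, 100), 100)))
  expect_true(is_active_period(sv_series(c(rep(1, 50), 0.6, 2.0), 100)))
  # range exactly at the threshold does not qualify
  expect_false(is_active_period(sv_series(c(1, 2.01), 100)))
  expect_true(is_active_period(sv_series(c(1, 2.011), 100)))
})

test_that("active-period is monotone when the maximum rises", {
  v <- c(rep(1, 30), 1.9)
  base <- is_active_period(sv_series(v, 100))
  v[31] <- 2.5
  expect_true(!base || is_active_period(sv_series(v, 100)))
  expect_true(is_active_period(sv_series(v, 100)))
})

test_that("window extraction slices [center - h, center + h) of the source", {
  sv <- sv_series(seq_len(6000) / 1000, 100)
  w <- extract_window(sv, 3001)           # 0-based center 3000
  expect_length(w$values, 200)
  expect_equal(w$values, sv$values[2901:3100])
  expect_equal(w$values[101], sv$values[3001])  # center at offset fs
  # length formula at another rate
  expect_length(extract_window(sv_series(rep(1, 100), 10), 50)$values, 20)
})

test_that("adjacent windows tile the source series", {
  sv <- sv_series(runif(1000) + 1, 100)
  w1 <- extract_window(sv, 301)
  w2 <- extract_window(sv, 501)
  expect_equal(c(w1$values, w2$values), sv$values[201:600])
})

test_that("edge-overrunning windows are skipped or reflected per policy", {
  sv <- sv_series(seq_len(500), 100)
  expect_null(extract_window(sv, 31))
  expect_error(extract_window(sv, 0), "out of bounds")
  expect_error(extract_window(sv, 501), "out of bounds")
  w <- extract_window(sv, 31, edge_policy = "reflect")
  expect_length(w$values, 200)
  # reflected prefix mirrors the series about sample 1
  expect_equal(w$values[70], sv$values[2])
  expect_equal(w$values[72], sv$values[2])
})

test_that("recording CSV round-trips and infers the sampling rate", {
  set.seed(2)
  rec <- recording(rnorm(100), rnorm(100), rnorm(100), fs = 100, id = "r1")
  p <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, p)
  back <- read_recording(p)
  expect_identical(back$fs, 100L)
  expect_equal(back$ax, rec$ax, tolerance = 1e-9)
  expect_equal(back$ay, rec$ay, tolerance = 1e-9)
  expect_equal(back$az, rec$az, tolerance = 1e-9)

  # fs inferred from the median time step
  df <- data.frame(time_s = seq(0, 0.99, by = 0.01), ax_g = 0, ay_g = 0,
                   az_g = 1)
  write.csv(df, p, row.names = FALSE)
  expect_identical(read_recording(p)$fs, 100L)
})

test_that("malformed recording files are rejected", {
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = 1:3 / 100, ax_g = 0, ay_g = 0),
            p, row.names = FALSE)
  expect_error(read_recording(p), "header")
  write.csv(data.frame(time_s = c(0, 0.02, 0.01), ax_g = 0, ay_g = 0,
                       az_g = 1), p, row.names = FALSE)
  expect_error(read_recording(p), "non-monotone")
  write.csv(data.frame(time_s = c(0, 0.01, 0.025, 0.035), ax_g = 0,
                       ay_g = 0, az_g = 1), p, row.names = FALSE)
  expect_error(read_recording(p), "jitter")
})

test_that("dataset manifest round-trips with labels preserved", {
  ds <- simulate_dataset(sim_config(n_falls = 2, n_adls = 2, seed = 3,
                                    duration_s = 10))
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  back <- read_dataset(file.path(d, "manifest.csv"))
  expect_identical(back$label, ds$label)
  expect_identical(back$id, ds$id)
  expect_equal(compute_sv(back$recordings[[1]])$values,
               compute_sv(ds$recordings[[1]])$values, tolerance = 1e-9)
})
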