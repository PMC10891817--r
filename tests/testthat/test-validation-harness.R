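# shared truth for harness tests: 12 well-spread landmarks and a known GS
o_truth <- local({
  set.seed(55)
  mv <- matrix(runif(36, -40, 40), 12, 3)
  gs_t <- rigid_from_params(c(20, -10, 35, 8, -3, 5))
  list(moving = landmark_set(mv, paste0("L", 1:12), "moving"),
       fixed = landmark_set(rt_apply(gs_t, mv), paste0("L", 1:12), "fixed"),
       gs = gold_standard(gs_t, landmark_set(mv, paste0("L", 1:12), "moving")))
})

test_that("observer placements are prefix-nested and seed-deterministic", {
  obs <- observer_spec(sigma_mm = 1, seed = 42)
  p5 <- place_landmarks(o_truth$fixed, o_truth$moving, obs, 5, trial = 2,
                        user = "u1")
  p8 <- place_landmarks(o_truth$fixed, o_truth$moving, obs, 8, trial = 2,
                        user = "u1")
  expect_equal(p8$fixed$points[1:5, ], p5$fixed$points)
  expect_equal(p8$moving$points[1:5, ], p5$moving$points)
  again <- place_landmarks(o_truth$fixed, o_truth$moving, obs, 5, trial = 2,
                           user = "u1")
  expect_identical(again$fixed$points, p5$fixed$points)
  other <- place_landmarks(o_truth$fixed, o_truth$moving, obs, 5, trial = 3,
                           user = "u1")
  expect_false(isTRUE(all.equal(other$fixed$points, p5$fixed$points)))
  expect_error(place_landmarks(o_truth$fixed, o_truth$moving, obs, 13),
               "exceeds")
})

test_that("zero-noise placements reproduce truth exactly", {
  obs <- observer_spec(sigma_mm = 0, seed = 1)
  p <- place_landmarks(o_truth$fixed, o_truth$moving, obs, 12)
  expect_equal(p$fixed$points, o_truth$fixed$points)
  expect_equal(p$moving$points, o_truth$moving$points)
})

test_that("placement noise has the declared per-coordinate variance", {
  obs <- observer_spec(sigma_mm = 1, seed = 7)
  errs <- vapply(1:2000, function(tr) {
    p <- place_landmarks(o_truth$fixed, o_truth$moving, obs, 12, trial = tr)
    mean((p$moving$points - o_truth$moving$points)^2)
  }, numeric(1))
  expect_equal(mean(errs), 1.0, tolerance = 0.05)
})

test_that("a zero-noise sweep yields zero errors and the right record count", {
  prot <- validation_protocol()
  recs <- run_sweep(o_truth$fixed, o_truth$moving, o_truth$gs, prot,
                    observers = observer_spec(sigma_mm = 0))
  expect_equal(nrow(recs), 10 * 10 * 2)          # N-values x trials x users
  expect_true(all(recs$fre < 1e-9))
  expect_true(all(recs$rmse2 < 1e-9))
  expect_true(all(recs$n_landmarks %in% 3:12))
})

test_that("sweep is reproducible and prefix-nested across N", {
  prot <- validation_protocol(trials = 3)
  obs <- observer_spec(sigma_mm = 1, seed = 9)
  r1 <- run_sweep(o_truth$fixed, o_truth$moving, o_truth$gs, prot, obs)
  r2 <- run_sweep(o_truth$fixed, o_truth$moving, o_truth$gs, prot, obs)
  expect_identical(r1, r2)
})

test_that("curves aggregate means and SDs per (patient, user, N)", {
  prot <- validation_protocol(trials = 4)
  recs <- run_sweep(o_truth$fixed, o_truth$moving, o_truth$gs, prot,
                    observer_spec(sigma_mm = 1, seed = 3))
  cur <- aggregate_curves(recs)
  expect_equal(nrow(cur), 10 * 2)                # N-values x users
  one <- recs[recs$user == "user1" & recs$n_landmarks == 5, ]
  row <- cur[cur$user == "user1" & cur$n_landmarks == 5, ]
  expect_equal(row$fre_mean, mean(one$fre))
  expect_equal(row$rmse2_sd, sd(one$rmse2))
  # identical records give SD zero and mean equal to the common value
  recs0 <- run_sweep(o_truth$fixed, o_truth$moving, o_truth$gs,
                     validation_protocol(trials = 2),
                     observer_spec(sigma_mm = 0))
  cur0 <- aggregate_curves(recs0)
  expect_true(all(cur0$fre_sd == 0))
})

test_that("optimal-N selection applies the tolerance-on-minimum rule", {
  prot <- validation_protocol()
  mk_curves <- function(rmse2_by_n) {
    data.frame(patient = "P1", user = "user1", n_landmarks = 3:12,
               rmse1_rot_mean = 0, rmse1_trans_mean = 0, fre_mean = 0,
               rmse2_mean = rmse2_by_n, rmse1_rot_sd = 0, rmse1_trans_sd = 0,
               fre_sd = 0, rmse2_sd = 0)
  }
  # strictly decreasing then flat from N = 10
  dec <- c(10, 8, 6, 5, 4, 3, 2, 1, 1, 1)
  expect_equal(select_optimal_n(mk_curves(dec), prot), 10L)
  # constant curve -> smallest N wins
  expect_equal(select_optimal_n(mk_curves(rep(2, 10)), prot), 3L)
  # single-N protocol returns that N
  one <- mk_curves(dec)[8, , drop = FALSE]
  expect_equal(select_optimal_n(one, validation_protocol(n_min = 10, n_max = 10,
                                                         chosen_n = 10)), 10L)
})

test_that("bounds checking is inclusive and lists offenders", {
  prot <- validation_protocol(trials = 2)
  recs <- run_sweep(o_truth$fixed, o_truth$moving, o_truth$gs, prot,
                    observer_spec(sigma_mm = 0))
  expect_true(check_bounds(recs, prot)$pass)
  at <- which(recs$n_landmarks == prot$chosen_n)
  recs$fre[at[1]] <- 8.0                     # exactly at the bound: passes
  expect_true(check_bounds(recs, prot)$pass)
  recs$fre[at[1]] <- 8.1                     # just above: fails, listed
  cb <- check_bounds(recs, prot)
  expect_false(cb$pass)
  expect_equal(nrow(cb$offenders), 1L)
  expect_equal(cb$offenders$fre, 8.1)
})

test_that("boxplot summaries use linear-interpolation quantiles and flag outliers", {
  recs <- data.frame(patient = "P1", user = "u1", trial = 1:5, n_landmarks = 10,
                     rmse1_rot = 0, rmse1_trans = 0, fre = c(1, 2, 3, 4, 5),
                     rmse2 = 0)
  s <- boxplot_summary(recs, 10)
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$max, 5)
  one <- boxplot_summary(recs[3, ], 10)
  expect_true(all(unlist(one[c("min", "q1", "median", "q3", "max")]) == 3))
  out <- recs[1:4, ]; out$fre <- c(2.0, 2.5, 3.0, 10.0)
  s2 <- boxplot_summary(out, 10)
  expect_equal(s2$n_outliers, 1L)
  expect_equal(s2$max, 10.0)
})

test_that("index-inflated noise makes mean FRE increase with N", {
  # sigma_k = sigma0 (1 + gamma k) emulates harder placement of later
  # landmarks; aggregate over many trials
  prot <- validation_protocol(trials = 150, users = "u1")
  obs <- observer_spec(sigma_mm = 0.8, index_inflation = 0.35, seed = 77)
  recs <- run_sweep(o_truth$fixed, o_truth$moving, o_truth$gs, prot, obs)
  cur <- aggregate_curves(recs)
  expect_true(all(diff(cur$fre_mean) > 0))
})
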