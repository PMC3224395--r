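test_that("activation matrix satisfies its structural invariants", {
  prof <- quick_profile()
  act <- make_activation_matrix(prof)
  expect_identical(dim(act), c(4L, 15L))
  expect_identical(rownames(act), c("ED", "PL", "FCU", "ECR"))
  expect_true(all(act >= 0 & act <= 1))
  # rest column is silent; every other class activates something
  expect_identical(unname(act[, 1]), rep(0, 4))
  expect_true(all(apply(act[, -1], 2, max) > 0))
  # muscle-function anatomy: FCU drives ulnar deviation, ECR radial
  expect_gt(act["FCU", 4], act["FCU", 3])
  expect_gt(act["FCU", 11], act["FCU", 10])
  expect_gt(act["ECR", 3], act["ECR", 4])
})

test_that("adjacent middle-ring pinches are the closest activation columns", {
  act <- make_activation_matrix(quick_profile())
  pinch <- c(5:8, 12:15)
  d <- as.matrix(dist(t(act[, pinch])))
  dimnames(d) <- list(pinch, pinch)
  diag(d) <- NA
  pairs <- which(!is.na(d) & upper.tri(d), arr.ind = TRUE)
  dists <- d[pairs]
  ord <- order(dists)
  top2 <- apply(pairs[ord[1:2], , drop = FALSE], 1, function(z) {
    paste(sort(as.integer(rownames(d)[z])), collapse = "-")
  })
  expect_setequal(top2, c("6-7", "13-14"))
})

test_that("separability scales between-class contrast monotonically", {
  p1 <- quick_profile(separability = 1)
  p05 <- quick_profile(separability = 0.5)
  a1 <- make_activation_matrix(p1, seed = 3)
  a05 <- make_activation_matrix(p05, seed = 3)
  d1 <- dist(t(a1[, -1]))
  d05 <- dist(t(a05[, -1]))
  expect_true(all(d1 > d05))
})

test_that("simulated recordings are deterministic and label-stable across seeds", {
  sched <- quick_schedule()
  prof <- quick_profile()
  r1 <- simulate_recording(sched, prof, seed = 10)
  r2 <- simulate_recording(sched, prof, seed = 10)
  expect_identical(r1$channels, r2$channels)
  expect_identical(r1$force, r2$force)
  r3 <- simulate_recording(sched, prof, seed = 11)
  expect_false(identical(r1$channels, r3$channels))
  expect_identical(r1$labels, r3$labels)
  expect_identical(nrow(r1$channels), length(r1$labels))
  expect_identical(length(r1$force), length(r1$labels))
})

test_that("rest-only stretches sit at the noise floor; events rise above it", {
  prof <- quick_profile()
  rec <- quick_recording(seed = 2, profile = prof)
  rest <- rec$labels == 1L
  for (m in c("ED", "PL", "FCU", "ECR")) {
    rest_rms <- sqrt(mean(rec$channels[rest, m]^2))
    expect_equal(rest_rms, prof$noise_floor, tolerance = 0.2)
    # grasp event (class 2) activates every muscle above rest level
    active_rms <- sqrt(mean(rec$channels[rec$labels == 2L, m]^2))
    expect_gt(active_rms, 2 * rest_rms)
  }
})

test_that("protocol D torque alternates sign three times per repetition", {
  prof <- quick_profile()
  sched <- protocol_schedule("D")
  rec <- simulate_recording(sched, prof, seed = 5)
  ev <- sched$events
  # mean torque during each sub-event, in chronological order
  signs <- sapply(seq_len(nrow(ev)), function(i) {
    idx <- which(rec$labels %in% 3:4 &
      seq_along(rec$labels) > ev$start_s[i] * rec$fs &
      seq_along(rec$labels) <= (ev$start_s[i] + ev$duration_s[i]) * rec$fs)
    sign(mean(rec$torque[idx]))
  })
  expect_identical(signs, rep(c(1, -1, 1, -1), 3))
  # three sign changes within each repetition block
  for (b in 0:2) {
    block <- signs[(4 * b + 1):(4 * b + 4)]
    expect_identical(sum(diff(block) != 0), 3L)
  }
  # radial positive, ulnar negative, near 50% MVC torque
  radial <- rec$torque[rec$labels == 3L]
  ulnar <- rec$torque[rec$labels == 4L]
  expect_gt(max(radial), 0.4 * prof$max_torque)
  expect_lt(min(ulnar), -0.4 * prof$max_torque)
})

test_that("force track follows grasp events toward the 50% MVC level", {
  prof <- quick_profile(max_force = 4)
  rec <- simulate_recording(protocol_schedule("C"), prof, seed = 8)
  grasp <- rec$labels == 2L
  expect_gt(max(rec$force[grasp]), 0.4 * prof$max_force)
  expect_lt(max(abs(rec$force[!grasp])), 0.2 * prof$max_force)
})

test_that("schedules whose events exceed the duration are rejected", {
  bad <- quick_schedule()
  bad$total_duration_s <- 3
  expect_error(simulate_recording(bad, quick_profile()), "exceed")
})

test_that("cohort simulation is reproducible with group-level contrasts", {
  p_sen <- draw_cohort_profiles(12, "senior", seed = 42)
  p_sen2 <- draw_cohort_profiles(12, "senior", seed = 42)
  expect_identical(p_sen, p_sen2)
  expect_identical(length(unique(vapply(p_sen, `[[`, "", "subject_id"))), 12L)
  p_yng <- draw_cohort_profiles(12, "young", seed = 42)
  f_sen <- vapply(p_sen, `[[`, 0, "max_force")
  f_yng <- vapply(p_yng, `[[`, 0, "max_force")
  expect_lt(mean(f_sen), mean(f_yng))
  s_sen <- vapply(p_sen, `[[`, 0, "separability")
  s_yng <- vapply(p_yng, `[[`, 0, "separability")
  expect_lt(mean(s_sen), mean(s_yng))
})

test_that("each cohort recording provides at least 6 s of labelled data", {
  recs <- simulate_cohort(
    2, "senior",
    protocols = standard_protocols(), seed = 9
  )
  expect_identical(length(recs), 12L) # 2 subjects x 6 protocols
  for (rec in recs) {
    expect_gte(sum(rec$labels > 1L), 6144L)
    expect_true(all(rec$labels %in% 1:15))
  }
})
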