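test_that("the 60-minute rolling gap splits records at the documented boundary", {
  expect_equal(nrow(aggregate_events(make_records(c(0, 59)))), 1L)
  expect_equal(nrow(aggregate_events(make_records(c(0, 60)))), 2L)

  ten <- make_records(seq(0, 90, by = 10))
  expect_equal(nrow(aggregate_events(ten, gap_min = 60)), 1L)
  expect_equal(nrow(aggregate_events(ten, gap_min = 5)), 10L)
})

test_that("event counts match the brute-force chain-splitting oracle", {
  set.seed(101)
  for (rep in 1:25) {
    minutes <- sort(sample.int(2000, sample(2:40, 1)))
    gap <- sample(c(5, 30, 60, 120), 1)
    got <- nrow(aggregate_events(make_records(minutes), gap_min = gap))
    expect_equal(got, oracle_split_count(minutes, gap))
  }
})

test_that("event count is monotone non-increasing in the gap and conserves records", {
  set.seed(7)
  minutes <- sort(sample.int(3000, 60))
  rec <- rbind(make_records(minutes, camera = "c1"),
               make_records(minutes + 13, camera = "c2"))
  gaps <- c(1, 5, 15, 30, 60, 120, 480)
  counts <- vapply(gaps, function(g) nrow(aggregate_events(rec, g)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  ev <- aggregate_events(rec, 60)
  expect_equal(sum(ev$n_images), nrow(rec))          # one annotation per image here
  asg <- event_assignments(rec)
  expect_true(all(tapply(asg$camera_id, asg$event_id,
                         function(x) length(unique(x)) == 1L)))
})

test_that("re-aggregating event-start records reproduces the segmentation", {
  set.seed(11)
  rec <- make_records(sort(sample.int(2000, 50)))
  ev <- aggregate_events(rec, 60)
  starts <- make_records(as.numeric(difftime(ev$start, min(rec$timestamp),
                                             units = "mins")))
  expect_equal(nrow(aggregate_events(starts, 60)), nrow(ev))
})

test_that("unsorted input is an error, never silently re-sorted", {
  rec <- make_records(c(100, 0))
  expect_error(aggregate_events(rec), "not time-sorted")
})

test_that("event composition takes the max of simultaneous counts and distinct ids", {
  # three images each with one adult female, no ids
  rec <- make_records(c(0, 1, 2))
  comp <- event_composition(rec)
  expect_equal(comp[["ADF"]], 1L)
  expect_equal(sum(comp), 1L)

  # at most 2 adult males per image, but 3 distinct identified males
  rec2 <- rbind(
    make_records(c(0, 0), age = "AD", sex = "M", id = c("m1", "m2"), side = "R"),
    make_records(c(1, 1), age = "AD", sex = "M", id = c("m2", "m3"), side = "R"))
  rec2$image_id <- c("i1", "i1", "i2", "i2")
  comp2 <- event_composition(rec2)
  # set-union oracle over the identified ids
  expect_equal(comp2[["ADM"]],
               length(unique(rec2$individual_id)))

  # five unannotatable animals in one image
  rec3 <- make_records(rep(0, 5), age = "UNK", sex = "U")
  rec3$image_id <- "img1"
  expect_equal(event_composition(rec3)[["UNK"]], 5L)
})

test_that("group size dominates the largest single-image animal count", {
  set.seed(23)
  sim <- simulate_photo_records(sim_config(n_events = 12), seed = 23)
  rec <- event_assignments(sim$records)
  ev <- aggregate_events(sim$records)
  for (e in ev$event_id) {
    er <- rec[rec$event_id == e, ]
    expect_gte(ev$group_size[ev$event_id == e], max(table(er$image_id)))
  }
})

test_that("trapping rate is simple arithmetic on totals", {
  expect_equal(trapping_rate(0, 500), 0)
  expect_equal(round_half_up(trapping_rate(32, 1328), 2), 2.41)
  expect_equal(trapping_rate(13, 1000), 1.30)
  expect_error(trapping_rate(3, 0), "positive")
  # invariant to how effort is split across cameras
  dep_a <- data.frame(detector_id = c("c1", "c2"),
                      start = "2018-01-01", end = c("2018-01-11", "2018-01-01"))
  dep_b <- data.frame(detector_id = c("c1", "c2"),
                      start = "2018-01-01", end = c("2018-01-06", "2018-01-06"))
  expect_equal(trapping_rate(4, effort_calendar(dep_a, 0)),
               trapping_rate(4, effort_calendar(dep_b, 0)))
})

test_that("naive occupancy counts detected sites over surveyed sites", {
  expect_equal(naive_occupancy(character(0), paste0("s", 1:71)), 0)
  expect_equal(naive_occupancy(paste0("s", 1:10), paste0("s", 1:10)), 1)
  expect_equal(naive_occupancy(paste0("s", 1:3), paste0("s", 1:10)), 0.3)
  expect_error(naive_occupancy("elsewhere", paste0("s", 1:10)), "not in the site list")
})

test_that("zone summaries restrict events, effort and sites to the zone", {
  set.seed(5)
  sim <- simulate_photo_records(sim_config(n_events = 30), seed = 5)
  ev <- aggregate_events(sim$records)
  dep <- data.frame(detector_id = sim$detectors$detector_id,
                    start = "2018-01-09", end = "2018-07-01")
  eff <- effort_calendar(dep, 0.75)
  core <- detection_summary(ev, eff, sim$detectors, zone = "core")
  # filter-and-count oracle
  core_ids <- sim$detectors$detector_id[sim$detectors$zone == "core"]
  expect_equal(core$n_events, sum(ev$camera_id %in% core_ids))
  expect_equal(core$effort_days, sum(eff$camera_days$days[eff$camera_days$detector_id %in% core_ids]))
  expect_equal(core$naive_occupancy,
               length(unique(ev$camera_id[ev$camera_id %in% core_ids])) / length(core_ids))
  # zones partition the cameras: per-zone event counts add up to the park total
  park <- detection_summary(ev, eff, sim$detectors)
  outer_z <- detection_summary(ev, eff, sim$detectors, zone = "park")
  expect_equal(core$n_events + outer_z$n_events, park$n_events)
  expect_error(detection_summary(ev, eff, sim$detectors, zone = "atlantis"),
               "unknown zone")
})
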