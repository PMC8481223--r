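test_that("published tallies load with the printed totals", {
  t17 <- table2_counts(2017)
  t18 <- table2_counts(2018)
  expect_equal(sum(t17), 159)
  expect_equal(sum(t18), 205)
  tbl <- niokolo_table2()
  expect_equal(sum(tbl$n_id_right[tbl$year == 2017]), 6)
  expect_equal(sum(tbl$n_id_right[tbl$year == 2018]), 40)
  expect_error(table2_counts(1999), "no tallies")
})

test_that("tallies over events conserve animals", {
  set.seed(44)
  sim <- simulate_photo_records(sim_config(n_events = 15), seed = 44)
  ev <- aggregate_events(sim$records)
  tl <- tally(ev)
  expect_equal(tl$total, sum(ev$group_size))
  by_year <- tally(ev, by_year = TRUE)
  expect_equal(sum(by_year$total), tl$total)

  one <- ev[1, ]
  one[CT_CATEGORIES] <- as.list(c(0, 1, rep(0, 9)))  # one adult female
  one$group_size <- 1
  expect_equal(tally(one)$ADF, 1)
  expect_equal(tally(one)$total, 1)
})

test_that("sex ratios reproduce the printed survey values", {
  t17 <- table2_counts(2017); t18 <- table2_counts(2018)
  expect_equal(sex_ratio(t17, "overall")$ratio_1dp, 1.0)   # 23:23
  expect_equal(sex_ratio(t17, "adult")$ratio_1dp, 0.7)     # 12:17
  expect_equal(sex_ratio(t18, "overall")$ratio_1dp, 1.3)   # 53:40
  expect_equal(sex_ratio(t18, "adult")$ratio_1dp, 0.9)     # 30:32
  none <- t17; none[c("ADF", "2YF", "1YF")] <- 0
  expect_error(sex_ratio(none, "overall"), "no females")
})

test_that("age structure excludes unknowns by default and sums to 100", {
  st <- age_structure(table2_counts(2017))
  expect_equal(sum(st$pct), 100)
  expect_equal(st$pct_int[st$class == "JUV"], 27)  # 32 / 119
  expect_equal(sum(st$n), 119)

  st18 <- age_structure(table2_counts(2018))
  expect_equal(st18$pct_int[st18$class == "1Y"], 13)

  stU <- age_structure(table2_counts(2017), include_unknown = TRUE)
  expect_equal(sum(stU$pct), 100)
  expect_equal(sum(stU$n), 159)

  solo <- setNames(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 7, 0), CT_CATEGORIES)
  expect_equal(age_structure(solo)$pct[1], 100)
})

test_that("unsexed adults are allocated by the adult sex ratio", {
  t17 <- table2_counts(2017)
  expect_equal(adjusted_adult_females(t17), 17 + 23 * 17 / 29, tolerance = 1e-12)
  expect_equal(round_half_up(adjusted_adult_females(t17)), 30)
  t18 <- table2_counts(2018)
  expect_equal(adjusted_adult_females(t18), 32 + 12 * 32 / 62, tolerance = 1e-12)
  no_adu <- t17; no_adu["ADU"] <- 0
  expect_equal(adjusted_adult_females(no_adu), 17)
})

test_that("vital rates follow the displayed stationary-population equations", {
  vr17 <- vital_rates(table2_counts(2017))
  expect_equal(vr17$N_1Y, 10)                        # 4 + 1 + 5, unsexed included
  expect_equal(vr17$S_JUV, 10 / 32)
  expect_equal(round_half_up(100 * vr17$S_JUV), 31)
  expect_equal(vr17$M_anADF, 6 * (10 / 32) / 17)     # sexed subadult females 5+1
  expect_equal(vr17$M_anADM, 11 * (10 / 32) / 12)

  vr18 <- vital_rates(table2_counts(2018))
  expect_equal(round_half_up(100 * vr18$S_JUV), 46)  # 22 / 48

  # equation limit: equal juvenile and yearling counts
  eq <- table2_counts(2017); eq["JUV"] <- 10
  vr <- vital_rates(eq)
  expect_equal(vr$M_anJUV, 0)
  expect_equal(vr$M_anADF, vr$N_SUBF / eq[["ADF"]])

  # sampling artifact: more yearlings than juveniles clamps at zero mortality
  inv <- table2_counts(2017); inv["JUV"] <- 5
  expect_warning(vc <- vital_rates(inv), "clamped")
  expect_equal(vc$M_anJUV, 0)
})

test_that("juvenile mortality decreases in the yearling count and stays in [0,1]", {
  base <- table2_counts(2017)
  m <- vapply(0:32, function(n1y) {
    cc <- base; cc[c("1YM", "1YF", "1YU")] <- c(n1y, 0, 0)
    vital_rates(cc)$M_anJUV
  }, numeric(1))
  expect_true(all(diff(m) < 0))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("group-size statistics honour exclusions and conservation", {
  ev <- tibble::tibble(event_id = sprintf("e%d", 1:5),
                       group_size = c(1, 4, 32, 7, 6))
  gs <- group_size_stats(ev)
  expect_equal(gs$mean * gs$n, sum(ev$group_size))
  expect_equal(gs$min, 1); expect_equal(gs$max, 32)

  gx <- group_size_stats(ev, exclusions = c("e3"))
  expect_equal(gx$n, 4)
  expect_equal(gx$max, 7)

  single <- group_size_stats(ev[2, ])
  expect_equal(single$mean, 4)
  expect_true(is.na(single$sd))
  expect_error(group_size_stats(ev, exclusions = ev$event_id), "no events left")
})

test_that("herd classification partitions events by sexed non-juvenile members", {
  ev <- tibble::tibble(event_id = c("mix", "solo", "unsexed", "unim", "unif"))
  comp <- matrix(0L, 5, length(CT_CATEGORIES),
                 dimnames = list(NULL, CT_CATEGORIES))
  comp["mix" == ev$event_id, c("ADM", "ADF")] <- c(2L, 1L)
  comp[2, "ADM"] <- 1L
  comp[3, "UNK"] <- 3L
  comp[4, c("2YM", "JUV")] <- c(2L, 1L)
  comp[5, c("ADF", "1YF")] <- c(3L, 1L)
  ev <- cbind(ev, tibble::as_tibble(as.data.frame(comp)))
  ev$group_size <- rowSums(comp)
  hr <- classify_herd(ev)
  expect_equal(hr$herd_type, c("MIX", "SOLITARY", "UNSEXED", "UNI-M", "UNI-F"))
  expect_true(all(table(hr$event_id) == 1))  # exactly one type each
})

test_that("identification success pools identified over recorded per category", {
  expect_equal(id_success_from_table(niokolo_table2(), "ADM"),
               (1 + 11) / (12 + 30))
  expect_error(id_success_from_table(niokolo_table2()[0, ], "ADM"), "no animals")

  rec <- make_records(c(0, 1), age = "AD", sex = "M",
                      id = c("m1", "m2"), side = "R")
  expect_equal(id_success_rate(rec, "ADM"), 1.0)
  rec_none <- make_records(c(0, 1), age = "AD", sex = "M")
  expect_equal(id_success_rate(rec_none, "ADM"), 0.0)
  expect_error(id_success_rate(rec_none, "ADF"), "no animals")
})

test_that("recaptures match a brute-force per-individual count", {
  set.seed(61)
  sim <- simulate_photo_records(sim_config(n_events = 40), seed = 61)
  rs <- recapture_summary(sim$records)
  asg <- event_assignments(sim$records)
  asg <- asg[!is.na(asg$individual_id), ]
  for (s in c("R", "L")) {
    ids <- unique(asg$individual_id[asg$side %in% c(s, "BOTH")])
    n_rec <- sum(vapply(ids, function(id) {
      length(unique(asg$event_id[asg$individual_id == id])) >= 2
    }, logical(1)))
    row <- rs$by_side[rs$by_side$side == s, ]
    expect_equal(row$n_individuals, length(ids))
    expect_equal(row$n_recaptured, n_rec)
  }

  # one sighting is no recapture; a 10-day revisit gives a 10-day gap
  rec <- rbind(make_records(0, id = "a1", side = "R"),
               make_records(0, date = "2018-02-11", id = "a1", side = "R"),
               make_records(30, id = "b2", side = "L"))
  rec$image_id <- paste0("i", seq_len(nrow(rec)))
  rec <- validate_photo_records(rec)
  rs2 <- recapture_summary(rec)
  expect_equal(rs2$by_side$n_recaptured[rs2$by_side$side == "R"], 1L)
  expect_equal(rs2$by_side$n_recaptured[rs2$by_side$side == "L"], 0L)
  expect_equal(rs2$gaps$mean, 10)
})
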