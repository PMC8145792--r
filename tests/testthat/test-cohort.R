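test_that("type proportions reproduce the published count arithmetic", {
  flex <- type_proportions(counts = c(C = 106, S = 113, A = 12))
  expect_equal(flex$percent, c(45.9, 48.9, 5.2))
  expect_equal(sum(flex$count), 231)
  ext <- type_proportions(counts = c(C = 108, S = 109, A = 14))
  expect_equal(ext$percent, c(46.8, 47.2, 6.1))
  pooled <- type_proportions(counts = c(C = 214, S = 222, A = 26))
  expect_equal(pooled$percent[1:2], c(46.3, 48.1))
  # single record
  one <- type_proportions(make_records("C0/C1", "flexion", "C", 3))
  expect_equal(one$percent, c(100, 0, 0))
  expect_error(type_proportions(data.frame()), class = "cervik_empty_cohort")
})

test_that("surplus statistics report mean, sample SD and range per group", {
  rec <- make_records("C1/C2", "flexion", "S", end_range = 5,
                      surplus_pro = c(1, 2, 3))
  st <- surplus_statistics(rec, "all")
  expect_equal(st$mean, 2)
  expect_equal(st$sd, 1)
  expect_equal(c(st$min, st$max), c(1, 3))
  # single-record group: SD reported as 0 with the n = 1 flag
  st1 <- surplus_statistics(make_records("C1/C2", "flexion", "S", 5, 2),
                            "all")
  expect_equal(st1$sd, 0)
  expect_true(st1$n1)
  # region split separates upper and lower surpluses
  rec <- make_records(c("C0/C1", "C1/C2", "C4/C5", "C5/C6"), "flexion",
                      "S", end_range = 5, surplus_pro = c(3, 3, 1, 1))
  str <- surplus_statistics(rec, "region")
  expect_equal(str$mean[str$group == "upper"], 3)
  expect_equal(str$mean[str$group == "lower"], 1)
  # type C and A records are excluded before aggregating
  rec2 <- rbind(rec, make_records("C0/C1", "flexion", "A", -2,
                                  surplus_pro = 9))
  expect_equal(surplus_statistics(rec2, "all")$n, 4)
})

test_that("quartile ranks put the smallest end-ranges in quartile 1", {
  # 8 joints, end-ranges 1..8, constant surplus 1
  rec <- make_records("C2/C3", "flexion", "S", end_range = 1:8,
                      surplus_pro = 1)
  qt <- quartile_table(rec, "flexion", regions = FALSE)
  expect_equal(qt$n, rep(2L, 4))
  expect_equal(qt$mean_surplus_deg, rep(1, 4))
  expect_equal(qt$mean_surplus_pct[1], mean(c(100 / 1, 100 / 2)))  # 75
  expect_equal(qt$mean_surplus_pct[4], mean(c(100 / 7, 100 / 8)),
               tolerance = 1e-12)  # 13.39%
  # 4 joints: exactly one per quartile
  rec4 <- make_records("C2/C3", "flexion", "S", end_range = 1:4,
                       surplus_pro = 1)
  expect_equal(quartile_table(rec4, "flexion", regions = FALSE)$n,
               rep(1L, 4))
  # 5 joints: the remainder fills quartile 1
  rec5 <- make_records("C2/C3", "flexion", "S", end_range = 1:5,
                       surplus_pro = 1)
  expect_equal(quartile_table(rec5, "flexion", regions = FALSE)$n,
               c(2L, 1L, 1L, 1L))
})

test_that("quartiles partition the records and zero end-ranges are logged", {
  rec <- make_records("C3/C4", "extension", "S",
                      end_range = c(0, 2, 3, 4, 5, 6, 7, 8),
                      surplus_pro = 2)
  qt <- quartile_table(rec, "extension", regions = FALSE)
  expect_equal(sum(qt$n), 8)
  expect_equal(sum(qt$n_pct_excluded), 1)
  # constant surplus: quartile means in degrees all equal
  expect_equal(unique(qt$mean_surplus_deg), 2)
  # region rows pool and re-rank
  qtr <- quartile_table(rec, "extension", regions = TRUE)
  expect_true(all(c("C3/C4", "lower") %in% qtr$level))
  expect_equal(sum(qtr$n[qtr$level == "lower"]), 8)
})

test_that("surplus percent decreases across quartiles when surplus is flat", {
  # end-range-independent surplus: percent denominators grow with quartile
  set.seed(31)
  rec <- make_records(rep(joint_levels(), each = 20), "flexion", "S",
                      end_range = stats::runif(140, 0.5, 12),
                      surplus_pro = 2)
  qt <- quartile_table(rec, "flexion")
  for (lv in unique(qt$level)) {
    p <- qt$mean_surplus_pct[qt$level == lv]
    expect_true(all(diff(p) < 0))
  }
})

test_that("anti-directional tables report both panels per level", {
  rec <- rbind(
    make_records("C0/C1", "flexion", "A", end_range = -2.16),
    make_records("C0/C1", "flexion", "C", end_range = 3,
                 surplus_anti = c(0.5, 1.5)),
    make_records("C5/C6", "flexion", "S", end_range = 4, surplus_pro = 1))
  at <- anti_directional_table(rec, "flexion")
  r1 <- at[at$level == "C0/C1", ]
  expect_equal(r1$n_endrange, 1)
  expect_equal(r1$endrange_mean, 2.16)  # magnitude reported positive
  expect_equal(r1$n_surplus, 2)
  expect_equal(r1$surplus_mean, 1)
  # level with no anti-directional motion: empty panels
  r2 <- at[at$level == "C5/C6", ]
  expect_equal(r2$n_endrange, 0)
  expect_equal(r2$n_surplus, 0)
  expect_true(is.na(r2$endrange_mean))
})

test_that("maximum demonstrated motion is the per-level cohort maximum", {
  rec <- make_records(c("C0/C1", "C0/C1", "C3/C4"), "extension", "C",
                      end_range = c(3, 5, 17.7), surplus_pro = 0)
  mx <- max_demonstrated(rec, "extension")
  expect_equal(mx$max_deg[mx$level == "C0/C1"], 5)
  expect_equal(mx$max_deg[mx$level == "C3/C4"], 17.7)
})

test_that("frequency statistics compute crossing rates and the 1-in-N rate", {
  rec <- make_records(
    rep("C0/C1", 10), "flexion",
    motion_type = c(rep("C", 6), rep("S", 3), "A"),
    end_range = c(rep(4, 9), -1), surplus_pro = c(rep(0, 6), 1, 1, 1, 1))
  fs <- frequency_stats(rec)
  expect_equal(fs$one_in_n, 10)
  expect_equal(fs$by_direction$pct_passed_endrange_pro, 40)  # 3 S + 1 A
  # published pooled counts: 26 type A among 462 records -> 1 in 18
  big <- make_records(rep("C0/C1", 462), rep(c("flexion", "extension"), 231),
                      motion_type = c(rep("C", 436), rep("A", 26)),
                      end_range = c(rep(4, 436), rep(-1, 26)))
  expect_equal(frequency_stats(big)$one_in_n, 18)
  # no type A record: rate is not applicable
  expect_true(is.na(frequency_stats(
    make_records("C0/C1", "flexion", "C", c(3, 4)))$one_in_n))
})

test_that("reported percentages recompute from reported counts", {
  set.seed(32)
  rec <- make_records(rep(joint_levels(), 6), "extension",
                      motion_type = sample(c("C", "S", "A"), 42, TRUE,
                                           prob = c(0.45, 0.45, 0.1)),
                      end_range = stats::runif(42, 1, 10))
  tp <- type_proportions(rec)
  expect_equal(tp$percent, round(100 * tp$count / sum(tp$count), 1))
  expect_equal(sum(tp$percent_raw), 100)
})
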