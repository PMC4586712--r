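test_that("YLL is a direct (sex, age) life-table lookup", {
  lt <- shared_life_table()
  rec <- data.frame(date = as.Date("2000-07-01"), age = 60L, sex = "male",
                    ses_value = 10)
  expect_equal(compute_yll(rec, lt), lt$ex[lt$sex == "male" & lt$age == 60])

  terminal <- data.frame(date = as.Date("2000-07-01"), age = 100L,
                         sex = "female", ses_value = 10)
  v <- compute_yll(terminal, lt)
  expect_equal(v, lt$ex[lt$sex == "female" & lt$age == 100])
  expect_gt(v, 0)

  beyond <- data.frame(date = as.Date("2000-07-02"), age = 101L,
                       sex = "male", ses_value = 10)
  expect_error(compute_yll(beyond, lt), "2000-07-02")
})

test_that("summed YLL matches a brute-force loop over the raw table", {
  lt <- shared_life_table()
  set.seed(11)
  n <- 1000
  rec <- data.frame(date = as.Date("2000-06-01") + sample(0:91, n, TRUE),
                    age = sample(35:100, n, TRUE),
                    sex = sample(c("female", "male"), n, TRUE),
                    ses_value = runif(n, 0, 100))
  brute <- 0
  for (i in seq_len(n)) {
    row <- lt[lt$sex == rec$sex[i] & lt$age == rec$age[i], ]
    brute <- brute + row$ex
  }
  expect_equal(sum(compute_yll(rec, lt)), brute, tolerance = 1e-12)
})

test_that("tercile assignment follows type-1 quantile cuts and the tie rule", {
  rec <- data.frame(ses_value = c(10, 20, 30, 40, 50, 60))
  lab <- assign_terciles(rec)
  expect_equal(as.character(lab$tercile),
               c("high", "high", "mid", "mid", "low", "low"))

  # ties at a cut go to the less-deprived (lower-vulnerability) group
  tied <- data.frame(ses_value = c(10, 20, 20, 50, 80, 90))
  lab2 <- assign_terciles(tied)
  cuts <- attr(lab2, "tercile_cuts")
  expect_true(all(lab2$tercile[tied$ses_value == cuts[1]] == "high"))

  expect_error(assign_terciles(data.frame(ses_value = rep(5, 10))), "undefined")
  expect_error(assign_terciles(data.frame(ses_value = c(1, 2))), "undefined")
})

test_that("tercile group sizes match a sort-based oracle on random inputs", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(6:60, 1)
    v <- sample(round(runif(n, 0, 100), sample(0:1, 1)))
    lab <- assign_terciles(data.frame(ses_value = v))
    # oracle: sort values, cut at order statistics ceiling(n/3), ceiling(2n/3)
    s <- sort(v)
    c1 <- s[ceiling(n / 3)]
    c2 <- s[ceiling(2 * n / 3)]
    oracle <- ifelse(v <= c1, "high", ifelse(v <= c2, "mid", "low"))
    expect_equal(as.character(lab$tercile), oracle)
    n_ties <- sum(v == c1) + sum(v == c2)
    sizes <- table(lab$tercile)
    expect_lte(max(sizes) - min(sizes), n_ties + 2)
  }
})

test_that("daily aggregation keeps empty days, handles singletons, rejects strays", {
  lt <- shared_life_table()
  cal <- as.Date("2001-06-01") + 0:9
  one <- data.frame(date = as.Date("2001-06-03"), age = 60L, sex = "male",
                    ses_value = 90, tercile = factor("low", c("low", "mid", "high")))
  agg <- aggregate_daily(one, lt, cal)
  expect_equal(nrow(agg), 10L)
  yll60 <- lt$ex[lt$sex == "male" & lt$age == 60]
  expect_equal(agg$yll_total[3], yll60)
  expect_equal(agg$yll_low[3], yll60)
  expect_equal(agg$yll_mid[3], 0)
  expect_equal(agg$yll_high[3], 0)
  expect_true(all(agg$yll_total[-3] == 0))

  stray <- one
  stray$date <- as.Date("2001-09-01")
  expect_error(aggregate_daily(stray, lt, cal), "2001-09-01")
})

test_that("tercile YLL conserves the total and is permutation invariant", {
  cfg <- quick_config(seed = 3)
  st <- simulate_study(cfg)
  agg <- st$daily
  expect_true(all(abs(agg$yll_low + agg$yll_mid + agg$yll_high - agg$yll_total) <=
                    1e-9 * pmax(agg$yll_total, 1)))
  expect_true(all(agg$yll_total >= 0))

  lab <- assign_terciles(st$deaths)
  shuffled <- lab[sample(nrow(lab)), , drop = FALSE]
  agg2 <- aggregate_daily(shuffled, st$life_table, st$weather$date)
  expect_equal(agg, agg2)
})

test_that("adding one death moves exactly its day and tercile", {
  lt <- shared_life_table()
  set.seed(31)
  n <- 200
  rec <- data.frame(date = as.Date("2001-06-01") + sample(0:91, n, TRUE),
                    age = sample(40:95, n, TRUE),
                    sex = sample(c("female", "male"), n, TRUE),
                    ses_value = runif(n, 0, 100))
  cal <- as.Date("2001-06-01") + 0:91
  base <- aggregate_daily(assign_terciles(rec), lt, cal)

  extra <- data.frame(date = as.Date("2001-06-15"), age = 70L, sex = "female",
                      ses_value = rec$ses_value[1])  # reuse a value: cuts shift only by ties
  rec2 <- rbind(rec, extra)
  lab2 <- assign_terciles(rec2)
  agg2 <- aggregate_daily(lab2, lt, cal)
  v <- lt$ex[lt$sex == "female" & lt$age == 70]
  d_idx <- which(cal == extra$date)
  expect_equal(agg2$yll_total[d_idx] - base$yll_total[d_idx], v)
  g <- as.character(lab2$tercile[nrow(lab2)])
  same_cuts <- identical(attr(lab2, "tercile_cuts"), attr(assign_terciles(rec), "tercile_cuts"))
  if (same_cuts) {
    col <- paste0("yll_", g)
    expect_equal(agg2[[col]][d_idx] - base[[col]][d_idx], v)
    expect_equal(agg2$yll_total[-d_idx], base$yll_total[-d_idx])
  }
})
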