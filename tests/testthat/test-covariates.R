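test_that("David's score orders a transitive tournament and ties a symmetric one", {
  b <- do.call(rbind, lapply(1:5, function(i) data.frame(
    winner_id = c("A", "B", "A"), loser_id = c("B", "C", "C"),
    date = as.Date("2016-06-01"), stringsAsFactors = FALSE)))
  r <- estimate_ranks(b, 2016)
  sc <- setNames(r$rank_score, r$animal_id)
  expect_true(sc["A"] > sc["B"] && sc["B"] > sc["C"])
  expect_equal(mean(r$rank_score), 0, tolerance = 1e-12)
  expect_equal(sd(r$rank_score), 1, tolerance = 1e-12)

  sym <- data.frame(winner_id = c("A", "B", "B", "C", "A", "C"),
                    loser_id = c("B", "A", "C", "B", "C", "A"),
                    date = as.Date("2016-06-01"), stringsAsFactors = FALSE)
  rs <- estimate_ranks(sym, 2016)
  expect_equal(rs$rank_score, rep(0, 3))
  expect_error(estimate_ranks(b, 2019), "no bouts")
})

test_that("a steep simulated hierarchy is recovered at rho >= 0.9", {
  set.seed(9)
  ids <- sprintf("R%02d", 1:12)
  truth <- seq(2, -2, length.out = 12)
  pairs <- t(combn(12, 2))
  pairs <- pairs[rep(seq_len(nrow(pairs)), 6), ]
  p <- plogis(2.5 * (truth[pairs[, 1]] - truth[pairs[, 2]]))
  w <- runif(nrow(pairs)) < p
  b <- data.frame(winner_id = ids[ifelse(w, pairs[, 1], pairs[, 2])],
                  loser_id = ids[ifelse(w, pairs[, 2], pairs[, 1])],
                  date = as.Date("2016-06-01"), stringsAsFactors = FALSE)
  r <- estimate_ranks(b, 2016)
  rho <- cor(r$rank_score[match(ids, r$animal_id)], truth,
             method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("rank assignment follows the maternal-fallback rules", {
  dem <- tiny_demography()
  ranks <- data.frame(animal_id = c("M1", "M2", "A3"), year = 2017,
                      rank_score = c(1.2, -0.4, 0.8))
  # ego -> mother's score, even as an infant
  expect_equal(assign_rank("E1", 2017, dem, ranks), 1.2)
  # adult alter (A3 born 2012, age 5) -> own score
  expect_equal(assign_rank("A3", 2017, dem, ranks), 0.8)
  # infant alter A1 (born 2016, mother M1) -> maternal score
  expect_equal(assign_rank("A1", 2017, dem, ranks), 1.2)
  # young alter with unranked mother but ranked grandmother
  dem2 <- rbind(dem, data.frame(
    animal_id = c("G1", "U1", "K1"), sex = "F",
    birth_date = as.Date(c("2000-01-01", "2014-01-01", "2016-08-01")),
    matriline_id = "MC", mother_id = c(NA, "G1", "U1"),
    removal_date = as.Date(NA), cohort = "other"))
  ranks2 <- rbind(ranks, data.frame(animal_id = "G1", year = 2017,
                                    rank_score = 2.0))
  expect_equal(assign_rank("K1", 2017, dem2, ranks2), 2.0)
  # no rankable relative -> error naming the animal
  dem3 <- rbind(dem, data.frame(
    animal_id = "X1", sex = "M", birth_date = as.Date("2016-09-01"),
    matriline_id = "MX", mother_id = NA, removal_date = as.Date(NA),
    cohort = "other"))
  expect_error(assign_rank("X1", 2017, dem3, ranks), "X1")
})

test_that("dyadic covariates capture assortativity, kinship and flags", {
  dem <- tiny_demography()
  ranks <- do.call(rbind, lapply(2016:2019, function(y)
    data.frame(animal_id = c("M1", "M2", "A3"), year = y,
               rank_score = c(1.2, -0.4, 0.8))))
  # E1 (F, mother M1) with A1 (F, mother M1): siblings, same sex
  cv <- dyad_covariates("E1", "A1", 2, dem, ranks)
  expect_true(cv$same_sex)
  expect_equal(cv$kinship, "sibling")
  expect_equal(cv$rank_diff, 0)        # both carry M1's rank
  expect_equal(cv$ego_maternal_rank, 1.2)
  # A1 born 2016-06-01 falls in E1's partition 1 (Apr-Sep 2016), so the
  # partition-2 row flags a recent birth and later rows do not
  expect_true(cv$alter_born_flag)
  expect_false(dyad_covariates("E1", "A1", 3, dem, ranks)$alter_born_flag)
  # E2 (M, matriline MB) with A2 (M, matriline MB, different mother):
  # co-matriline, same sex, removed 2018-06-15 during E2's partition 3
  cv2 <- dyad_covariates("E2", "A2", 3, dem, ranks)
  expect_equal(cv2$kinship, "comatriline")
  expect_true(cv2$same_sex)
  expect_true(cv2$alter_removed_flag)
  expect_false(dyad_covariates("E2", "A2", 2, dem, ranks)$alter_removed_flag)
  # age difference at the partition midpoint: E2 born 2017-05-10,
  # A2 born 2013-04-01 -> about 4.1 years
  expect_equal(cv2$age_diff_years, 4.1, tolerance = 0.1)
  # opposite sexes
  expect_false(dyad_covariates("E1", "E2", 2, dem, ranks)$same_sex)
})

test_that("born flag marks alters born during the previous partition", {
  dem <- tiny_demography()
  dem$birth_date[dem$animal_id == "A1"] <- as.Date("2016-12-15")
  ranks <- do.call(rbind, lapply(2016:2019, function(y)
    data.frame(animal_id = c("M1", "M2", "A3"), year = y,
               rank_score = c(1.2, -0.4, 0.8))))
  # E1's partition 2 = Oct 2016 - Mar 2017 contains A1's birth:
  # flag on the partition-3 row, not partition 2 or 4
  expect_false(dyad_covariates("E1", "A1", 2, dem, ranks)$alter_born_flag)
  expect_true(dyad_covariates("E1", "A1", 3, dem, ranks)$alter_born_flag)
  expect_false(dyad_covariates("E1", "A1", 4, dem, ranks)$alter_born_flag)
})

test_that("lags shift versatility forward one partition", {
  vers <- data.frame(
    ego_id = "E1", behaviour = "proximity",
    partition_index = c(1L, 2L, 3L), alter_id = "A1",
    versatility = c(0.4, 0.3, 0.2), zero_populated = FALSE,
    stringsAsFactors = FALSE)
  lags <- build_lags(vers)
  expect_equal(lags$lag_proximity[lags$partition_index == 2], 0.4)
  expect_equal(lags$lag_proximity[lags$partition_index == 3], 0.3)
  # lag alignment is equivariant to shifting all partition labels
  shifted <- vers
  shifted$partition_index <- shifted$partition_index + 1L
  lags2 <- build_lags(shifted)
  expect_equal(lags2$lag_proximity[lags2$partition_index == 3], 0.4)
  expect_equal(lags2$lag_proximity[lags2$partition_index == 4], 0.3)
})

test_that("binarization keeps state behaviours and thresholds directed ones", {
  expect_equal(binarize_directed(c(0, 0.003, 0.8), "groom"), c(0, 1, 1))
  expect_equal(binarize_directed(0, "play"), 0)
  expect_equal(binarize_directed(0.37, "contact"), 0.37)
  expect_error(binarize_directed(-0.1, "play"), "nonnegative")
})

test_that("predictors scale to mean 0 and sd 0.5", {
  x <- data.frame(ego_maternal_rank = rnorm(50, 10, 2),
                  rank_diff = runif(50), age_diff_years = runif(50),
                  partition_linear = rep(2:4, length.out = 50),
                  lag_aggression = runif(50), lag_contact = runif(50),
                  lag_groom = runif(50), lag_play = runif(50),
                  lag_proximity = runif(50), same_sex = rep(c(TRUE, FALSE), 25))
  sc <- scale_predictors(x)
  for (p in continuous_predictors()) {
    expect_equal(mean(sc$table[[p]]), 0, tolerance = 1e-9)
    expect_equal(sd(sc$table[[p]]), 0.5, tolerance = 1e-9)
  }
  expect_identical(sc$table$same_sex, x$same_sex)
  # value 14 in a mean-10 sd-2 predictor maps to 1.0
  expect_equal((14 - sc$scaling$mean[1]) / (2 * sc$scaling$sd[1]),
               (14 - mean(x$ego_maternal_rank)) /
                 (2 * sd(x$ego_maternal_rank)))
  x$rank_diff <- 1
  expect_error(scale_predictors(x), "rank_diff")
})

test_that("model table assembly joins responses, lags and covariates", {
  dem <- tiny_demography()
  ranks <- do.call(rbind, lapply(2016:2019, function(y)
    data.frame(animal_id = c("M1", "M2", "A3"), year = y,
               rank_score = c(1.2, -0.4, 0.8))))
  # E1 x A1 realized in proximity partitions 1-4; zero-populate fills the
  # other behaviours
  vers <- data.frame(ego_id = "E1", behaviour = "proximity",
                     partition_index = 1:4, alter_id = "A1",
                     versatility = c(0.5, 0.4, 0.3, 0.2),
                     zero_populated = FALSE, stringsAsFactors = FALSE)
  vz <- zero_populate(vers, dem, partition_scheme())
  tab <- assemble_model_table(vz, dem, ranks)
  expect_equal(nrow(tab), 3) # partitions 2-4
  expect_equal(tab$partition_index, 2:4)
  expect_equal(tab$proximity_vers, c(0.4, 0.3, 0.2))
  expect_equal(tab$lag_proximity, c(0.5, 0.4, 0.3))
  expect_equal(tab$aggr_bin, rep(0, 3))
  expect_equal(tab$partition_linear, c(2, 3, 4))
  expect_false(anyNA(tab))
})

test_that("feasibility rules determine the joined row count", {
  # 2 egos x 3 alters, all feasible partitions 1-4 -> 18 rows; removing one
  # alter during partition 3 drops its partition-4 row -> 17
  dem <- data.frame(
    animal_id = c("MM", "E1", "E2", "P1", "P2", "P3"),
    sex = c("F", "F", "M", "F", "M", "F"),
    birth_date = as.Date(c("2005-01-01", "2016-04-10", "2016-05-10",
                           "2015-06-01", "2015-07-01", "2016-06-01")),
    matriline_id = "MA",
    mother_id = c(NA, "MM", "MM", "MM", "MM", "MM"),
    removal_date = as.Date(NA), cohort = c("other", "2016", "2016",
                                           "other", "other", "other"),
    stringsAsFactors = FALSE)
  ranks <- do.call(rbind, lapply(2016:2019, function(y)
    data.frame(animal_id = "MM", year = y, rank_score = 0.5)))
  vers <- expand.grid(ego_id = c("E1", "E2"), alter_id = c("P1", "P2", "P3"),
                      partition_index = 1:4, stringsAsFactors = FALSE)
  vers$behaviour <- "proximity"
  vers$versatility <- 0.3
  vers$zero_populated <- FALSE
  vz <- zero_populate(vers, dem, partition_scheme())
  tab <- assemble_model_table(vz, dem, ranks)
  expect_equal(nrow(tab), 18)

  dem2 <- dem
  dem2$removal_date[dem2$animal_id == "P3"] <- as.Date("2017-08-15")
  vers2 <- vers[!(vers$alter_id == "P3" & vers$partition_index == 4), ]
  vz2 <- zero_populate(vers2, dem2, partition_scheme())
  tab2 <- assemble_model_table(vz2, dem2, ranks)
  expect_equal(nrow(tab2), 16)
  expect_true(all(tab2$alter_removed_flag[tab2$alter_id == "P3" &
                                            tab2$partition_index == 3]))

  # duplicated versatility rows are rejected
  expect_error(assemble_model_table(rbind(vz, vz[1, ]), dem, ranks),
               "duplicate")
})
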