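test_that("label_sequence maps items and reports gaps", {
  lab <- subcategory_labeling(c("cat", "dog", "crow"),
                              c("pets", "pets", "birds"), "manual")
  rec <- fluency_record("p1", "healthy", 70, c("cat", "dog", "crow"))
  expect_equal(label_sequence(rec, lab), c("pets", "pets", "birds"))

  empty <- fluency_record("p2", "AD", 80, character(0))
  expect_equal(label_sequence(empty, lab), character(0))

  bad <- fluency_record("p3", "aMCI", 75, c("cat", "unicorn"))
  expect_error(label_sequence(bad, lab), "unicorn")
  expect_error(label_sequence(bad, lab), "p3")
  expect_warning(got <- label_sequence(bad, lab, skip_unlabeled = TRUE),
                 "skipped")
  expect_equal(got, "pets")
})

test_that("worked metric examples score exactly", {
  m <- compute_metrics(c("A", "A", "B", "A"))
  expect_equal(m$n_words, 4L); expect_equal(m$n_subcategories, 2L)
  expect_equal(m$n_switches, 2L); expect_equal(m$n_returns, 1L)
  expect_equal(m$adj_returns, 25.0)

  m <- compute_metrics(c("A", "A", "A"))
  expect_equal(m$n_subcategories, 1L)
  expect_equal(m$n_switches, 0L); expect_equal(m$n_returns, 0L)

  m <- compute_metrics(c("A", "B", "C", "A", "B"))
  expect_equal(m$n_switches, 4L); expect_equal(m$n_returns, 2L)
  expect_equal(m$adj_switches, 80.0); expect_equal(m$adj_returns, 40.0)

  z <- compute_metrics(character(0))
  expect_equal(z$n_words, 0L)
  expect_equal(z$adj_returns, 0)
})

test_that("run-length identities hold on random sequences (oracle check)", {
  set.seed(40)
  for (i in 1:300) {
    labels <- random_label_sequence()
    m <- compute_metrics(labels)
    o <- rle_oracle(labels)
    expect_identical(m$n_words, o$n_words)
    expect_identical(m$n_subcategories, o$n_subcategories)
    expect_identical(m$n_switches, o$n_switches)
    expect_identical(m$n_returns, o$n_returns)
    expect_equal(m$adj_switches, o$adj_switches)
    expect_equal(m$adj_returns, o$adj_returns)
    if (m$n_words > 0) {
      runs <- m$n_switches + 1L
      expect_identical(m$n_switches, runs - 1L)
      expect_identical(m$n_returns, runs - m$n_subcategories)
      expect_identical(m$n_returns, m$n_switches - (m$n_subcategories - 1L))
      expect_true(m$n_returns >= 0L && m$n_returns <= m$n_switches)
      vp <- visitation_profile(labels)
      expect_equal(sum(vp$length), m$n_words)
      expect_equal(nrow(vp), m$n_switches + 1L)
    }
  }
})

test_that("scoring is stateless and label-name symmetric", {
  set.seed(41)
  for (i in 1:30) {
    labels <- random_label_sequence(5, 30)
    if (length(labels) == 0) next
    doubled <- c(labels, labels)
    m <- compute_metrics(doubled)
    o <- rle_oracle(doubled)
    expect_identical(m$n_switches, o$n_switches)
    expect_identical(m$n_returns, o$n_returns)
    # permuting label NAMES leaves every metric unchanged
    perm <- sample(LETTERS[1:8])
    names(perm) <- LETTERS[1:8]
    mp <- compute_metrics(unname(perm[labels]))
    expect_identical(mp[c("n_words", "n_subcategories", "n_switches",
                          "n_returns")],
                     compute_metrics(labels)[c("n_words", "n_subcategories",
                                               "n_switches", "n_returns")])
  }
})

test_that("visitation profiles index visits and returns per sub-category", {
  vp <- visitation_profile(c("A", "A", "B", "A", "A", "A"))
  expect_equal(vp$label, c("A", "B", "A"))
  expect_equal(vp$length, c(2L, 1L, 3L))
  expect_equal(vp$visit, c(1L, 1L, 2L))
  expect_equal(vp$is_return, c(FALSE, FALSE, TRUE))

  one <- visitation_profile("A")
  expect_equal(one$length, 1L)
  expect_equal(nrow(visitation_profile(character(0))), 0L)
})

test_that("cohort table carries counts, proportions and metrics per row", {
  lab <- subcategory_labeling(c("cat", "dog", "crow"),
                              c("pets", "pets", "birds"), "manual")
  recs <- list(
    fluency_record("p1", "healthy", 71, c("cat", "dog", "crow")),
    fluency_record("p2", "aMCI", 75, c("cat", "crow")),
    fluency_record("p3", "AD", 80, c("cat", "crow", "dog")))
  tab <- cohort_metrics_table(recs, lab)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$prop_pets, c(2 / 3, 1 / 2, 2 / 3))
  expect_equal(tab$prop_birds, c(1 / 3, 1 / 2, 1 / 3))
  expect_equal(rowSums(tab[, c("prop_pets", "prop_birds")]), rep(1, 3))
  expect_equal(tab$n_returns, c(0L, 0L, 1L))
  expect_s3_class(tab$group, "factor")
  expect_equal(levels(tab$group), c("healthy", "aMCI", "AD"))

  expect_warning(
    tab2 <- cohort_metrics_table(
      c(recs, list(fluency_record("p4", "AD", 82, character(0)))), lab),
    "empty")
  expect_equal(tab2$n_words[4], 0)
  expect_equal(tab2$prop_pets[4], 0)
})

test_that("perseveration collapsing is optional and off by default", {
  lab <- subcategory_labeling(c("cat", "dog"), c("pets", "pets"), "manual")
  rec <- fluency_record("p1", "healthy", 70, c("cat", "cat", "dog"))
  on <- cohort_metrics_table(list(rec), lab, collapse_repetitions = TRUE)
  off <- cohort_metrics_table(list(rec), lab)
  expect_equal(off$n_words, 3)
  expect_equal(on$n_words, 2)
})

test_that("transcript CSV round-trips and orders by position", {
  recs <- list(fluency_record("p1", "healthy", 70.5, c("cat", "dog")),
               fluency_record("p2", "AD", 81, c("crow")))
  p <- tempfile(fileext = ".csv")
  write_transcripts(recs, p)
  got <- read_transcripts(p)
  expect_equal(length(got), 2L)
  expect_equal(got[[1]]$items, c("cat", "dog"))
  expect_equal(got[[2]]$group, "AD")
  expect_equal(got[[1]]$age, 70.5)
})

test_that("group visitation summary aggregates mean run lengths", {
  lab <- subcategory_labeling(c("cat", "dog", "crow", "owl"),
                              c("pets", "pets", "birds", "birds"), "manual")
  recs <- list(
    fluency_record("p1", "healthy", 70, c("cat", "dog", "crow", "cat")),
    fluency_record("p2", "AD", 80, c("cat", "crow", "owl")))
  gs <- group_visitation_summary(recs, lab)
  h1 <- gs[gs$group == "healthy" & gs$visit == 1, ]
  expect_equal(h1$mean_length, mean(c(2, 1)))   # runs (cat,dog) and (crow)
  h2 <- gs[gs$group == "healthy" & gs$visit == 2, ]
  expect_equal(h2$mean_length, 1)               # the return to pets
  expect_equal(gs[gs$group == "AD" & gs$visit == 1, "mean_length"],
               mean(c(1, 2)))
})
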