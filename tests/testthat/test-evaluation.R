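# a tiny labelled cohort shared by the evaluation tests
eval_samples <- local({
  spec <- cohort_spec(n_subjects = 2, sessions_per_subject = 2,
                      master_seed = 808)
  extract_cohort_samples(simulate_cohort(spec))
})

test_that("the iterated scheme scores the expected number of samples", {
  subj <- eval_samples[eval_samples$subject_id == "subject1", ]
  s_plus <- head(subj[subj$klass == "concentrated", ], 8)
  s_minus <- head(subj[subj$klass == "non_concentrated", ], 10)
  scored <- run_iterated(s_plus, s_minus, n_iterations = 10, seed = 3)
  # 8 positives: 6 train / 2 held out, plus all 10 negatives, per iteration
  expect_equal(nrow(scored), 10 * (2 + 10))
  expect_equal(sum(scored$truth), 10 * 2)
  expect_true(all(is.finite(scored$score)))
  expect_equal(sort(unique(scored$iteration)), 1:10)
})

test_that("train-set size follows the floor rule with a minimum of two", {
  subj <- eval_samples[eval_samples$subject_id == "subject1", ]
  pos7 <- head(subj[subj$klass == "concentrated", ], 7)
  neg <- head(subj[subj$klass == "non_concentrated", ], 4)
  scored <- run_iterated(pos7, neg, n_iterations = 3, seed = 1)
  # floor(0.75 * 7) = 5 train, 2 held out
  expect_equal(nrow(scored), 3 * (2 + 4))

  pos4 <- head(subj[subj$klass == "concentrated", ], 4)
  scored4 <- run_iterated(pos4, neg, n_iterations = 2, seed = 1)
  expect_equal(nrow(scored4), 2 * (1 + 4))   # 3 train / 1 test
})

test_that("too few positive samples is an insufficient-data error", {
  subj <- eval_samples[eval_samples$subject_id == "subject1", ]
  pos2 <- head(subj[subj$klass == "concentrated", ], 2)
  neg <- head(subj[subj$klass == "non_concentrated", ], 4)
  expect_error(run_iterated(pos2, neg, n_iterations = 2),
               "Insufficient.*subject1")
})

test_that("a fixed master seed reproduces scores bit for bit", {
  subj <- eval_samples[eval_samples$subject_id == "subject2", ]
  s_plus <- head(subj[subj$klass == "concentrated", ], 6)
  s_minus <- head(subj[subj$klass == "non_concentrated", ], 5)
  a <- run_iterated(s_plus, s_minus, n_iterations = 5, seed = 77)
  b <- run_iterated(s_plus, s_minus, n_iterations = 5, seed = 77)
  expect_identical(a, b)
  c <- run_iterated(s_plus, s_minus, n_iterations = 5, seed = 78)
  expect_false(identical(a$score, c$score))
})

test_that("experiment preconditions are enforced", {
  one_subj <- eval_samples[eval_samples$subject_id == "subject1", ]
  expect_error(experiment_subject_id(one_subj, "subject1",
                                     n_iterations = 2),
               "at least 2 subjects")
  expect_error(experiment_inter_subject(one_subj, "subject1"),
               "at least 2 subjects")
  expect_error(experiment_inter_subject(eval_samples, "nobody"),
               "Unknown subject")
  no_neg <- eval_samples[eval_samples$klass == "concentrated", ]
  expect_error(experiment_intra_detection(no_neg, "subject1",
                                          n_iterations = 2),
               "no non-concentrated")
})

test_that("both inter-subject directions run and give a pooled ROC", {
  r1 <- experiment_inter_subject(eval_samples, "subject1", seed = 5)
  r2 <- experiment_inter_subject(eval_samples, "subject1", seed = 5,
                                 direction = "train_target")
  expect_s3_class(r1, "conc_roc")
  expect_s3_class(r2, "conc_roc")
  expect_true(r1$n_pos > 0 && r1$n_neg > 0)
  # train_others scores only the target subject's samples
  subj1 <- eval_samples[eval_samples$subject_id == "subject1", ]
  expect_equal(r1$n_pos + r1$n_neg, nrow(subj1))
  expect_equal(r2$n_pos + r2$n_neg,
               nrow(eval_samples) - nrow(subj1))
})

test_that("the fusion sweep enumerates subsets in deterministic order", {
  subs <- channel_subsets()
  expect_equal(nrow(subs), 15)
  expect_equal(subs$size, c(rep(1, 4), rep(2, 6), rep(3, 4), 4))
  expect_equal(subs$label[1:5], c("HR", "BR", "SC", "ST", "HR+BR"))
  expect_equal(tail(subs$label, 1), "HR+BR+SC+ST")
  expect_equal(nrow(channel_subsets(c("HR", "BR", "SC"))), 7)
  expect_equal(nrow(channel_subsets("ST")), 1)
  expect_error(channel_subsets(character(0)), "at least one")
})

test_that("a two-channel sweep produces one row per subset and subject", {
  sweep <- fusion_sweep(eval_samples, "intra_detection",
                        channels = c("HR", "ST"), n_iterations = 3,
                        seed = 2, max_iter = 20)
  expect_equal(nrow(sweep), 3 * 2)             # 3 subsets x 2 subjects
  expect_equal(unique(sweep$label), c("HR", "ST", "HR+ST"))
  expect_true(all(sweep$auc >= 0 & sweep$auc <= 1))
  expect_error(fusion_sweep(eval_samples, "inter_subject"),
               "intra-subject")
})

test_that("experiment reports carry per-subject rows plus an average", {
  results <- tibble::tibble(subject_id = c("subject1", "subject2"),
                            auc = c(0.9, 0.8), eer = c(0.1, 0.2))
  rep <- report_experiments(results)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$subject_id[3], "Average")
  expect_equal(rep$auc[3], 0.85)
  single <- report_experiments(results[1, ])
  expect_equal(single$auc[2], single$auc[1])
})

test_that("the fusion report is a wide table with indicator columns", {
  sweep <- tibble::tibble(
    subset_id = rep(1:3, each = 2),
    size = rep(c(1, 1, 2), each = 2),
    label = rep(c("HR", "ST", "HR+ST"), each = 2),
    subject_id = rep(c("s1", "s2"), 3),
    auc = seq(0.5, 1, length.out = 6),
    eer = rev(seq(0.1, 0.6, length.out = 6))
  )
  wide <- report_fusion(sweep)
  expect_equal(nrow(wide), 3)
  expect_true(all(c("hr", "st", "auc_avg", "eer_avg") %in% names(wide)))
  expect_equal(wide$hr, c(1L, 0L, 1L))
  expect_equal(wide$st, c(0L, 1L, 1L))
})
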