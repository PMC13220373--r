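test_that("edge categories follow the zero/non-zero rules with a strict threshold", {
  w_a <- sym_matrix(4, list(c(1, 2, 3), c(1, 3, 10), c(1, 4, 10), c(2, 3, 5)))
  w_b <- sym_matrix(4, list(c(1, 3, 11.0), c(1, 4, 11.1), c(2, 3, 5),
                            c(2, 4, 2)))
  et <- classify_edges(w_a, w_b, over_threshold_pct = 10)
  cat_of <- function(i, j) as.character(et$category[et$i == i & et$j == j])
  expect_equal(cat_of(1, 2), "disconnection")       # 3 -> 0
  expect_equal(cat_of(1, 3), "persistent-other")    # exactly +10% is not > 10%
  expect_equal(cat_of(1, 4), "over-connection")     # +11% > 10%
  expect_equal(cat_of(2, 3), "persistent-other")    # unchanged
  expect_equal(cat_of(2, 4), "re-emerging")         # 0 -> 2
  expect_equal(cat_of(3, 4), "absent-both")
  expect_equal(et$rel_change_pct[et$i == 1 & et$j == 4], 11)
  expect_true(is.na(et$rel_change_pct[et$i == 1 & et$j == 2]))
  expect_error(classify_edges(-w_a, w_b),
               class = "disconnectome_validation_error")
})

test_that("the five categories partition all P(P-1)/2 edges", {
  for (seed in c(61, 62, 63)) {
    co <- generate_cohort(shrinking_config(seed = seed, jitter = 0.6))
    w <- lapply(co$masks, function(m)
      weight_patient(co$healthy,
                     disconnection_fractions(co$streamlines, co$healthy, m)))
    tr <- default_transitions(3)
    for (r in seq_len(nrow(tr))) {
      et <- classify_edges(w[[tr[r, 1]]], w[[tr[r, 2]]])
      P <- nrow(co$healthy)
      expect_equal(nrow(et), P * (P - 1) / 2)
      expect_false(anyNA(et$category))
      expect_equal(sum(base::table(et$category)), P * (P - 1) / 2)
    }
  }
})

test_that("change counts, normalization and planted categories agree", {
  # plant 2 disconnections, 3 re-emerging, 4 over-connections in a 10-parcel net
  edges_a <- list(c(1, 2, 5), c(1, 3, 5),                      # lost
                  c(4, 5, 10), c(4, 6, 10), c(4, 7, 10), c(5, 6, 10),  # over
                  c(8, 9, 10), c(8, 10, 10))                   # stable
  edges_b <- list(c(2, 3, 5), c(1, 10, 5), c(2, 10, 5),        # gained
                  c(4, 5, 12), c(4, 6, 12), c(4, 7, 12), c(5, 6, 12),
                  c(8, 9, 10), c(8, 10, 10))
  w_a <- sym_matrix(10, edges_a)
  w_b <- sym_matrix(10, edges_b)
  et <- classify_edges(w_a, w_b)
  cc <- count_changes(et, binarize(w_a))
  expect_equal(cc$n_disconnections, 2L)
  expect_equal(cc$n_reemerging, 3L)
  expect_equal(cc$n_overconnections, 4L)
  expect_equal(cc$n_existing_baseline, 8L)
  expect_equal(cc$disconnections_norm_pct, 100 * 2 / 8)
  # 5 disconnections among 50 baseline edges normalize to 10%
  expect_equal(100 * 5 / 50, 10)
  # all baseline weights well above the floor here: both over variants agree
  expect_equal(cc$n_overconnections_floored, cc$n_overconnections)
  none <- classify_edges(w_a, w_a)
  cc0 <- count_changes(none, binarize(w_a))
  expect_equal(cc0$n_disconnections + cc0$n_reemerging + cc0$n_overconnections,
               0L)
  empty_base <- sym_matrix(10, list())
  expect_error(count_changes(classify_edges(empty_base, w_b),
                             binarize(empty_base)),
               class = "disconnectome_validation_error")
})

test_that("RSN gains and losses use dual attribution", {
  net <- c("X", "X", "Y", "Y", "Z")
  # one re-emerging X-Y edge, three lost intra-X-ish edges
  w_a <- sym_matrix(5, list(c(1, 2, 4), c(1, 5, 2), c(2, 5, 2)))
  w_b <- sym_matrix(5, list(c(1, 3, 1)))
  gl <- rsn_gain_loss(classify_edges(w_a, w_b), net)
  g <- function(n, col) gl[[col]][gl$network == n]
  expect_equal(g("X", "gained"), 1)  # (1,3) touches X once
  expect_equal(g("Y", "gained"), 1)  # and Y once
  expect_equal(g("X", "lost"), 3)    # (1,2), (1,5), (2,5) all touch X
  expect_equal(g("Z", "lost"), 2)
  expect_equal(g("X", "difference"), -2)
  # intra-network loss counts once for its network
  w_a2 <- sym_matrix(5, list(c(1, 2, 4)))
  gl2 <- rsn_gain_loss(classify_edges(w_a2, sym_matrix(5, list())), net)
  expect_equal(gl2$lost[gl2$network == "X"], 1)
  expect_true(all(gl2$gained == 0))
  # no changes at all -> all zeros
  gl3 <- rsn_gain_loss(classify_edges(w_a, w_a), net)
  expect_true(all(gl3$gained == 0 & gl3$lost == 0 & gl3$difference == 0))
})

test_that("threshold limits collapse over-connections as expected", {
  w_a <- sym_matrix(4, list(c(1, 2, 10), c(1, 3, 10), c(2, 3, 10)))
  w_b <- sym_matrix(4, list(c(1, 2, 10.5), c(1, 3, 30), c(2, 3, 10)))
  huge <- classify_edges(w_a, w_b, over_threshold_pct = 1e9)
  expect_equal(sum(huge$category == "over-connection"), 0L)
  tiny <- classify_edges(w_a, w_b, over_threshold_pct = 1e-9)
  persistent_up <- sum(huge$w_a > 0 & huge$w_b > huge$w_a)
  expect_equal(sum(tiny$category == "over-connection"), persistent_up)
})

test_that("an edge lost then regained is never a disconnection over the full span", {
  for (seed in c(71, 72)) {
    co <- generate_cohort(shrinking_config(seed = seed, jitter = 0.8))
    w <- lapply(co$masks, function(m)
      weight_patient(co$healthy,
                     disconnection_fractions(co$streamlines, co$healthy, m)))
    e12 <- classify_edges(w[[1]], w[[2]])
    e23 <- classify_edges(w[[2]], w[[3]])
    e13 <- classify_edges(w[[1]], w[[3]])
    lost_then_regained <- e12$category == "disconnection" &
      e23$category == "re-emerging"
    expect_true(all(e13$category[lost_then_regained] %in%
                      c("over-connection", "persistent-other")))
  }
})

test_that("the covariate table links lesion evolution to transition counts", {
  co <- generate_cohort(shrinking_config(seed = 44))
  w <- lapply(co$masks, function(m)
    weight_patient(co$healthy,
                   disconnection_fractions(co$streamlines, co$healthy, m)))
  tr <- default_transitions(3)
  counts <- lapply(seq_len(nrow(tr)), function(r)
    count_changes(classify_edges(w[[tr[r, 1]]], w[[tr[r, 2]]]),
                  binarize(w[[tr[r, 1]]])))
  covar <- lesion_covariate_table(co$masks, counts, tr)
  expect_equal(nrow(covar), 3)
  # nested shrinkage: positive volume change, no disconnections
  expect_true(all(covar$volume_pct_change > 0))
  expect_true(all(covar$n_disconnections == 0))
  expect_true(all(covar$reemerging_ratio_pct >= 0))
  # identical masks across a transition: DSC 1, zero volume change and
  # (identical weights) no discrete changes
  masks2 <- co$masks[c(1, 1)]
  counts2 <- list(count_changes(classify_edges(w[[1]], w[[1]]),
                                binarize(w[[1]])))
  cv2 <- lesion_covariate_table(masks2, counts2, cbind(1L, 2L))
  expect_equal(cv2$dsc, 1)
  expect_equal(cv2$volume_pct_change, 0)
  expect_equal(cv2$n_disconnections + cv2$n_reemerging, 0L)
  # jittered centers: imperfect overlap
  coj <- generate_cohort(shrinking_config(seed = 45, jitter = 1.5))
  wj <- lapply(coj$masks, function(m)
    weight_patient(coj$healthy,
                   disconnection_fractions(coj$streamlines, coj$healthy, m)))
  countsj <- lapply(seq_len(nrow(tr)), function(r)
    count_changes(classify_edges(wj[[tr[r, 1]]], wj[[tr[r, 2]]]),
                  binarize(wj[[tr[r, 1]]])))
  cvj <- lesion_covariate_table(coj$masks, countsj, tr)
  expect_true(all(cvj$dsc < 1))
})
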