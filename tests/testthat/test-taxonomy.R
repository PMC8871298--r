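test_that("two well-separated shape groups are recovered at k = 2", {
  tg <- two_group_panel(n_per = 12, seed = 2)
  for (dst in c("euclidean", "dtwarp")) {
    for (lk in c("complete", "ward")) {
      tax <- shape_taxonomy(tg$curves, dst, lk, k_range = 2:4)
      cl <- tax$levels[["2"]]$assignment
      expect_equal(adjusted_rand(cl, tg$groups), 1)
    }
  }
})

test_that("characteristic curves are the pointwise means of their members", {
  tg <- two_group_panel(n_per = 8, seed = 3)
  tax <- shape_taxonomy(tg$curves, "euclidean", "ward", k_range = 2:5)
  for (k in 2:5) {
    lev <- tax$levels[[as.character(k)]]
    for (g in seq_len(k)) {
      members <- names(lev$assignment)[lev$assignment == g]
      expect_equal(lev$centroids[g, ],
                   colMeans(tg$curves[members, , drop = FALSE]),
                   ignore_attr = TRUE)
    }
  }
})

test_that("a cut at k = n yields singletons whose centroids are the curves", {
  tg <- two_group_panel(n_per = 3, seed = 4)
  n <- nrow(tg$curves)
  tax <- shape_taxonomy(tg$curves, "euclidean", "complete", k_range = n)
  lev <- tax$levels[[as.character(n)]]
  expect_identical(sort(unname(lev$assignment)), 1:n)
  ord <- order(lev$assignment)
  expect_equal(lev$centroids[lev$assignment[ord], ],
               unname(tg$curves[ord, ]), ignore_attr = TRUE)
})

test_that("identical curves produce a degenerate-merge warning", {
  m <- matrix(rep(c(1, 2, 3, 2), each = 6), 6)
  expect_warning(tax <- shape_taxonomy(m, "euclidean", "ward", k_range = 2:3),
                 "degenerate")
  expect_true(all(tax$height == 0))
})

test_that("cuts larger than the panel are omitted with a warning", {
  tg <- two_group_panel(n_per = 3, seed = 5) # 6 curves
  expect_warning(tax <- shape_taxonomy(tg$curves, k_range = 2:10), "omitting")
  expect_identical(tax$k_range, 2:6)
})

test_that("membership assignment picks the nearest characteristic curve", {
  tg <- two_group_panel(n_per = 10, seed = 6)
  tax <- shape_taxonomy(tg$curves, "euclidean", "ward", k_range = 2:3)
  lev <- tax$levels[["2"]]
  for (g in 1:2)
    expect_identical(assign_membership(lev$centroids[g, ], tax, 2L), g)
  # training curves return to their own (separated) cluster
  pred <- predict(tax, tg$curves, k = 2L)
  expect_identical(unname(pred), unname(lev$assignment))
  # exact tie breaks toward the lower index
  mid <- colMeans(lev$centroids)
  expect_identical(assign_membership(mid, tax, 2L), 1L)
  expect_error(assign_membership(mid[-1], tax, 2L), "length")
})

test_that("membership tables encode one nominal column per sensor and cut", {
  px <- tiny_panels(n_cancer = 8, n_control = 8, n_sensors = 26, T = 30,
                    seed = 33)
  taxonomies <- build_taxonomies(px$panels, distance = "euclidean",
                                 linkage = "ward", k_range = 2:10)
  tab <- membership_feature_table(taxonomies, px$panels, px$labels)
  expect_identical(ncol(tab) - 2L, 234L)
  expect_true(all(vapply(tab[, -(1:2)], is.factor, logical(1))))

  one <- membership_feature_table(taxonomies[1L], px$panels[1L], px$labels)
  k2 <- membership_feature_table(
    build_taxonomies(px$panels[1L], k_range = 2L), px$panels[1L], px$labels)
  expect_identical(ncol(k2) - 2L, 1L)
  expect_true(all(k2[[3L]] %in% c("1", "2")))

  expect_error(membership_feature_table(taxonomies[-1L], px$panels,
                                        px$labels), "missing taxonomy")
})

test_that("held-out rows identical to training rows get identical features", {
  px <- tiny_panels(n_cancer = 8, n_control = 8, n_sensors = 3, seed = 34)
  train_idx <- 1:12
  train_panels <- lapply(px$panels, function(p)
    curve_panel(p$sensor_id, p$curves[train_idx, ], p$measurement_ids[train_idx]))
  taxonomies <- build_taxonomies(train_panels, k_range = 2:5)
  # duplicate a training row under a new id appended to each panel
  dup_panels <- lapply(px$panels, function(p)
    curve_panel(p$sensor_id,
                rbind(p$curves[train_idx, ], p$curves[3L, , drop = FALSE]),
                c(p$measurement_ids[train_idx], "dup")))
  labels <- c(px$labels, dup = unname(px$labels[3L]))
  names(labels)[length(labels)] <- "dup"
  tab <- membership_feature_table(taxonomies, dup_panels, labels)
  orig <- tab[3L, -(1:2)]
  dup <- tab[nrow(tab), -(1:2)]
  expect_equal(unname(unlist(orig)), unname(unlist(dup)))
})

test_that("taxonomy levels are nested across the full cut range", {
  px <- tiny_panels(n_cancer = 10, n_control = 10, n_sensors = 2, seed = 35)
  tax <- shape_taxonomy(px$panels[[1L]], "dtwarp", "complete", k_range = 2:10)
  for (k in 2:9) {
    a <- tax$levels[[as.character(k)]]$assignment
    b <- tax$levels[[as.character(k + 1L)]]$assignment
    tab <- table(b, a)
    expect_true(all(rowSums(tab > 0) == 1L))
    expect_identical(sum(colSums(tab > 0) == 2L), 1L)
  }
})
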