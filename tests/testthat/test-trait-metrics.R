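test_that("community weights exclude the focal and apply the alien rule", {
  nat <- make_plot("p1", c("focal", "A", "B"), c(30, 50, 20),
                   alien = c(FALSE, FALSE, TRUE))
  w <- community_weights(nat, "focal", "native")
  expect_equal(w, c(A = 1.0))
  ali <- make_plot("p2", c("focal", "A", "C"), c(30, 40, 40),
                   alien = c(TRUE, FALSE, FALSE), continent = "ContB")
  expect_equal(community_weights(ali, "focal", "alien"),
               c(A = 0.5, C = 0.5))
  ali2 <- make_plot("p3", c("focal", "A", "D"), c(30, 60, 20),
                    alien = c(TRUE, FALSE, TRUE), continent = "ContB")
  expect_equal(community_weights(ali2, "focal", "alien"), c(A = 1.0))
  # no eligible co-occurring species: flagged as NULL for downstream logging
  lone <- make_plot("p4", c("focal", "D"), c(30, 20),
                    alien = c(TRUE, TRUE), continent = "ContB")
  expect_null(community_weights(lone, "focal", "alien"))
})

test_that("CWM is the abundance-weighted mean of log traits", {
  tr <- traits_from_log(c("A", "B"), ln_sla = c(2, 4), ln_height = c(1, 5))
  one <- cwm_log_traits(c(A = 1), tr)
  expect_equal(unname(one[1:4]), c(2, 1, 2, 2), ignore_attr = TRUE)
  eq <- cwm_log_traits(c(A = 0.5, B = 0.5), tr)
  expect_equal(unname(eq[["sla"]]), 3)
  uneq <- cwm_log_traits(c(A = 0.75, B = 0.25), tr)
  expect_equal(unname(uneq[["height"]]), 2.0)
  # a species missing a trait is dropped with weight renormalisation
  tr$seed_mass_mg[2] <- NA
  dropped <- cwm_log_traits(c(A = 0.25, B = 0.75), tr)
  expect_equal(unname(dropped[["sla"]]), 2)
  expect_equal(attr(dropped, "n_dropped"), 1L)
  tr$seed_mass_mg <- NA
  expect_null(cwm_log_traits(c(A = 0.5, B = 0.5), tr))
})

test_that("Gower dissimilarity matches hand computation, is symmetric and bounded", {
  r1 <- rep(1, 4)
  expect_equal(gower_dissimilarity(rep(0.3, 4), rep(0.3, 4), r1), 0)
  expect_equal(gower_dissimilarity(c(0.2, 0.2, 0.2, 0.2),
                                   c(0.4, 0.1, 0.2, 0.6), r1), 0.175)
  # focal at global max, community at global min on every trait
  r <- c(2, 3, 1, 0.5)
  expect_equal(gower_dissimilarity(r, rep(0, 4), r), 1)
  set.seed(42)
  for (i in 1:20) {
    # points inside the unit box with ranges > 1 keep d within [0, 1]
    f <- runif(4); c <- runif(4); rr <- runif(4, 1.5, 3)
    expect_equal(gower_dissimilarity(f, c, rr), gower_dissimilarity(c, f, rr))
    expect_equal(gower_dissimilarity(f, c, rr), naive_gower(f, c, rr),
                 tolerance = 1e-10)
    # triangle inequality of the underlying Manhattan form
    g <- runif(4)
    expect_lte(gower_dissimilarity(f, c, rr),
               gower_dissimilarity(f, g, rr) + gower_dissimilarity(g, c, rr)
               + 1e-12)
  }
  expect_error(gower_dissimilarity(rep(1, 4), rep(0, 4), c(1, 1, 0, 1)),
               "positive")
})

test_that("Euclidean dissimilarity matches arithmetic", {
  r1 <- rep(1, 4)
  expect_equal(euclidean_dissimilarity(rep(0.2, 4), rep(0.2, 4), r1), 0)
  expect_equal(euclidean_dissimilarity(c(1, 0, 0, 0), rep(0, 4), c(1, 2, 3, 4)), 1)
  expect_equal(euclidean_dissimilarity(c(0.2, 0.1, 0, 0.4), rep(0, 4), r1),
               sqrt(0.21), tolerance = 1e-12)
})

test_that("competitive differences carry the focal-minus-community sign", {
  expect_equal(unname(competitive_differences(rep(1, 4), rep(1, 4))), rep(0, 4))
  d <- competitive_differences(c(1, 3.4, 1, 1), c(1, 2.9, 1, 1))
  expect_equal(unname(d[["d_height"]]), 0.5)
  expect_gt(d[["d_height"]], 0)  # taller than its community
  # translation equivariance: shifting both leaves the difference unchanged
  f <- c(0.3, 1.1, -0.4, 2); cw <- c(0.1, 0.9, 0.2, 1.5)
  expect_equal(competitive_differences(f + 3, cw + 3),
               competitive_differences(f, cw))
})

test_that("trait ranges cover the reference set and reject degenerate traits", {
  tr <- traits_from_log(c("a", "b", "c"), ln_sla = c(1, 2, 5))
  expect_equal(unname(trait_ranges(tr)[["sla"]]), 4)
  expect_error(trait_ranges(tr[1, , drop = FALSE]), "two species")
  same <- traits_from_log(c("a", "b"), ln_sla = c(1, 1), ln_height = c(0, 2))
  expect_error(trait_ranges(same), "degenerate")
  set.seed(7)
  tr6 <- random_traits(letters[1:6])
  r <- trait_ranges(tr6)
  lt <- log_traits(tr6)
  for (t in colnames(lt))
    expect_equal(unname(r[[t]]), max(lt[, t]) - min(lt[, t]), tolerance = 1e-12)
})

test_that("pipeline metrics equal naive per-species loops on small plots", {
  set.seed(13)
  for (rep in 1:15) {
    k <- sample(2:6, 1)
    sp <- c("focal", paste0("co", seq_len(k)))
    tr <- random_traits(sp)
    plot <- make_plot("p", sp, runif(k + 1, 5, 40))
    w <- community_weights(plot, "focal", "native")
    expect_equal(sum(w), 1, tolerance = 1e-12)
    cwm <- cwm_log_traits(w, tr)
    expect_equal(unname(cwm[1:4]), naive_cwm(w, tr), tolerance = 1e-10,
                 ignore_attr = TRUE)
    lt <- log_traits(tr)
    rr <- trait_ranges(tr)
    expect_equal(gower_dissimilarity(lt["focal", ], cwm, rr),
                 naive_gower(lt["focal", ], cwm, rr), tolerance = 1e-10)
    expect_equal(unname(competitive_differences(lt["focal", ], cwm)),
                 as.numeric(lt["focal", ]) - naive_cwm(w, tr),
                 tolerance = 1e-10)
  }
})
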