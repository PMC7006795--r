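test_that("plot filters are inclusive minima, log removals per rule, and are idempotent", {
  ok <- function(id, ...) make_plot(id, c("a", "b", "c"), c(20, 20, 20), ...)
  plots <- rbind(
    ok("p01", tree_layer_cover = 25, area = 100),      # boundary: retained
    ok("p02"), ok("p03"), ok("p04"), ok("p05"), ok("p06"),
    ok("p07", tree_layer_cover = 24),                  # cover violation
    make_plot("p08", c("a", "b"), 30),                 # 2 woody species
    ok("p09", area = 99),                              # area violation
    make_plot("p10", c("a", "b", "c", "h"), 20,
              woody = c(TRUE, TRUE, FALSE, FALSE)))    # richness violation
  f <- filter_plots(plots)
  log <- attr(f, "removal_log")
  expect_setequal(unique(f$plot_id), sprintf("p%02d", 1:6))
  expect_equal(nrow(log), 4L)
  expect_equal(sort(log$plot_id), c("p07", "p08", "p09", "p10"))
  expect_equal(log$rule[log$plot_id == "p08"], "woody_richness")
  # idempotent: a second pass removes nothing
  f2 <- filter_plots(f)
  strip <- function(d) { attr(d, "removal_log") <- NULL; d }
  expect_equal(strip(f2), strip(f))
  expect_equal(nrow(attr(f2, "removal_log")), 0L)
  # missing metadata is a validation error naming the plot
  bad <- ok("pX"); bad$area_m2 <- NA
  expect_error(filter_plots(rbind(plots, bad)), "pX")
})

test_that("relative abundance is the focal share of woody cover only", {
  p <- make_plot("p1", c("focal", "A", "B"), c(30, 50, 20))
  expect_equal(relative_abundance(p, "focal"), 0.30)
  # non-woody cover is excluded from the denominator: 30 / (30 + 50)
  p2 <- make_plot("p1", c("focal", "A", "herb"), c(30, 50, 400),
                  woody = c(TRUE, TRUE, FALSE))
  expect_equal(relative_abundance(p2, "focal"), 0.375)
  # sole woody species
  expect_equal(relative_abundance(p2[-2, ], "focal"), 30 / 30)
  # invariant to uniform cover rescaling; shares sum to 1
  p3 <- p; p3$cover <- p3$cover * 7.3
  expect_equal(relative_abundance(p3, "focal"), 0.30)
  shares <- vapply(c("focal", "A", "B"), function(s)
    relative_abundance(p, s), numeric(1))
  expect_equal(sum(shares), 1, tolerance = 1e-12)
  expect_error(relative_abundance(p, "absent"), "absent")
  expect_error(relative_abundance(p2, "herb"), "non-woody")
})

test_that("woody richness counts distinct woody species with positive cover", {
  p <- make_plot("p1", c("a", "b", "c", "h1", "h2"), 10,
                 woody = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(woody_richness(p)), 3L)
  # a species recorded in two layers counts once (cover pooled on read)
  lay <- read_veg_plots(rbind(p, make_plot("p1", "a", 5)))
  expect_equal(unname(woody_richness(lay)), 3L)
  expect_equal(lay$cover[lay$species_id == "a"], 15)
  herbs <- make_plot("p2", c("h1", "h2"), 10, woody = FALSE)
  expect_equal(unname(woody_richness(herbs)), 0L)
})

test_that("alien plots on a focal species' native continent are excluded", {
  nat <- make_plot("n1", c("focal", "x", "y"), 20, continent = "Eurasia")
  # alien occurrence on the native continent -> plot excluded
  a_same <- make_plot("a1", c("focal", "x", "y"), 20, continent = "Eurasia",
                      alien = c(TRUE, FALSE, FALSE))
  a_same2 <- make_plot("a2", c("focal", "z", "y"), 20, continent = "Eurasia",
                       alien = c(TRUE, FALSE, FALSE))
  a_other <- make_plot("a3", c("focal", "x", "y"), 20, continent = "Americas",
                       alien = c(TRUE, FALSE, FALSE))
  other <- make_plot("n2", c("x", "y", "z"), 20, continent = "Eurasia")
  plots <- rbind(nat, a_same, a_same2, a_other, other)
  kept <- exclude_same_continent_aliens(plots, "focal", "Eurasia")
  expect_setequal(unique(kept$plot_id), c("n1", "a3", "n2"))
  # focal native to the Americas, alien in Eurasia: the intended
  # cross-continent comparison, retained
  kept2 <- exclude_same_continent_aliens(a_same, "focal", "Americas")
  expect_equal(unique(kept2$plot_id), "a1")
  bad <- nat; bad$continent <- NA
  expect_error(exclude_same_continent_aliens(bad, "focal", "Eurasia"),
               "continent")
})

test_that("focal species need at least three plots in each range", {
  mk <- function(sp, n_nat, n_ali) {
    plots <- list()
    for (i in seq_len(n_nat))
      plots[[length(plots) + 1L]] <-
        make_plot(paste0(sp, "n", i), c(sp, "f1", "f2"), 20)
    for (i in seq_len(n_ali))
      plots[[length(plots) + 1L]] <-
        make_plot(paste0(sp, "a", i), c(sp, "f1", "f2"), 20,
                  alien = c(TRUE, FALSE, FALSE), continent = "ContB")
    do.call(rbind, plots)
  }
  # 8 candidates; exactly 5 meet the 3 + 3 rule
  counts <- list(s1 = c(3, 3), s2 = c(10, 2), s3 = c(5, 3), s4 = c(2, 8),
                 s5 = c(4, 4), s6 = c(3, 5), s7 = c(0, 6), s8 = c(7, 3))
  plots <- do.call(rbind, lapply(names(counts), function(s)
    mk(s, counts[[s]][1], counts[[s]][2])))
  keep <- select_focal_species(plots, names(counts))
  expect_setequal(keep, c("s1", "s3", "s5", "s6", "s8"))
  rc <- attr(keep, "range_counts")
  expect_equal(rc$n_native[rc$species_id == "s2"], 10L)
  expect_equal(rc$n_alien[rc$species_id == "s2"], 2L)
})
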