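test_that("anhydrous recipes give mole fractions proportional to parts", {
  r <- des_recipe("dry", list(toy_constituent("a", 100, rep(1, 10)),
                              toy_constituent("b", 50, rep(2, 10))),
                  c(1, 3), water_wt_percent = 0)
  comp <- mole_fractions_from_recipe(r)
  expect_equal(unname(comp$X), c(0.25, 0.75, 0))
  expect_equal(sum(comp$X), 1, tolerance = 1e-12)
})

test_that("symmetric molar masses at 50 wt% water give X = (1/4, 1/4, 1/2)", {
  r <- des_recipe("sym", list(toy_constituent("a", 18.015, rep(1, 10)),
                              toy_constituent("b", 18.015, rep(1, 10))),
                  c(1, 1), water_wt_percent = 50)
  comp <- mole_fractions_from_recipe(r)
  expect_equal(unname(comp$X), c(0.25, 0.25, 0.5))
})

test_that("hydrated ChCl:Gly composition matches an independent mass balance", {
  r <- des_recipe("ChCl:Gly 1:2 + 30%",
                  list(constituent("choline chloride", "HBA",
                                   descriptors = toy_descriptors(rep(1, 10))),
                       constituent("glycerol", "HBD",
                                   descriptors = toy_descriptors(rep(1, 10)))),
                  c(1, 2), water_wt_percent = 30)
  comp <- mole_fractions_from_recipe(r)

  # independent route: a 100 g basis, masses first, then moles
  m_total <- 100
  m_water <- 30
  m_des <- 70
  f_chcl <- 139.62 / (139.62 + 2 * 92.09)   # mass share of ChCl in the DES
  n_chcl <- m_des * f_chcl / 139.62
  n_gly <- m_des * (1 - f_chcl) / 92.09
  n_wat <- m_water / 18.015
  expect_equal(unname(comp$X),
               c(n_chcl, n_gly, n_wat) / (n_chcl + n_gly + n_wat),
               tolerance = 1e-12)
  # moles of glycerol are exactly twice those of choline chloride
  expect_equal(comp$X[[2]] / comp$X[[1]], 2, tolerance = 1e-12)
})

test_that("mole fractions are invariant to scaling all molar parts", {
  cons <- list(toy_constituent("a", 80, rep(1, 10)),
               toy_constituent("b", 120, rep(1, 10)))
  c1 <- mole_fractions_from_recipe(des_recipe("x", cons, c(1, 2), 30))
  c2 <- mole_fractions_from_recipe(des_recipe("x", cons, c(7, 14), 30))
  expect_equal(c1$X, c2$X, tolerance = 1e-12)
})

test_that("invalid recipes are rejected", {
  cons <- list(toy_constituent("a", 80, rep(1, 10)))
  expect_error(des_recipe("x", cons, 1, 100), "water_wt_percent")
  expect_error(des_recipe("x", cons, c(1, 2), 10), "length")
  expect_error(des_recipe("x", cons, -1, 10), "positive")
  expect_error(constituent("mystery", "HBD"), "molar mass")
})

test_that("descriptor mixing is the mole-fraction-weighted sum", {
  a <- toy_constituent("a", 60, c(1, 0, 2, 0, 3, 0, 4, 0, 5, 0))
  b <- toy_constituent("b", 90, c(0, 2, 0, 4, 0, 6, 0, 8, 0, 10))
  w <- constituent("water", "water", descriptors = toy_descriptors(rep(1, 10)))

  # single constituent, X = 1: identity
  comp1 <- mole_fractions_from_recipe(des_recipe("one", list(a), 1, 0))
  m1 <- mix_descriptors(comp1, list(a, w))
  expect_identical(unname(m1$S), unname(a$descriptors$S))

  # identical descriptor vectors: convexity fixed point
  a2 <- toy_constituent("a2", 70, c(1, 0, 2, 0, 3, 0, 4, 0, 5, 0))
  comp2 <- mole_fractions_from_recipe(des_recipe("two", list(a, a2), c(1, 3), 0))
  m2 <- mix_descriptors(comp2, list(a, a2, w))
  expect_equal(unname(m2$S), unname(a$descriptors$S), tolerance = 1e-15)

  # hand-computed weighted sum at X = (0.2, 0.3, 0.5)
  cc <- toy_constituent("c", 50, rep(2, 10))
  comp3 <- structure(list(X = c(0.2, 0.3, 0.5), NC = 3L, label = "hand"),
                     class = "mixture_composition")
  m3 <- mix_descriptors(comp3, list(a, b, cc))
  expect_equal(unname(m3$S),
               0.2 * c(1, 0, 2, 0, 3, 0, 4, 0, 5, 0) +
               0.3 * c(0, 2, 0, 4, 0, 6, 0, 8, 0, 10) + 0.5 * rep(2, 10))
  expect_error(mix_descriptors(comp3, list(a, b)), "match")
})

test_that("mixing is linear in the composition", {
  set.seed(9)
  cons <- lapply(1:3, function(i)
    toy_constituent(paste0("c", i), 50 + 20 * i, runif(10, 0, 5)))
  mk <- function(X) structure(list(X = X, NC = 3L, label = "l"),
                              class = "mixture_composition")
  X1 <- c(0.5, 0.3, 0.2); X2 <- c(0.1, 0.2, 0.7); al <- 0.35
  blend <- mix_descriptors(mk(al * X1 + (1 - al) * X2), cons)
  parts <- al * mix_descriptors(mk(X1), cons)$S +
    (1 - al) * mix_descriptors(mk(X2), cons)$S
  expect_equal(blend$S, parts, tolerance = 1e-15)

  # total mixture area is the weighted total area
  expect_equal(sum(mix_descriptors(mk(X1), cons)$S),
               sum(vapply(seq_along(cons), function(j)
                 X1[j] * sum(cons[[j]]$descriptors$S), numeric(1))),
               tolerance = 1e-12)
})

test_that("library enumeration drops solids and labels by system and level", {
  lib <- des_library_screening()
  expect_length(lib$recipes, 28)
  labels <- vapply(lib$recipes, function(r) r$label, character(1))
  expect_true(all(c("DES 1.1", "DES 4.3", "DES 10.3") %in% labels))
  expect_false(any(c("DES 4.1", "DES 4.2") %in% labels))
  # DES s.2 is always the 30 wt% member
  w <- vapply(lib$recipes, function(r) r$water_wt_percent, numeric(1))
  expect_true(all(w[grepl("\\.2$", labels)] == 30))

  one <- enumerate_library(list(des_system(1, list(toy_constituent("a", 70, rep(1, 10))), 1)),
                           water_levels = 30)
  expect_length(one, 1)
})

test_that("enumeration count equals a brute-force filter for random solid flags", {
  set.seed(31)
  cons <- list(toy_constituent("a", 70, rep(1, 10)))
  levels <- c(10, 30, 50)
  for (rep_i in 1:20) {
    n_sys <- sample(3:10, 1)
    solid <- matrix(runif(n_sys * 3) < 0.25, n_sys, 3)
    systems <- lapply(seq_len(n_sys), function(i)
      des_system(i, cons, 1, solid_at = levels[solid[i, ]]))
    lib <- enumerate_library(systems, levels)
    expect_length(lib, sum(!solid))
  }
})
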